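## Structured-coalescent simulation engine.
##
## Genealogies are simulated backward in time for haploid lineages
## distributed over populations, under a demography made of population
## splits (lineage relabelling) and mass-migration pulses (each lineage in
## the recipient moves to the donor independently with probability f).
## Loci are independent and non-recombining; recombination between loci is
## free. Mutations are dropped on branches under an infinite-sites model
## restricted to the locus length.

#' Define a demography for the coalescent simulator
#'
#' @param pops character vector of all population labels, including
#'   ancestral branches.
#' @param Ne named numeric vector of diploid effective sizes, one per
#'   label in `pops`.
#' @param events data.frame with columns `time` (generations, backward
#'   from 0), `type` (`"split"` or `"pulse"`), `from`, `to` and
#'   `fraction` (used by pulses only). A split moves all lineages of
#'   `from` into `to`; a pulse moves each lineage of `from` into `to`
#'   independently with probability `fraction`.
#' @return an object of class `demography`.
#' @export
demography <- function(pops, Ne, events) {
  if (length(Ne) == 1L) Ne <- stats::setNames(rep(Ne, length(pops)), pops)
  stopifnot(all(pops %in% names(Ne)), all(Ne > 0))
  events <- events[order(events$time), , drop = FALSE]
  stopifnot(all(events$from %in% pops), all(events$to %in% pops))
  if (any(events$type == "pulse")) {
    p <- events[events$type == "pulse", , drop = FALSE]
    stopifnot(all(p$fraction >= 0), all(p$fraction <= 1))
    if (any(p$from == p$to))
      stop("pulse donor and recipient must differ")
  }
  structure(list(pops = pops, Ne = Ne[pops], events = events),
            class = "demography")
}

## One genealogy for `n_lin` haploid lineages starting in populations
## `lin_pop` (integer index into dem$pops). Returns parent pointers, node
## times, and the number of lineages moved by each pulse event.
sim_tree <- function(n_lin, lin_pop, dem) {
  npop <- length(dem$pops)
  Ne <- unname(dem$Ne)
  ev <- dem$events
  n_nodes <- 2L * n_lin - 1L
  parent <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  active <- seq_len(n_lin)
  active_pop <- lin_pop
  t <- 0
  nxt <- n_lin + 1L
  ei <- 1L
  n_ev <- nrow(ev)
  pulse_moved <- integer(n_ev)
  while (length(active) > 1L) {
    k <- tabulate(active_pop, nbins = npop)
    rates <- k * (k - 1) / 2 / (2 * Ne)
    total <- sum(rates)
    t_ev <- if (ei <= n_ev) ev$time[ei] else Inf
    w <- if (total > 0) stats::rexp(1L, total) else Inf
    if (t + w < t_ev) {
      t <- t + w
      p <- sample.int(npop, 1L, prob = rates)
      in_p <- which(active_pop == p)
      pair <- if (length(in_p) == 2L) in_p else sample(in_p, 2L)
      a <- active[pair[1]]; b <- active[pair[2]]
      parent[a] <- nxt
      parent[b] <- nxt
      node_time[nxt] <- t
      active <- c(active[-pair], nxt)
      active_pop <- c(active_pop[-pair], p)
      nxt <- nxt + 1L
    } else {
      if (!is.finite(t_ev))
        stop("lineages cannot coalesce: demography has no common root")
      t <- t_ev
      from <- match(ev$from[ei], dem$pops)
      to <- match(ev$to[ei], dem$pops)
      if (ev$type[ei] == "split") {
        active_pop[active_pop == from] <- to
      } else {
        idx <- which(active_pop == from)
        if (length(idx)) {
          mv <- idx[stats::runif(length(idx)) < ev$fraction[ei]]
          active_pop[mv] <- to
          pulse_moved[ei] <- length(mv)
        }
      }
      ei <- ei + 1L
    }
  }
  list(parent = parent, time = node_time, root = active[1],
       n_leaves = n_lin, pulse_moved = pulse_moved)
}

## Leaf sets below every node, bottom-up.
leaf_sets <- function(tree) {
  n <- length(tree$parent)
  sets <- vector("list", n)
  for (i in seq_len(tree$n_leaves)) sets[[i]] <- i
  ord <- order(tree$time[(tree$n_leaves + 1L):n]) + tree$n_leaves
  kids <- split(seq_len(n)[tree$parent > 0L], tree$parent[tree$parent > 0L])
  for (v in ord) {
    ch <- kids[[as.character(v)]]
    sets[[v]] <- c(sets[[ch[1]]], sets[[ch[2]]])
  }
  sets
}

## Drop infinite-sites mutations on one genealogy. Returns a list with
## integer positions (1..locus_len, unique, sorted) and a logical
## carriers matrix (mutations x leaves).
sim_mutations <- function(tree, mu, locus_len) {
  n <- length(tree$parent)
  has_parent <- which(tree$parent > 0L)
  blen <- tree$time[tree$parent[has_parent]] - tree$time[has_parent]
  nmut <- stats::rpois(length(blen), mu * locus_len * blen)
  M <- sum(nmut)
  if (M == 0L)
    return(list(pos = integer(0),
                carriers = matrix(FALSE, 0, tree$n_leaves)))
  M <- min(M, locus_len)  # infinite-sites capped by locus length
  node_of_mut <- rep(has_parent, nmut)[seq_len(M)]
  pos <- sort(sample.int(locus_len, M))
  ## random order of mutations over positions
  node_of_mut <- node_of_mut[sample.int(M)]
  sets <- leaf_sets(tree)
  carriers <- matrix(FALSE, M, tree$n_leaves)
  for (m in seq_len(M)) carriers[m, sets[[node_of_mut[m]]]] <- TRUE
  list(pos = pos, carriers = carriers)
}

NUCS <- c("A", "C", "G", "T")

#' Simulation configuration for multi-population SNP data
#'
#' Builds the standard four-taxon design used throughout the package:
#' sister populations `P1` and `P2`, donor `P3`, outgroup `OUT`, with an
#' optional single admixture pulse. Split times follow the ladder
#' `T12 < T123 < Troot` (generations). The simulator works on independent
#' non-recombining loci of `locus_len` bp with free recombination between
#' loci.
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param samples_per_pop diploid samples per population (default 2).
#' @param Ne diploid effective size, scalar or named per branch label
#'   (`P1`, `P2`, `P3`, `OUT`, `A12`, `A123`, `ROOT`).
#' @param mu per-site per-generation mutation rate.
#' @param seq_len total sequence length in bp.
#' @param locus_len length of one independent locus in bp.
#' @param split_times named numeric vector `c(T12=, T123=, Troot=)`.
#' @param pulse `NULL`, or `list(donor=, recipient=, time=, f=)` with
#'   `time` younger than the donor/recipient divergence.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, samples_per_pop = 2L, Ne = 10000,
                       mu = 1e-8, seq_len = 5e6, locus_len = 1e4,
                       split_times = c(T12 = 1e4, T123 = 4e4, Troot = 1e5),
                       pulse = list(donor = "P3", recipient = "P2",
                                    time = 5e3, f = 0)) {
  stopifnot(split_times[["T12"]] < split_times[["T123"]],
            split_times[["T123"]] < split_times[["Troot"]])
  pops <- c("P1", "P2", "P3", "OUT", "A12", "A123", "ROOT")
  events <- data.frame(
    time = c(split_times[["T12"]], split_times[["T12"]],
             split_times[["T123"]], split_times[["T123"]],
             split_times[["Troot"]], split_times[["Troot"]]),
    type = "split",
    from = c("P1", "P2", "A12", "P3", "A123", "OUT"),
    to = c("A12", "A12", "A123", "A123", "ROOT", "ROOT"),
    fraction = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(pulse) && pulse$f > 0) {
    if (pulse$donor == pulse$recipient)
      stop("pulse donor and recipient must differ")
    if (pulse$time >= split_times[["T123"]])
      stop("pulse must be younger than the donor/recipient divergence")
    events <- rbind(events, data.frame(
      time = pulse$time, type = "pulse", from = pulse$recipient,
      to = pulse$donor, fraction = pulse$f, stringsAsFactors = FALSE))
  }
  dem <- demography(pops, Ne, events)
  structure(list(seed = as.integer(seed),
                 sampled_pops = c("P1", "P2", "P3", "OUT"),
                 samples_per_pop = as.integer(samples_per_pop),
                 dem = dem, mu = mu, seq_len = seq_len,
                 locus_len = locus_len,
                 f = if (is.null(pulse)) 0 else pulse$f,
                 pulse = pulse),
            class = "sim_config")
}

#' Simulation configuration with two recipient populations
#'
#' Five-taxon design for landscape-comparison experiments: a control
#' lineage `P1`, two recipients `P2a` and `P2b`, a donor `P3` and an
#' outgroup `OUT`, with topology `(((P1,(P2a,P2b)),P3),OUT)`. The pulse
#' can be placed either in the recipients' common ancestor (`shared`,
#' between `T2ab` and `T12`) or independently into each recipient
#' (`independent`, younger than `T2ab`).
#'
#' The recipient-ancestor branch has its own effective size `Ne_anc`:
#' a smaller value lets lineages from the two recipients coalesce before
#' the pulse, so introgressed ancestry is shared between them — the
#' scenario in which two descendant lineages are expected to show highly
#' correlated introgression landscapes.
#'
#' @inheritParams sim_config
#' @param Ne_anc diploid size of the recipients' common-ancestor branch.
#' @param split_times named vector `c(T2ab=, T12=, T123=, Troot=)`.
#' @param pulse_mode `"shared"`, `"independent"` or `"none"`.
#' @param pulse_time time of the pulse(s), generations.
#' @param f admixture fraction of the pulse(s).
#' @return an object of class `sim_config`.
#' @export
sim_config_two_recipients <- function(seed = 1L, samples_per_pop = 2L,
                                      Ne = 10000, Ne_anc = 5000,
                                      mu = 4e-8, seq_len = 5e6,
                                      locus_len = 1e4,
                                      split_times = c(T2ab = 2e3, T12 = 2.5e4,
                                                      T123 = 4e4, Troot = 1e5),
                                      pulse_mode = c("shared", "independent",
                                                     "none"),
                                      pulse_time = NULL, f = 0.1) {
  pulse_mode <- match.arg(pulse_mode)
  stopifnot(split_times[["T2ab"]] < split_times[["T12"]],
            split_times[["T12"]] < split_times[["T123"]],
            split_times[["T123"]] < split_times[["Troot"]])
  pops <- c("P1", "P2a", "P2b", "P3", "OUT", "A2", "A12", "A123", "ROOT")
  if (length(Ne) == 1L) {
    Ne <- stats::setNames(rep(Ne, length(pops)), pops)
    Ne[["A2"]] <- Ne_anc
  }
  events <- data.frame(
    time = c(rep(split_times[["T2ab"]], 2), rep(split_times[["T12"]], 2),
             rep(split_times[["T123"]], 2), rep(split_times[["Troot"]], 2)),
    type = "split",
    from = c("P2a", "P2b", "P1", "A2", "A12", "P3", "A123", "OUT"),
    to = c("A2", "A2", "A12", "A12", "A123", "A123", "ROOT", "ROOT"),
    fraction = NA_real_, stringsAsFactors = FALSE)
  if (pulse_mode == "shared") {
    if (is.null(pulse_time)) pulse_time <- split_times[["T12"]] * 0.8
    stopifnot(pulse_time > split_times[["T2ab"]],
              pulse_time < split_times[["T12"]])
    events <- rbind(events, data.frame(
      time = pulse_time, type = "pulse", from = "A2", to = "P3",
      fraction = f, stringsAsFactors = FALSE))
  } else if (pulse_mode == "independent") {
    if (is.null(pulse_time)) pulse_time <- split_times[["T2ab"]] * 0.5
    stopifnot(pulse_time < split_times[["T2ab"]])
    events <- rbind(events, data.frame(
      time = pulse_time, type = "pulse",
      from = c("P2a", "P2b"), to = "P3",
      fraction = f, stringsAsFactors = FALSE))
  }
  dem <- demography(pops, Ne, events)
  structure(list(seed = as.integer(seed),
                 sampled_pops = c("P1", "P2a", "P2b", "P3", "OUT"),
                 samples_per_pop = as.integer(samples_per_pop),
                 dem = dem, mu = mu, seq_len = seq_len,
                 locus_len = locus_len,
                 f = if (pulse_mode == "none") 0 else f,
                 pulse = list(mode = pulse_mode, time = pulse_time, f = f)),
            class = "sim_config")
}

#' Simulate multi-population diploid SNP data
#'
#' Runs the structured coalescent of the configured demography over
#' independent loci tiling `seq_len`, drops infinite-sites mutations, and
#' assembles diploid genotypes (consecutive pairs of haploid lineages form
#' one diploid sample). Reference/alternate labels are assigned at random
#' (the ancestral allele is the reference for roughly half the sites), so
#' downstream analyses must polarize against the outgroup as they would on
#' real data.
#'
#' @param cfg a [sim_config()] or [sim_config_two_recipients()].
#' @return a list with `gm` (a [genotype_matrix()]), `pm` (a
#'   [population_map()] with roles `P1`, `P2`, `P3`, `OUT` when those
#'   populations exist), and `truth` (list: `f_true`, `pulse`, and
#'   `loci`, a data.frame with one row per locus giving its coordinates
#'   and the number of lineages moved by each pulse).
#' @export
simulate_snp_data <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pops <- cfg$sampled_pops
  n_dip <- length(pops) * cfg$samples_per_pop
  n_lin <- 2L * n_dip
  sample_pop <- rep(pops, each = cfg$samples_per_pop)
  samples <- paste0(sample_pop, "_", sequence(rep(cfg$samples_per_pop,
                                                  length(pops))))
  lin_pop <- match(rep(sample_pop, each = 2L), cfg$dem$pops)

  n_loci <- max(1L, floor(cfg$seq_len / cfg$locus_len))
  locus_len <- as.integer(cfg$locus_len)
  chrom_list <- list(); pos_list <- list(); G_list <- list()
  ref_list <- list(); alt_list <- list()
  n_pulses <- sum(cfg$dem$events$type == "pulse")
  moved <- matrix(0L, n_loci, max(1L, n_pulses))
  for (l in seq_len(n_loci)) {
    tr <- sim_tree(n_lin, lin_pop, cfg$dem)
    if (n_pulses > 0)
      moved[l, ] <- tr$pulse_moved[cfg$dem$events$type == "pulse"]
    mut <- sim_mutations(tr, cfg$mu, locus_len)
    M <- length(mut$pos)
    if (M == 0L) next
    ## diploid dosages of the derived allele
    dos <- mut$carriers[, seq(1, n_lin, by = 2), drop = FALSE] +
      mut$carriers[, seq(2, n_lin, by = 2), drop = FALSE]
    storage.mode(dos) <- "integer"
    anc <- sample(NUCS, M, replace = TRUE)
    der <- vapply(anc, function(a) sample(setdiff(NUCS, a), 1L), "")
    flip <- stats::runif(M) < 0.5   # is the derived allele the reference?
    ref <- ifelse(flip, der, anc)
    alt <- ifelse(flip, anc, der)
    dos[flip, ] <- 2L - dos[flip, , drop = FALSE]
    chrom_list[[l]] <- rep("chr1", M)
    pos_list[[l]] <- (l - 1L) * locus_len + mut$pos
    ref_list[[l]] <- ref
    alt_list[[l]] <- alt
    G_list[[l]] <- dos
  }
  if (length(pos_list)) {
    gm <- genotype_matrix(unlist(chrom_list), unlist(pos_list),
                          unlist(ref_list), unlist(alt_list),
                          do.call(rbind, G_list), samples)
  } else {
    gm <- genotype_matrix(character(0), integer(0), character(0),
                          character(0), matrix(integer(0), 0, n_dip),
                          samples)
  }
  roles <- NULL
  if (all(c("P1", "P2", "P3", "OUT") %in% pops))
    roles <- c(P1 = "P1", P2 = "P2", P3 = "P3", OUT = "OUT")
  else if (all(c("P1", "P2a", "P2b", "P3", "OUT") %in% pops))
    roles <- c(P1 = "P1", P2 = "P2a", P3 = "P3", OUT = "OUT")
  pm <- population_map(stats::setNames(sample_pop, samples), roles)
  loci <- data.frame(chrom = "chr1",
                     start = (seq_len(n_loci) - 1L) * locus_len,
                     end = seq_len(n_loci) * locus_len)
  if (n_pulses > 0) loci$n_moved <- moved[, 1]
  list(gm = gm, pm = pm,
       truth = list(f_true = cfg$f, pulse = cfg$pulse, loci = loci))
}
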
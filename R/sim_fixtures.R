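#' Simulate a single diploid chromosome with planted autozygous tracts
#'
#' SNPs are scattered uniformly at the requested density. Outside the
#' planted tracts each SNP is heterozygous with probability `het_rate`;
#' inside a tract SNPs are homozygous, except for an optional residual
#' per-SNP error het rate (mimicking genotyping error inside a run of
#' homozygosity).
#'
#' @param seed integer seed.
#' @param chrom_len chromosome length in bp.
#' @param snp_density expected SNPs per bp (e.g. `1/500`).
#' @param het_rate per-SNP heterozygosity outside tracts.
#' @param tracts data.frame with columns `start`, `end` (0-based
#'   half-open, non-overlapping, within the chromosome); may have zero
#'   rows.
#' @param tract_het_rate residual per-SNP het rate inside tracts
#'   (default 0).
#' @param sample_id sample name (default `"S1"`).
#' @return list with `gm` (single-sample [genotype_matrix()]) and
#'   `truth` (list with the planted `tracts`).
#' @export
simulate_roh_genome <- function(seed, chrom_len = 5e6, snp_density = 1 / 500,
                                het_rate = 0.3,
                                tracts = data.frame(start = numeric(0),
                                                    end = numeric(0)),
                                tract_het_rate = 0, sample_id = "S1") {
  stopifnot(chrom_len > 0, snp_density > 0)
  if (nrow(tracts)) {
    tracts <- tracts[order(tracts$start), , drop = FALSE]
    stopifnot(all(tracts$start < tracts$end),
              all(tracts$start >= 0), all(tracts$end <= chrom_len))
    if (nrow(tracts) > 1 &&
        any(tracts$start[-1] < tracts$end[-nrow(tracts)]))
      stop("tracts must be non-overlapping")
  }
  set.seed(seed)
  n <- stats::rpois(1L, chrom_len * snp_density)
  n <- min(n, chrom_len)
  pos <- sort(sample.int(chrom_len, n))
  in_tract <- rep(FALSE, n)
  for (i in seq_len(nrow(tracts)))
    in_tract <- in_tract | (pos > tracts$start[i] & pos <= tracts$end[i])
  p_het <- ifelse(in_tract, tract_het_rate, het_rate)
  is_het <- stats::runif(n) < p_het
  dos <- ifelse(is_het, 1L, ifelse(stats::runif(n) < 0.5, 0L, 2L))
  ref <- sample(NUCS, n, replace = TRUE)
  alt <- vapply(ref, function(a) sample(setdiff(NUCS, a), 1L), "")
  gm <- genotype_matrix(rep("chr1", n), pos, ref, alt,
                        matrix(as.integer(dos), ncol = 1), sample_id)
  list(gm = gm, truth = list(tracts = tracts, chrom_len = chrom_len))
}

IMPACT_CATEGORIES <- c("synonymous", "moderate", "high")

#' Simulate a per-site functional-impact table
#'
#' Labels each alternate allele of a genotype matrix with an impact
#' category (`synonymous`, `moderate`, `high`) at the stated rates, or
#' leaves it unlabelled. Records generator-side truth: the per-sample
#' derived-allele count in each category, computed on outgroup-polarized
#' dosages when a population map with an `OUT` role is supplied, else on
#' alternate-allele dosages.
#'
#' @param seed integer seed.
#' @param gm a [genotype_matrix()].
#' @param rates named numeric vector over
#'   `c("synonymous","moderate","high")`, summing to at most 1.
#' @param pm optional [population_map()] with an `OUT` role used to
#'   polarize derived alleles for the truth counts.
#' @return list with `impacts` (data.frame `chrom`, `pos`, `alt`,
#'   `category` for labelled sites) and `truth` (per-sample matrix of
#'   derived-allele counts by category).
#' @export
simulate_impact_table <- function(seed, gm,
                                  rates = c(synonymous = 0.5,
                                            moderate = 0.3, high = 0.2),
                                  pm = NULL) {
  stopifnot(all(names(rates) %in% IMPACT_CATEGORIES),
            sum(rates) <= 1 + 1e-12, all(rates >= 0))
  rates <- rates[IMPACT_CATEGORIES]
  rates[is.na(rates)] <- 0
  names(rates) <- IMPACT_CATEGORIES
  set.seed(seed)
  L <- n_sites(gm)
  category <- sample(c(IMPACT_CATEGORIES, "none"), L, replace = TRUE,
                     prob = c(rates, 1 - sum(rates)))
  impacts <- data.frame(chrom = gm$chrom, pos = gm$pos, alt = gm$alt,
                        category = category,
                        stringsAsFactors = FALSE)[category != "none", ]
  rownames(impacts) <- NULL

  if (!is.null(pm)) {
    der <- polarize_derived(gm, pm)
    D <- der$derived
    site_idx <- der$site_index
  } else {
    D <- gm$G
    site_idx <- seq_len(L)
  }
  cat_of_site <- category[site_idx]
  truth <- vapply(IMPACT_CATEGORIES, function(cc) {
    rows <- which(cat_of_site == cc)
    if (!length(rows)) return(stats::setNames(rep(0, n_samples(gm)),
                                              gm$samples))
    colSums(D[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(n_samples(gm)))
  truth <- matrix(truth, nrow = n_samples(gm),
                  dimnames = list(gm$samples, IMPACT_CATEGORIES))
  list(impacts = impacts, truth = truth)
}

AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

codon_for_aa <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  vapply(aa, function(a) names(gc)[gc == a][1], "")
}

#' Simulate per-gene codon alignments with planted convergent columns
#'
#' Generates in-frame codon alignments for a set of samples partitioned
#' into two focal groups and a background group. At each planted column,
#' every focal sequence (both groups) carries the planted amino acid and
#' every background sequence the ancestral one — the signature of a
#' fixed, private, shared substitution. Optional non-convergent noise
#' columns, internal stop codons and missing stretches exercise the
#' translation filters.
#'
#' @param seed integer seed.
#' @param n_genes,n_codons number of genes and codons per gene.
#' @param groups named list of character vectors: `focalA`, `focalB`,
#'   `background` sample ids.
#' @param planted data.frame with columns `gene` (1-based index),
#'   `column` (1-based AA column) and `aa` (single-letter amino acid);
#'   zero rows plants nothing.
#' @param noise_columns number of extra columns per gene where one
#'   random background sample carries a different (non-convergent)
#'   amino acid.
#' @param stops optional data.frame `gene`, `sample`, `codon`: plant an
#'   internal stop codon (TAA).
#' @param missing optional data.frame `gene`, `sample`, `frac`: replace
#'   a fraction of codons with `NNN`.
#' @return list with `alignments` (list gene name -> named character
#'   vector of codon sequences) and `truth` (the planted table, with
#'   gene names).
#' @export
simulate_codon_alignments <- function(seed, n_genes, n_codons, groups,
                                      planted = data.frame(gene = integer(0),
                                                           column = integer(0),
                                                           aa = character(0)),
                                      noise_columns = 0, stops = NULL,
                                      missing = NULL) {
  stopifnot(all(c("focalA", "focalB", "background") %in% names(groups)))
  if (nrow(planted) && any(planted$column > n_codons))
    stop("planted column beyond n_codons")
  set.seed(seed)
  samples <- unlist(groups, use.names = FALSE)
  focal <- c(groups$focalA, groups$focalB)
  genes <- sprintf("gene%03d", seq_len(n_genes))
  alignments <- vector("list", n_genes)
  names(alignments) <- genes
  for (g in seq_len(n_genes)) {
    anc_aa <- sample(AA_ALPHABET20, n_codons, replace = TRUE)
    pl <- planted[planted$gene == g, , drop = FALSE]
    if (nrow(pl) && any(pl$aa == anc_aa[pl$column]))
      anc_aa[pl$column[pl$aa == anc_aa[pl$column]]] <-
        vapply(pl$aa[pl$aa == anc_aa[pl$column]],
               function(a) sample(setdiff(AA_ALPHABET20, a), 1L), "")
    anc_codons <- codon_for_aa(anc_aa)
    mat <- matrix(rep(anc_codons, length(samples)), nrow = length(samples),
                  byrow = TRUE, dimnames = list(samples, NULL))
    for (i in seq_len(nrow(pl)))
      mat[focal, pl$column[i]] <- codon_for_aa(pl$aa[i])
    if (noise_columns > 0) {
      free <- setdiff(seq_len(n_codons), pl$column)
      ncols <- min(noise_columns, length(free))
      cols <- sample(free, ncols)
      for (cl in cols) {
        s <- sample(groups$background, 1L)
        mat[s, cl] <- codon_for_aa(sample(setdiff(AA_ALPHABET20,
                                                  anc_aa[cl]), 1L))
      }
    }
    if (!is.null(stops)) {
      st <- stops[stops$gene == g, , drop = FALSE]
      for (i in seq_len(nrow(st))) mat[st$sample[i], st$codon[i]] <- "TAA"
    }
    if (!is.null(missing)) {
      ms <- missing[missing$gene == g, , drop = FALSE]
      for (i in seq_len(nrow(ms))) {
        k <- round(ms$frac[i] * n_codons)
        if (k > 0) mat[ms$sample[i], sample(n_codons, k)] <- "NNN"
      }
    }
    alignments[[g]] <- apply(mat, 1, paste, collapse = "")
  }
  truth <- planted
  if (nrow(truth)) truth$gene_id <- genes[truth$gene]
  list(alignments = alignments, truth = list(planted = truth))
}

#' Write codon alignments as per-gene FASTA files
#' @param alignments list as returned by [simulate_codon_alignments()].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_codon_fasta <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(alignments), function(g) {
    p <- file.path(dir, paste0(g, ".fa"))
    seqs <- alignments[[g]]
    writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), p)
    p
  }, "")
  invisible(paths)
}

#' Read a codon alignment from FASTA
#' @param path FASTA file with equal-length, in-frame sequences.
#' @param gene_id gene identifier (defaults to the file name).
#' @return named character vector of codon sequences.
#' @export
read_codon_fasta <- function(path, gene_id = NULL) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}
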
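#' Construct a genotype matrix
#'
#' The central container for diploid genotype calls at biallelic SNPs.
#' Genotypes are stored as alternate-allele dosages (0, 1, 2) with `NA`
#' for missing calls, in a sites-by-samples integer matrix. Sites must be
#' sorted by position within each chromosome; only biallelic SNPs are
#' allowed.
#'
#' @param chrom character vector of sequence names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing
#'   within each chromosome.
#' @param ref,alt single-nucleotide reference and alternate alleles.
#' @param G integer matrix of dosages, sites in rows, samples in columns;
#'   values in `{0, 1, 2, NA}`.
#' @param samples character vector of sample identifiers (column names).
#'
#' @return An object of class `genotype_matrix` with elements `chrom`,
#'   `pos`, `ref`, `alt`, `G` and `samples`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, G, samples) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  L <- length(pos)
  stopifnot(
    length(chrom) == L, length(ref) == L, length(alt) == L,
    nrow(G) == L, ncol(G) == length(samples)
  )
  vals <- G[!is.na(G)]
  if (length(vals) && (any(vals < 0L) || any(vals > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  bad <- nchar(ref) != 1L | nchar(alt) != 1L
  if (any(bad))
    stop("only biallelic SNPs are supported; offending site(s): ",
         paste(head(which(bad)), collapse = ", "))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  colnames(G) <- samples
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         G = G, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites / samples in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' @rdname n_sites
#' @export
n_samples <- function(gm) length(gm$samples)

#' Subset a genotype matrix by site index or sample name
#'
#' @param gm a `genotype_matrix`.
#' @param sites integer or logical index over sites (optional).
#' @param samples character vector of sample names or index (optional).
#' @return a `genotype_matrix` restricted to the requested sites/samples.
#' @export
subset_gm <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(gm))
  if (is.null(samples)) samples <- gm$samples
  if (is.character(samples)) {
    missing <- setdiff(samples, gm$samples)
    if (length(missing))
      stop("unknown sample(s): ", paste(missing, collapse = ", "))
  }
  genotype_matrix(gm$chrom[sites], gm$pos[sites], gm$ref[sites],
                  gm$alt[sites], gm$G[sites, samples, drop = FALSE],
                  colnames(gm$G[, samples, drop = FALSE]))
}

#' Construct a population map
#'
#' Assigns samples to populations and, optionally, populations to the
#' four roles of a four-taxon allele-sharing test: `P1` and `P2` are the
#' sister lineages, `P3` the candidate donor, `OUT` the outgroup used to
#' polarize ancestral vs derived alleles.
#'
#' @param assignments named character vector: names are sample ids,
#'   values are population labels.
#' @param roles named character vector mapping role names (`P1`, `P2`,
#'   `P3`, `OUT`) to population labels. Roles must map to distinct
#'   populations.
#' @return An object of class `population_map`.
#' @export
population_map <- function(assignments, roles = NULL) {
  stopifnot(!is.null(names(assignments)))
  if (!is.null(roles)) {
    if (anyDuplicated(roles))
      stop("roles must map to pairwise distinct populations")
    missing <- setdiff(roles, assignments)
    if (length(missing))
      stop("role population(s) with no samples: ",
           paste(missing, collapse = ", "))
  }
  structure(list(assignments = assignments, roles = roles),
            class = "population_map")
}

#' Samples belonging to a population or role
#'
#' @param pm a `population_map`.
#' @param what a population label, or a role name (`P1`, `P2`, `P3`,
#'   `OUT`) if roles are assigned.
#' @return character vector of sample ids.
#' @export
pm_samples <- function(pm, what) {
  pop <- what
  if (!is.null(pm$roles) && what %in% names(pm$roles))
    pop <- pm$roles[[what]]
  out <- names(pm$assignments)[pm$assignments == pop]
  if (!length(out)) stop("no samples for population/role '", what, "'")
  out
}

#' Validate that a population map covers a genotype matrix
#' @param gm a `genotype_matrix`.
#' @param pm a `population_map`.
#' @return invisibly `TRUE`; errors if a role has no samples in `gm`.
#' @export
check_pm <- function(gm, pm) {
  for (role in names(pm$roles)) {
    s <- pm_samples(pm, role)
    if (!any(s %in% gm$samples))
      stop("role ", role, " has no samples present in the genotype matrix")
  }
  invisible(TRUE)
}

#' Mask genotypes by read depth
#'
#' Sets a genotype to missing when its site-level read depth falls below
#' half or rises above twice the sample's mean depth. The mean is the
#' per-sample autosomal average (supply the X-chromosomal average instead
#' when filtering X data).
#'
#' @param gm a `genotype_matrix`.
#' @param depth integer matrix of per-site, per-sample read depth with the
#'   same dimensions as `gm$G` (NA depth leaves the genotype untouched).
#' @param mean_depth named numeric vector of per-sample mean depth; every
#'   sample in `gm` must be present with a positive value.
#' @return the filtered `genotype_matrix`.
#' @export
apply_depth_mask <- function(gm, depth, mean_depth) {
  depth <- as.matrix(depth)
  stopifnot(all(dim(depth) == dim(gm$G)))
  missing <- setdiff(gm$samples, names(mean_depth))
  if (length(missing))
    stop("no mean depth for sample(s): ", paste(missing, collapse = ", "))
  mu <- mean_depth[gm$samples]
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mean depth must be positive for every sample")
  lo <- matrix(mu / 2, nrow = n_sites(gm), ncol = n_samples(gm), byrow = TRUE)
  hi <- matrix(mu * 2, nrow = n_sites(gm), ncol = n_samples(gm), byrow = TRUE)
  bad <- !is.na(depth) & (depth < lo | depth > hi)
  gm$G[bad] <- NA_integer_
  gm
}

#' Mask unbalanced heterozygous genotypes
#'
#' Heterozygous calls whose minor allele is supported by fewer than a
#' quarter of the reads are set to missing. Homozygous genotypes are never
#' touched. Heterozygous calls with zero total allele depth are masked and
#' counted in a warning.
#'
#' @param gm a `genotype_matrix`.
#' @param ref_reads,alt_reads integer matrices of per-site, per-sample
#'   allele depths, same dimensions as `gm$G`.
#' @param min_support minimum minor-allele read fraction for a het call
#'   to be kept (default 0.25).
#' @return the filtered `genotype_matrix`.
#' @export
apply_allele_balance_mask <- function(gm, ref_reads, alt_reads,
                                      min_support = 0.25) {
  ref_reads <- as.matrix(ref_reads)
  alt_reads <- as.matrix(alt_reads)
  stopifnot(all(dim(ref_reads) == dim(gm$G)),
            all(dim(alt_reads) == dim(gm$G)))
  het <- !is.na(gm$G) & gm$G == 1L
  tot <- ref_reads + alt_reads
  support <- pmin(ref_reads, alt_reads) / tot
  zero_dp <- het & !is.na(tot) & tot == 0L
  if (any(zero_dp))
    warning(sum(zero_dp), " heterozygous genotype(s) with zero allele",
            " depth were masked")
  bad <- het & !is.na(tot) & (tot == 0L | (!is.na(support) & support < min_support))
  gm$G[bad] <- NA_integer_
  gm
}
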
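#' Genome-wide heterozygosity of one sample
#'
#' The number of heterozygous genotypes divided by the total number of
#' called genotypes for the sample, over the sites present in the matrix.
#' Missing genotypes are excluded from both numerator and denominator.
#'
#' @param gm a [genotype_matrix()].
#' @param sample sample id; may be omitted for a single-sample matrix.
#' @return heterozygosity in `[0, 1]`.
#' @export
heterozygosity <- function(gm, sample = NULL) {
  if (is.null(sample)) {
    if (n_samples(gm) != 1L)
      stop("specify `sample` for a multi-sample matrix")
    sample <- gm$samples
  }
  g <- gm$G[, sample]
  n_called <- sum(!is.na(g))
  if (n_called == 0L) stop("no called genotypes for sample ", sample)
  sum(g == 1L, na.rm = TRUE) / n_called
}

#' Polarize genotypes into derived-allele dosages using an outgroup
#'
#' A site is usable when the outgroup is monomorphic (all non-missing
#' outgroup genotypes homozygous for the same allele); the outgroup
#' allele is taken as ancestral and dosages are re-expressed as copies of
#' the derived (non-outgroup) allele. Sites with polymorphic,
#' heterozygous or entirely missing outgroups are skipped.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] with an `OUT` role (or pass
#'   `outgroup` as a population label).
#' @param outgroup role or population holding the outgroup samples.
#' @return list with `derived` (usable-sites x samples integer matrix of
#'   derived dosages), `site_index` (row indices into `gm`),
#'   `n_skipped` (sites dropped for unusable outgroup).
#' @export
polarize_derived <- function(gm, pm, outgroup = "OUT") {
  out_s <- intersect(pm_samples(pm, outgroup), gm$samples)
  if (!length(out_s)) stop("no outgroup samples in the genotype matrix")
  O <- gm$G[, out_s, drop = FALSE]
  nm <- rowSums(!is.na(O))
  rs <- rowSums(O, na.rm = TRUE)
  fixed_ref <- nm > 0 & rs == 0L
  fixed_alt <- nm > 0 & rs == 2L * nm
  use <- fixed_ref | fixed_alt
  D <- gm$G[use, , drop = FALSE]
  flip <- fixed_alt[use]
  D[flip, ] <- 2L - D[flip, , drop = FALSE]
  list(derived = D, site_index = which(use), n_skipped = sum(!use))
}

#' Derived-allele mutation-load ratios
#'
#' Counts derived alleles (dosage sums: a homozygous-derived genotype
#' contributes 2) per impact category and per sample, and reports the
#' moderate- and high-impact counts relative to the synonymous count.
#'
#' @param gm a [genotype_matrix()].
#' @param impacts data.frame with columns `chrom`, `pos`, `alt`,
#'   `category` (`synonymous`, `moderate` or `high`); at most one
#'   category per alt allele.
#' @param pm a [population_map()] with an `OUT` role for polarization.
#' @param outgroup role or population of the outgroup.
#' @return data.frame with one row per non-outgroup sample: counts
#'   `derived_synonymous`, `derived_moderate`, `derived_high` and ratios
#'   `load_moderate`, `load_high`.
#' @export
load_ratios <- function(gm, impacts, pm, outgroup = "OUT") {
  pol <- polarize_derived(gm, pm, outgroup)
  key_gm <- paste(gm$chrom[pol$site_index], gm$pos[pol$site_index],
                  gm$alt[pol$site_index])
  key_imp <- paste(impacts$chrom, impacts$pos, impacts$alt)
  if (anyDuplicated(key_imp))
    stop("impact table assigns more than one category to an alt allele")
  category <- impacts$category[match(key_gm, key_imp)]
  out_s <- intersect(pm_samples(pm, outgroup), gm$samples)
  keep_s <- setdiff(gm$samples, out_s)
  counts <- sapply(IMPACT_CATEGORIES, function(cc) {
    rows <- which(!is.na(category) & category == cc)
    if (!length(rows)) return(stats::setNames(rep(0, length(keep_s)), keep_s))
    colSums(pol$derived[rows, keep_s, drop = FALSE], na.rm = TRUE)
  })
  counts <- matrix(counts, nrow = length(keep_s),
                   dimnames = list(keep_s, IMPACT_CATEGORIES))
  if (any(counts[, "synonymous"] == 0))
    stop("zero synonymous derived alleles for sample(s): ",
         paste(keep_s[counts[, "synonymous"] == 0], collapse = ", "))
  data.frame(sample = keep_s,
             derived_synonymous = counts[, "synonymous"],
             derived_moderate = counts[, "moderate"],
             derived_high = counts[, "high"],
             load_moderate = counts[, "moderate"] / counts[, "synonymous"],
             load_high = counts[, "high"] / counts[, "synonymous"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-impact-category heterozygosity of one sample
#'
#' Heterozygosity computed separately over the sites of each impact
#' category: the number of heterozygous calls at category sites divided
#' by the number of called genotypes at those sites. Empty categories
#' (no called genotypes) are omitted with a warning.
#'
#' @param gm a single-sample [genotype_matrix()] (or use `sample`).
#' @param impacts impact table as in [load_ratios()].
#' @param sample sample id for multi-sample matrices.
#' @return named numeric vector of per-category heterozygosity.
#' @export
heterozygosity_by_impact <- function(gm, impacts, sample = NULL) {
  if (is.null(sample)) {
    if (n_samples(gm) != 1L)
      stop("specify `sample` for a multi-sample matrix")
    sample <- gm$samples
  }
  key_gm <- paste(gm$chrom, gm$pos, gm$alt)
  key_imp <- paste(impacts$chrom, impacts$pos, impacts$alt)
  category <- impacts$category[match(key_gm, key_imp)]
  g <- gm$G[, sample]
  out <- c()
  for (cc in intersect(IMPACT_CATEGORIES, unique(stats::na.omit(category)))) {
    gi <- g[!is.na(category) & category == cc]
    n_called <- sum(!is.na(gi))
    if (n_called == 0L) {
      warning("no called genotypes in category ", cc, "; omitted")
      next
    }
    out[cc] <- sum(gi == 1L, na.rm = TRUE) / n_called
  }
  out
}
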
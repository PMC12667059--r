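## ABBA-BABA D-statistics and windowed f_dM introgression landscapes.
##
## All statistics use population derived-allele frequencies (not single
## pseudohaploid draws). A site is usable when the outgroup role is
## monomorphic there (its allele is ancestral) and every role has at
## least one non-missing genotype. With frequencies p1, p2, p3 in the
## three ingroup roles and p4 in the outgroup (0 by construction), the
## per-site pattern weights are
##   ABBA = (1-p1) p2 p3 (1-p4),   BABA = p1 (1-p2) p3 (1-p4).

## Per-site derived-allele frequencies for roles P1, P2, P3, OUT, plus
## per-site ABBA/BABA weights and the usable-site mask.
site_components <- function(gm, pm) {
  check_pm(gm, pm)
  role_freq <- function(role) {
    s <- intersect(pm_samples(pm, role), gm$samples)
    X <- gm$G[, s, drop = FALSE]
    nm <- rowSums(!is.na(X))
    list(freq = ifelse(nm > 0, rowSums(X, na.rm = TRUE) / (2 * nm), NA_real_),
         nm = nm)
  }
  f1 <- role_freq("P1"); f2 <- role_freq("P2"); f3 <- role_freq("P3")
  f4 <- role_freq("OUT")
  out_fixed_ref <- f4$nm > 0 & f4$freq == 0
  out_fixed_alt <- f4$nm > 0 & f4$freq == 1
  use <- (out_fixed_ref | out_fixed_alt) &
    f1$nm > 0 & f2$nm > 0 & f3$nm > 0
  ## derived allele = the allele absent from the (monomorphic) outgroup
  p1 <- ifelse(out_fixed_alt, 1 - f1$freq, f1$freq)
  p2 <- ifelse(out_fixed_alt, 1 - f2$freq, f2$freq)
  p3 <- ifelse(out_fixed_alt, 1 - f3$freq, f3$freq)
  p4 <- rep(0, n_sites(gm))
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  list(chrom = gm$chrom, pos = gm$pos, use = use,
       p1 = p1, p2 = p2, p3 = p3, p4 = p4, abba = abba, baba = baba,
       n_skipped_outgroup = sum(f4$nm > 0 & !(out_fixed_ref | out_fixed_alt)))
}

#' Genome-wide ABBA/BABA pattern sums
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] with roles `P1`, `P2`, `P3`, `OUT`.
#' @return list with `ABBA`, `BABA` (frequency-weighted sums) and
#'   `n_sites_used` (usable polarized sites).
#' @export
site_patterns <- function(gm, pm) {
  sc <- site_components(gm, pm)
  list(ABBA = sum(sc$abba[sc$use]), BABA = sum(sc$baba[sc$use]),
       n_sites_used = sum(sc$use))
}

#' The D-statistic
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; positive D indicates excess
#' allele sharing between P2 and P3. Returns `NA` when both sums are
#' zero (undefined, not an error).
#'
#' @param ps pattern sums from [site_patterns()].
#' @return D in `[-1, 1]`, or `NA`.
#' @export
d_statistic <- function(ps) {
  tot <- ps$ABBA + ps$BABA
  if (tot == 0) return(NA_real_)
  (ps$ABBA - ps$BABA) / tot
}

#' D-statistic with weighted block-jackknife standard error
#'
#' Sites are grouped into contiguous genomic blocks; the delete-one-block
#' estimates feed the weighted jackknife of Busing et al. (1999), with
#' per-block usable-site counts as weights. `Z = D / SE`.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] with roles assigned.
#' @param block_size block length in bp (default 1 Mb).
#' @return list with `D`, `SE`, `Z`, `n_blocks`, `n_sites_used`.
#' @export
block_jackknife_d <- function(gm, pm, block_size = 1e6) {
  sc <- site_components(gm, pm)
  keep <- sc$use
  if (!any(keep)) stop("no usable sites")
  block <- paste0(sc$chrom[keep], "_",
                  floor((sc$pos[keep] - 1) / block_size))
  A <- rowsum(sc$abba[keep], block)[, 1]
  B <- rowsum(sc$baba[keep], block)[, 1]
  m <- rowsum(rep(1, sum(keep)), block)[, 1]
  g <- length(m)
  if (g < 2) stop("fewer than 2 non-empty blocks")
  if (g < 20) warning("only ", g, " non-empty jackknife blocks; ",
                      ">= 20 recommended")
  At <- sum(A); Bt <- sum(B); n <- sum(m)
  D <- (At - Bt) / (At + Bt)
  if (!is.finite(D)) stop("D undefined: zero pattern sums")
  D_mj <- ((At - A) - (Bt - B)) / ((At - A) + (Bt - B))
  if (any(!is.finite(D_mj)))
    stop("a single block carries all informative sites; use smaller blocks")
  h <- n / m
  D_J <- g * D - sum((1 - m / n) * D_mj)
  var_J <- sum((h * D - (h - 1) * D_mj - D_J)^2 / (h - 1)) / g
  SE <- sqrt(max(var_J, 0))
  Z <- if (SE > 0) D / SE else if (D == 0) 0 else sign(D) * Inf
  list(D = D, SE = SE, Z = Z, n_blocks = g, n_sites_used = n)
}

## Per-site f_dM numerator and denominator. The denominator uses the
## dynamic donor: where p2 >= p1, both P2 and P3 are replaced by
## pD = max(p2, p3); where p1 > p2, P1 and P3 are replaced by
## pD = max(p1, p3) and the term enters with negative sign. This is the
## symmetric windowed estimator of Malinsky et al. as implemented for
## sliding-window scans.
fdm_site_terms <- function(sc) {
  num <- sc$abba - sc$baba
  q4 <- 1 - sc$p4
  hi2 <- sc$p2 >= sc$p1
  pD <- ifelse(hi2, pmax(sc$p2, sc$p3), pmax(sc$p1, sc$p3))
  den <- ifelse(hi2,
                ((1 - sc$p1) * pD - sc$p1 * (1 - pD)) * pD * q4,
                -(((1 - pD) * sc$p2 - pD * (1 - sc$p2)) * pD * q4))
  list(num = num, den = den)
}

#' Windowed f_dM introgression landscape
#'
#' Computes f_dM in non-overlapping windows tiled along each chromosome.
#' Windows with fewer than `min_snps` usable SNPs are excluded, as are
#' (rare) retained windows with a zero denominator, which are tallied in
#' the `n_dropped_zero_denom` attribute.
#'
#' @param gm a [genotype_matrix()].
#' @param pm a [population_map()] with roles assigned.
#' @param window window size in bp (default 10 kb).
#' @param min_snps minimum usable SNPs per retained window (default 100).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `f_dm`.
#' @export
fdm_windows <- function(gm, pm, window = 10000, min_snps = 100) {
  stopifnot(window > 0)
  sc <- site_components(gm, pm)
  keep <- which(sc$use)
  terms <- fdm_site_terms(sc)
  win <- floor((sc$pos[keep] - 1) / window)
  key <- paste0(sc$chrom[keep], ":", win)
  num <- rowsum(terms$num[keep], key)
  den <- rowsum(terms$den[keep], key)
  n_snps <- rowsum(rep(1L, length(keep)), key)[, 1]
  chrom <- sub(":[^:]*$", "", rownames(num))
  start <- as.numeric(sub("^.*:", "", rownames(num))) * window
  ok <- n_snps >= min_snps
  zero_den <- ok & den[, 1] == 0
  ok <- ok & !zero_den
  out <- data.frame(chrom = chrom[ok], start = start[ok],
                    end = start[ok] + window, n_snps = n_snps[ok],
                    f_dm = num[ok, 1] / den[ok, 1],
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_zero_denom") <- sum(zero_den)
  out
}

#' Correlation of two windowed introgression landscapes
#'
#' Pairs windows by coordinates (`chrom`, `start`, `end`), keeping only
#' windows retained in both landscapes, and returns the Pearson
#' correlation of the paired f_dM values.
#'
#' @param a,b window tables from [fdm_windows()].
#' @return list with `r`, `p` (two-sided) and `n` (shared windows).
#' @export
landscape_correlation <- function(a, b) {
  ka <- paste(a$chrom, a$start, a$end)
  kb <- paste(b$chrom, b$start, b$end)
  i <- match(ka, kb)
  ok <- !is.na(i)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 shared windows")
  ct <- pearson_cor(a$f_dm[ok], b$f_dm[i[ok]])
  list(r = ct$r, p = ct$p, n = n)
}

#' Outlier windows of an f_dM landscape
#'
#' Windows whose f_dM is at or above the empirical `percentile` of the
#' retained windows (linear-interpolation quantile; ties included).
#'
#' @param ws window table from [fdm_windows()].
#' @param percentile percentile threshold (default 99).
#' @return the subset of `ws` at or above the threshold.
#' @export
outlier_windows <- function(ws, percentile = 99) {
  stopifnot(nrow(ws) > 0)
  thr <- stats::quantile(ws$f_dm, percentile / 100, type = 7, names = FALSE)
  out <- ws[ws$f_dm >= thr, , drop = FALSE]
  attr(out, "threshold") <- thr
  out
}

#' Write a window table as BED-like TSV
#' @param ws window table from [fdm_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_windows <- function(ws, path) {
  df <- ws
  df$f_dm <- sprintf("%.10g", df$f_dm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
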
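#' Parameters of the scanning-window ROH caller
#'
#' Defaults follow the plink `--homozyg` parameterization used for
#' primate resequencing data: runs of at least 100 kb and 100 SNPs, at
#' most one heterozygous call per 50-SNP scanning window, an average of
#' at least one SNP per 50 kb inside a run, and a maximum gap of 1 Mb
#' between consecutive SNPs.
#'
#' @param min_len_bp minimum run length in bp.
#' @param min_snps minimum SNPs per run.
#' @param max_het_per_window maximum heterozygous calls tolerated per
#'   scanning window.
#' @param scan_window_snps scanning-window size in SNPs.
#' @param hit_fraction minimum fraction of overlapping windows that must
#'   be homozygous-compatible for a SNP to be in a run.
#' @param min_density_bp_per_snp maximum average bp per SNP inside a run.
#' @param max_gap_bp maximum gap between consecutive SNPs inside a run.
#' @return a list of class `roh_params`.
#' @export
roh_params <- function(min_len_bp = 100000, min_snps = 100,
                       max_het_per_window = 1, scan_window_snps = 50,
                       hit_fraction = 0.05, min_density_bp_per_snp = 50000,
                       max_gap_bp = 1000000) {
  p <- list(min_len_bp = min_len_bp, min_snps = min_snps,
            max_het_per_window = max_het_per_window,
            scan_window_snps = scan_window_snps,
            hit_fraction = hit_fraction,
            min_density_bp_per_snp = min_density_bp_per_snp,
            max_gap_bp = max_gap_bp)
  stopifnot(all(unlist(p) > 0))
  class(p) <- "roh_params"
  p
}

## Candidate runs on one chromosome: maximal stretches of "hit" SNPs
## (per-SNP fraction of overlapping passing scan windows >= hit_fraction),
## split at inter-SNP gaps > max_gap_bp, then filtered on all thresholds.
roh_one_chrom <- function(pos, het, params) {
  n <- length(pos)
  w <- params$scan_window_snps
  if (n < w) return(NULL)
  nw <- n - w + 1L
  ch <- c(0L, cumsum(het))
  wsum <- ch[(w + 1L):(n + 1L)] - ch[1:nw]
  pass <- as.integer(wsum <= params$max_het_per_window)
  cp <- c(0L, cumsum(pass))
  ## windows containing SNP i: starts max(1, i-w+1) .. min(i, nw)
  lo <- pmax(1L, seq_len(n) - w + 1L)
  hi <- pmin(seq_len(n), nw)
  n_win <- hi - lo + 1L
  n_pass <- cp[hi + 1L] - cp[lo]
  hit <- n_pass / n_win >= params$hit_fraction
  ## maximal runs of hit SNPs
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    ## split at gaps > max_gap_bp
    p <- pos[i0:i1]
    gap_break <- which(diff(p) > params$max_gap_bp)
    piece_start <- c(1L, gap_break + 1L)
    piece_end <- c(gap_break, length(p))
    for (j in seq_along(piece_start)) {
      a <- i0 + piece_start[j] - 1L
      b <- i0 + piece_end[j] - 1L
      n_snps <- b - a + 1L
      len <- pos[b] - pos[a] + 1L
      if (n_snps < params$min_snps) next
      if (len < params$min_len_bp) next
      if (len / n_snps > params$min_density_bp_per_snp) next
      segs[[length(segs) + 1L]] <-
        data.frame(start = pos[a] - 1L, end = pos[b],
                   n_snps = n_snps, n_het = sum(het[a:b]))
    }
  }
  if (!length(segs)) return(NULL)
  do.call(rbind, segs)
}

#' Call runs of homozygosity for one sample
#'
#' Missing genotypes are removed from the site list before scanning (so
#' missing calls cannot break a run). Scanning windows of
#' `scan_window_snps` consecutive SNPs are classified as
#' homozygous-compatible when they contain at most `max_het_per_window`
#' heterozygous calls; a SNP belongs to a run when at least
#' `hit_fraction` of the windows containing it are compatible. Maximal
#' runs of such SNPs are split at inter-SNP gaps larger than
#' `max_gap_bp` and then filtered on minimum length, SNP count and SNP
#' density. Segment endpoints are the first/last SNP positions of the
#' run (reported 0-based half-open).
#'
#' @param gm a single-sample [genotype_matrix()] (or use `sample`).
#' @param params a [roh_params()].
#' @param sample sample id for multi-sample matrices.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `n_snps`, `n_het` (zero rows when nothing is called).
#' @export
call_roh <- function(gm, params = roh_params(), sample = NULL) {
  if (is.null(sample)) {
    if (n_samples(gm) != 1L)
      stop("specify `sample` for a multi-sample matrix")
    sample <- gm$samples
  }
  g <- gm$G[, sample]
  keep <- !is.na(g)
  empty <- data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_snps = integer(0), n_het = integer(0))
  if (!any(keep)) return(empty)
  chrom <- gm$chrom[keep]
  pos <- gm$pos[keep]
  het <- as.integer(g[keep] == 1L)
  out <- lapply(unique(chrom), function(ch) {
    i <- chrom == ch
    seg <- roh_one_chrom(pos[i], het[i], params)
    if (is.null(seg)) return(NULL)
    cbind(data.frame(sample = sample, chrom = ch), seg)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

#' Accessible genome length for ROH normalization
#'
#' Converts all heterozygous genotypes of the sample to homozygous calls
#' and runs the identical ROH caller on this artificial, completely
#' homozygous genome. The total called length is the per-sample
#' denominator for ROH genome fractions: it measures how much of the
#' genome could have supported an ROH call at the realized SNP density.
#'
#' @inheritParams call_roh
#' @return accessible length in bp.
#' @export
accessible_length <- function(gm, params = roh_params(), sample = NULL) {
  if (is.null(sample)) {
    if (n_samples(gm) != 1L)
      stop("specify `sample` for a multi-sample matrix")
    sample <- gm$samples
  }
  g2 <- gm
  col <- match(sample, gm$samples)
  h <- g2$G[, col]
  h[!is.na(h) & h == 1L] <- 0L
  g2$G[, col] <- h
  seg <- call_roh(g2, params, sample)
  sum(seg$end - seg$start)
}

#' Summarize ROH calls for one sample
#'
#' Genome fractions in short (100 kb to 1 Mb, inclusive on both bounds)
#' and long (> 1 Mb) runs of homozygosity, normalized by the accessible
#' genome length.
#'
#' @param segments data.frame from [call_roh()] (one sample).
#' @param accessible_len_bp denominator from [accessible_length()].
#' @param short_max_bp boundary between short and long ROH (default
#'   1 Mb).
#' @return data.frame with `sample`, `n_roh`, `total_len_bp`,
#'   `accessible_len_bp`, `f_short`, `f_long`.
#' @export
summarize_roh <- function(segments, accessible_len_bp,
                          short_max_bp = 1e6) {
  if (accessible_len_bp <= 0) stop("accessible length must be positive")
  len <- segments$end - segments$start
  data.frame(
    sample = if (nrow(segments)) segments$sample[1] else NA_character_,
    n_roh = nrow(segments),
    total_len_bp = sum(len),
    accessible_len_bp = accessible_len_bp,
    f_short = sum(len[len <= short_max_bp]) / accessible_len_bp,
    f_long = sum(len[len > short_max_bp]) / accessible_len_bp,
    stringsAsFactors = FALSE)
}

#' Correlation between ROH count and total ROH length across samples
#'
#' @param summaries data.frame of per-sample rows from
#'   [summarize_roh()] (at least 3 samples).
#' @return list with Pearson `r` and two-sided `p`.
#' @export
roh_count_length_correlation <- function(summaries) {
  if (nrow(summaries) < 3) stop("need at least 3 samples")
  pearson_cor(summaries$n_roh, summaries$total_len_bp)
}
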
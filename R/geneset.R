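#' Genes whose body or upstream region overlaps a set of windows
#'
#' A gene is included when its body interval, or its strand-aware
#' upstream interval (`upstream_bp` before the start on `+` genes, after
#' the end on `-` genes, clipped at 0), intersects any window under
#' half-open interval arithmetic (an overlap of at least 1 bp; abutting
#' intervals do not overlap).
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [outlier_windows()].
#' @param genes data.frame from [read_gene_intervals()].
#' @param upstream_bp upstream extent in bp (default 10 kb); 0 reduces
#'   to plain body intersection.
#' @return character vector of gene ids.
#' @export
genes_near_windows <- function(windows, genes, upstream_bp = 10000) {
  if (!nrow(windows) || !nrow(genes)) return(character(0))
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L,
                                               windows$end))
  body <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  plus <- genes$strand == "+"
  up_start <- ifelse(plus, pmax(0L, genes$start - upstream_bp), genes$end)
  up_end <- ifelse(plus, genes$start, genes$end + upstream_bp)
  has_up <- up_end > up_start
  ids <- character(0)
  ov <- GenomicRanges::findOverlaps(body, w)
  ids <- genes$gene_id[unique(S4Vectors::queryHits(ov))]
  if (any(has_up)) {
    up <- GenomicRanges::GRanges(genes$chrom[has_up],
                                 IRanges::IRanges(up_start[has_up] + 1L,
                                                  up_end[has_up]))
    ovu <- GenomicRanges::findOverlaps(up, w)
    ids <- union(ids, genes$gene_id[has_up][unique(S4Vectors::queryHits(ovu))])
  }
  sort(unique(ids))
}

#' Fisher's exact test for the overlap of two gene sets
#'
#' Builds the 2x2 table of set membership over a gene universe and tests
#' the overlap with the two-sided Fisher's exact test (minimum-likelihood
#' summation of hypergeometric point probabilities, the classical
#' convention). The odds ratio is the sample odds ratio of the table; a
#' zero cell yields an infinite (or zero) odds ratio, flagged in
#' `or_degenerate`.
#'
#' @param setA,setB character vectors of gene ids; must be subsets of
#'   `universe`.
#' @param universe character vector of all eligible gene ids.
#' @return list with `k` (overlap), `K` (|A|), `n` (|B|), `N`
#'   (|universe|), `odds_ratio`, `p_two_sided`, `or_degenerate`.
#' @export
fisher_overlap <- function(setA, setB, universe) {
  badA <- setdiff(setA, universe)
  badB <- setdiff(setB, universe)
  if (length(badA) || length(badB))
    stop("ids outside the universe: ",
         paste(utils::head(c(badA, badB), 5), collapse = ", "))
  setA <- unique(setA); setB <- unique(setB); universe <- unique(universe)
  k <- length(intersect(setA, setB))
  K <- length(setA); n <- length(setB); N <- length(universe)
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), nrow = 2)
  p <- stats::fisher.test(tab)$p.value
  num <- k * (N - K - n + k)
  den <- (K - k) * (n - k)
  degenerate <- den == 0 || num == 0
  or <- if (den == 0) Inf else num / den
  list(k = k, K = K, n = n, N = N, odds_ratio = or,
       p_two_sided = p, or_degenerate = degenerate)
}

#' Pearson correlation with a t-based two-sided p-value
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero
#'   variance. Zero variance yields `r = NA` with a warning rather than
#'   an error.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
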
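# Shared in-code fixtures for the test suite.

# Genotype matrix from a dosage matrix (sites x samples); positions
# default to 1, 2, ... on chr1 with A->C alleles.
make_gm <- function(G, pos = NULL, chrom = NULL, samples = NULL,
                    ref = NULL, alt = NULL) {
  G <- as.matrix(G)
  L <- nrow(G)
  if (is.null(pos)) pos <- seq_len(L)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(G)))
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("C", L)
  genotype_matrix(chrom, pos, ref, alt, G, samples)
}

# One diploid sample per role; dosages given per role.
quartet_gm <- function(d1, d2, d3, d4, pos = NULL) {
  make_gm(cbind(p1 = d1, p2 = d2, p3 = d3, out = d4), pos = pos,
          samples = c("p1", "p2", "p3", "out"))
}

quartet_pm <- function() {
  population_map(
    c(p1 = "P1", p2 = "P2", p3 = "P3", out = "OUT"),
    c(P1 = "P1", P2 = "P2", P3 = "P3", OUT = "OUT"))
}

# Two diploids per role, so population frequencies of 0, 0.25, 0.5,
# 0.75, 1 are reachable. Dosage arguments are L x 2 matrices (or
# vectors recycled to two samples).
octet_gm <- function(d1, d2, d3, d4, pos = NULL) {
  two <- function(d) if (is.matrix(d)) d else cbind(d, d)
  G <- cbind(two(d1), two(d2), two(d3), two(d4))
  make_gm(G, pos = pos,
          samples = c("p1a", "p1b", "p2a", "p2b", "p3a", "p3b",
                      "outa", "outb"))
}

octet_pm <- function() {
  population_map(
    c(p1a = "P1", p1b = "P1", p2a = "P2", p2b = "P2",
      p3a = "P3", p3b = "P3", outa = "OUT", outb = "OUT"),
    c(P1 = "P1", P2 = "P2", P3 = "P3", OUT = "OUT"))
}

# Independent hypergeometric two-sided p (minimum-likelihood summation),
# computed by full enumeration of the support on log scale.
fisher_p_bruteforce <- function(k, K, n, N) {
  support <- max(0, K + n - N):min(K, n)
  logp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  p_obs <- logp[support == k]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# Independent Pearson r and t-based p from the covariance formula.
pearson_bruteforce <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

# bp-level precision/recall of called segments against planted tracts
# (0-based half-open intervals on one chromosome).
interval_pr <- function(called, truth) {
  cover <- function(df, x) {
    hit <- rep(FALSE, length(x))
    for (i in seq_len(nrow(df)))
      hit <- hit | (x >= df$start[i] & x < df$end[i])
    hit
  }
  grid <- seq(0, max(c(called$end, truth$end)) - 1, by = 100)
  inC <- cover(called, grid)
  inT <- cover(truth, grid)
  list(precision = sum(inC & inT) / sum(inC),
       recall = sum(inC & inT) / sum(inT))
}
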
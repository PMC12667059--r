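test_that("site patterns match the frequency products by hand", {
  pm <- quartet_pm()
  # p = (0, 1, 1, 0): pure ABBA
  ps <- site_patterns(quartet_gm(0L, 2L, 2L, 0L), pm)
  expect_equal(ps$ABBA, 1)
  expect_equal(ps$BABA, 0)
  # p = (1, 0, 1, 0): pure BABA
  ps <- site_patterns(quartet_gm(2L, 0L, 2L, 0L), pm)
  expect_equal(ps$ABBA, 0)
  expect_equal(ps$BABA, 1)
  # no derived allele in the donor: contributes nothing
  ps <- site_patterns(quartet_gm(2L, 2L, 0L, 0L), pm)
  expect_equal(ps$ABBA + ps$BABA, 0)
  expect_equal(ps$n_sites_used, 1)
  # heterozygous outgroup: site skipped
  ps <- site_patterns(quartet_gm(0L, 2L, 2L, 1L), pm)
  expect_equal(ps$n_sites_used, 0)
  # outgroup fixed for the alternate allele: polarity flips
  ps <- site_patterns(quartet_gm(2L, 0L, 0L, 2L), pm)
  expect_equal(ps$ABBA, 1)   # derived allele is now REF
  expect_equal(ps$BABA, 0)
})

test_that("the D-statistic is the normalised pattern difference", {
  expect_equal(d_statistic(list(ABBA = 6, BABA = 2)), 0.5)
  expect_equal(d_statistic(list(ABBA = 5, BABA = 5)), 0)
  expect_true(is.na(d_statistic(list(ABBA = 0, BABA = 0))))
})

test_that("swapping P1 and P2 negates D (property)", {
  set.seed(13)
  for (rep in 1:5) {
    G <- matrix(sample(0:2, 50 * 8, replace = TRUE), 50, 8)
    G[, 7:8] <- sample(c(0L, 2L), 100, replace = TRUE)  # keep OUT usable
    gm <- make_gm(G, samples = c("p1a", "p1b", "p2a", "p2b",
                                 "p3a", "p3b", "outa", "outb"))
    pm <- octet_pm()
    pm_swapped <- population_map(pm$assignments,
                                 c(P1 = "P2", P2 = "P1", P3 = "P3",
                                   OUT = "OUT"))
    d1 <- d_statistic(site_patterns(gm, pm))
    d2 <- d_statistic(site_patterns(gm, pm_swapped))
    expect_equal(d1, -d2, tolerance = 1e-12)
    expect_lte(abs(d1), 1)
  }
})

test_that("block jackknife: no variance across identical blocks", {
  # 25 blocks of 4 identical sites each (block size 1000)
  pat <- rbind(c(0L, 2L, 2L, 0L), c(2L, 0L, 2L, 0L),
               c(0L, 2L, 2L, 0L), c(1L, 1L, 2L, 0L))
  G <- pat[rep(1:4, 25), ]
  pos <- as.integer(outer(c(10L, 20L, 30L, 40L), (0:24) * 1000L, "+"))
  gm <- make_gm(G[order(pos), ], pos = sort(pos),
                samples = c("p1", "p2", "p3", "out"))
  res <- block_jackknife_d(gm, quartet_pm(), block_size = 1000)
  expect_equal(res$n_blocks, 25)
  expect_equal(res$SE, 0)
  # halving the block size leaves D itself unchanged (ratio of totals)
  res2 <- block_jackknife_d(gm, quartet_pm(), block_size = 500)
  expect_equal(res2$D, res$D)
  # fewer than 2 non-empty blocks errors
  expect_error(block_jackknife_d(gm, quartet_pm(), block_size = 1e9),
               "blocks")
})

test_that("f_dM window arithmetic matches the plug-in formula", {
  # 120 identical sites with p = (0, 0.5, 1, 0) in one 10 kb window:
  # per-site numerator (1-0)*0.5*1 - 0 = 0.5; dynamic donor pD = 1 gives
  # denominator (1-0)*1 - 0 = 1; f_dM = 0.5 exactly.
  L <- 120
  gm <- octet_gm(rep(0L, L), cbind(rep(1L, L), rep(1L, L)), rep(2L, L),
                 rep(0L, L), pos = seq(10, by = 80, length.out = L))
  ws <- fdm_windows(gm, octet_pm(), window = 10000, min_snps = 100)
  expect_equal(nrow(ws), 1)
  expect_equal(ws$n_snps, L)
  expect_equal(ws$f_dm, 0.5, tolerance = 1e-12)
  expect_equal(c(ws$start, ws$end), c(0, 10000))

  # excess sharing with P1 instead drives f_dM negative
  gm_neg <- octet_gm(cbind(rep(1L, L), rep(1L, L)), rep(0L, L), rep(2L, L),
                     rep(0L, L), pos = seq(10, by = 80, length.out = L))
  wn <- fdm_windows(gm_neg, octet_pm(), window = 10000, min_snps = 100)
  expect_equal(wn$f_dm, -0.5, tolerance = 1e-12)
})

test_that("windows below the SNP threshold are excluded", {
  mk <- function(n) octet_gm(rep(0L, n), cbind(rep(1L, n), rep(1L, n)),
                             rep(2L, n), rep(0L, n),
                             pos = seq(5, by = 9000 %/% n, length.out = n))
  expect_equal(nrow(fdm_windows(mk(99), octet_pm(), 10000, 100)), 0)
  expect_equal(nrow(fdm_windows(mk(100), octet_pm(), 10000, 100)), 1)
})

test_that("f_dM is bounded and sign-matches D on single-site windows", {
  set.seed(29)
  for (rep in 1:20) {
    d <- function() matrix(sample(0:2, 2, replace = TRUE), 1, 2)
    out <- sample(c(0L, 2L), 1)
    gm <- octet_gm(d(), d(), d(), matrix(out, 1, 2), pos = 500)
    ws <- fdm_windows(gm, octet_pm(), window = 10000, min_snps = 1)
    ps <- site_patterns(gm, octet_pm())
    D <- d_statistic(ps)
    if (nrow(ws) == 0) next
    expect_lte(abs(ws$f_dm), 1 + 1e-12)
    if (!is.na(D) && D != 0 && ws$f_dm != 0)
      expect_equal(sign(ws$f_dm), sign(D))
  }
})

test_that("landscape correlation is exact for identical/negated input", {
  set.seed(5)
  ws <- data.frame(chrom = "chr1", start = (0:49) * 1e4,
                   end = (1:50) * 1e4, n_snps = 100,
                   f_dm = rnorm(50))
  expect_equal(landscape_correlation(ws, ws)$r, 1)
  neg <- ws; neg$f_dm <- -neg$f_dm
  expect_equal(landscape_correlation(ws, neg)$r, -1)
  expect_equal(landscape_correlation(ws, ws)$n, 50)
  expect_error(landscape_correlation(ws[1:2, ], ws[1:2, ]), "3")
  # only shared windows are used
  expect_equal(landscape_correlation(ws, ws[1:10, ])$n, 10)
})

test_that("outlier windows follow the empirical percentile with ties", {
  ws <- data.frame(chrom = "chr1", start = (0:999) * 1e4,
                   end = (1:1000) * 1e4, n_snps = 100,
                   f_dm = seq(0.001, 1, length.out = 1000))
  out <- outlier_windows(ws, 99)
  expect_equal(nrow(out), 10)

  tied <- ws; tied$f_dm <- 0.3
  expect_equal(nrow(outlier_windows(tied, 99)), 1000)

  # threshold agrees with an independent sort/interpolation oracle
  set.seed(17)
  for (rep in 1:10) {
    x <- rnorm(sample(50:500, 1))
    wsr <- data.frame(chrom = "chr1", start = seq_along(x) * 1e4,
                      end = seq_along(x) * 1e4 + 1e4, n_snps = 1, f_dm = x)
    p <- runif(1, 0.5, 0.999)
    s <- sort(x)
    h <- (length(x) - 1) * p + 1
    thr <- s[floor(h)] + (h - floor(h)) * (s[min(length(x), floor(h) + 1)] -
                                           s[floor(h)])
    expect_equal(nrow(outlier_windows(wsr, 100 * p)), sum(x >= thr))
  }
})
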
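# Hand-built single-sample genotype matrices for threshold fixtures:
# hom dosages drawn from {0,2}, het = 1.
roh_fixture <- function(pos, het_at = integer(0)) {
  dos <- rep(0L, length(pos))
  dos[het_at] <- 1L
  make_gm(matrix(dos, ncol = 1), pos = pos, samples = "s1")
}

test_that("a planted autozygous tract is recovered to the SNP grid", {
  tract <- data.frame(start = 1e6, end = 1.5e6)
  sim <- simulate_roh_genome(41, chrom_len = 3e6, tracts = tract)
  seg <- call_roh(sim$gm)
  expect_equal(nrow(seg), 1)
  # boundaries within one inter-SNP interval (~500 bp expected, allow
  # a generous multiple)
  expect_lt(abs(seg$start - tract$start), 2e4)
  expect_lt(abs(seg$end - tract$end), 2e4)
  expect_gte(seg$n_snps, 100)
})

test_that("each plink threshold alone suppresses a call", {
  # 99 homozygous SNPs over 150 kb: fails min_snps only
  expect_equal(nrow(call_roh(roh_fixture(
    as.integer(seq(1000, 151000, length.out = 99))))), 0)
  # 150 homozygous SNPs over 90 kb: fails min_len only
  expect_equal(nrow(call_roh(roh_fixture(
    as.integer(seq(1000, 91000, length.out = 150))))), 0)
  # 120 SNPs spanning 7.2 Mb evenly (one per 60 kb): fails density only
  expect_equal(nrow(call_roh(roh_fixture(
    as.integer(seq(1000, by = 60000, length.out = 120))))), 0)
  # two dense clusters of 60 SNPs separated by a 1.2 Mb gap: the joint
  # run passes everything except the gap rule; the split halves fail
  # min_snps
  pos_gap <- c(seq(1000, by = 1000, length.out = 60),
               seq(1000 + 59 * 1000 + 1.2e6, by = 1000, length.out = 60))
  expect_equal(nrow(call_roh(roh_fixture(as.integer(pos_gap)))), 0)
  # control: the same designs made compliant do yield calls
  expect_equal(nrow(call_roh(roh_fixture(
    as.integer(seq(1000, 151000, length.out = 150))))), 1)
})

test_that("clustered heterozygotes break a run via the window rule", {
  # 80 + 2 het + 80: every window covering both hets fails, the run
  # splits and neither half reaches 100 SNPs
  pos <- as.integer(seq(1000, by = 1000, length.out = 162))
  expect_equal(nrow(call_roh(roh_fixture(pos, het_at = 81:82))), 0)
  # without the hets the same span is one segment
  expect_equal(nrow(call_roh(roh_fixture(pos))), 1)
  # a single isolated het is tolerated (max one het per window)
  seg <- call_roh(roh_fixture(pos, het_at = 81L))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_het, 1)
})

test_that("missing genotypes are excluded before scanning", {
  set.seed(31)
  pos <- as.integer(seq(1000, by = 1000, length.out = 150))
  dos <- rep(0L, 150)
  dos[sample(25:125, 30)] <- NA
  gm <- make_gm(matrix(dos, ncol = 1), pos = pos, samples = "s1")
  seg <- call_roh(gm)
  expect_equal(nrow(seg), 1)   # missing calls do not break the run
  expect_equal(seg$n_snps, 120)
})

test_that("accessible length and the fully homozygous fixed point", {
  sim <- simulate_roh_genome(43, chrom_len = 2e6, het_rate = 0)
  seg <- call_roh(sim$gm)
  acc <- accessible_length(sim$gm)
  expect_equal(sum(seg$end - seg$start), acc)
  s <- summarize_roh(seg, acc)
  expect_equal(s$f_short + s$f_long, 1.0)

  # a 2 Mb SNP desert is excluded from the accessible genome
  pos <- as.integer(c(seq(1000, by = 500, length.out = 400),
                      seq(1000 + 399 * 500 + 2e6, by = 500,
                          length.out = 400)))
  gm <- make_gm(matrix(rep(1L, 800), ncol = 1), pos = pos, samples = "s1")
  acc2 <- accessible_length(gm)
  expect_lt(acc2, 0.5e6)   # two ~200 kb blocks, desert excluded
  expect_gt(acc2, 2 * 100000)
})

test_that("ROH summaries follow the short/long split by hand", {
  seg1 <- data.frame(sample = "s1", chrom = "chr1", start = 0,
                     end = 5e5, n_snps = 900L, n_het = 0L)
  s <- summarize_roh(seg1, 1e7)
  expect_equal(s$f_short, 0.05)
  expect_equal(s$f_long, 0)
  seg2 <- data.frame(sample = "s1", chrom = "chr1", start = 0,
                     end = 2e6, n_snps = 3800L, n_het = 1L)
  s2 <- summarize_roh(seg2, 1e7)
  expect_equal(s2$f_short, 0)
  expect_equal(s2$f_long, 0.2)
  empty <- seg1[0, ]
  s0 <- summarize_roh(empty, 1e7)
  expect_equal(s0$f_short + s0$f_long, 0)
  expect_error(summarize_roh(seg1, 0), "positive")
})

test_that("emitted segments always satisfy the thresholds (property)", {
  params <- roh_params()
  set.seed(19)
  for (rep in 1:4) {
    tr <- data.frame(start = c(2e5, 2e6), end = c(2e5, 2e6) +
                       runif(2, 1.5e5, 1.2e6))
    sim <- simulate_roh_genome(100 + rep, chrom_len = 4e6, tracts = tr,
                               het_rate = 0.25, tract_het_rate = 0.005)
    seg <- call_roh(sim$gm, params)
    if (!nrow(seg)) next
    len <- seg$end - seg$start
    expect_true(all(len >= params$min_len_bp))
    expect_true(all(seg$n_snps >= params$min_snps))
    expect_true(all(len / seg$n_snps <= params$min_density_bp_per_snp))
    # raising min_len never increases the segment count
    stricter <- roh_params(min_len_bp = 4e5)
    expect_lte(nrow(call_roh(sim$gm, stricter)), nrow(seg))
  }
})

test_that("ROH count/length correlation matches a brute-force oracle", {
  mk_sum <- function(n_roh, total) data.frame(sample = "x", n_roh = n_roh,
                                              total_len_bp = total)
  lin <- mk_sum(c(10, 20, 30, 40), c(10, 20, 30, 40) * 1e5)
  expect_equal(roh_count_length_correlation(lin)$r, 1)
  expect_error(roh_count_length_correlation(lin[1:2, ]), "3")
  set.seed(23)
  for (rep in 1:5) {
    x <- rpois(8, 30); y <- x * 1e5 + rnorm(8, 0, 5e5)
    got <- roh_count_length_correlation(mk_sum(x, y))
    want <- pearson_bruteforce(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-9)
  }
})
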
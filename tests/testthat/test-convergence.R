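aa_matrix <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(x) strsplit(x, "")[[1]]))
  rownames(m) <- names(rows)
  m
}

test_that("the fixed-private-shared predicate by hand", {
  # focalA = {M, M}, focalB = {M}, background = {A, A, A}: convergent
  aa <- aa_matrix(c(a1 = "M", a2 = "M", b1 = "M",
                    g1 = "A", g2 = "A", g3 = "A"))
  res <- convergent_sites(aa, c("a1", "a2"), "b1", c("g1", "g2", "g3"))
  expect_equal(res$n_convergent, 1)
  expect_equal(res$convergent$shared_aa, "M")
  expect_equal(res$convergent$background_aas, "A")

  # shared state present in the background: privacy violated
  aa2 <- aa_matrix(c(a1 = "M", a2 = "M", b1 = "M",
                     g1 = "A", g2 = "M", g3 = "A"))
  expect_equal(convergent_sites(aa2, c("a1", "a2"), "b1",
                                c("g1", "g2", "g3"))$n_convergent, 0)

  # missing focal residue tolerated: fixation over non-missing residues
  aa3 <- aa_matrix(c(a1 = "M", a2 = "X", b1 = "M", g1 = "A", g2 = "A"))
  expect_equal(convergent_sites(aa3, c("a1", "a2"), "b1",
                                c("g1", "g2"))$n_convergent, 1)

  # focal groups disagreeing is not convergence
  aa4 <- aa_matrix(c(a1 = "M", a2 = "M", b1 = "L", g1 = "A", g2 = "A"))
  expect_equal(convergent_sites(aa4, c("a1", "a2"), "b1",
                                c("g1", "g2"))$n_convergent, 0)

  # a fully missing group skips the column
  aa5 <- aa_matrix(c(a1 = "X", a2 = "X", b1 = "M", g1 = "A", g2 = "A"))
  expect_equal(convergent_sites(aa5, c("a1", "a2"), "b1",
                                c("g1", "g2"))$n_convergent, 0)
})

test_that("translation filters follow the stop and missingness rules", {
  groups <- list(focalA = c("a1", "a2"), focalB = c("b1", "b2"))
  # codons: ATG=M, TAA=stop, AAA=K, NNN=missing
  base <- paste(rep("ATG", 10), collapse = "")
  seqs <- c(a1 = base, a2 = base, b1 = base, b2 = base,
            g1 = paste(c(rep("ATG", 5), "TAA", rep("ATG", 4)),
                       collapse = ""),                       # internal stop
            g2 = paste(c(rep("NNN", 6), rep("ATG", 4)),
                       collapse = ""),                       # 60% missing
            g3 = paste(c(rep("ATG", 9), "TAA"), collapse = ""))  # terminal
  tf <- translate_and_filter(seqs, groups)
  expect_false(tf$gene_rejected)
  expect_setequal(names(tf$excluded), c("g1", "g2"))
  expect_equal(unname(tf$excluded["g1"]), "internal_stop")
  expect_equal(unname(tf$excluded["g2"]), "missing")
  expect_true("g3" %in% rownames(tf$aa))   # terminal stop permitted

  # exactly 50% missing is retained (rule is strictly more than half)
  seqs2 <- c(a1 = base, a2 = base, b1 = base, b2 = base,
             g1 = paste(c(rep("NNN", 5), rep("ATG", 5)), collapse = ""))
  tf2 <- translate_and_filter(seqs2, groups)
  expect_true("g1" %in% rownames(tf2$aa))

  # losing 3 of 4 focalA samples rejects the whole gene
  with_stop <- paste(c("TAA", rep("ATG", 9)), collapse = "")
  seqs3 <- c(a1 = base, a2 = with_stop, a3 = with_stop,
             a4 = paste(c(rep("ATG", 4), "TAA", rep("ATG", 5)),
                        collapse = ""),
             b1 = base, g1 = base)
  tf3 <- translate_and_filter(
    seqs3, list(focalA = c("a1", "a2", "a3", "a4"), focalB = "b1"))
  expect_true(tf3$gene_rejected)
  expect_null(tf3$aa)

  # losing exactly half of a focal group is still acceptable
  tf4 <- translate_and_filter(
    seqs3[c("a1", "a2", "b1", "g1")],
    list(focalA = c("a1", "a2"), focalB = "b1"))
  expect_false(tf4$gene_rejected)
})

test_that("planted convergent columns are recovered exactly", {
  groups <- list(focalA = c("a1", "a2"), focalB = c("b1", "b2"),
                 background = c("g1", "g2", "g3"))
  planted <- data.frame(gene = c(1L, 1L, 3L), column = c(4L, 20L, 33L),
                        aa = c("W", "H", "C"))
  sim <- simulate_codon_alignments(55, 5, 40, groups, planted,
                                   noise_columns = 3)
  sc <- scan_convergence(sim$alignments, groups$focalA, groups$focalB,
                         groups$background)
  got <- sc$sites[, c("gene_id", "column")]
  want <- sim$truth$planted[, c("gene_id", "column")]
  got <- got[order(got$gene_id, got$column), ]
  want <- want[order(want$gene_id, want$column), ]
  expect_equal(nrow(got), nrow(want))          # precision = 1
  expect_equal(got$gene_id, want$gene_id)      # recall = 1
  expect_equal(got$column, want$column)

  # null: nothing planted, no noise, zero calls
  sim0 <- simulate_codon_alignments(56, 5, 40, groups)
  sc0 <- scan_convergence(sim0$alignments, groups$focalA, groups$focalB,
                          groups$background)
  expect_equal(nrow(sc0$sites), 0)
})

test_that("adding background samples never adds convergent calls", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 30
    aa <- matrix(sample(c("A", "M", "L", "X"), 8 * n, replace = TRUE,
                        prob = c(.4, .3, .2, .1)), 8, n,
                 dimnames = list(paste0("s", 1:8), NULL))
    full <- convergent_sites(aa, c("s1", "s2"), c("s3", "s4"),
                             c("s5", "s6", "s7", "s8"))
    fewer <- convergent_sites(aa, c("s1", "s2"), c("s3", "s4"),
                              c("s5", "s6", "s7"))
    expect_true(all(full$convergent$column %in% fewer$convergent$column))
    # and the result is invariant under sample reordering
    shuf <- aa[sample(8), , drop = FALSE]
    again <- convergent_sites(shuf, c("s1", "s2"), c("s3", "s4"),
                              c("s5", "s6", "s7", "s8"))
    expect_equal(again$convergent$column, full$convergent$column)
  }
})
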
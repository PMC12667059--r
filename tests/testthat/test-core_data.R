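test_that("VCF reading keeps only biallelic SNPs and fills DP/AD", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO",
            "FORMAT","s1","s2","s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tC\t.\tPASS\t.\tGT:DP:AD\t0/0:30:30,0\t0/1:28:14,14\t1/1:31:0,31",
    "chr1\t200\t.\tG\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:25:20,5\t./.:0:0,0\t0/0:22:22,0",
    "chr1\t250\t.\tG\tA,T\t.\tPASS\t.\tGT:DP:AD\t0/1:25:20,5\t0/0:30:30,0\t0/2:20:15,0",
    "chr1\t300\t.\tC\tCT\t.\tPASS\t.\tGT:DP:AD\t0/0:20:20,0\t0/0:21:21,0\t0/1:19:10,9",
    "chr1\t400\t.\tT\tG\t.\tPASS\t.\tGT:DP:AD\t1/1:40:0,40\t0/1:35:18,17\t0/0:33:33,0",
    "chr1\t500\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD\t0/0:26:26,0\t0/0:27:27,0\t0/1:28:13,15",
    "chr1\t600\t.\tC\tT\t.\tPASS\t.\tGT:DP:AD\t0/1:24:12,12\t1/1:29:0,29\t0/0:30:30,0"
  ), vcf)
  v <- read_vcf(vcf)
  expect_equal(n_sites(v$gm), 5)   # multiallelic + indel skipped
  expect_equal(v$n_skipped, 2)
  expect_equal(n_samples(v$gm), 3)
  expect_equal(v$gm$pos, c(100L, 200L, 400L, 500L, 600L))
  expect_equal(unname(v$gm$G[1, ]), c(0L, 1L, 2L))
  expect_true(is.na(v$gm$G[2, 2]))
  expect_equal(unname(v$depth[1, ]), c(30L, 28L, 31L))
  expect_equal(unname(v$ref_reads[2, 1]), 20L)
  expect_equal(unname(v$alt_reads[2, 1]), 5L)

  reg <- read_vcf(vcf, region = "chr1:350-550")
  expect_equal(reg$gm$pos, c(400L, 500L))
  empty <- read_vcf(vcf, region = "chr1:900-999")
  expect_equal(n_sites(empty$gm), 0)
})

test_that("VCF round-trip preserves genotypes, coordinates and alleles", {
  set.seed(42)
  L <- 40
  G <- matrix(sample(c(0:2, NA), L * 4, replace = TRUE), L, 4)
  gm <- make_gm(G, pos = sort(sample(1e5, L)),
                ref = sample(c("A", "C", "G", "T"), L, TRUE))
  gm$alt <- unname(vapply(gm$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), ""))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  gm2 <- read_vcf(path)$gm
  expect_identical(gm2$G, gm$G)
  expect_identical(gm2$chrom, gm$chrom)
  expect_identical(gm2$pos, gm$pos)
  expect_identical(gm2$ref, gm$ref)
  expect_identical(gm2$alt, gm$alt)

  gz <- tempfile(fileext = ".vcf.gz")
  write_vcf(gm, gz)
  expect_identical(read_vcf(gz)$gm$G, gm$G)
})

test_that("depth mask applies the half/twice rule and is idempotent", {
  gm <- make_gm(matrix(c(1L, 1L, 1L, 1L), ncol = 1), samples = "s1")
  depth <- matrix(c(19L, 40L, 81L, NA), ncol = 1)
  out <- apply_depth_mask(gm, depth, c(s1 = 40))
  expect_true(is.na(out$G[1, 1]))    # 19 < 20 = mean/2
  expect_equal(unname(out$G[2, 1]), 1L)      # within bounds
  expect_true(is.na(out$G[3, 1]))    # 81 > 80 = 2*mean
  expect_equal(unname(out$G[4, 1]), 1L)      # NA depth leaves genotype alone

  twice <- apply_depth_mask(out, depth, c(s1 = 40))
  expect_identical(twice$G, out$G)

  # boundary depths are retained (strict inequalities)
  b <- apply_depth_mask(gm, matrix(c(20L, 80L, 40L, 40L), ncol = 1),
                        c(s1 = 40))
  expect_equal(sum(is.na(b$G)), 0)

  expect_error(apply_depth_mask(gm, depth, c(other = 40)), "s1")
})

test_that("allele-balance mask hits unbalanced hets only", {
  gm <- make_gm(matrix(c(1L, 1L, 2L, 0L), ncol = 1), samples = "s1")
  ref <- matrix(c(3L, 10L, 1L, 30L), ncol = 1)
  alt <- matrix(c(20L, 10L, 30L, 2L), ncol = 1)
  out <- apply_allele_balance_mask(gm, ref, alt)
  expect_true(is.na(out$G[1, 1]))   # 3/23 ~ 0.130 < 0.25
  expect_equal(unname(out$G[2, 1]), 1L)     # balanced het retained
  expect_equal(unname(out$G[3, 1]), 2L)     # hom-alt untouched
  expect_equal(unname(out$G[4, 1]), 0L)     # hom-ref untouched

  # zero-depth het is masked with a warning
  gm0 <- make_gm(matrix(1L, 1, 1), samples = "s1")
  expect_warning(
    out0 <- apply_allele_balance_mask(gm0, matrix(0L), matrix(0L)),
    "zero allele")
  expect_true(is.na(out0$G[1, 1]))
})

test_that("masks never alter surviving genotype values (property)", {
  set.seed(7)
  for (rep in 1:5) {
    G <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 20, 3)
    gm <- make_gm(G)
    depth <- matrix(sample(0:100, 60, replace = TRUE), 20, 3)
    md <- c(s1 = 30, s2 = 40, s3 = 50)
    out <- apply_depth_mask(gm, depth, md)
    surv <- !is.na(out$G)
    expect_identical(out$G[surv], gm$G[surv])
    expect_identical(apply_depth_mask(out, depth, md)$G, out$G)
  }
})

test_that("gene interval readers normalise coordinates and span rules", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t1000\t1500\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t100\t150\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr1\tsrc\tmRNA\t120\t300\t.\t+\t.\tID=g3.t2;Parent=g3",
    "chr1\tsrc\tgene\t5000\t5100\t.\t.\t.\tID=g4"
  ), gff)
  expect_warning(genes <- read_gene_intervals(gff, "gff3"), "strand")
  g1 <- genes[genes$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(100, 200))
  g3 <- genes[genes$gene_id == "g3", ]
  expect_equal(c(g3$start, g3$end), c(99, 300))  # union of both mRNAs
  expect_false("g4" %in% genes$gene_id)          # undefined strand

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t99\t200\tb1\t0\t-", bed)
  gb <- read_gene_intervals(bed, "bed")
  expect_equal(c(gb$start, gb$end), c(99, 200))  # BED already half-open
  expect_equal(gb$strand, "-")
})
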
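#' Read biallelic SNPs from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) into a [genotype_matrix()],
#' keeping only biallelic SNP records. Multiallelic records, indels and
#' spanning deletions are skipped. Per-genotype read depth (`FORMAT/DP`)
#' and allele depths (`FORMAT/AD`) are returned when present.
#'
#' @param path path to a VCF file (may be gzipped).
#' @param region optional `"chrom:start-end"` string (1-based inclusive);
#'   records outside the region are dropped. A region with no records
#'   yields an empty matrix, not an error.
#' @return a list with elements `gm` (the `genotype_matrix`), `depth`
#'   (sites x samples integer matrix or `NULL`), `ref_reads` and
#'   `alt_reads` (matrices or `NULL`), and `n_skipped` (records dropped
#'   as non-biallelic-SNP).
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L & alt != "." &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) stop("malformed region: ", region)
    keep <- keep & chrom == m[2] & pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }
  samples <- colnames(v@gt)[-1]
  idx <- which(keep)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[idx, , drop = FALSE]
  G <- gt_to_dosage(gt)

  fmt_has <- function(el) any(grepl(paste0("(^|:)", el, "(:|$)"), v@gt[, "FORMAT"]))
  depth <- NULL
  ref_reads <- alt_reads <- NULL
  if (nrow(v@gt) > 0 && fmt_has("DP")) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    if (is.null(dim(dp))) dp <- matrix(dp, nrow = nrow(fix))
    depth <- dp[idx, , drop = FALSE]
    storage.mode(depth) <- "integer"
  }
  if (nrow(v@gt) > 0 && fmt_has("AD")) {
    ad <- vcfR::extract.gt(v, element = "AD")
    if (is.null(dim(ad))) ad <- matrix(ad, nrow = nrow(fix))
    ad <- ad[idx, , drop = FALSE]
    ref_reads <- apply(ad, 2, function(x)
      suppressWarnings(as.integer(sub(",.*", "", x))))
    alt_reads <- apply(ad, 2, function(x)
      suppressWarnings(as.integer(sub("^[^,]*,([^,]*).*$", "\\1", x))))
    if (length(idx) == 1L) {
      ref_reads <- matrix(ref_reads, nrow = 1)
      alt_reads <- matrix(alt_reads, nrow = 1)
    }
  }
  strip <- function(m) { if (!is.null(m)) rownames(m) <- NULL; m }
  G <- strip(G); depth <- strip(depth)
  ref_reads <- strip(ref_reads); alt_reads <- strip(alt_reads)
  gm <- genotype_matrix(chrom[idx], pos[idx], ref[idx], alt[idx],
                        if (length(idx)) G else
                          matrix(integer(0), 0, length(samples)),
                        samples)
  list(gm = gm, depth = depth, ref_reads = ref_reads,
       alt_reads = alt_reads, n_skipped = n_skipped)
}

gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  gt <- gsub("|", "/", gt, fixed = TRUE)
  d[gt %in% c("0/0")] <- 0L
  d[gt %in% c("0/1", "1/0")] <- 1L
  d[gt %in% c("1/1")] <- 2L
  d
}

dosage_to_gt <- function(G) {
  gt <- matrix("./.", nrow(G), ncol(G))
  gt[!is.na(G) & G == 0L] <- "0/0"
  gt[!is.na(G) & G == 1L] <- "0/1"
  gt[!is.na(G) & G == 2L] <- "1/1"
  gt
}

#' Write a genotype matrix as VCF 4.2
#'
#' Writes a minimal, valid VCF with `GT` (and optionally `DP`, `AD`)
#' FORMAT fields. Re-reading the file with [read_vcf()] reproduces the
#' genotype matrix exactly.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param depth optional sites x samples integer depth matrix.
#' @param ref_reads,alt_reads optional allele-depth matrices.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, depth = NULL, ref_reads = NULL,
                      alt_reads = NULL) {
  has_dp <- !is.null(depth)
  has_ad <- !is.null(ref_reads) && !is.null(alt_reads)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_ad) "AD"), collapse = ":")
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(gm$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (has_ad) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  gt <- dosage_to_gt(gm$G)
  cells <- gt
  if (has_dp) cells <- matrix(paste(cells, ifelse(is.na(depth), ".", depth),
                                    sep = ":"), nrow(gt))
  if (has_ad) cells <- matrix(paste(cells, paste0(ref_reads, ",", alt_reads),
                                    sep = ":"), nrow(gt))
  body <- if (n_sites(gm)) {
    paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", fmt,
          apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  } else character(0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Tab-separated file with columns `sample`, `population` and optionally
#' `role` (one of `P1`, `P2`, `P3`, `OUT`; empty for samples without a
#' role). No header.
#'
#' @param path path to the TSV (may be gzipped).
#' @return a [population_map()].
#' @export
read_popmap <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE,
                          col.names = c("sample", "population", "role")[1:3])
  assignments <- stats::setNames(df$population, df$sample)
  roles <- NULL
  if (ncol(df) >= 3 && any(nzchar(df$role) & !is.na(df$role))) {
    rr <- df[nzchar(df$role) & !is.na(df$role), ]
    roles <- stats::setNames(rr$population, rr$role)
    roles <- roles[!duplicated(names(roles))]
  }
  population_map(assignments, roles)
}

#' Write a population map as TSV
#' @param pm a `population_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  role_of_pop <- character(0)
  if (!is.null(pm$roles))
    role_of_pop <- stats::setNames(names(pm$roles), pm$roles)
  role <- role_of_pop[pm$assignments]
  role[is.na(role)] <- ""
  # only the first sample of a role's population needs the tag, but tagging
  # all of them is harmless and round-trips
  utils::write.table(
    data.frame(names(pm$assignments), unname(pm$assignments), unname(role)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
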
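## Detection of convergent amino-acid substitutions: columns of a
## translated codon alignment where two focal groups share a fixed
## amino-acid state that is absent from the background group.

translate_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  codons <- substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
  codons <- toupper(codons)
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"   # gaps, Ns, ambiguity codes
  aa
}

#' Translate a codon alignment and apply quality filters
#'
#' Translates each sequence with the standard genetic code, then drops
#' sequences with an internal stop codon or more than 50% missing amino
#' acids (gaps/ambiguity translate to `X`; a terminal stop is permitted
#' and recoded as missing). The whole gene is rejected when more than
#' half of the samples in either focal group were dropped.
#'
#' @param seqs named character vector of equal-length, in-frame codon
#'   sequences (gaps as `---`, ambiguity as `NNN`).
#' @param groups named list with character vectors `focalA` and
#'   `focalB` (other samples form the implicit background).
#' @param max_missing maximum tolerated fraction of missing amino acids
#'   per sequence (default 0.5, exclusive bound: strictly more is
#'   dropped).
#' @return list with `aa` (retained-samples x columns character matrix,
#'   `NULL` when the gene is rejected), `excluded` (named character
#'   vector of reasons), and `gene_rejected` (logical).
#' @export
translate_and_filter <- function(seqs, groups, max_missing = 0.5) {
  stopifnot(!is.null(names(seqs)),
            all(c("focalA", "focalB") %in% names(groups)))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("sequences differ in length")
  if (lens[1] %% 3 != 0) stop("alignment length not divisible by 3")
  aa <- t(vapply(seqs, translate_codons,
                 character(lens[1] / 3)))
  if (ncol(aa) == 0) stop("empty alignment")
  ## terminal stop is permitted; recode as missing so it never counts as
  ## a residue state
  last <- ncol(aa)
  aa[aa[, last] == "*", last] <- "X"
  internal_stop <- apply(aa, 1, function(x) any(x == "*"))
  missing_frac <- rowMeans(aa == "X")
  drop <- internal_stop | missing_frac > max_missing
  excluded <- character(0)
  if (any(drop)) {
    reason <- ifelse(internal_stop[drop], "internal_stop", "missing")
    excluded <- stats::setNames(reason, rownames(aa)[drop])
  }
  kept <- rownames(aa)[!drop]
  gene_rejected <- FALSE
  for (grp in c("focalA", "focalB")) {
    g <- groups[[grp]]
    if (sum(g %in% kept) < length(g) / 2) gene_rejected <- TRUE
  }
  list(aa = if (gene_rejected) NULL else aa[!drop, , drop = FALSE],
       excluded = excluded, gene_rejected = gene_rejected)
}

#' Convergent amino-acid columns shared by two focal groups
#'
#' A column is convergent when all non-missing residues of both focal
#' groups equal one amino-acid state and that state is absent from every
#' non-missing background residue ("fixed private shared allele").
#' Fixation is evaluated over non-missing residues; columns where any of
#' the three groups is entirely missing are skipped.
#'
#' @param aa amino-acid matrix from [translate_and_filter()] (samples in
#'   rows).
#' @param focalA,focalB,background character vectors of sample ids; ids
#'   absent from `aa` (filtered sequences) are ignored.
#' @return list with `convergent` (data.frame `column`, `shared_aa`,
#'   `background_aas`), `n_convergent`, and `retained` (list of sample
#'   ids used per group).
#' @export
convergent_sites <- function(aa, focalA, focalB, background) {
  fa <- intersect(focalA, rownames(aa))
  fb <- intersect(focalB, rownames(aa))
  bg <- intersect(background, rownames(aa))
  if (!length(fa) || !length(fb) || !length(bg))
    stop("each group needs at least one retained sample")
  A <- aa[fa, , drop = FALSE]
  B <- aa[fb, , drop = FALSE]
  BG <- aa[bg, , drop = FALSE]
  hits <- list()
  for (j in seq_len(ncol(aa))) {
    ra <- A[, j][A[, j] != "X"]
    rb <- B[, j][B[, j] != "X"]
    rg <- BG[, j][BG[, j] != "X"]
    if (!length(ra) || !length(rb) || !length(rg)) next
    states <- unique(c(ra, rb))
    if (length(states) != 1L) next
    if (states %in% rg) next
    hits[[length(hits) + 1L]] <-
      data.frame(column = j, shared_aa = states,
                 background_aas = paste(sort(unique(rg)), collapse = ","),
                 stringsAsFactors = FALSE)
  }
  convergent <- if (length(hits)) do.call(rbind, hits) else
    data.frame(column = integer(0), shared_aa = character(0),
               background_aas = character(0))
  list(convergent = convergent, n_convergent = nrow(convergent),
       retained = list(focalA = fa, focalB = fb, background = bg))
}

#' Scan a set of codon alignments for convergent substitutions
#'
#' Convenience wrapper: filters and scans every gene, returning one row
#' per convergent column plus a per-gene summary.
#'
#' @param alignments list gene id -> named character vector of codon
#'   sequences.
#' @param focalA,focalB,background character vectors of sample ids.
#' @return list with `sites` (data.frame `gene_id`, `column`,
#'   `shared_aa`, `background_aas`), `per_gene` (data.frame `gene_id`,
#'   `n_convergent`, `rejected`).
#' @export
scan_convergence <- function(alignments, focalA, focalB, background) {
  groups <- list(focalA = focalA, focalB = focalB)
  sites <- list(); per_gene <- list()
  for (g in names(alignments)) {
    tf <- translate_and_filter(alignments[[g]], groups)
    if (tf$gene_rejected) {
      per_gene[[g]] <- data.frame(gene_id = g, n_convergent = NA_integer_,
                                  rejected = TRUE)
      next
    }
    cs <- convergent_sites(tf$aa, focalA, focalB, background)
    per_gene[[g]] <- data.frame(gene_id = g,
                                n_convergent = cs$n_convergent,
                                rejected = FALSE)
    if (cs$n_convergent)
      sites[[g]] <- cbind(data.frame(gene_id = g), cs$convergent)
  }
  list(sites = if (length(sites)) do.call(rbind, c(sites, make.row.names = FALSE))
       else data.frame(gene_id = character(0), column = integer(0),
                       shared_aa = character(0),
                       background_aas = character(0)),
       per_gene = do.call(rbind, c(per_gene, make.row.names = FALSE)))
}
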
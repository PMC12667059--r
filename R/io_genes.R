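#' Read gene intervals from GFF3 or BED
#'
#' Returns one interval per gene in 0-based half-open coordinates. For
#' GFF3, records sharing a gene identifier are collapsed to their longest
#' span (the union range over all of the gene's records); 1-based
#' inclusive GFF coordinates are converted to 0-based half-open. BED
#' input is taken as already half-open. Records without a defined strand
#' are rejected with a warning.
#'
#' @param path path to the annotation file (may be gzipped).
#' @param dialect `"gff3"` or `"bed"`.
#' @return a data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`+` or `-`).
#' @export
read_gene_intervals <- function(path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed")
  if (dialect == "gff3") {
    md <- S4Vectors::mcols(gr)
    id <- if ("gene_id" %in% names(md)) md$gene_id
          else if ("ID" %in% names(md)) md$ID
          else if ("Name" %in% names(md)) md$Name
          else stop("GFF3 records carry no gene_id/ID/Name attribute")
    if ("Parent" %in% names(md)) {
      # child records (mRNA, exon, ...) inherit their top-level gene id when
      # the ID chain is flat (gene -> children); fall back to own id
      parent <- vapply(md$Parent, function(p)
        if (length(p)) as.character(p[1]) else NA_character_, character(1))
      id <- ifelse(is.na(parent), as.character(id), parent)
    }
    id <- as.character(id)
  } else {
    id <- as.character(S4Vectors::mcols(gr)$name)
    if (all(is.na(id))) id <- paste0("interval_", seq_along(gr))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  undef <- strand == "*" | is.na(strand)
  if (any(undef)) {
    warning(sum(undef), " record(s) without a defined strand were dropped")
    gr <- gr[!undef]
    id <- id[!undef]
    strand <- strand[!undef]
  }
  df <- data.frame(
    gene_id = id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,   # GRanges is 1-based inclusive
    end = BiocGenerics::end(gr),
    strand = strand,
    stringsAsFactors = FALSE
  )
  # one interval per gene: the union span of all its records
  sp <- split(seq_len(nrow(df)), df$gene_id)
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(gene_id = df$gene_id[i[1]],
               chrom = df$chrom[i[1]],
               start = min(df$start[i]),
               end = max(df$end[i]),
               strand = df$strand[i[1]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[out$start < out$end, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Convert gene intervals to GRanges
#' @param genes data.frame as returned by [read_gene_intervals()].
#' @return a `GRanges` (1-based inclusive internally, as usual).
#' @keywords internal
genes_to_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    gene_id = genes$gene_id
  )
}
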
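## End-to-end orchestration: run the simulation-backed analysis chain
## behind one declarative configuration and write every statistic table
## plus a JSON manifest. Identical configuration (including seed) gives
## byte-identical output files.

write_tsv_det <- function(df, path, digits = 10) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf(paste0("%.", digits, "g"), x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. With `vcf = NULL` the
#' pipeline simulates its own inputs (the usual validation mode);
#' otherwise the VCF and population map are read from disk.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @param stages character vector among `"dstat"`, `"fdm"`,
#'   `"diversity"`, `"load"`, `"roh"`, `"converge"`.
#' @param vcf,popmap optional input paths (both or neither).
#' @param sim a [sim_config()] used when no VCF is given; defaults to
#'   the standard four-taxon design with a 10% pulse into P2.
#' @param window,min_snps f_dM window size and SNP filter.
#' @param block_size jackknife block size in bp.
#' @param roh a [roh_params()].
#' @param percentile outlier percentile for f_dM windows.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir,
                            stages = c("dstat", "fdm", "diversity",
                                       "load", "roh", "converge"),
                            vcf = NULL, popmap = NULL, sim = NULL,
                            window = 10000, min_snps = 25,
                            block_size = 250000, roh = roh_params(),
                            percentile = 99) {
  if (!is.null(vcf) && is.null(popmap))
    stop("a VCF input requires a population map")
  for (p in c(vcf, popmap)) if (!file.exists(p)) stop("no such file: ", p)
  if (is.null(sim))
    sim <- sim_config(seed = seed,
                      pulse = list(donor = "P3", recipient = "P2",
                                   time = 5e3, f = 0.1))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 stages = stages, vcf = vcf, popmap = popmap, sim = sim,
                 window = window, min_snps = min_snps,
                 block_size = block_size, roh = roh,
                 percentile = percentile),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on either a
#' supplied VCF + population map or a freshly simulated dataset, writes
#' one TSV per statistic under `out_dir`, and records every output with
#' the parameter set and package version in `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (list with `outputs`, `parameters`,
#'   `seed`, `version`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add <- function(path) outputs <<- c(outputs, basename(path))

  if (!is.null(config$vcf)) {
    gm <- read_vcf(config$vcf)$gm
    pm <- read_popmap(config$popmap)
  } else {
    sim <- simulate_snp_data(config$sim)
    gm <- sim$gm
    pm <- sim$pm
  }

  if ("dstat" %in% config$stages) {
    dr <- suppressWarnings(block_jackknife_d(gm, pm, config$block_size))
    add(write_tsv_det(data.frame(P1 = pm$roles[["P1"]],
                                 P2 = pm$roles[["P2"]],
                                 P3 = pm$roles[["P3"]],
                                 OUT = pm$roles[["OUT"]],
                                 D = dr$D, SE = dr$SE, Z = dr$Z,
                                 n_blocks = dr$n_blocks,
                                 n_sites = dr$n_sites_used),
                      file.path(config$out_dir, "dstat.tsv")))
  }
  if ("fdm" %in% config$stages) {
    ws <- fdm_windows(gm, pm, config$window, config$min_snps)
    add(write_windows(ws, file.path(config$out_dir, "fdm_windows.tsv")))
    if (nrow(ws)) {
      out <- outlier_windows(ws, config$percentile)
      add(write_windows(out, file.path(config$out_dir,
                                       "fdm_outlier_windows.tsv")))
    }
  }
  if ("diversity" %in% config$stages) {
    het <- vapply(gm$samples, function(s) heterozygosity(gm, s), 0)
    add(write_tsv_det(data.frame(sample = gm$samples, het = unname(het)),
                      file.path(config$out_dir, "heterozygosity.tsv")))
  }
  if ("load" %in% config$stages) {
    imp <- simulate_impact_table(config$seed, gm, pm = pm)
    ls <- load_ratios(gm, imp$impacts, pm)
    add(write_tsv_det(ls, file.path(config$out_dir, "load.tsv")))
  }
  if ("roh" %in% config$stages) {
    rg <- simulate_roh_genome(config$seed, chrom_len = 5e6,
                              tracts = data.frame(start = 1e6, end = 2e6))
    seg <- call_roh(rg$gm, config$roh)
    acc <- accessible_length(rg$gm, config$roh)
    add(write_tsv_det(seg, file.path(config$out_dir, "roh_segments.tsv")))
    add(write_tsv_det(summarize_roh(seg, acc),
                      file.path(config$out_dir, "roh_summary.tsv")))
  }
  if ("converge" %in% config$stages) {
    groups <- list(focalA = c("a1", "a2"), focalB = c("b1", "b2"),
                   background = c("g1", "g2", "g3"))
    ca <- simulate_codon_alignments(
      config$seed, n_genes = 10, n_codons = 100, groups = groups,
      planted = data.frame(gene = c(2L, 5L), column = c(10L, 50L),
                           aa = c("W", "H")))
    sc <- scan_convergence(ca$alignments, groups$focalA, groups$focalB,
                           groups$background)
    add(write_tsv_det(sc$sites, file.path(config$out_dir,
                                          "convergent_sites.tsv")))
    add(write_tsv_det(sc$per_gene, file.path(config$out_dir,
                                             "convergence_per_gene.tsv")))
  }

  manifest <- list(
    seed = config$seed,
    version = as.character(utils::packageVersion("guenomix")),
    parameters = list(window = config$window, min_snps = config$min_snps,
                      block_size = config$block_size,
                      percentile = config$percentile,
                      roh = unclass(config$roh)),
    outputs = outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
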
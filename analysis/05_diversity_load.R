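#!/usr/bin/env Rscript
# Per-sample heterozygosity, derived-allele polarization and mutation
# load. Load is the count of moderate- or high-impact derived alleles
# relative to synonymous derived alleles; the generator's truth counts
# let us verify the bookkeeping exactly.

suppressMessages(library(guenomix))

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_snp_data(sim_config(
  seed = 1L, seq_len = 5e6,
  pulse = list(donor = "P3", recipient = "P2", time = 5e3, f = 0.1)))
imp <- simulate_impact_table(101L, sim$gm, pm = sim$pm)

focal <- setdiff(sim$gm$samples, pm_samples(sim$pm, "OUT"))
het <- vapply(focal, function(s) heterozygosity(sim$gm, s), 0)
ls <- load_ratios(sim$gm, imp$impacts, sim$pm)
ls$het <- unname(het[ls$sample])
write.table(format(ls, digits = 6), file.path(out, "diversity_load.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("per-sample heterozygosity and load ratios:")
for (i in seq_len(nrow(ls)))
  message(sprintf("  %-6s H = %.4f  load_moderate = %.3f  load_high = %.3f",
                  ls$sample[i], ls$het[i], ls$load_moderate[i],
                  ls$load_high[i]))

err <- max(abs(cbind(ls$derived_synonymous, ls$derived_moderate,
                     ls$derived_high) -
               imp$truth[ls$sample, c("synonymous", "moderate", "high")]))
message("max |count - generator truth| = ", err)

# per-category heterozygosity for one sample
h_by <- heterozygosity_by_impact(sim$gm, imp$impacts,
                                 sample = focal[1])
message(sprintf("per-category H for %s: %s", focal[1],
                paste(names(h_by), sprintf("%.4f", h_by),
                      collapse = ", ", sep = " = ")))
message("With impact labels assigned independently of genotype, the",
        " per-category H values coincide up to sampling noise, as expected.")
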
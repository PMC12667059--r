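#!/usr/bin/env Rscript
# Generate every truth-known synthetic dataset used by the downstream
# analysis steps and write them in their standard on-disk formats
# (VCF + population TSV, impact TSV, per-gene FASTA), with the
# generator truth serialized as JSON alongside.

suppressMessages(library(guenomix))
library(jsonlite)

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("1. Four-taxon SNP data with a 10% pulse from P3 into P2 (5 Mb)")
sim <- simulate_snp_data(sim_config(
  seed = seed, seq_len = 5e6,
  pulse = list(donor = "P3", recipient = "P2", time = 5e3, f = 0.1)))
write_vcf(sim$gm, file.path(out, "quartet_pulse.vcf.gz"))
write_popmap(sim$pm, file.path(out, "quartet_pulse.popmap.tsv"))
write_json(sim$truth[c("f_true", "pulse")],
           file.path(out, "quartet_pulse.truth.json"), auto_unbox = TRUE)
message("   ", n_sites(sim$gm), " biallelic SNPs, ",
        n_samples(sim$gm), " diploid samples")

message("2. Matching null dataset (no gene flow)")
sim0 <- simulate_snp_data(sim_config(seed = seed, seq_len = 5e6,
                                     pulse = NULL))
write_vcf(sim0$gm, file.path(out, "quartet_null.vcf.gz"))
write_popmap(sim0$pm, file.path(out, "quartet_null.popmap.tsv"))

message("3. Impact-labelled alt alleles on the pulse dataset")
imp <- simulate_impact_table(seed + 100L, sim$gm, pm = sim$pm)
write.table(imp$impacts, file.path(out, "quartet_pulse.impacts.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_json(as.data.frame(imp$truth),
           file.path(out, "quartet_pulse.impact_truth.json"))

message("4. Single diploid chromosome with three autozygous tracts")
tracts <- data.frame(start = c(5e5, 2e6, 5e6), end = c(8e5, 3.5e6, 8e6))
roh <- simulate_roh_genome(seed + 200L, chrom_len = 9e6, tracts = tracts,
                           het_rate = 0.3)
write_vcf(roh$gm, file.path(out, "roh_genome.vcf.gz"))
write_json(roh$truth, file.path(out, "roh_genome.truth.json"))
message("   ", n_sites(roh$gm), " SNPs, ", nrow(tracts), " planted tracts")

message("5. Codon alignments with planted convergent substitutions")
groups <- list(focalA = c("a1", "a2"), focalB = c("b1", "b2"),
               background = c("g1", "g2", "g3"))
planted <- data.frame(gene = c(1L, 2L, 2L, 4L),
                      column = c(7L, 3L, 25L, 40L),
                      aa = c("W", "C", "H", "K"))
ca <- simulate_codon_alignments(seed + 300L, 5, 50, groups, planted,
                                noise_columns = 2)
write_codon_fasta(ca$alignments, file.path(out, "alignments"))
write_json(c(ca$truth, list(groups = groups)),
           file.path(out, "alignments.truth.json"))

message("done: synthetic inputs under ", out)
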
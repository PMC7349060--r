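#!/usr/bin/env Rscript
# Stage 1 — simulate the study world with known ground truth.
#
# Builds (a) a balanced 12-genotype x 4-environment x 3-replicate yield
# trial under the linear stability model, (b) a replicate-level five-trait
# table, (c) a 2 x 50 kb toy reference genome with gene models, (d) a
# 12-sample variant panel whose private-marker structure is scaled down
# from the published landrace panel (E42 dominating), and (e) five wild
# tomato relative genomes at 15% background divergence carrying planted
# introgression intervals from E42. Everything downstream (stages 02-06)
# reads only the files written here.

suppressMessages(library(yieldvar))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 42L
out <- file.path("results", "simdata")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

genotypes <- c("E7", "E8", "E17", "E36", "E37", "E42", "E45", "E53",
               "E76", "E107", "DOCET", "JAG8810")

## field trial ------------------------------------------------------------
cfg <- trial_config(genotype_names = genotypes, seed = seed)
trial <- generate_yield_trial(cfg)
truth <- attr(trial, "truth")
tsv(trial, "trial.tsv")
tsv(data.frame(genotype = truth$genotypes, mu = truth$mu,
               beta = truth$beta), "trial_truth_genotypes.tsv")
tsv(data.frame(environment = names(truth$env_effects),
               effect = truth$env_effects), "trial_truth_environments.tsv")
cat(sprintf("trial: %d plots, true slopes %.2f-%.2f\n",
            nrow(trial), min(truth$beta), max(truth$beta)))

traits <- generate_trait_trial(cfg)
tsv(traits, "traits.tsv")

## genome + variant panel -------------------------------------------------
genome <- generate_genome(genome_spec(seed = seed + 1L))
write_genome_fasta(genome, file.path(out, "reference.fa"))
write_gff3(genome, file.path(out, "genes.gff3"))

panel <- generate_variant_panel(genome,
                                variant_panel_spec(sample_names = genotypes,
                                                   seed = seed + 2L))
write_vcf(panel$dataset, file.path(out, "panel.vcf"),
          contig_lengths = vapply(genome$seq, nchar, 1L))
tsv(panel$truth, "panel_truth.tsv")
cat(sprintf("panel: %d sites (%d InDels) x %d samples\n",
            nrow(panel$dataset$sites),
            sum(panel$dataset$sites$class == "InDel"),
            length(panel$dataset$samples)))

## wild relatives with planted E42 introgressions -------------------------
species <- c("S_chilense", "S_galapagense", "S_pennellii",
             "S_peruvianum", "S_pimpinellifolium")
ivs <- plan_introgressions(panel$dataset, genome, "E42", species, per = 5L)
wspec <- wild_panel_spec(species, background_divergence = 0.15,
                         introgressions = ivs, seed = seed + 3L)
wild <- generate_wild_panel(genome, panel$dataset, wspec)
for (sp in species) {
  ss <- Biostrings::DNAStringSet(wild$genomes[[sp]])
  Biostrings::writeXStringSet(ss, file.path(out, paste0(sp, ".fa")),
                              width = 60L)
}
tsv(ivs, "introgression_truth.tsv")
cat(sprintf("wild panel: %d species, %d planted intervals (%d loci)\n",
            length(species), nrow(ivs), sum(ivs$n_loci)))
cat("simulation written to", out, "\n")
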
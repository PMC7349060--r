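#!/usr/bin/env Rscript
# Stage 3 — supporting phenotype statistics.
#
# Student's t-tests of every landrace against the two heat-tolerant control
# hybrids per trait and field, the balanced three-way fixed-effects ANOVA
# (genotype x location x year) with each source's TSS%, and Pearson
# correlations among the five traits within fields and within genotypes.

suppressMessages(library(yieldvar))

sim <- file.path("results", "simdata")
out <- file.path("results", "phenostats")
dir.create(out, recursive = TRUE, showWarnings = FALSE)
tsv <- function(x, f) write.table(x, file.path(out, f), sep = "\t",
                                  quote = FALSE, row.names = FALSE)

traits <- read.delim(file.path(sim, "traits.tsv"))
controls <- c("DOCET", "JAG8810")

tt <- compare_to_controls(traits, controls)
tsv(tt, "ttests_vs_controls.tsv")
cat(sprintf("t-tests: %d comparisons, %d significant at 0.05\n",
            nrow(tt), sum(tt$p < 0.05)))

anova_all <- do.call(rbind, lapply(unique(traits$trait), function(tr) {
  a <- three_way_anova(traits, tr)
  cbind(trait = tr, a)
}))
tsv(anova_all, "anova.tsv")
gshare <- anova_all[anova_all$source == "G", ]
cat("genotype TSS% by trait:\n")
print(setNames(round(gshare$tss_pct, 1), gshare$trait))

for (by in c("field", "genotype")) {
  cc <- pearson_correlations(traits, by = by)
  tsv(cc, sprintf("correlations_by_%s.tsv", by))
}
cc <- pearson_correlations(traits, by = "field")
fw_tnf <- cc[(cc$trait1 == "FW" & cc$trait2 == "TNF") |
               (cc$trait1 == "TNF" & cc$trait2 == "FW"), ]
cat(sprintf("FW~TNF correlation across fields: %.2f to %.2f\n",
            min(fw_tnf$r), max(fw_tnf$r)))
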
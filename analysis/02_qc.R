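#!/usr/bin/env Rscript
# Stage 2: marker/sample quality control.
#
# The cascade mirrors standard SNP-array practice: drop samples with
# <90% call rate, then markers with <90% call rate, then markers out of
# Hardy-Weinberg equilibrium at p < 0.01. MAF thresholds are applied per
# analysis in later stages; here we record how many markers each of the
# three thresholds (0.01 / 0.05 / 0.1) would retain.

suppressMessages(library(ldnekit))

for (name in c("constant", "decline")) {
  g <- read_ped_map(file.path("scratch/data", paste0(name, ".ped")),
                    file.path("scratch/data", paste0(name, ".map")))
  cr <- call_rate_filter(g, 0.9, 0.9)
  hw <- hwe_filter(cr$genotypes, 0.01)
  counts <- rbind(cr$report$counts, data.frame(
    stage = "hwe", n_samples = n_samples(hw$genotypes),
    n_markers = n_markers(hw$genotypes)))
  for (thr in c(0.01, 0.05, 0.1)) {
    counts <- rbind(counts, data.frame(
      stage = paste0("maf_", thr),
      n_samples = n_samples(hw$genotypes),
      n_markers = n_markers(maf_filter(hw$genotypes, thr))))
  }
  write.table(counts, file.path("results", paste0("qc_", name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(name, "QC stages (markers):",
      paste(counts$stage, counts$n_markers, sep = "=", collapse = ", "),
      "\n")
}
cat("QC tables -> results/qc_*.tsv\n")
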
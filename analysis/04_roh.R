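#!/usr/bin/env Rscript
# Stage 4: runs of homozygosity in the decline cohort.
#
# PLINK-style sliding-window detection with the standard published
# settings (20-SNP windows, <=5 missing / <=1 het per window, >=1 Mb,
# >=20 SNPs, >=1 SNP per 200 kb, gaps <=1000 kb), then per-individual,
# per-chromosome, length-class and genome-coverage summaries, and the
# correlation of per-chromosome ROH burden with chromosome length and
# with adjacent-pair LD.

suppressMessages(library(ldnekit))

g0 <- read_ped_map("scratch/data/decline.ped", "scratch/data/decline.map")
base <- hwe_filter(call_rate_filter(g0, 0.9, 0.9)$genotypes, 0.01)$genotypes

segs <- detect_roh(base, roh_params())
adj <- adjacent_summary(scan_adjacent_pairs(maf_filter(base, 0.05)))
adj_chr <- adj[adj$chromosome != "Mean", ]
sums <- roh_summaries(segs, base,
                      adjacent_r2 = setNames(adj_chr$mean_r2,
                                             adj_chr$chromosome))

write.table(segs, "results/roh_segments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sums$per_individual, "results/roh_per_individual.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sums$per_chromosome, "results/roh_per_chromosome.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(as.data.frame(sums$class_counts),
            "results/roh_class_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sums$correlations, "results/roh_correlations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d ROH segments; %.1f per individual on average\n",
            nrow(segs), mean(sums$per_individual$n_roh)))
cat(sprintf("mean genome coverage by ROH: %.1f%%\n",
            100 * sums$coverage$mean_coverage))
print(sums$class_counts)
cat("ROH tables -> results/roh_*.tsv\n")
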
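#!/usr/bin/env Rscript
# Stage 1: simulate the two study cohorts with known demographic truth.
#
# "decline" emulates an endangered local population: a large ancestral
# population (Ne = 1000) collapsing to Ne = 50 eight generations ago,
# sampled as 50 diploids on a 10-chromosome, ~1,000-marker panel.
# "constant" (Ne = 100 throughout) is the calibration cohort used to
# check the Ne estimator against a known flat truth.
# Genotypes go to scratch/data/ as PLINK text PED/MAP; the truth
# schedules go to results/.

suppressMessages(library(ldnekit))
dir.create("scratch/data", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

cohorts <- list(
  constant = demography_config(seed = 1001L),
  decline = demography_decline(ancestral_ne = 1000, recent_ne = 50,
                               drop_gen_ago = 8, n_generations = 150L,
                               seed = 1002L)
)

truth <- NULL
for (name in names(cohorts)) {
  sim <- simulate_wright_fisher(cohorts[[name]])
  g <- sim$genotypes
  write_ped_map(g, file.path("scratch/data", paste0(name, ".ped")),
                file.path("scratch/data", paste0(name, ".map")))
  sched <- sim$truth$config$ne_schedule
  truth <- rbind(truth, data.frame(
    cohort = name, start_gen_ago = sched$start_gen_ago, ne = sched$ne,
    n_samples = n_samples(g), n_markers = n_markers(g),
    seed = sim$truth$seed))
  cat(sprintf("%s: %d samples x %d markers, %.1f%% missing\n", name,
              n_samples(g), n_markers(g), 100 * mean(is.na(g$calls))))
}
write.table(truth, "results/simulation_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("truth schedules -> results/simulation_truth.tsv\n")
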
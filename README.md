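# ldnekit

Linkage disequilibrium, runs of homozygosity and LD-based effective
population size from diploid SNP-array genotypes.

`ldnekit` is aimed at population geneticists working with medium-density
SNP panels in small or endangered livestock populations, where three
questions recur: how far does linkage disequilibrium (LD) extend (hence
what marker density association mapping needs), how much recent
inbreeding do runs of homozygosity (ROH) reveal, and what does LD decay
say about the trajectory of effective population size (Ne)?

## What it computes

**Pairwise LD.** For each syntenic marker pair closer than 50 Mb,
two-locus haplotype frequencies are estimated from unphased genotypes by
multi-start EM (only double heterozygotes are phase-ambiguous), giving

- `D = f_AB − p_A p_B`, `D' = |D| / D_max`,
  `r² = D² / (p_A q_A p_B q_B)`,
- the haplotype-count correction
  `r²_corrected = (r² − 1/n) / (1 − 1/n)`, `n` = number of haplotypes,
- 16 conventional distance bins (0–19 kb … 30,000–49,999 kb),
  adjacent-pair per-chromosome summaries, and non-syntenic background
  LD from a random marker subset.

**ROH.** PLINK-style sliding windows (20 SNPs, ≤5 missing, ≤1
heterozygote) call candidate-homozygous SNPs by hit proportion;
candidate stretches are split at gaps >1000 kb and kept if ≥1 Mb,
≥20 SNPs and ≥1 SNP/200 kb, then classified into seven length classes
and summarised per individual, per chromosome and as genome coverage.

**Ne trajectory.** Distance-binned adjusted r² (`r²_adj = r² − 1/(2N)`)
is inverted through Sved's relation `E(r²_adj) = 1/(a + 4 Ne c)` with
the mapping `f(c) = d(1 − d/2)` at 1 cM/Mb, dating each bin at
`t = 1/(2 f(c))` generations ago:

```
Ne(t) = (1 / (4 f(c))) · (1 / mean(r²_adj) − a)
```

**Synthetic truth.** A forward Wright–Fisher simulator (piecewise-
constant Ne, uniform recombination, genotype missingness) generates
PED/MAP panels with known demographic truth, so every stage above is
validated against simulations and deterministic fixtures rather than
undeposited data.

## Worked example

Simulate an endangered-population cohort (ancestral Ne 1000 collapsing
to 50 eight generations ago; 50 diploids, ~1,000 markers on 10
chromosomes), then estimate its Ne trajectory:

```r
library(ldnekit)

sim <- simulate_wright_fisher(demography_decline(
  ancestral_ne = 1000, recent_ne = 50, drop_gen_ago = 8,
  n_generations = 150L, seed = 1002L))
g <- maf_filter(sim$genotypes, 0.05)

pairs <- scan_syntenic_pairs(g)            # EM LD for every syntenic pair
traj <- ne_trajectory(pairs, n_samples(g),
                      bin_edges = ne_bin_edges(0.2e6, 10e6, 10))
round(traj[!is.na(traj$ne), c("t_generations", "mean_r2_adj", "ne")], 3)
```

The same cohort driven through the numbered scripts under `analysis/`
(simulation → QC → LD decay → ROH → Ne) prints, among other findings:

```
decline QC stages (markers): input=1000, sample_call_rate=1000,
  marker_call_rate=1000, hwe=995, maf_0.01=906, maf_0.05=839, maf_0.1=731
MAF 0.01: 906 markers, 40655 pairs; shortest occupied bin [0,20) kb
  mean r2 = 0.129 (corrected 0.120); background r2 = 0.0196
MAF 0.10: 731 markers, 26585 pairs; shortest occupied bin [0,20) kb
  mean r2 = 0.164 (corrected 0.156); background r2 = 0.0201
164 ROH segments; 3.3 per individual on average
mean genome coverage by ROH: 14.5%
decline cohort: mean Ne falls from 708 (~202 generations ago) to 57
  (~7 generations ago); truth drops 1000 -> 50 at generation 8
constant cohort (truth Ne = 100): median bin estimate 117
```

Reading these: short-range r² rises with the MAF threshold (rare
alleles dilute r²); background (non-syntenic) r² sits near the 1/n
sampling floor (1/100 = 0.01–0.02 here); the heavy ROH coverage
reflects the recent collapse to Ne = 50; and the estimated trajectory
declines toward the present, ending near the true recent Ne, while the
constant-Ne calibration cohort recovers its flat truth within sampling
error. `run_pipeline()` wraps the same stages into one call that writes
all report tables plus a run manifest.

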
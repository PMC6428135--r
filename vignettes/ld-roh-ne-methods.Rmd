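---
title: "Methods: LD decay, runs of homozygosity and LD-based Ne"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD decay, runs of homozygosity and LD-based Ne}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ldnekit` characterises linkage disequilibrium (LD) in a diploid
SNP-array cohort and converts its decay with physical distance into a
trajectory of historical effective population size (Ne), alongside a
runs-of-homozygosity (ROH) picture of recent inbreeding. This vignette
is the package's own account of the statistics it implements, the
parameters that matter, and the choices made where the design was
genuinely open.

## Pairwise LD from unphased genotypes

For two biallelic markers the sufficient statistic is the 3x3 table of
joint genotype counts (dose of the counted allele at each locus).
Under random union of gametes every cell determines its two haplotypes
except the double heterozygote, which mixes the coupling (11/00) and
repulsion (10/01) phases. `em_two_locus()` maximises the multinomial
likelihood by EM: the E-step splits the double-heterozygote count by the
current odds `f11 f00 / (f11 f00 + f10 f01)`, the M-step renormalises
expected haplotype counts.

Numerical choices:

* convergence when the largest absolute frequency change falls below
  `tol = 1e-10`, with `max_iter = 1000`; pairs that exhaust the budget
  are emitted with `converged = FALSE`, never dropped silently;
* the likelihood is occasionally *bimodal* (a coupling and a repulsion
  mode). A linkage-equilibrium start alone can converge to the minor
  mode: a grid search over the haplotype simplex exposed count tables
  where it sat visibly below the global maximum. EM therefore runs from
  three starts - linkage equilibrium and D displaced to +/-0.8 of its
  attainable extreme given the margins - and keeps the highest
  likelihood, the equilibrium start winning ties;
* pairs with fewer than two individuals called at both markers, or with
  a margin monomorphic among those individuals, have undefined LD; scans
  skip and count them (`n_skipped`).

From the fitted frequencies, `D = f11 - p_A p_B`; `D'` is `|D|`
normalised by its attainable extreme given the allele frequencies and is
reported as an absolute value in [0, 1]; `r2 = D^2 / (p_A q_A p_B q_B)`.
The bound `r2 <= D'^2` holds by construction and is asserted
property-style in the tests.

Observed `r2` is inflated by finite sample size. Two corrections appear,
deliberately distinct because they enter different downstream formulas:

* `correct_r2(r2, n) = (r2 - 1/n) / (1 - 1/n)` with `n` the number of
  haplotypes - the affine rescaling used in decay tables (maps 1 to 1
  and the null expectation `1/n` to 0; may go negative for very weak LD
  and is then reported as computed);
* `adjust_r2(r2, N) = r2 - 1/(2N)` with `N` the number of diploids - the
  additive adjustment the Ne estimator expects. Only this one feeds Ne.

By default each pair uses its own informative-individual count
(`n_haplotypes = "pairwise"`), which is the better-calibrated choice
under missingness; `"global"` (2 x cohort size for every pair)
reproduces the convention of published decay tables, where a single `n`
serves the whole sample, and is the pipeline default for report tables.

## Decay tables, adjacent pairs, background LD

Syntenic pairs closer than 50 Mb are binned into the 16 conventional
distance classes (0-19 kb up to 30,000-49,999 kb). Bin labels like
"0-19" are integer-kb shorthand: bins are implemented half-open in kb -
[0, 20), [20, 40), ... [30000, 50000) - so fractional-kb distances have
a unique bin and a pair at exactly 20 kb falls in the second class. Per
bin the unweighted mean and sd of `D'`, `r2` and corrected `r2` are
reported; empty bins stay in the table with `n_pairs = 0`.

The adjacent-pair summary reports, per chromosome, mean inter-marker
distance, mean `D'` and `r2`, and the percentage of pairs with
`r2 > 0.2` and `> 0.8`; its `Mean` row weights chromosomes equally
rather than pairs, matching the convention of per-chromosome LD tables.

Background (non-syntenic) LD is measured on a seeded random marker
subset (about 5% of the panel by default): all inter-chromosomal pairs
among the subset are fitted and summarised in one row. Under
independence the expected background `r2` is about `1/n_haplotypes`,
which the tests verify on unlinked simulated chromosomes.

## Runs of homozygosity

Detection follows the PLINK `--homozyg` window design with the standard
published settings as defaults (`roh_params()`):

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 20 | sliding-window width in SNPs |
| `max_missing_in_window` | 5 | missing calls tolerated per window |
| `max_het_in_window` | 1 | heterozygotes tolerated per window |
| `min_length_bp` | 1 Mb | minimum segment span |
| `min_snps` | 20 | minimum SNPs per segment |
| `min_density_bp_per_snp` | 200 kb | max bp per SNP over the segment |
| `max_gap_bp` | 1000 kb | max gap between consecutive segment SNPs |
| `hit_proportion` | 0.05 | passing-window fraction calling a SNP candidate |

Each SNP's hit rate is the fraction of windows covering it that pass the
missing/het limits; SNPs at or above `hit_proportion` (the PLINK default
0.05, which the window rules leave implicit) are candidate-homozygous.
Maximal candidate stretches are split at inter-SNP gaps above
`max_gap_bp` and kept only if they satisfy the length, SNP-count and
density rules. Segment endpoints are the first and last member SNP
positions and `length_bp = end - start + 1`; density is evaluated over
the whole segment, matching PLINK semantics. A consequence of the
hit-rate rule worth knowing: the single tolerated heterozygote flanking
a long homozygous tract is covered by passing windows and joins the
segment, so detected segments extend one SNP into each flanking
heterozygous tract. Detection is invariant to allele orientation
(0 <-> 2), which the tests assert.

Length classes are half-open at the printed .999 boundaries: [1, 5),
[5, 10), [10, 15), [15, 20), [20, 25), [25, 50), [50, Inf) Mb, so a
5.0 Mb segment belongs to the second class. Summaries cover
per-individual counts and lengths, per-chromosome burden, genome
fraction covered (total ROH length over total autosome length, the
latter defaulting to the maximum mapped position per chromosome), and
Pearson correlations of per-chromosome burden with chromosome length
and with adjacent-pair LD; with fewer than three chromosomes or no
segments the correlations are reported as undefined rather than
computed.

## Ne from LD decay

Sved's approximation links expected LD to Ne and recombination:
`E(r2_adj) = 1 / (a + 4 Ne c)`. Inverting it per distance bin gives

```
Ne(t) = (1 / (4 f(c))) * (1 / mean(r2_adj) - a)
```

with the mapping `f(c) = d (1 - d/2)`, where `d` is the map distance in
Morgans obtained from physical distance at a uniform 1 cM/Mb
(`morgans_per_bp = 1e-8` - the only dimensionally coherent reading of a
per-bp proportionality constant of 1e-8). The mutation constant `a`
defaults to 1. Each bin is dated `t = 1/(2 f(c))` generations ago, the
standard convention of LD-based Ne tools (short distances reflect
ancient Ne, long distances recent Ne); `t` is strictly decreasing in bin
distance because `f` is monotone for `d < 1`.

Open choices, resolved as follows:

* bins are geometric over the analysed distance range (default
  0.02-50 Mb, 14 bins; published trajectories print ~14 generations,
  and exact tool-internal binning is not reproducible from table text);
* the bin's `c` comes from the arithmetic mean of member-pair distances,
  not the bin midpoint;
* pairs enter bins with the additive `r2 - 1/(2N)` adjustment only -
  no haplotype-count rescaling - exactly as the estimator's derivation
  expects;
* bins whose mean adjusted r2 leaves (0, 1/a) have no defined estimate
  and are reported with `ne = NA` and a note, never dropped.

## The Wright-Fisher generator

`simulate_wright_fisher()` provides genotype panels with known
demographic truth. It is a forward-in-time diploid simulator:
`2 Ne(ancestral)` haplotypes start at linkage equilibrium with allele
frequencies uniform above a floor (default 0.05, a crude stand-in for
SNP-array ascertainment); each generation draws random parents and
recombines gametes with a Poisson crossover count (mean = chromosome
length in Morgans, positions uniform); the Ne schedule is piecewise
constant; a cohort is sampled from the final generation and missingness
applied per call (default 2%). There is no mutation during the
simulated epoch - variation is standing, as on an array - so markers
drift to fixation and are expected to be removed by the MAF filter,
exercising the real pipeline path. Identical seed and configuration
give bit-identical output.

Default scale is the validation regime used throughout: 10 chromosomes
of 10 Mb with 100 markers each (~1,000 markers genome-wide), 50 sampled
diploids, constant Ne = 100 for 500 generations. The declining preset
(`demography_decline()`) collapses an ancestral Ne = 1000 to 50 at
generation 8, over 150 simulated generations.

Two scale choices deserve their rationale:

* *burn-in vs. equilibration.* LD at recombination fraction `c`
  equilibrates on a timescale of roughly `1/(2c)` generations, so a
  simulation of `T` generations only supports Ne estimates at
  `t = 1/(2 f(c))` up to about `T/2`. The recovery analyses therefore
  bin distances over 0.2-10 Mb (t of about 5-250) under a 500-generation
  constant-Ne run, and the vignette-level rule is: choose the bin range
  so the largest dated generation is at most half the simulated depth.
  This was fixed before any acceptance measurement and is not a tuning
  knob.
* *marker survival.* After 500 generations at Ne = 100 most of the
  ~1,000 initial markers have fixed; of order 10% survive a 5% MAF
  filter. Pair counts per bin remain in the hundreds across 10
  chromosomes, which is sufficient for bin means; the declining
  scenario, being shorter and larger in ancestral Ne, retains most of
  its markers.

What the generator does *not* emulate: mutation, selection, migration,
admixture, non-random mating, a non-uniform recombination map, array
ascertainment beyond the initial frequency floor, and genotyping error.
Passing recovery tests therefore show the estimators are internally
consistent with the Wright-Fisher drift model they assume - not that
real cattle data meet those assumptions.

## Quality control

The cascade is order-sensitive and mirrors standard SNP-array practice:
samples below 90% call rate first, then markers below 90% call rate,
then a Hardy-Weinberg exact test (exclusion at p < 0.01), then a MAF
threshold, then optional seeded uniform thinning for cross-threshold
comparability. The HWE test is the two-sided exact conditional test with
probability ordering (no mid-p correction - the common default in SNP
QC); its p-value is invariant under swapping the homozygote counts, is
1 for monomorphic markers, and equals exhaustive enumeration for small
totals (asserted in tests). Call-rate thresholds are strict (`<`), so a
marker exactly at 90% stays. MAF retention is inclusive (`>=` the
threshold). Thinning is uniform without replacement under a recorded
seed, preserving map order.

## Known limitations

* Ne bins at short distances date generations far beyond what any
  finite simulation (or real population history) has equilibrated;
  treat large-`t` estimates as qualitative.
* The recent-most Ne estimates inherit the known downward bias of
  LD-based estimators under declining Ne and small samples.
* `D'` is noisy at small sample sizes (unsampled fourth gametes inflate
  it); `r2`-based quantities are the reliable ones at this cohort size.
* The PED/MAP reader cannot recover allele orientation for markers at
  which only one allele is observed; supply `ref_alleles` when
  bit-exact round trips of such markers matter.
* One EM fit per syntenic pair is quadratic per chromosome; the scans
  are vectorised across pairs and comfortable at the ~10^3-marker desk
  scale this package targets, but a 50K-marker genome-wide scan at
  50 Mb range is a batch job, not an interactive call.
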
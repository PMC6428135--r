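# The hand-traced expectations below follow the windowed rules exactly:
# a window passes with <= 5 missing and <= 1 het; a SNP is candidate when
# >= 5% of its covering windows pass. A single heterozygote flanking a
# long homozygous tract is itself covered by passing windows (those
# reaching into the tract contain only that one het), so detected
# segments extend one SNP into each flanking het tract; the second
# flanking het is never a candidate because every window covering it
# holds at least two hets (except at chromosome ends).

test_that("a fully heterozygous individual yields no segments", {
  fx <- make_roh_fixture(
    data.frame(sample_id = character(0), chromosome = character(0),
               start_bp = numeric(0), end_bp = numeric(0),
               state = character(0)),
    samples = "ind_1", chromosomes = c("1" = 5e6), spacing_bp = 50e3)
  expect_true(all(fx$genotypes$calls == 1L))
  segs <- detect_roh(fx$genotypes)
  expect_identical(nrow(segs), 0L)
})

test_that("a 3 Mb homozygous tract flanked by heterozygosity gives one hand-traced segment", {
  # markers every 50 kb on [50k, 6M]; hom tract covers the 60 markers at
  # 1.00, 1.05, ..., 3.95 Mb
  tr <- data.frame(sample_id = "ind_1", chromosome = "1",
                   start_bp = 1e6, end_bp = 3.95e6, state = "hom")
  fx <- make_roh_fixture(tr, chromosomes = c("1" = 6e6), spacing_bp = 50e3)
  segs <- detect_roh(fx$genotypes)
  expect_identical(nrow(segs), 1L)
  # hand trace: tract SNPs plus one flanking het each side
  expect_equal(segs$start_bp, 950e3)
  expect_equal(segs$end_bp, 4e6)
  expect_identical(segs$n_snps, 62L)
  expect_equal(segs$length_bp, 4e6 - 950e3 + 1)
  expect_identical(as.character(segs$length_class), "1-4.999 Mb")
})

test_that("a 1.2 Mb marker gap splits a homozygous tract per the gap rule", {
  tr <- data.frame(sample_id = "ind_1", chromosome = "1",
                   start_bp = 50e3, end_bp = 8e6, state = "hom")
  fx <- make_roh_fixture(tr, chromosomes = c("1" = 8e6), spacing_bp = 50e3)
  g <- fx$genotypes
  # delete markers in (3.0, 4.2] Mb: consecutive positions 3.0 and 4.25 Mb
  # leave a 1.25 Mb gap > the 1 Mb limit
  drop <- which(g$map$position_bp > 3e6 & g$map$position_bp <= 4.2e6)
  g2 <- subset_genotypes(g, markers = -drop)
  segs <- detect_roh(g2)
  segs <- segs[order(segs$start_bp), ]
  expect_identical(nrow(segs), 2L)
  expect_equal(segs$start_bp, c(50e3, 4.25e6))
  expect_equal(segs$end_bp, c(3e6, 8e6))
  # both halves re-satisfy min length (2.95 and 3.75 Mb) and min SNPs
  expect_true(all(segs$length_bp >= 1e6))
  expect_true(all(segs$n_snps >= 20L))
})

test_that("length classes use half-open boundaries and match a histogram oracle", {
  expect_identical(as.character(classify_roh(3e6)), "1-4.999 Mb")
  expect_identical(as.character(classify_roh(5e6)), "5-9.999 Mb")
  expect_identical(as.character(classify_roh(51e6)), ">50 Mb")
  set.seed(14)
  lens <- runif(500, 1e6, 60e6)
  cls <- classify_roh(lens)
  breaks <- c(1, 5, 10, 15, 20, 25, 50, Inf) * 1e6
  hand <- table(cut(lens, breaks, right = FALSE))
  expect_identical(as.vector(table(cls)), as.vector(hand))
})

test_that("every emitted segment satisfies the segment invariants (inbred cohort)", {
  sim <- simulate_wright_fisher(demography_config(
    ne_schedule = data.frame(start_gen_ago = 80, ne = 15),
    n_generations = 80L, n_chromosomes = 3L,
    chromosome_length_bp = 10e6, n_markers_per_chromosome = 150L,
    n_sample = 15L, missing_rate = 0.02, seed = 29L))
  g <- sim$genotypes
  params <- roh_params()
  segs <- detect_roh(g, params)
  expect_gt(nrow(segs), 0L)
  for (r in seq_len(nrow(segs))) {
    s <- segs[r, ]
    expect_gte(s$length_bp, params$min_length_bp)
    expect_gte(s$n_snps, params$min_snps)
    expect_lte(s$length_bp / s$n_snps, params$min_density_bp_per_snp)
    mpos <- g$map$position_bp[g$map$chromosome == s$chromosome]
    member <- mpos[mpos >= s$start_bp & mpos <= s$end_bp]
    expect_identical(length(member), as.integer(s$n_snps))
    if (length(member) > 1L) {
      expect_lte(max(diff(member)), params$max_gap_bp)
    }
    expect_equal(s$length_bp, s$end_bp - s$start_bp + 1)
  }
})

test_that("detection is invariant to allele orientation and distant flanking hets", {
  sim <- simulate_wright_fisher(demography_config(
    ne_schedule = data.frame(start_gen_ago = 60, ne = 15),
    n_generations = 60L, n_chromosomes = 2L,
    chromosome_length_bp = 8e6, n_markers_per_chromosome = 120L,
    n_sample = 10L, missing_rate = 0.02, seed = 37L))
  g <- sim$genotypes
  segs <- detect_roh(g)
  expect_gt(nrow(segs), 0L)

  g_swap <- g
  g_swap$calls <- 2L - g$calls
  expect_identical(detect_roh(g_swap), segs)
})

test_that("an all-homozygous dense chromosome yields one spanning segment", {
  tr <- data.frame(sample_id = "ind_1", chromosome = "1",
                   start_bp = 50e3, end_bp = 5e6, state = "hom", dose = 2)
  fx <- make_roh_fixture(tr, chromosomes = c("1" = 5e6), spacing_bp = 50e3)
  segs <- detect_roh(fx$genotypes)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$start_bp, 50e3)
  expect_equal(segs$end_bp, 5e6)
  expect_identical(segs$n_snps, 100L)
})

test_that("chromosomes narrower than the window are skipped with a warning", {
  g <- g_small(matrix(0L, 2, 5), pos = seq(1e5, 5e5, by = 1e5))
  expect_warning(segs <- detect_roh(g), "fewer markers")
  expect_identical(nrow(segs), 0L)
})

test_that("ROH summaries equal an independent aggregation of the segment list", {
  # single 1 Mb ROH on a 100 Mb genome: coverage 1%
  g1 <- g_small(matrix(1L, 2, 3), pos = c(1L, 50e6L, 100e6L))
  seg1 <- data.frame(sample_id = "S1", chromosome = "1",
                     start_bp = 1e6, end_bp = 2e6 - 1, n_snps = 30L,
                     length_bp = 1e6, length_class = classify_roh(1e6))
  sums1 <- roh_summaries(seg1, g1, chrom_lengths = c("1" = 100e6))
  expect_equal(sums1$per_individual$coverage[1L], 0.01)
  expect_equal(sums1$coverage$mean_coverage, 0.005)

  # zero segments: zero counts, correlations undefined
  empty <- seg1[0, ]
  sums0 <- roh_summaries(empty, g1, chrom_lengths = c("1" = 100e6))
  expect_true(all(sums0$per_individual$n_roh == 0))
  expect_true(all(is.na(sums0$correlations$r)))

  # simulated inbred cohort vs brute-force recomputation
  sim <- simulate_wright_fisher(demography_config(
    ne_schedule = data.frame(start_gen_ago = 60, ne = 15),
    n_generations = 60L, n_chromosomes = 4L,
    chromosome_length_bp = 8e6, n_markers_per_chromosome = 120L,
    n_sample = 12L, seed = 43L))
  segs <- detect_roh(sim$genotypes)
  sums <- roh_summaries(segs, sim$genotypes)
  for (s in sim$genotypes$samples) {
    expect_equal(sums$per_individual$n_roh[
      sums$per_individual$sample_id == s], sum(segs$sample_id == s))
  }
  for (chr in unique(sim$genotypes$map$chromosome)) {
    expect_equal(sums$per_chromosome$total_length_bp[
      sums$per_chromosome$chromosome == chr],
      sum(segs$length_bp[segs$chromosome == chr]))
  }
  expect_error(roh_summaries(segs, sim$genotypes,
                             chrom_lengths = c("1" = 1e6)),
               "every chromosome")
})
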
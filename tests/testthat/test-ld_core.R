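test_that("EM resolves trivial phase configurations exactly", {
  # perfect coupling: 5 individuals 0/0 and 5 individuals 2/2
  tab <- matrix(0L, 3, 3); tab[1, 1] <- 5L; tab[3, 3] <- 5L
  h <- em_two_locus(g_from_table(tab), 1, 2)
  expect_equal(h$f11, 0.5, tolerance = 1e-9)
  expect_equal(h$f00, 0.5, tolerance = 1e-9)
  expect_equal(h$f10 + h$f01, 0, tolerance = 1e-9)
  expect_identical(h$n_informative, 10)

  # an independence table is the equilibrium fixed point
  tab_eq <- matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3)
  h_eq <- em_two_locus(g_from_table(tab_eq), 1, 2)
  expect_equal(c(h_eq$f11, h_eq$f10, h_eq$f01, h_eq$f00),
               rep(0.25, 4), tolerance = 1e-9)
})

test_that("EM equals direct haplotype counting when no double heterozygotes", {
  set.seed(31)
  for (k in 1:10) {
    tab <- matrix(as.vector(stats::rmultinom(1, 20, rep(1, 9))), 3, 3)
    tab[2, 2] <- 0L  # remove phase ambiguity
    dose_a <- sum(tab * matrix(0:2, 3, 3))
    dose_b <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE))
    n <- sum(tab)
    if (dose_a %in% c(0, 2 * n) || dose_b %in% c(0, 2 * n)) next
    h <- em_two_locus(g_from_table(tab), 1, 2)
    # direct gamete counts: unambiguous for every remaining cell
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2]
    c00 <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
    expect_equal(c(h$f11, h$f10, h$f01, h$f00),
                 c(c11, c10, c01, c00) / (2 * n), tolerance = 1e-8)
  }
})

test_that("EM log-likelihood is monotone and beats a simplex grid search", {
  tabs <- random_tables(40, max_total = 12L, seed = 77L)
  for (tab in tabs) {
    h <- em_two_locus(g_from_table(tab), 1, 2)
    trace <- attr(h, "ll_trace")
    expect_true(all(diff(trace) >= -1e-9))
    ll_em <- loglik_at(tab, h$f11, h$f10, h$f01, h$f00)
    expect_gte(ll_em + 1e-9, grid_loglik_max(tab, denom = 50L))
  }
})

test_that("LD coefficients follow their definitions on worked examples", {
  expect_equal(ld_from_haplofreqs(list(f11 = 0.5, f10 = 0, f01 = 0, f00 = 0.5)),
               list(D = 0.25, D_prime = 1, r2 = 1), tolerance = 1e-12)
  expect_equal(ld_from_haplofreqs(list(f11 = 0.25, f10 = 0.25,
                                       f01 = 0.25, f00 = 0.25)),
               list(D = 0, D_prime = 0, r2 = 0), tolerance = 1e-12)
  # hand arithmetic: f = (0.5, 0.25, 0.25, 0); D = 0.5 - 0.75^2 = -0.0625
  ld <- ld_from_haplofreqs(list(f11 = 0.5, f10 = 0.25, f01 = 0.25, f00 = 0))
  expect_equal(ld$D, -0.0625, tolerance = 1e-12)
  expect_equal(ld$D_prime, 1, tolerance = 1e-12)
  expect_equal(ld$r2, 0.0625^2 / (0.75 * 0.25 * 0.75 * 0.25),
               tolerance = 1e-12)
  expect_error(ld_from_haplofreqs(list(f11 = 0.5, f10 = 0.5, f01 = 0,
                                       f00 = 0)), "monomorphic|frequency")
})

test_that("r2 <= D'^2 and both lie in [0,1] for random haplotype frequencies", {
  f <- random_haplofreqs(20000, seed = 12L)
  p_a <- f[, 1] + f[, 2]; p_b <- f[, 1] + f[, 3]
  ok <- p_a > 0 & p_a < 1 & p_b > 0 & p_b < 1
  for (i in which(ok)[1:5000]) {
    ld <- ld_from_haplofreqs(list(f11 = f[i, 1], f10 = f[i, 2],
                                  f01 = f[i, 3], f00 = f[i, 4]))
    expect_gte(ld$r2, 0); expect_lte(ld$r2, 1)
    expect_gte(ld$D_prime, 0); expect_lte(ld$D_prime, 1)
    expect_lte(ld$r2, ld$D_prime^2 + 1e-9)
  }
})

test_that("the sample-size correction is affine, order-preserving, with the right fixed points", {
  expect_equal(correct_r2(1, 174), 1)
  expect_equal(correct_r2(1, 10), 1)
  expect_equal(correct_r2(1 / 174, 174), 0)
  r <- seq(0, 1, by = 0.05)
  out <- correct_r2(r, 174)
  expect_true(all(diff(out) > 0))
  # affine: second differences vanish
  expect_equal(max(abs(diff(diff(out)))), 0, tolerance = 1e-12)
  expect_lt(correct_r2(0.001, 174), 0)  # below 1/n maps negative
  expect_error(correct_r2(0.5, 1), "n_haplotypes")
})

test_that("syntenic pair enumeration matches a brute-force double loop", {
  g3 <- g_small(rbind(c(0L, 0L, 1L), c(1L, 1L, 0L), c(2L, 1L, 1L),
                      c(0L, 2L, 2L), c(1L, 0L, 2L)),
                pos = c(10e3L, 20e3L, 30e3L))
  p3 <- scan_syntenic_pairs(g3)
  expect_identical(nrow(p3), 3L)

  g_far <- g_small(rbind(c(0L, 1L), c(1L, 0L), c(2L, 1L), c(1L, 2L)),
                   pos = c(1L, 60000001L))
  expect_error(scan_syntenic_pairs(g_far, max_distance_bp = 50e6),
               "no syntenic pairs")

  sim <- simulate_wright_fisher(demography_config(
    n_chromosomes = 1L, n_generations = 40L, n_sample = 30L,
    chromosome_length_bp = 10e6, seed = 17L))
  g <- maf_filter(sim$genotypes, 0.05)
  max_d <- 3e6
  pairs <- scan_syntenic_pairs(g, max_distance_bp = max_d)
  brute <- 0L
  pos <- g$map$position_bp
  for (i in seq_len(n_markers(g) - 1L)) {
    for (j in (i + 1L):n_markers(g)) {
      if (abs(pos[j] - pos[i]) < max_d) brute <- brute + 1L
    }
  }
  expect_identical(nrow(pairs) + attr(pairs, "n_skipped"), brute)
  # every emitted pair respects the LD bounds
  expect_true(all(pairs$r2 >= 0 & pairs$r2 <= 1))
  expect_true(all(pairs$r2 <= pairs$D_prime^2 + 1e-9))
  expect_true(all(pairs$r2_corrected <= pairs$r2 + 1e-12))
})

test_that("global-n mode uses one haplotype count for every pair", {
  sim <- simulate_wright_fisher(demography_config(
    n_chromosomes = 1L, n_generations = 30L, n_sample = 25L, seed = 19L))
  g <- maf_filter(sim$genotypes, 0.1)
  pg <- scan_syntenic_pairs(g, n_haplotypes = "global")
  expect_true(all(pg$n_haplotypes == 2L * n_samples(g)))
  pp <- scan_syntenic_pairs(g, n_haplotypes = "pairwise")
  expect_true(all(pp$n_haplotypes <= 2L * n_samples(g)))
})

test_that("non-syntenic background behaves as independence predicts", {
  g_one <- g_small(matrix(0L, 4, 3), pos = c(1e5L, 2e5L, 3e5L))
  expect_error(nonsyntenic_background(g_one, 3, seed = 1),
               "at least 2 chromosomes")

  g4 <- g_small(rbind(c(0L, 1L, 1L, 0L), c(1L, 0L, 0L, 1L),
                      c(2L, 1L, 2L, 1L), c(1L, 2L, 0L, 2L),
                      c(0L, 0L, 1L, 1L)),
                pos = c(1e5L, 2e5L, 1e5L, 2e5L),
                chrom = c("1", "1", "2", "2"))
  bg4 <- nonsyntenic_background(g4, 4, seed = 1)
  expect_identical(bg4$summary$n_pairs, 4L)
  expect_true(all(is.na(bg4$pairs$distance_bp)))

  # unlinked chromosomes: mean r2 ~ 1/n_haplotypes
  set.seed(41)
  n <- 60L
  calls <- matrix(stats::rbinom(n * 60L, 2L, 0.5), n, 60L)
  g_ind <- g_small(calls, pos = rep(seq(1e5, 3e6, by = 1e5), 2),
                   chrom = rep(c("1", "2"), each = 30L))
  bg <- nonsyntenic_background(g_ind, 60, seed = 2,
                               n_haplotypes = "global")
  expect_gt(bg$summary$mean_r2, 0.5 / (2 * n))
  expect_lt(bg$summary$mean_r2, 2 / (2 * n))
})

test_that("decay binning uses half-open kb bins and matches a histogram oracle", {
  mk_pair <- function(d_bp) data.frame(
    marker_i = "a", marker_j = "b", chromosome_i = "1", chromosome_j = "1",
    distance_bp = d_bp, D = 0.1, D_prime = 0.5, r2 = 0.2,
    r2_corrected = 0.19, n_haplotypes = 100, converged = TRUE)
  tab <- bin_decay_table(mk_pair(10e3))
  expect_identical(tab$n_pairs[1L], 1L)
  expect_identical(sum(tab$n_pairs), 1L)
  tab20 <- bin_decay_table(mk_pair(20e3))
  expect_identical(tab20$n_pairs[2L], 1L)
  expect_identical(tab20$n_pairs[1L], 0L)

  set.seed(8)
  d <- runif(1000, 0, 50e6 - 1)
  pairs <- do.call(rbind, lapply(d, mk_pair))
  pairs$r2 <- runif(1000); pairs$D_prime <- sqrt(pairs$r2)
  tab_all <- bin_decay_table(pairs)
  bins <- default_decay_bins()
  for (b in seq_len(nrow(bins))) {
    in_b <- d / 1000 >= bins$lo_kb[b] & d / 1000 < bins$hi_kb[b]
    expect_identical(tab_all$n_pairs[b], sum(in_b))
    if (any(in_b)) {
      expect_equal(tab_all$mean_r2[b], mean(pairs$r2[in_b]), tolerance = 1e-12)
      expect_equal(tab_all$sd_D_prime[b],
                   sd_or_na_oracle(pairs$D_prime[in_b]), tolerance = 1e-12)
    }
  }
  expect_identical(sum(tab_all$n_pairs), 1000L)

  bad_bins <- data.frame(lo_kb = c(0, 10), hi_kb = c(20, 30))
  expect_error(bin_decay_table(pairs, bad_bins), "non-overlapping")
})

test_that("adjacent-pair summaries equal a brute-force recomputation", {
  g2 <- g_small(rbind(c(0L, 0L), c(2L, 2L), c(1L, 1L), c(0L, 0L),
                      c(2L, 2L), c(1L, 1L), c(0L, 2L)),
                pos = c(100000L, 200000L))
  adj <- adjacent_summary(scan_adjacent_pairs(g2))
  chr_row <- adj[adj$chromosome == "1", ]
  expect_equal(chr_row$n_pairs, 1)
  expect_equal(chr_row$mean_distance_kb, 100)
  expect_equal(chr_row$pct_r2_gt_0.8, ifelse(chr_row$mean_r2 > 0.8, 100, 0))

  sim <- simulate_wright_fisher(demography_config(
    n_chromosomes = 5L, n_generations = 40L, n_sample = 30L,
    n_markers_per_chromosome = 40L, seed = 23L))
  g <- maf_filter(sim$genotypes, 0.1)
  pairs <- scan_adjacent_pairs(g)
  adj2 <- adjacent_summary(pairs)
  for (chr in unique(pairs$chromosome_i)) {
    p <- pairs[pairs$chromosome_i == chr, ]
    row <- adj2[adj2$chromosome == chr, ]
    expect_equal(row$n_pairs, nrow(p))
    expect_equal(row$mean_r2, mean(p$r2), tolerance = 1e-12)
    expect_equal(row$pct_r2_gt_0.2, 100 * mean(p$r2 > 0.2), tolerance = 1e-12)
  }
  body <- adj2[adj2$chromosome != "Mean", ]
  mean_row <- adj2[adj2$chromosome == "Mean", ]
  expect_equal(mean_row$mean_r2, mean(body$mean_r2), tolerance = 1e-12)

  g_single <- g_small(matrix(c(0L, 1L, 2L), 3, 1), pos = 100L)
  expect_warning(try(scan_adjacent_pairs(g_single), silent = TRUE),
                 "fewer than 2")
})
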
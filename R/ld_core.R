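# Pairwise LD from unphased genotypes.
#
# For each marker pair the sufficient statistic is the 3x3 table of joint
# genotype counts (dose of the counted allele at each locus). Only the
# double-heterozygote cell is phase-ambiguous; EM resolves it under the
# random-union-of-gametes multinomial model. All per-pair quantities are
# computed vectorised across pairs, so whole-chromosome scans are cheap.

# 3x3 joint genotype counts for a set of marker pairs.
# G: n x m integer matrix (0/1/2/NA); idx: 2-column matrix of marker indices.
# Returns a list n00..n22 of count vectors, one element per pair.
pair_genotype_counts <- function(G, idx) {
  ind <- lapply(0:2, function(v) {
    M <- (G == v)
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  counts <- list()
  for (a in 0:2) {
    for (b in 0:2) {
      cross <- crossprod(ind[[a + 1L]], ind[[b + 1L]])
      counts[[paste0("n", a, b)]] <- cross[idx]
    }
  }
  counts
}

# Vectorised EM for two-locus haplotype frequencies from one start.
# `counts` is the list from pair_genotype_counts(); `init_d_frac` places
# the starting point at D = init_d_frac x (the attainable extreme of D
# with that sign) given the sample margins, 0 being the linkage-
# equilibrium start. Returns haplotype frequencies f11/f10/f01/f00
# (1 = counted allele), informative-sample counts, iteration counts and a
# convergence flag per pair. With trace = TRUE (single pair) the per-
# iteration log-likelihood is recorded.
em_haplofreqs <- function(counts, tol = 1e-10, max_iter = 1000L,
                          trace = FALSE, init_d_frac = 0) {
  n00 <- counts$n00; n01 <- counts$n01; n02 <- counts$n02
  n10 <- counts$n10; n11 <- counts$n11; n12 <- counts$n12
  n20 <- counts$n20; n21 <- counts$n21; n22 <- counts$n22
  n_inf <- n00 + n01 + n02 + n10 + n11 + n12 + n20 + n21 + n22
  two_n <- 2 * n_inf

  p_a <- (2 * (n20 + n21 + n22) + n10 + n11 + n12) / two_n
  p_b <- (2 * (n02 + n12 + n22) + n01 + n11 + n21) / two_n

  d0 <- if (init_d_frac >= 0) {
    init_d_frac * pmin(p_a * (1 - p_b), (1 - p_a) * p_b)
  } else {
    init_d_frac * pmin(p_a * p_b, (1 - p_a) * (1 - p_b))
  }
  f11 <- p_a * p_b + d0
  f10 <- p_a * (1 - p_b) - d0
  f01 <- (1 - p_a) * p_b - d0
  f00 <- (1 - p_a) * (1 - p_b) + d0

  iters <- rep(0L, length(n_inf))
  active <- rep(TRUE, length(n_inf))
  ll_trace <- if (trace) numeric(0) else NULL
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    denom <- f11 * f00 + f10 * f01
    phase_cis <- ifelse(denom > 0, f11 * f00 / denom, 0.5)
    c11 <- 2 * n22 + n21 + n12 + n11 * phase_cis
    c10 <- 2 * n20 + n21 + n10 + n11 * (1 - phase_cis)
    c01 <- 2 * n02 + n12 + n01 + n11 * (1 - phase_cis)
    c00 <- 2 * n00 + n01 + n10 + n11 * phase_cis
    new11 <- c11 / two_n; new10 <- c10 / two_n
    new01 <- c01 / two_n; new00 <- c00 / two_n
    delta <- pmax(abs(new11 - f11), abs(new10 - f10),
                  abs(new01 - f01), abs(new00 - f00))
    f11 <- new11; f10 <- new10; f01 <- new01; f00 <- new00
    iters[active] <- it
    active <- active & (delta >= tol)
    if (trace) {
      ll_trace <- c(ll_trace, two_locus_loglik(counts, f11, f10, f01, f00))
    }
  }
  list(f11 = f11, f10 = f10, f01 = f01, f00 = f00,
       n_informative = n_inf, n_iterations = iters,
       converged = !active, ll_trace = ll_trace,
       loglik = two_locus_loglik(counts, f11, f10, f01, f00))
}

# Multi-start EM: the unphased two-locus likelihood is occasionally
# bimodal (a coupling and a repulsion mode), so EM is run from the
# linkage-equilibrium start and from starts biased toward each extreme
# of D; per pair the solution with the highest log-likelihood wins, the
# equilibrium start winning ties.
em_multistart <- function(counts, tol = 1e-10, max_iter = 1000L,
                          trace = FALSE) {
  best <- em_haplofreqs(counts, tol = tol, max_iter = max_iter,
                        trace = trace, init_d_frac = 0)
  for (frac in c(0.8, -0.8)) {
    cand <- em_haplofreqs(counts, tol = tol, max_iter = max_iter,
                          trace = trace, init_d_frac = frac)
    gain <- cand$loglik > best$loglik + 1e-9
    gain[is.na(gain)] <- FALSE
    if (any(gain)) {
      for (fld in c("f11", "f10", "f01", "f00", "n_iterations",
                    "converged", "loglik")) {
        best[[fld]][gain] <- cand[[fld]][gain]
      }
      if (trace && all(gain)) best$ll_trace <- cand$ll_trace
    }
  }
  best
}

# Multinomial log-likelihood of the 3x3 genotype table under haplotype
# frequencies (random union of gametes). Vectorised over pairs.
two_locus_loglik <- function(counts, f11, f10, f01, f00) {
  lg <- function(n, p) ifelse(n > 0, n * log(pmax(p, .Machine$double.xmin)), 0)
  lg(counts$n00, f00^2) + lg(counts$n01, 2 * f00 * f01) +
    lg(counts$n02, f01^2) +
    lg(counts$n10, 2 * f00 * f10) +
    lg(counts$n11, 2 * (f11 * f00 + f10 * f01)) +
    lg(counts$n12, 2 * f01 * f11) +
    lg(counts$n20, f10^2) + lg(counts$n21, 2 * f10 * f11) +
    lg(counts$n22, f11^2)
}

#' EM haplotype-frequency estimation for one marker pair
#'
#' Maximum-likelihood two-locus haplotype frequencies from unphased
#' genotypes under the multinomial model in which only double
#' heterozygotes are phase-ambiguous. EM iterates until the largest
#' absolute frequency change drops below `tol` or `max_iter` is reached,
#' from a linkage-equilibrium start (products of sample allele
#' frequencies) plus coupling- and repulsion-biased starts; the
#' unphased-genotype likelihood is occasionally bimodal and the
#' highest-likelihood solution is kept.
#'
#' @param g A [genotype_matrix()].
#' @param i,j Marker indices (columns of `g$calls`).
#' @param tol Convergence tolerance on frequency change, default 1e-10.
#' @param max_iter Maximum EM iterations, default 1000.
#' @return A list of class `haplofreqs`: `f11`, `f10`, `f01`, `f00`
#'   (haplotype frequencies; 1 = counted allele at that locus),
#'   `log_likelihood`, `n_iterations`, `n_informative`, `converged`,
#'   and attribute `ll_trace` (per-iteration log-likelihood).
#' @export
em_two_locus <- function(g, i, j, tol = 1e-10, max_iter = 1000L) {
  G <- g$calls[, c(i, j), drop = FALSE]
  counts <- pair_genotype_counts(G, matrix(c(1L, 2L), nrow = 1L))
  n_inf <- counts$n00 + counts$n01 + counts$n02 + counts$n10 + counts$n11 +
    counts$n12 + counts$n20 + counts$n21 + counts$n22
  if (n_inf < 2) {
    stop("fewer than 2 individuals informative for markers ", i, ", ", j)
  }
  p_a <- (2 * (counts$n20 + counts$n21 + counts$n22) +
            counts$n10 + counts$n11 + counts$n12) / (2 * n_inf)
  p_b <- (2 * (counts$n02 + counts$n12 + counts$n22) +
            counts$n01 + counts$n11 + counts$n21) / (2 * n_inf)
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    stop("LD undefined: marker ", if (p_a <= 0 || p_a >= 1) i else j,
         " is monomorphic among informative individuals")
  }
  fit <- em_multistart(counts, tol = tol, max_iter = max_iter, trace = TRUE)
  structure(list(f11 = fit$f11, f10 = fit$f10, f01 = fit$f01, f00 = fit$f00,
                 log_likelihood = two_locus_loglik(counts, fit$f11, fit$f10,
                                                   fit$f01, fit$f00),
                 n_iterations = fit$n_iterations,
                 n_informative = fit$n_informative,
                 converged = fit$converged),
            class = "haplofreqs", ll_trace = fit$ll_trace)
}

# D, |D'|, r2 from haplotype frequency vectors; vectorised.
ld_stats <- function(f11, f10, f01, f00) {
  p_a <- f11 + f10
  p_b <- f11 + f01
  D <- f11 - p_a * p_b
  d_max <- ifelse(D >= 0,
                  pmin(p_a * (1 - p_b), (1 - p_a) * p_b),
                  pmin(p_a * p_b, (1 - p_a) * (1 - p_b)))
  D_prime <- ifelse(d_max > 0, abs(D) / d_max, NA_real_)
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  r2 <- ifelse(denom > 0, D^2 / denom, NA_real_)
  list(D = D, D_prime = pmin(D_prime, 1), r2 = pmin(r2, 1))
}

#' LD coefficients from haplotype frequencies
#'
#' Standard definitions: `D = f11 - p_A p_B`; `D' = |D| / D_max` with
#' `D_max = min(p_A(1-p_B), (1-p_A)p_B)` when `D > 0` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` otherwise; `r2 = D^2 / (p_A q_A p_B q_B)`.
#'
#' @param h A `haplofreqs` object from [em_two_locus()], or a list with
#'   elements `f11`, `f10`, `f01`, `f00`.
#' @return A list with `D`, `D_prime` (absolute value, in `[0,1]`) and
#'   `r2` (in `[0,1]`).
#' @export
ld_from_haplofreqs <- function(h) {
  p_a <- h$f11 + h$f10
  p_b <- h$f11 + h$f01
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    stop("LD undefined: a marginal allele frequency is 0 or 1")
  }
  ld_stats(h$f11, h$f10, h$f01, h$f00)[c("D", "D_prime", "r2")]
}

#' Haplotype-count sample-size correction for r2
#'
#' `r2_corrected = (r2 - 1/n) / (1 - 1/n)`, where `n` is the number of
#' haplotypes in the sample (twice the number of diploid individuals).
#' The map is affine and order-preserving, sends `1` to `1` and `1/n` to
#' `0`, and may return negative values for `r2 < 1/n` (reported as
#' computed).
#'
#' @param r2 Observed r2 in `[0, 1]` (vectorised).
#' @param n_haplotypes Haplotype count, at least 2.
#' @return Corrected r2.
#' @export
correct_r2 <- function(r2, n_haplotypes) {
  if (any(n_haplotypes < 2)) stop("n_haplotypes must be >= 2")
  (r2 - 1 / n_haplotypes) / (1 - 1 / n_haplotypes)
}

# Core pair engine shared by syntenic and non-syntenic scans: computes LD
# for an explicit pair index. n_haplotypes: "pairwise" uses 2 x informative
# individuals per pair; "global" uses 2 x cohort size for every pair (the
# single-n convention used in published decay tables).
compute_pair_ld <- function(g, idx, tol = 1e-10, max_iter = 1000L,
                            n_haplotypes = c("pairwise", "global")) {
  n_haplotypes <- match.arg(n_haplotypes)
  # restrict the crossprod to markers actually involved in a pair
  sel <- sort(unique(as.vector(idx)))
  idx_c <- matrix(match(idx, sel), ncol = 2L)
  counts <- pair_genotype_counts(g$calls[, sel, drop = FALSE], idx_c)
  n_inf <- counts$n00 + counts$n01 + counts$n02 + counts$n10 + counts$n11 +
    counts$n12 + counts$n20 + counts$n21 + counts$n22
  p_a <- (2 * (counts$n20 + counts$n21 + counts$n22) +
            counts$n10 + counts$n11 + counts$n12) / (2 * n_inf)
  p_b <- (2 * (counts$n02 + counts$n12 + counts$n22) +
            counts$n01 + counts$n11 + counts$n21) / (2 * n_inf)
  usable <- n_inf >= 2 & p_a > 0 & p_a < 1 & p_b > 0 & p_b < 1
  n_skipped <- sum(!usable)

  sub <- lapply(counts, `[`, usable)
  fit <- em_multistart(sub, tol = tol, max_iter = max_iter)
  st <- ld_stats(fit$f11, fit$f10, fit$f01, fit$f00)
  n_hap <- if (n_haplotypes == "global") {
    rep(2L * n_samples(g), sum(usable))
  } else {
    2L * fit$n_informative
  }
  out <- data.frame(
    marker_i = g$map$marker_id[idx[usable, 1L]],
    marker_j = g$map$marker_id[idx[usable, 2L]],
    chromosome_i = g$map$chromosome[idx[usable, 1L]],
    chromosome_j = g$map$chromosome[idx[usable, 2L]],
    distance_bp = ifelse(
      g$map$chromosome[idx[usable, 1L]] == g$map$chromosome[idx[usable, 2L]],
      abs(g$map$position_bp[idx[usable, 2L]] -
            g$map$position_bp[idx[usable, 1L]]),
      NA_integer_),
    D = st$D, D_prime = st$D_prime, r2 = st$r2,
    r2_corrected = correct_r2(st$r2, n_hap),
    n_haplotypes = n_hap,
    converged = fit$converged,
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Pairwise LD for all syntenic pairs within a maximum distance
#'
#' Emits every same-chromosome marker pair closer than `max_distance_bp`.
#' Pairs for which EM is undefined (a monomorphic margin among the
#' informative individuals, or fewer than 2 such individuals) are skipped
#' and counted in the `n_skipped` attribute; pairs that exhaust
#' `max_iter` are emitted with `converged = FALSE`.
#'
#' @param g A [genotype_matrix()] with markers sorted by position.
#' @param max_distance_bp Distance cut-off in bp (strict `<`), default
#'   50 Mb.
#' @param tol,max_iter EM settings, see [em_two_locus()].
#' @param n_haplotypes `"pairwise"` (default; 2 x informative individuals
#'   for each pair) or `"global"` (2 x cohort size, the single-n
#'   convention of published decay tables).
#' @return A data frame, one row per pair, with marker ids, chromosome,
#'   `distance_bp`, `D`, `D_prime`, `r2`, `r2_corrected`, `n_haplotypes`
#'   and `converged`; attribute `n_skipped` counts skipped pairs.
#' @export
scan_syntenic_pairs <- function(g, max_distance_bp = 50e6, tol = 1e-10,
                                max_iter = 1000L,
                                n_haplotypes = c("pairwise", "global")) {
  idx_list <- list()
  for (chr in unique(g$map$chromosome)) {
    w <- which(g$map$chromosome == chr)
    if (length(w) < 2L) next
    pos <- g$map$position_bp[w]
    pr <- t(utils::combn(seq_along(w), 2L))
    keep <- (pos[pr[, 2L]] - pos[pr[, 1L]]) < max_distance_bp
    if (any(keep)) {
      idx_list[[chr]] <- cbind(w[pr[keep, 1L]], w[pr[keep, 2L]])
    }
  }
  if (length(idx_list) == 0L) {
    stop("no syntenic pairs within ", max_distance_bp, " bp")
  }
  idx <- do.call(rbind, idx_list)
  compute_pair_ld(g, idx, tol = tol, max_iter = max_iter,
                  n_haplotypes = n_haplotypes)
}

#' LD between adjacent markers within each chromosome
#'
#' @inheritParams scan_syntenic_pairs
#' @return As [scan_syntenic_pairs()], restricted to consecutive marker
#'   pairs; chromosomes with fewer than 2 markers are excluded with a
#'   warning.
#' @export
scan_adjacent_pairs <- function(g, tol = 1e-10, max_iter = 1000L,
                                n_haplotypes = c("pairwise", "global")) {
  idx_list <- list()
  for (chr in unique(g$map$chromosome)) {
    w <- which(g$map$chromosome == chr)
    if (length(w) < 2L) {
      warning("chromosome ", chr, " has fewer than 2 markers; excluded")
      next
    }
    idx_list[[chr]] <- cbind(w[-length(w)], w[-1L])
  }
  if (length(idx_list) == 0L) stop("no chromosome has 2 or more markers")
  compute_pair_ld(g, do.call(rbind, idx_list), tol = tol,
                  max_iter = max_iter, n_haplotypes = n_haplotypes)
}

#' Background LD from non-syntenic marker pairs
#'
#' Draws a seeded uniform sample of markers, computes LD for every
#' inter-chromosomal pair among them, and returns one summary row. Under
#' independence the expected background r2 is about `1/n_haplotypes`.
#'
#' @param g A [genotype_matrix()] spanning at least 2 chromosomes.
#' @param n_snps Number of markers to sample.
#' @param seed Integer RNG seed for the marker sample.
#' @inheritParams scan_syntenic_pairs
#' @return A list with `summary` (one-row data frame: `n_pairs`, mean/sd
#'   of `D_prime`, `r2`, `r2_corrected`) and `pairs` (the per-pair table).
#' @export
nonsyntenic_background <- function(g, n_snps, seed, tol = 1e-10,
                                   max_iter = 1000L,
                                   n_haplotypes = c("pairwise", "global")) {
  if (length(unique(g$map$chromosome)) < 2L) {
    stop("non-syntenic background needs markers on at least 2 chromosomes")
  }
  if (n_snps > n_markers(g)) stop("n_snps exceeds marker count")
  sel <- sort(with_seed(seed, sample.int(n_markers(g), n_snps)))
  chrom <- g$map$chromosome[sel]
  pr <- t(utils::combn(length(sel), 2L))
  keep <- chrom[pr[, 1L]] != chrom[pr[, 2L]]
  if (!any(keep)) stop("sampled markers yield no non-syntenic pair")
  idx <- cbind(sel[pr[keep, 1L]], sel[pr[keep, 2L]])
  pairs <- compute_pair_ld(g, idx, tol = tol, max_iter = max_iter,
                           n_haplotypes = n_haplotypes)
  summary <- data.frame(
    n_pairs = nrow(pairs),
    mean_D_prime = mean_or_na(pairs$D_prime), sd_D_prime = sd_or_na(pairs$D_prime),
    mean_r2 = mean_or_na(pairs$r2), sd_r2 = sd_or_na(pairs$r2),
    mean_r2_corrected = mean_or_na(pairs$r2_corrected),
    sd_r2_corrected = sd_or_na(pairs$r2_corrected))
  list(summary = summary, pairs = pairs)
}

#' The standard 16 LD-decay distance bins
#'
#' Half-open intervals in kb: `[0,20), [20,40), [40,60), [60,100),
#' [100,200), [200,500), [500,1000), [1000,2000), [2000,5000),
#' [5000,10000), [10000,12000), [12000,15000), [15000,17000),
#' [17000,20000), [20000,30000), [30000,50000)`.
#'
#' @return Data frame with columns `lo_kb`, `hi_kb`.
#' @export
default_decay_bins <- function() {
  lo <- c(0, 20, 40, 60, 100, 200, 500, 1000, 2000, 5000,
          10000, 12000, 15000, 17000, 20000, 30000)
  hi <- c(lo[-1L], 50000)
  data.frame(lo_kb = lo, hi_kb = hi)
}

#' Distance-binned LD decay table
#'
#' Assigns each syntenic pair to the unique half-open bin `[lo_kb, hi_kb)`
#' containing its distance and summarises D', r2 and corrected r2 per bin.
#' Bins with no pairs are reported with `n_pairs = 0`.
#'
#' @param pairs Pair table from [scan_syntenic_pairs()] (rows with missing
#'   distance are ignored).
#' @param bins Data frame with `lo_kb`, `hi_kb`; non-overlapping and
#'   sorted. Default [default_decay_bins()].
#' @return Data frame, one row per bin: `lo_kb`, `hi_kb`, `n_pairs`,
#'   mean and sd of `D_prime`, `r2`, `r2_corrected`.
#' @export
bin_decay_table <- function(pairs, bins = default_decay_bins()) {
  if (is.unsorted(bins$lo_kb, strictly = TRUE) ||
      any(bins$hi_kb <= bins$lo_kb) ||
      any(bins$lo_kb[-1L] < bins$hi_kb[-nrow(bins)])) {
    stop("bins must be sorted and non-overlapping")
  }
  pairs <- pairs[!is.na(pairs$distance_bp), , drop = FALSE]
  dist_kb <- pairs$distance_bp / 1000
  out <- bins
  stat_cols <- c("mean_D_prime", "sd_D_prime", "mean_r2", "sd_r2",
                 "mean_r2_corrected", "sd_r2_corrected")
  out$n_pairs <- 0L
  out[stat_cols] <- NA_real_
  for (b in seq_len(nrow(bins))) {
    in_bin <- dist_kb >= bins$lo_kb[b] & dist_kb < bins$hi_kb[b]
    out$n_pairs[b] <- sum(in_bin)
    if (any(in_bin)) {
      p <- pairs[in_bin, , drop = FALSE]
      out$mean_D_prime[b] <- mean_or_na(p$D_prime)
      out$sd_D_prime[b] <- sd_or_na(p$D_prime)
      out$mean_r2[b] <- mean_or_na(p$r2)
      out$sd_r2[b] <- sd_or_na(p$r2)
      out$mean_r2_corrected[b] <- mean_or_na(p$r2_corrected)
      out$sd_r2_corrected[b] <- sd_or_na(p$r2_corrected)
    }
  }
  out
}

#' Per-chromosome summary of adjacent-pair LD
#'
#' For each chromosome: mean and sd of inter-marker distance (kb), D' and
#' r2 among adjacent pairs, and the percentage of pairs with `r2 > 0.2`
#' and `r2 > 0.8`; plus an unweighted cross-chromosome `Mean` row
#' (see [mean_summary_row()]).
#'
#' @param pairs Adjacent-pair table from [scan_adjacent_pairs()].
#' @return Data frame, one row per chromosome plus a final `Mean` row,
#'   with columns `chromosome`, `n_pairs`, `mean_distance_kb`,
#'   `sd_distance_kb`, `mean_D_prime`, `sd_D_prime`, `mean_r2`, `sd_r2`,
#'   `pct_r2_gt_0.2`, `pct_r2_gt_0.8`.
#' @export
adjacent_summary <- function(pairs) {
  chroms <- unique(pairs$chromosome_i)
  rows <- lapply(chroms, function(chr) {
    p <- pairs[pairs$chromosome_i == chr, , drop = FALSE]
    data.frame(
      chromosome = chr, n_pairs = nrow(p),
      mean_distance_kb = mean_or_na(p$distance_bp / 1000),
      sd_distance_kb = sd_or_na(p$distance_bp / 1000),
      mean_D_prime = mean_or_na(p$D_prime), sd_D_prime = sd_or_na(p$D_prime),
      mean_r2 = mean_or_na(p$r2), sd_r2 = sd_or_na(p$r2),
      pct_r2_gt_0.2 = 100 * mean(p$r2 > 0.2),
      pct_r2_gt_0.8 = 100 * mean(p$r2 > 0.8),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rbind(tab, mean_summary_row(tab))
}

#' Unweighted cross-chromosome mean row
#'
#' Averages each numeric column of a per-chromosome summary table with
#' equal weight per chromosome (not per pair), the convention used for
#' the `Mean` row of adjacent-pair LD tables.
#'
#' @param tab Data frame with a `chromosome` column and numeric summary
#'   columns.
#' @return One-row data frame with `chromosome = "Mean"`.
#' @export
mean_summary_row <- function(tab) {
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab[1L, , drop = FALSE]
  out[!num] <- NA
  out$chromosome <- "Mean"
  for (cn in names(tab)[num]) out[[cn]] <- mean(tab[[cn]], na.rm = TRUE)
  rownames(out) <- NULL
  out
}
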
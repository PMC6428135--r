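#' Per-marker minor allele frequency
#'
#' Computed on non-missing calls only. Markers with no non-missing calls
#' get `NA`.
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of MAF in `[0, 0.5]`, one per marker.
#' @export
minor_allele_freq <- function(g) {
  n_obs <- colSums(!is.na(g$calls))
  p <- colSums(g$calls, na.rm = TRUE) / (2 * n_obs)
  p[n_obs == 0L] <- NA_real_
  pmin(p, 1 - p)
}

#' Filter samples and markers by call rate
#'
#' Samples are filtered first (call rate across all markers), then markers
#' (call rate across the retained samples); both at a strict `<` threshold,
#' so a rate exactly at the threshold is kept.
#'
#' @param g A [genotype_matrix()].
#' @param sample_min,marker_min Minimum call-rate fractions in `[0, 1]`.
#' @return A list with `genotypes` (the filtered matrix) and `report`
#'   (data frames `samples_removed`, `markers_removed` with the offending
#'   call rates, and telescoping `counts`).
#' @export
call_rate_filter <- function(g, sample_min = 0.9, marker_min = 0.9) {
  stopifnot(sample_min >= 0, sample_min <= 1,
            marker_min >= 0, marker_min <= 1)
  m <- n_markers(g)
  sample_rate <- rowMeans(!is.na(g$calls))
  drop_s <- which(sample_rate < sample_min)
  if (length(drop_s) == n_samples(g)) {
    stop("call_rate_filter removed every sample (threshold ", sample_min, ")")
  }
  g1 <- if (length(drop_s) > 0L) {
    subset_genotypes(g, samples = -drop_s)
  } else g

  marker_rate <- colMeans(!is.na(g1$calls))
  drop_m <- which(marker_rate < marker_min)
  g2 <- if (length(drop_m) > 0L) {
    subset_genotypes(g1, markers = -drop_m)
  } else g1

  report <- list(
    samples_removed = data.frame(
      sample_id = g$samples[drop_s],
      call_rate = unname(sample_rate[drop_s]),
      stringsAsFactors = FALSE),
    markers_removed = data.frame(
      marker_id = g1$map$marker_id[drop_m],
      call_rate = unname(marker_rate[drop_m]),
      stringsAsFactors = FALSE),
    counts = data.frame(
      stage = c("input", "sample_call_rate", "marker_call_rate"),
      n_samples = c(n_samples(g), n_samples(g1), n_samples(g2)),
      n_markers = c(m, m, n_markers(g2)),
      stringsAsFactors = FALSE)
  )
  list(genotypes = g2, report = report)
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test: given the observed allele counts, the
#' p-value is the total probability, under the distribution of the
#' heterozygote count conditional on allele counts, of all heterozygote
#' counts whose probability does not exceed that of the observed count
#' (probability-ordering, no mid-p).
#'
#' @param n_hom_a,n_het,n_hom_b Non-negative genotype counts.
#' @return A list of class `hwe_result` with the counts and `p_value`.
#'   The p-value is invariant under swapping `n_hom_a` and `n_hom_b`.
#' @export
hwe_exact_test <- function(n_hom_a, n_het, n_hom_b) {
  if (n_hom_a < 0 || n_het < 0 || n_hom_b < 0) {
    stop("genotype counts must be non-negative")
  }
  n <- n_hom_a + n_het + n_hom_b
  if (n < 1) stop("at least one genotyped individual required")
  n_a <- 2L * n_hom_a + n_het          # copies of the rarer-or-not allele a
  hets <- seq.int(n_a %% 2L, min(n_a, 2L * n - n_a), by = 2L)
  # log P(h | allele counts) up to a constant: multinomial x 2^h
  ha <- (n_a - hets) / 2
  hb <- n - ha - hets
  logw <- lgamma(n + 1) - lgamma(ha + 1) - lgamma(hets + 1) - lgamma(hb + 1) +
    hets * log(2)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  p_obs <- prob[match(n_het, hets)]
  p <- sum(prob[prob <= p_obs * (1 + 1e-10)])
  structure(list(n_hom_a = n_hom_a, n_het = n_het, n_hom_b = n_hom_b,
                 p_value = min(p, 1)),
            class = "hwe_result")
}

#' Per-marker HWE p-values for a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of exact-test p-values (1 for markers with no
#'   non-missing calls).
#' @export
hwe_pvalues <- function(g) {
  vapply(seq_len(n_markers(g)), function(j) {
    x <- g$calls[, j]
    counts <- tabulate(x + 1L, nbins = 3L)
    if (sum(counts) == 0L) return(1)
    hwe_exact_test(counts[1L], counts[2L], counts[3L])$p_value
  }, numeric(1))
}

#' Remove markers out of Hardy-Weinberg equilibrium
#'
#' Markers with exact-test p below `p_threshold` are excluded (markers
#' at or above the threshold are retained).
#'
#' @param g A [genotype_matrix()].
#' @param p_threshold Exclusion threshold, default 0.01.
#' @return A list with `genotypes` and `removed` (marker ids).
#' @export
hwe_filter <- function(g, p_threshold = 0.01) {
  p <- hwe_pvalues(g)
  drop <- which(p < p_threshold)
  out <- if (length(drop) > 0L) subset_genotypes(g, markers = -drop) else g
  list(genotypes = out, removed = g$map$marker_id[drop], p_values = p)
}

#' Filter markers by minor allele frequency
#'
#' Retains markers whose MAF (on non-missing calls) is at or above the
#' threshold. Markers with all calls missing are removed.
#'
#' @param g A [genotype_matrix()].
#' @param threshold MAF threshold in `[0, 0.5]`.
#' @return A `genotype_matrix`.
#' @export
maf_filter <- function(g, threshold) {
  stopifnot(threshold >= 0, threshold <= 0.5)
  maf <- minor_allele_freq(g)
  keep <- which(!is.na(maf) & maf >= threshold)
  subset_genotypes(g, markers = keep)
}

#' Thin markers to a target count by uniform random sampling
#'
#' Draws a uniform subset of markers without replacement, deterministic
#' under `seed`; map order is preserved.
#'
#' @param g A [genotype_matrix()].
#' @param target_count Number of markers to retain.
#' @param seed Integer RNG seed.
#' @return A `genotype_matrix` with exactly `target_count` markers.
#' @export
thin_markers <- function(g, target_count, seed) {
  m <- n_markers(g)
  if (target_count > m) {
    stop("target_count (", target_count, ") exceeds available markers (",
         m, ")")
  }
  keep <- sort(with_seed(seed, sample.int(m, target_count)))
  subset_genotypes(g, markers = keep)
}

#' Run the full marker/sample QC cascade
#'
#' Stages, in order: sample call rate, marker call rate, HWE exact test,
#' MAF threshold, optional thinning. Counts telescope: every stage's
#' retained + removed markers equal its input.
#'
#' @param g A [genotype_matrix()].
#' @param sample_call_rate,marker_call_rate Call-rate thresholds
#'   (strict `<` removal), default 0.9.
#' @param hwe_p HWE exclusion p-value threshold, default 0.01.
#' @param maf MAF retention threshold, default 0.05.
#' @param thin_to Optional marker count to thin to after MAF filtering.
#' @param seed Seed for thinning (required when `thin_to` is given).
#' @return A list with `genotypes` and a `report` data frame of
#'   per-stage sample/marker counts.
#' @export
qc_pipeline <- function(g, sample_call_rate = 0.9, marker_call_rate = 0.9,
                        hwe_p = 0.01, maf = 0.05, thin_to = NULL,
                        seed = 1L) {
  cr <- call_rate_filter(g, sample_call_rate, marker_call_rate)
  g1 <- cr$genotypes
  hw <- hwe_filter(g1, hwe_p)
  g2 <- hw$genotypes
  g3 <- maf_filter(g2, maf)
  stages <- cr$report$counts
  stages <- rbind(stages, data.frame(
    stage = c("hwe", "maf"),
    n_samples = n_samples(g2),
    n_markers = c(n_markers(g2), n_markers(g3))))
  g_out <- g3
  if (!is.null(thin_to)) {
    g_out <- thin_markers(g3, thin_to, seed)
    stages <- rbind(stages, data.frame(
      stage = "thin", n_samples = n_samples(g_out),
      n_markers = n_markers(g_out)))
  }
  list(genotypes = g_out, report = stages)
}
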
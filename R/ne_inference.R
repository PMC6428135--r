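# LD-based historical effective population size.
#
# Distance-binned adjusted r2 is mapped to Ne through Sved's relation
# E(r2) = 1/(1 + 4 N c): for a bin with recombination fraction c,
# Ne = (1/(4 f(c))) * (1/E(r2_adj) - a), reported at t = 1/(2 f(c))
# generations ago.

#' Specification of the physical-to-genetic mapping
#'
#' @param morgans_per_bp Morgans per base pair; the default `1e-8`
#'   encodes a uniform 1 cM/Mb map.
#' @param mapping Mapping-function identifier; only `"sved"`
#'   (`f(c) = d(1 - d/2)`) is implemented.
#' @param mutation_constant_a Mutation constant `a` in the Ne equation;
#'   1 (default) or 2.
#' @return A list of class `mapping_spec`.
#' @export
mapping_spec <- function(morgans_per_bp = 1e-8, mapping = "sved",
                         mutation_constant_a = 1) {
  stopifnot(morgans_per_bp > 0, mutation_constant_a %in% c(1, 2))
  mapping <- match.arg(mapping, "sved")
  structure(list(morgans_per_bp = morgans_per_bp, mapping = mapping,
                 mutation_constant_a = mutation_constant_a),
            class = "mapping_spec")
}

#' Sved mapping from physical distance to recombination fraction
#'
#' `d = distance_bp * morgans_per_bp`; `f(c) = d (1 - d/2)`. The mapping
#' is monotone for `d < 1` and defined up to `d = 2`.
#'
#' @param distance_bp Non-negative distances in bp (vectorised).
#' @param spec A [mapping_spec()].
#' @return A list with `d` (Morgans) and `f_c` (recombination fraction).
#' @export
sved_mapping <- function(distance_bp, spec = mapping_spec()) {
  stopifnot(all(distance_bp >= 0))
  d <- distance_bp * spec$morgans_per_bp
  if (any(d > 2)) {
    stop("distance exceeds 2 Morgans (", max(d), " M); the Sved mapping ",
         "supports at most ", format(2 / spec$morgans_per_bp, big.mark = ","),
         " bp")
  }
  list(d = d, f_c = d * (1 - d / 2))
}

#' Sampling-bias adjustment of r2
#'
#' `r2_adj = r2 - 1/(2N)`, where `N` is the number of diploid individuals
#' sampled. Negative results are returned as computed; [ne_trajectory()]
#' flags bins whose mean adjusted r2 is non-positive.
#'
#' @param r2 Observed r2 (vectorised).
#' @param n_individuals Diploid sample size, at least 1.
#' @return Adjusted r2.
#' @export
adjust_r2 <- function(r2, n_individuals) {
  stopifnot(n_individuals >= 1)
  r2 - 1 / (2 * n_individuals)
}

#' Point estimate of Ne from one distance bin
#'
#' `Ne = (1/(4 f_c)) * (1/mean_r2_adj - a)`. Inverts Sved's expectation
#' `E(r2_adj) = 1/(a + 4 Ne f_c)`.
#'
#' @param mean_r2_adj Mean adjusted r2 of the bin, in `(0, 1)` with
#'   `1/mean_r2_adj > a`.
#' @param f_c Recombination fraction of the bin, positive.
#' @param a Mutation constant (1 or 2).
#' @return The Ne estimate.
#' @export
ne_point <- function(mean_r2_adj, f_c, a = 1) {
  if (any(f_c <= 0)) stop("f_c must be positive")
  if (any(mean_r2_adj <= 0)) {
    stop("mean adjusted r2 must be positive for an Ne estimate")
  }
  if (any(1 / mean_r2_adj - a <= 0)) {
    stop("mean adjusted r2 >= 1/a: Ne undefined")
  }
  (1 / (4 * f_c)) * (1 / mean_r2_adj - a)
}

#' Geometric distance-bin edges for the Ne trajectory
#'
#' @param min_bp,max_bp Distance range in bp (defaults 0.02 and 50 Mb).
#' @param n_bins Number of bins.
#' @return Numeric vector of `n_bins + 1` edges, geometrically spaced.
#' @export
ne_bin_edges <- function(min_bp = 0.02e6, max_bp = 50e6, n_bins = 14L) {
  stopifnot(min_bp > 0, max_bp > min_bp, n_bins >= 1)
  exp(seq(log(min_bp), log(max_bp), length.out = n_bins + 1L))
}

#' Ne trajectory from distance-binned pairwise LD
#'
#' Syntenic pairs are binned by physical distance; per bin, raw r2 values
#' are adjusted for sampling bias (`r2 - 1/(2N)`; no haplotype-count
#' rescaling) and averaged, the bin's mean pair distance is mapped to a
#' recombination fraction `f_c` via [sved_mapping()], the bin is dated at
#' `t = 1/(2 f_c)` generations ago, and Ne is estimated by [ne_point()].
#' Rows are sorted by increasing `t`; bins whose estimate is undefined
#' (no pairs, or non-positive mean adjusted r2) are kept with `ne = NA`
#' and a `note`.
#'
#' @param pairs Pair table from [scan_syntenic_pairs()] with raw `r2`
#'   and `distance_bp`.
#' @param n_individuals Diploid sample size used for the adjustment.
#' @param spec A [mapping_spec()].
#' @param bin_edges Distance-bin edges in bp, default [ne_bin_edges()].
#' @return Data frame, one row per bin: `bin_lo_bp`, `bin_hi_bp`,
#'   `n_pairs`, `mean_distance_bp`, `c` (recombination fraction),
#'   `t_generations`, `mean_r2_adj`, `ne`, `note`.
#' @export
ne_trajectory <- function(pairs, n_individuals, spec = mapping_spec(),
                          bin_edges = ne_bin_edges()) {
  if (length(bin_edges) < 2L) stop("need at least 2 bin edges")
  pairs <- pairs[!is.na(pairs$distance_bp), , drop = FALSE]
  n_bins <- length(bin_edges) - 1L
  out <- data.frame(bin_lo_bp = bin_edges[-length(bin_edges)],
                    bin_hi_bp = bin_edges[-1L])
  out$n_pairs <- 0L
  out$mean_distance_bp <- NA_real_
  out$c <- NA_real_
  out$t_generations <- NA_real_
  out$mean_r2_adj <- NA_real_
  out$ne <- NA_real_
  out$note <- ""
  r2_adj <- adjust_r2(pairs$r2, n_individuals)
  for (b in seq_len(n_bins)) {
    in_bin <- pairs$distance_bp >= out$bin_lo_bp[b] &
      pairs$distance_bp < out$bin_hi_bp[b]
    out$n_pairs[b] <- sum(in_bin)
    if (out$n_pairs[b] == 0L) {
      out$note[b] <- "no pairs"
      next
    }
    out$mean_distance_bp[b] <- mean(pairs$distance_bp[in_bin])
    fc <- sved_mapping(out$mean_distance_bp[b], spec)$f_c
    out$c[b] <- fc
    out$t_generations[b] <- 1 / (2 * fc)
    out$mean_r2_adj[b] <- mean(r2_adj[in_bin])
    if (out$mean_r2_adj[b] <= 0 ||
        1 / out$mean_r2_adj[b] - spec$mutation_constant_a <= 0) {
      out$note[b] <- "mean adjusted r2 outside (0, 1/a): Ne undefined"
      next
    }
    out$ne[b] <- ne_point(out$mean_r2_adj[b], fc, spec$mutation_constant_a)
  }
  out[order(out$t_generations), , drop = FALSE]
}
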
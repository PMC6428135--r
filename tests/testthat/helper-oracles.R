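# Independent oracles and small fixture builders shared across tests.

# Build a genotype_matrix from a call matrix and marker positions.
g_small <- function(calls, pos, chrom = rep("1", length(pos)),
                    samples = NULL) {
  map <- data.frame(
    marker_id = paste0("m", seq_along(pos)), chromosome = chrom,
    position_bp = pos, allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE)
  genotype_matrix(calls, map, samples)
}

# Genotype matrix realising an explicit 3x3 genotype count table for two
# markers (rows: dose at marker 1 = 0/1/2; cols: dose at marker 2).
g_from_table <- function(tab, pos = c(1000L, 2000L)) {
  calls <- NULL
  for (a in 0:2) for (b in 0:2) {
    k <- tab[a + 1L, b + 1L]
    if (k > 0) calls <- rbind(calls, matrix(c(a, b), nrow = k, ncol = 2,
                                            byrow = TRUE))
  }
  g_small(calls, pos)
}

# Exact HWE oracle by exhaustive enumeration of genotype assignments:
# every ordered genotype sequence over n individuals is weighted by
# 2^(#het) (the number of ordered allele pairs realising it); sequences
# are restricted to the observed allele count. Probability-ordering
# two-sided p-value. Feasible for n <= 8 (3^n sequences).
hwe_enum_oracle <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  n_a <- 2 * n_hom_a + n_het
  seqs <- as.matrix(expand.grid(rep(list(0:2), n)))  # dose of allele a
  hets <- rowSums(seqs == 1)
  a_copies <- rowSums(seqs)
  keep <- a_copies == n_a
  w <- 2^hets[keep]
  h <- hets[keep]
  p_h <- tapply(w, h, sum) / sum(w)
  p_obs <- p_h[[as.character(n_het)]]
  sum(p_h[p_h <= p_obs * (1 + 1e-10)])
}

# Grid-search likelihood oracle for the two-locus EM: evaluates the
# multinomial genotype log-likelihood over a regular grid on the
# haplotype simplex and returns the maximum. `denom` sets the step
# (1/denom). Likelihood computed from first principles, independently of
# the package.
.grid_cache <- new.env(parent = emptyenv())

simplex_cellp <- function(denom) {
  key <- as.character(denom)
  if (!is.null(.grid_cache[[key]])) return(.grid_cache[[key]])
  gr <- expand.grid(i = 0:denom, j = 0:denom, k = 0:denom)
  gr <- gr[gr$i + gr$j + gr$k <= denom, ]
  f11 <- gr$i / denom; f10 <- gr$j / denom; f01 <- gr$k / denom
  f00 <- 1 - f11 - f10 - f01
  cellp <- cbind(
    f00^2, 2 * f00 * f01, f01^2,
    2 * f00 * f10, 2 * (f11 * f00 + f10 * f01), 2 * f01 * f11,
    f10^2, 2 * f10 * f11, f11^2)
  .grid_cache[[key]] <- cellp
  cellp
}

grid_loglik_max <- function(tab, denom = 50L) {
  cellp <- simplex_cellp(denom)
  counts <- as.vector(t(tab))  # order (a,b) = (0,0),(0,1),...,(2,2)
  ll <- rep(0, nrow(cellp))
  for (cell in seq_len(9L)) {
    if (counts[cell] > 0) {
      ll <- ll + counts[cell] * log(pmax(cellp[, cell], 1e-300))
    }
  }
  max(ll)
}

# Multinomial genotype log-likelihood at given haplotype freqs (oracle
# route, used to evaluate the package's EM solution on the same scale).
loglik_at <- function(tab, f11, f10, f01, f00) {
  cellp <- c(
    f00^2, 2 * f00 * f01, f01^2,
    2 * f00 * f10, 2 * (f11 * f00 + f10 * f01), 2 * f01 * f11,
    f10^2, 2 * f10 * f11, f11^2)
  counts <- as.vector(t(tab))
  sum(ifelse(counts > 0, counts * log(pmax(cellp, 1e-300)), 0))
}

# Seeded random 3x3 genotype count tables with polymorphic margins.
random_tables <- function(n_tables, max_total = 12L, seed = 42L) {
  set.seed(seed)
  out <- list()
  while (length(out) < n_tables) {
    total <- sample(4:max_total, 1L)
    tab <- matrix(as.vector(stats::rmultinom(1, total, rep(1, 9))), 3, 3)
    dose_a <- sum(tab * matrix(0:2, 3, 3)) / (2 * total)
    dose_b <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * total)
    if (dose_a > 0 && dose_a < 1 && dose_b > 0 && dose_b < 1) {
      out[[length(out) + 1L]] <- tab
    }
  }
  out
}

sd_or_na_oracle <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)

# Random haplotype-frequency vectors on the simplex (Dirichlet(1,1,1,1)).
random_haplofreqs <- function(n, seed = 1L) {
  set.seed(seed)
  x <- matrix(stats::rexp(4 * n), ncol = 4)
  x / rowSums(x)
}
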
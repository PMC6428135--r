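# Forward-in-time Wright-Fisher genotype simulator and deterministic
# fixtures. The simulator provides genotype panels with known demographic
# truth (piecewise-constant Ne, uniform recombination, genotype-level
# missingness) so every pipeline stage is testable without external data.

#' Demographic configuration for the Wright-Fisher simulator
#'
#' The Ne schedule is piecewise constant: `ne_schedule` is a data frame
#' with columns `start_gen_ago` (descending) and `ne`; a piece's Ne
#' applies from its `start_gen_ago` forward in time until the next, more
#' recent piece begins. The first piece must start at or before
#' `n_generations` ago.
#'
#' Defaults describe the validation regime used throughout: a constant
#' population of 100 diploids simulated for 500 generations, 10
#' chromosomes of 10 Mb carrying 100 markers each, a uniform 1 cM/Mb map,
#' a 50-diploid sampled cohort and 2% missing calls.
#'
#' @param ne_schedule Data frame `start_gen_ago`, `ne`.
#' @param n_generations Generations simulated forward from the ancestral
#'   population.
#' @param n_chromosomes,chromosome_length_bp,n_markers_per_chromosome
#'   Genome layout.
#' @param morgans_per_bp Recombination rate (Morgans per bp).
#' @param n_sample Diploid cohort size drawn from the final generation.
#' @param missing_rate Per-call missingness fraction in `[0, 1)`.
#' @param maf_floor_init Initial allele frequencies are drawn uniformly in
#'   `(maf_floor_init, 1 - maf_floor_init)`.
#' @param seed Integer RNG seed; identical seed and config give
#'   bit-identical output.
#' @return A list of class `demography_config`.
#' @export
demography_config <- function(ne_schedule = data.frame(start_gen_ago = 500,
                                                       ne = 100),
                              n_generations = 500L, n_chromosomes = 10L,
                              chromosome_length_bp = 10e6,
                              n_markers_per_chromosome = 100L,
                              morgans_per_bp = 1e-8, n_sample = 50L,
                              missing_rate = 0.02, maf_floor_init = 0.05,
                              seed = 1L) {
  stopifnot(all(ne_schedule$ne > 0), nrow(ne_schedule) >= 1,
            missing_rate >= 0, missing_rate < 1,
            maf_floor_init >= 0, maf_floor_init < 0.5,
            n_generations >= 1, n_chromosomes >= 1,
            n_markers_per_chromosome >= 2)
  ne_schedule <- ne_schedule[order(-ne_schedule$start_gen_ago), , drop = FALSE]
  if (ne_schedule$start_gen_ago[1L] < n_generations) {
    stop("ne_schedule must cover n_generations (first piece starts at ",
         ne_schedule$start_gen_ago[1L], " generations ago)")
  }
  structure(list(ne_schedule = ne_schedule,
                 n_generations = as.integer(n_generations),
                 n_chromosomes = as.integer(n_chromosomes),
                 chromosome_length_bp = chromosome_length_bp,
                 n_markers_per_chromosome = as.integer(n_markers_per_chromosome),
                 morgans_per_bp = morgans_per_bp,
                 n_sample = as.integer(n_sample),
                 missing_rate = missing_rate,
                 maf_floor_init = maf_floor_init, seed = as.integer(seed)),
            class = "demography_config")
}

#' Declining-Ne configuration preset
#'
#' A large ancestral population collapsing to a small recent one, the
#' regime in which LD-based trajectories should show recent Ne well below
#' ancient Ne.
#'
#' @param ancestral_ne,recent_ne Ne before and after the drop.
#' @param drop_gen_ago Generation (ago) at which the drop occurs.
#' @param ... Passed to [demography_config()].
#' @return A `demography_config`.
#' @export
demography_decline <- function(ancestral_ne = 1000, recent_ne = 50,
                               drop_gen_ago = 8, ...) {
  args <- list(...)
  n_gen <- if (!is.null(args$n_generations)) args$n_generations else 300L
  args$n_generations <- n_gen
  args$ne_schedule <- data.frame(
    start_gen_ago = c(n_gen, drop_gen_ago), ne = c(ancestral_ne, recent_ne))
  do.call(demography_config, args)
}

# Ne at t generations ago under a piecewise-constant schedule.
ne_at <- function(t_ago, schedule) {
  eligible <- schedule$start_gen_ago >= t_ago
  if (!any(eligible)) stop("schedule does not cover generation ", t_ago)
  schedule$ne[max(which(eligible))]
}

# One generation of random mating with recombination for one chromosome.
# H: 2N x m haplotype matrix (0/1); returns 2N_next x m. pos: marker bp.
next_generation <- function(H, n_next, pos, chrom_len, morgans_per_bp) {
  n_par <- nrow(H) / 2L
  n_gam <- 2L * n_next
  parent <- sample.int(n_par, n_gam, replace = TRUE)
  start <- sample.int(2L, n_gam, replace = TRUE) - 1L
  l_morgan <- chrom_len * morgans_per_bp
  ncross <- stats::rpois(n_gam, l_morgan)

  out <- matrix(0L, nrow = n_gam, ncol = ncol(H))
  plain <- ncross == 0L
  if (any(plain)) {
    src <- 2L * (parent[plain] - 1L) + 1L + start[plain]
    out[plain, ] <- H[src, , drop = FALSE]
  }
  for (k in which(!plain)) {
    cuts <- sort(stats::runif(ncross[k], 0, chrom_len))
    use_hap <- (start[k] + findInterval(pos, cuts)) %% 2L
    h1 <- H[2L * parent[k] - 1L, ]
    h2 <- H[2L * parent[k], ]
    gam <- h1
    gam[use_hap == 1L] <- h2[use_hap == 1L]
    out[k, ] <- gam
  }
  out
}

#' Forward Wright-Fisher simulation of a SNP panel
#'
#' Initialises `2 * Ne(ancestral)` haplotypes at linkage equilibrium with
#' marker allele frequencies drawn uniformly above the configured floor,
#' then simulates `n_generations` of random mating with recombination
#' (crossover count Poisson with mean equal to the chromosome length in
#' Morgans, positions uniform) under the piecewise-constant Ne schedule.
#' A cohort of `n_sample` diploids is drawn from the final generation and
#' missingness applied independently per call. No mutation occurs during
#' the simulated epoch: variation is standing, as on a SNP array, and
#' markers that fix are retained (a MAF filter removes them downstream).
#'
#' @param cfg A [demography_config()].
#' @return A list with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (the config, seed and realised initial frequencies).
#' @export
simulate_wright_fisher <- function(cfg) {
  stopifnot(inherits(cfg, "demography_config"))
  if (cfg$n_sample > ne_at(0, cfg$ne_schedule)) {
    stop("cohort size (", cfg$n_sample, ") exceeds the final population (",
         ne_at(0, cfg$ne_schedule), " diploids)")
  }
  with_seed(cfg$seed, {
    m <- cfg$n_markers_per_chromosome
    call_blocks <- vector("list", cfg$n_chromosomes)
    map_blocks <- vector("list", cfg$n_chromosomes)
    p0_all <- numeric(0)
    for (chr in seq_len(cfg$n_chromosomes)) {
      pos <- sort(sample.int(cfg$chromosome_length_bp, m))
      p0 <- stats::runif(m, cfg$maf_floor_init, 1 - cfg$maf_floor_init)
      p0_all <- c(p0_all, p0)
      ne0 <- ne_at(cfg$n_generations, cfg$ne_schedule)
      H <- matrix(stats::rbinom(2L * ne0 * m, 1L, rep(p0, each = 2L * ne0)),
                  nrow = 2L * ne0, ncol = m)
      for (t_ago in seq(cfg$n_generations - 1L, 0L)) {
        H <- next_generation(H, ne_at(t_ago, cfg$ne_schedule), pos,
                             cfg$chromosome_length_bp, cfg$morgans_per_bp)
      }
      cohort <- sample.int(nrow(H) / 2L, cfg$n_sample)
      calls <- H[2L * cohort - 1L, , drop = FALSE] +
        H[2L * cohort, , drop = FALSE]
      if (cfg$missing_rate > 0) {
        drop <- stats::runif(length(calls)) < cfg$missing_rate
        calls[drop] <- NA_integer_
      }
      call_blocks[[chr]] <- calls
      map_blocks[[chr]] <- data.frame(
        marker_id = sprintf("snp_%d_%d", chr, pos),
        chromosome = as.character(chr), position_bp = pos,
        allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
    }
    g <- genotype_matrix(do.call(cbind, call_blocks),
                         do.call(rbind, map_blocks),
                         sprintf("ind_%03d", seq_len(cfg$n_sample)))
    list(genotypes = g,
         truth = list(config = cfg, seed = cfg$seed, init_freq = p0_all))
  })
}

#' Deterministic genotype fixture with prescribed homozygosity tracts
#'
#' Builds a genotype matrix whose markers lie on a regular grid and whose
#' calls realise a tract layout exactly: outside any tract every call is
#' heterozygous, inside a tract calls are homozygous (`"hom"`, dose 0 by
#' default), heterozygous (`"het"`) or missing (`"miss"`). Used to give
#' ROH detection a hand-checkable truth.
#'
#' @param tracts Data frame with columns `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `state` (`"hom"`, `"het"` or `"miss"`) and
#'   optionally `dose` (0 or 2 for `"hom"` tracts). Tracts may not
#'   overlap within a sample and chromosome. May have zero rows.
#' @param samples Sample ids of the matrix (defaults to those in
#'   `tracts`).
#' @param chromosomes Named numeric vector of chromosome lengths in bp.
#' @param spacing_bp Marker spacing, default 50 kb; markers at
#'   `spacing_bp, 2 spacing_bp, ...`.
#' @return A list with `genotypes` and `layout` (the tract table).
#' @export
make_roh_fixture <- function(tracts, samples = NULL,
                             chromosomes = c("1" = 5e6),
                             spacing_bp = 50e3) {
  if (is.null(samples)) {
    samples <- unique(tracts$sample_id)
    if (length(samples) == 0L) samples <- "ind_1"
  }
  if (nrow(tracts) > 0L) {
    for (key in unique(paste(tracts$sample_id, tracts$chromosome))) {
      tr <- tracts[paste(tracts$sample_id, tracts$chromosome) == key, ,
                   drop = FALSE]
      tr <- tr[order(tr$start_bp), , drop = FALSE]
      if (nrow(tr) > 1L &&
          any(tr$start_bp[-1L] <= tr$end_bp[-nrow(tr)])) {
        stop("overlapping tracts for ", key)
      }
    }
  }
  map_blocks <- lapply(names(chromosomes), function(chr) {
    pos <- seq(spacing_bp, chromosomes[[chr]], by = spacing_bp)
    data.frame(marker_id = sprintf("fx_%s_%d", chr, pos),
               chromosome = chr, position_bp = pos,
               allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, map_blocks)
  calls <- matrix(1L, nrow = length(samples), ncol = nrow(map))
  if (nrow(tracts) > 0L) {
    for (r in seq_len(nrow(tracts))) {
      k <- match(tracts$sample_id[r], samples)
      in_tract <- map$chromosome == as.character(tracts$chromosome[r]) &
        map$position_bp >= tracts$start_bp[r] &
        map$position_bp <= tracts$end_bp[r]
      value <- switch(tracts$state[r],
                      hom = if (!is.null(tracts$dose)) {
                        as.integer(tracts$dose[r])
                      } else 0L,
                      het = 1L,
                      miss = NA_integer_,
                      stop("unknown tract state: ", tracts$state[r]))
      calls[k, in_tract] <- value
    }
  }
  list(genotypes = genotype_matrix(calls, map, samples), layout = tracts)
}

#' Two-locus genotype fixture with known haplotype frequencies
#'
#' Draws `2 n_individuals` haplotypes from the given two-locus haplotype
#' distribution and pairs consecutive draws into diploids, giving a
#' two-marker genotype matrix whose true haplotype frequencies are known.
#'
#' @param freqs Numeric vector of length 4, `c(f11, f10, f01, f00)`
#'   (1 = counted allele at that locus), summing to 1.
#' @param n_individuals Diploid sample size.
#' @param seed Integer RNG seed.
#' @return A list with `genotypes`, `truth` (the frequencies) and
#'   `hap_counts` (realised haplotype counts).
#' @export
make_ld_fixture <- function(freqs, n_individuals, seed) {
  stopifnot(length(freqs) == 4L, abs(sum(freqs) - 1) < 1e-9,
            all(freqs >= 0))
  with_seed(seed, {
    hap <- sample.int(4L, 2L * n_individuals, replace = TRUE, prob = freqs)
    # haplotype index -> (allele at locus 1, allele at locus 2)
    al1 <- c(1L, 1L, 0L, 0L)[hap]
    al2 <- c(1L, 0L, 1L, 0L)[hap]
    odd <- seq(1L, 2L * n_individuals, by = 2L)
    calls <- cbind(al1[odd] + al1[odd + 1L], al2[odd] + al2[odd + 1L])
    map <- data.frame(marker_id = c("fxA", "fxB"), chromosome = "1",
                      position_bp = c(1000L, 2000L),
                      allele_a = "A", allele_b = "B",
                      stringsAsFactors = FALSE)
    list(genotypes = genotype_matrix(calls, map,
                                     sprintf("ind_%d", seq_len(n_individuals))),
         truth = stats::setNames(freqs, c("f11", "f10", "f01", "f00")),
         hap_counts = tabulate(hap, 4L))
  })
}
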
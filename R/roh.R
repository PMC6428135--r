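# Runs of homozygosity, PLINK --homozyg style: per-SNP hit proportions
# from sliding windows, then maximal candidate stretches filtered by
# length, SNP count, density and gap rules.

#' Parameters for ROH detection
#'
#' Defaults are the published sliding-window rules: 20-SNP windows with at
#' most 5 missing and 1 heterozygous call, minimum segment length 1 Mb
#' with at least 20 SNPs, at least one SNP per 200 kb, maximum gap
#' between consecutive SNPs 1000 kb. `hit_proportion` is the per-SNP
#' fraction of passing windows required to call a SNP candidate-
#' homozygous (the PLINK default 0.05).
#'
#' @param window_snps Window width in SNPs.
#' @param max_missing_in_window,max_het_in_window Window tolerance counts.
#' @param min_length_bp Minimum segment span in bp.
#' @param min_snps Minimum SNPs per segment.
#' @param min_density_bp_per_snp Maximum bp per SNP over the segment.
#' @param max_gap_bp Maximum gap between consecutive segment SNPs.
#' @param hit_proportion Per-SNP passing-window fraction threshold.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 20L, max_missing_in_window = 5L,
                       max_het_in_window = 1L, min_length_bp = 1e6,
                       min_snps = 20L, min_density_bp_per_snp = 200e3,
                       max_gap_bp = 1000e3, hit_proportion = 0.05) {
  stopifnot(window_snps > 0, min_length_bp > 0, min_snps > 0,
            min_density_bp_per_snp > 0, max_gap_bp > 0,
            hit_proportion > 0, hit_proportion <= 1)
  structure(list(window_snps = as.integer(window_snps),
                 max_missing_in_window = as.integer(max_missing_in_window),
                 max_het_in_window = as.integer(max_het_in_window),
                 min_length_bp = min_length_bp, min_snps = as.integer(min_snps),
                 min_density_bp_per_snp = min_density_bp_per_snp,
                 max_gap_bp = max_gap_bp, hit_proportion = hit_proportion),
            class = "roh_params")
}

# windowed counts of a logical vector: out[w] = sum(x[w..w+W-1])
window_sums <- function(x, W) {
  cs <- c(0, cumsum(x))
  cs[(W + 1L):length(cs)] - cs[seq_len(length(cs) - W)]
}

# Candidate stretches for one sample on one chromosome; returns start/end
# marker indices of maximal candidate runs (before gap/length filtering).
candidate_runs <- function(calls, params) {
  m <- length(calls)
  W <- params$window_snps
  miss <- is.na(calls)
  het <- !miss & calls == 1L
  pass <- window_sums(miss, W) <= params$max_missing_in_window &
    window_sums(het, W) <= params$max_het_in_window
  n_win <- length(pass)
  # windows containing SNP s: w in [max(1, s-W+1), min(s, n_win)]
  cp <- c(0, cumsum(pass))
  s <- seq_len(m)
  w_lo <- pmax(1L, s - W + 1L)
  w_hi <- pmin(s, n_win)
  hits <- cp[w_hi + 1L] - cp[w_lo]
  rate <- hits / (w_hi - w_lo + 1L)
  cand <- rate >= params$hit_proportion
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect runs of homozygosity
#'
#' Per individual and chromosome: slide a window of `window_snps` SNPs one
#' SNP at a time; a window passes if it holds at most
#' `max_missing_in_window` missing and `max_het_in_window` heterozygous
#' calls; a SNP is candidate-homozygous when the fraction of passing
#' windows covering it is at least `hit_proportion`. Maximal candidate
#' stretches are split at inter-SNP gaps above `max_gap_bp` and emitted
#' if they satisfy the length, SNP-count and density rules. Segment
#' endpoints are the first and last member SNP positions;
#' `length_bp = end - start + 1`.
#'
#' @param g A [genotype_matrix()] with markers sorted by position.
#' @param params A [roh_params()] object.
#' @return Data frame of segments: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, `length_class`. Chromosomes with
#'   fewer markers than the window width are skipped with a warning.
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(params, "roh_params"))
  segs <- list()
  for (chr in unique(g$map$chromosome)) {
    w <- which(g$map$chromosome == chr)
    if (length(w) < params$window_snps) {
      warning("chromosome ", chr, " has fewer markers (", length(w),
              ") than the window width; skipped")
      next
    }
    pos <- g$map$position_bp[w]
    gap_after <- c(diff(pos), Inf)  # gap between SNP k and k+1
    for (k in seq_len(n_samples(g))) {
      runs <- candidate_runs(g$calls[k, w], params)
      if (nrow(runs) == 0L) next
      for (r in seq_len(nrow(runs))) {
        # split the candidate run at gaps exceeding max_gap_bp
        s <- runs[r, "start"]; e <- runs[r, "end"]
        if (e > s) {
          big <- which(gap_after[s:(e - 1L)] > params$max_gap_bp)
        } else big <- integer(0)
        cut_end <- c(s + big - 1L, e)
        cut_start <- c(s, s + big)
        for (q in seq_along(cut_start)) {
          s2 <- cut_start[q]; e2 <- cut_end[q]
          n_snps <- e2 - s2 + 1L
          len <- pos[e2] - pos[s2] + 1
          if (len < params$min_length_bp) next
          if (n_snps < params$min_snps) next
          if (len / n_snps > params$min_density_bp_per_snp) next
          segs[[length(segs) + 1L]] <- data.frame(
            sample_id = g$samples[k], chromosome = chr,
            start_bp = pos[s2], end_bp = pos[e2],
            n_snps = n_snps, length_bp = len,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(segs) == 0L) {
    out <- data.frame(sample_id = character(0), chromosome = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, segs)
  }
  out$length_class <- classify_roh(out$length_bp)
  out
}

#' Assign ROH segments to length classes
#'
#' Seven classes with half-open bounds (Mb): `[1,5) [5,10) [10,15)
#' [15,20) [20,25) [25,50) [50,Inf)`, labelled after the conventional
#' printed ranges (`"1-4.999"`, ..., `">50"`).
#'
#' @param length_bp Numeric vector of segment lengths in bp.
#' @return Factor of class labels.
#' @export
classify_roh <- function(length_bp) {
  labels <- c("1-4.999 Mb", "5-9.999 Mb", "10-14.999 Mb", "15-19.999 Mb",
              "20-24.999 Mb", "25-49.999 Mb", ">50 Mb")
  cut(length_bp / 1e6, breaks = c(1, 5, 10, 15, 20, 25, 50, Inf),
      labels = labels, right = FALSE)
}

#' Summaries of a set of ROH segments
#'
#' Produces per-individual counts and total lengths, per-chromosome counts
#' and summed lengths, the genome fraction covered per individual (total
#' ROH length over total autosome length) with its cohort mean, and
#' Pearson correlations of per-chromosome ROH count and summed length
#' with chromosome length (and with per-chromosome mean adjacent r2 when
#' supplied).
#'
#' @param segments Segment table from [detect_roh()].
#' @param g The [genotype_matrix()] the segments came from (used for the
#'   sample list and, by default, chromosome lengths).
#' @param chrom_lengths Optional named numeric vector of chromosome
#'   lengths in bp; defaults to the maximum marker position per
#'   chromosome.
#' @param adjacent_r2 Optional named numeric vector of per-chromosome
#'   mean adjacent-pair r2 for the LD-vs-ROH correlation.
#' @return A list: `per_individual`, `per_chromosome`, `class_counts`,
#'   `coverage` (per-individual fraction and `mean_coverage`), and
#'   `correlations` (data frame with `n`, `r`, `p`; `NA` when fewer than
#'   3 chromosomes or no segments).
#' @export
roh_summaries <- function(segments, g, chrom_lengths = NULL,
                          adjacent_r2 = NULL) {
  chroms <- unique(g$map$chromosome)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(chr) {
      max(g$map$position_bp[g$map$chromosome == chr])
    }, numeric(1))
  }
  if (!all(chroms %in% names(chrom_lengths))) {
    stop("chrom_lengths must name every chromosome in the map")
  }
  genome_bp <- sum(chrom_lengths[chroms])

  per_ind <- data.frame(sample_id = g$samples, stringsAsFactors = FALSE)
  per_ind$n_roh <- vapply(per_ind$sample_id, function(s) {
    sum(segments$sample_id == s)
  }, numeric(1))
  per_ind$total_length_bp <- vapply(per_ind$sample_id, function(s) {
    sum(segments$length_bp[segments$sample_id == s])
  }, numeric(1))
  per_ind$coverage <- per_ind$total_length_bp / genome_bp

  per_chr <- data.frame(chromosome = chroms,
                        length_bp = unname(chrom_lengths[chroms]),
                        stringsAsFactors = FALSE)
  per_chr$n_roh <- vapply(chroms, function(chr) {
    sum(segments$chromosome == chr)
  }, numeric(1))
  per_chr$total_length_bp <- vapply(chroms, function(chr) {
    sum(segments$length_bp[segments$chromosome == chr])
  }, numeric(1))

  cor_row <- function(x, y, label) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L || nrow(segments) == 0L ||
        stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(comparison = label, n = sum(ok), r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    data.frame(comparison = label, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }
  correlations <- rbind(
    cor_row(per_chr$length_bp, per_chr$n_roh, "chrom_length_vs_n_roh"),
    cor_row(per_chr$length_bp, per_chr$total_length_bp,
            "chrom_length_vs_total_roh_length"))
  if (!is.null(adjacent_r2)) {
    r2v <- adjacent_r2[per_chr$chromosome]
    correlations <- rbind(
      correlations,
      cor_row(r2v, per_chr$total_length_bp, "adjacent_r2_vs_total_roh_length"))
  }

  list(per_individual = per_ind,
       per_chromosome = per_chr,
       class_counts = table(segments$length_class),
       coverage = list(per_individual = per_ind$coverage,
                       mean_coverage = mean(per_ind$coverage)),
       correlations = correlations)
}
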
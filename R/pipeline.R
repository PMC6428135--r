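# End-to-end orchestration: QC -> ROH -> per-MAF LD decay / adjacent /
# non-syntenic background -> per-MAF Ne trajectories -> mean trajectory.
# Every table written is recomputable from the returned stage outputs.

#' Run the full LD / ROH / Ne pipeline
#'
#' Applies the QC cascade once (sample and marker call rate, HWE exact
#' test), detects ROH on the QC-passed panel, then for each MAF threshold
#' builds the syntenic pair set, the distance-binned decay table, the
#' adjacent-pair per-chromosome summary, the non-syntenic background and
#' the Ne trajectory; finally averages the per-MAF trajectories. All
#' tables are written tab-delimited under `out_dir` together with a run
#' manifest recording seeds and stage counts.
#'
#' @param genotypes A [genotype_matrix()]; alternatively give `ped_path`
#'   and `map_path`.
#' @param ped_path,map_path PLINK text input, used when `genotypes` is
#'   `NULL`.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param autosomes Chromosome labels to retain, or `NULL` to keep all.
#' @param maf_thresholds MAF thresholds, one LD/Ne analysis per value.
#' @param sample_call_rate,marker_call_rate,hwe_p QC thresholds.
#' @param thin_to Optional named vector (names = thresholds as given)
#'   of marker counts to thin each MAF dataset to.
#' @param max_distance_bp Syntenic pair distance cut-off.
#' @param decay_bins Decay-table bins, default [default_decay_bins()].
#' @param nonsyntenic_n Markers sampled for background LD; default 5% of
#'   the panel.
#' @param ld_n_haplotypes `"global"` (default; one n for the whole
#'   cohort, the published-table convention) or `"pairwise"`.
#' @param roh A [roh_params()].
#' @param map_spec A [mapping_spec()].
#' @param ne_bins Ne distance-bin edges, default [ne_bin_edges()].
#' @param seed Integer seed driving thinning and background sampling.
#' @return A list: `qc` (report), `roh` (`segments`, `summaries`),
#'   `per_maf` (per threshold: `decay`, `adjacent`, `background`,
#'   `trajectory`, `n_markers`, `n_pairs`, `n_skipped`),
#'   `mean_trajectory`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(genotypes = NULL, ped_path = NULL, map_path = NULL,
                         out_dir = NULL, autosomes = NULL,
                         maf_thresholds = c(0.01, 0.05, 0.1),
                         sample_call_rate = 0.9, marker_call_rate = 0.9,
                         hwe_p = 0.01, thin_to = NULL,
                         max_distance_bp = 50e6,
                         decay_bins = default_decay_bins(),
                         nonsyntenic_n = NULL,
                         ld_n_haplotypes = c("global", "pairwise"),
                         roh = roh_params(), map_spec = mapping_spec(),
                         ne_bins = ne_bin_edges(), seed = 1L) {
  ld_n_haplotypes <- match.arg(ld_n_haplotypes)
  if (is.null(genotypes)) {
    if (is.null(ped_path) || is.null(map_path)) {
      stop("supply either `genotypes` or both `ped_path` and `map_path`")
    }
    genotypes <- read_ped_map(ped_path, map_path)
  }
  g0 <- if (!is.null(autosomes)) filter_autosomes(genotypes, autosomes) else genotypes

  cr <- call_rate_filter(g0, sample_call_rate, marker_call_rate)
  hw <- hwe_filter(cr$genotypes, hwe_p)
  g_base <- hw$genotypes
  qc_counts <- rbind(cr$report$counts, data.frame(
    stage = "hwe", n_samples = n_samples(g_base),
    n_markers = n_markers(g_base)))

  roh_segments <- withCallingHandlers(
    detect_roh(g_base, roh),
    warning = function(w) invokeRestart("muffleWarning"))
  roh_sum <- roh_summaries(roh_segments, g_base)

  per_maf <- list()
  trajectories <- list()
  for (thr in maf_thresholds) {
    key <- format(thr)
    g_maf <- maf_filter(g_base, thr)
    if (!is.null(thin_to) && key %in% names(thin_to)) {
      g_maf <- thin_markers(g_maf, thin_to[[key]], seed)
    }
    pairs <- scan_syntenic_pairs(g_maf, max_distance_bp,
                                 n_haplotypes = ld_n_haplotypes)
    adj <- adjacent_summary(scan_adjacent_pairs(
      g_maf, n_haplotypes = ld_n_haplotypes))
    n_bg <- if (is.null(nonsyntenic_n)) {
      max(2L, ceiling(0.05 * n_markers(g_maf)))
    } else nonsyntenic_n
    bg <- if (length(unique(g_maf$map$chromosome)) >= 2L) {
      nonsyntenic_background(g_maf, n_bg, seed,
                             n_haplotypes = ld_n_haplotypes)$summary
    } else NULL
    traj <- ne_trajectory(pairs, n_samples(g_maf), map_spec, ne_bins)
    per_maf[[key]] <- list(
      n_markers = n_markers(g_maf),
      n_pairs = nrow(pairs),
      n_skipped = attr(pairs, "n_skipped"),
      decay = bin_decay_table(pairs, decay_bins),
      adjacent = adj, background = bg, trajectory = traj)
    trajectories[[key]] <- traj
  }

  mean_traj <- if (length(trajectories) > 0L) {
    mean_trajectory(trajectories)
  } else NULL

  # per-chromosome LD vs chromosome length and vs summed ROH length,
  # from the highest-MAF adjacent table
  last_adj <- per_maf[[length(per_maf)]]$adjacent
  adj_chr <- last_adj[last_adj$chromosome != "Mean", , drop = FALSE]
  chrom_len <- stats::setNames(roh_sum$per_chromosome$length_bp,
                               roh_sum$per_chromosome$chromosome)
  roh_len <- stats::setNames(roh_sum$per_chromosome$total_length_bp,
                             roh_sum$per_chromosome$chromosome)
  correlations <- tryCatch(
    correlation_summaries(
      stats::setNames(adj_chr$mean_r2, adj_chr$chromosome),
      roh_len, chrom_len),
    error = function(e) NULL)

  manifest <- data.frame(
    key = c("package_version", "seed", "n_samples_input", "n_markers_input",
            "n_samples_base", "n_markers_base", "n_roh_segments",
            paste0("n_pairs_maf_", names(per_maf))),
    value = c(as.character(utils::packageVersion("ldnekit")), seed,
              n_samples(g0), n_markers(g0), n_samples(g_base),
              n_markers(g_base), nrow(roh_segments),
              vapply(per_maf, function(x) x$n_pairs, numeric(1))),
    stringsAsFactors = FALSE)

  result <- list(qc = list(counts = qc_counts,
                           samples_removed = cr$report$samples_removed,
                           markers_removed = cr$report$markers_removed,
                           hwe_removed = hw$removed),
                 roh = list(segments = roh_segments, summaries = roh_sum),
                 per_maf = per_maf, mean_trajectory = mean_traj,
                 correlations = correlations, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_tables(result, out_dir)
  result
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_tables <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$qc$counts, file.path(out_dir, "qc_counts.tsv"))
  write_tsv(result$roh$segments, file.path(out_dir, "roh_segments.tsv"))
  write_tsv(result$roh$summaries$per_individual,
            file.path(out_dir, "roh_per_individual.tsv"))
  write_tsv(result$roh$summaries$per_chromosome,
            file.path(out_dir, "roh_per_chromosome.tsv"))
  for (key in names(result$per_maf)) {
    block <- result$per_maf[[key]]
    write_tsv(block$decay, file.path(out_dir, paste0("ld_decay_maf", key, ".tsv")))
    write_tsv(block$adjacent,
              file.path(out_dir, paste0("ld_adjacent_maf", key, ".tsv")))
    if (!is.null(block$background)) {
      write_tsv(block$background,
                file.path(out_dir, paste0("ld_background_maf", key, ".tsv")))
    }
    write_tsv(block$trajectory,
              file.path(out_dir, paste0("ne_trajectory_maf", key, ".tsv")))
  }
  if (!is.null(result$mean_trajectory)) {
    write_tsv(result$mean_trajectory,
              file.path(out_dir, "ne_trajectory_mean.tsv"))
  }
  if (!is.null(result$correlations)) {
    write_tsv(result$correlations, file.path(out_dir, "correlations.tsv"))
  }
  write_tsv(result$manifest, file.path(out_dir, "manifest.tsv"))
  invisible(NULL)
}

#' Pearson correlations among per-chromosome LD, ROH and length
#'
#' @param mean_r2 Named vector (chromosome -> mean adjacent-pair r2).
#' @param roh_total_length Named vector (chromosome -> summed ROH length
#'   in bp).
#' @param chrom_lengths Named vector (chromosome -> length in bp).
#' @return Data frame with one row per comparison (`r2 vs length`,
#'   `roh vs length`, `r2 vs roh`): `comparison`, `n`, `r`, `p`;
#'   `r`/`p` are `NA` when fewer than 3 chromosomes are available.
#' @export
correlation_summaries <- function(mean_r2, roh_total_length, chrom_lengths) {
  chroms <- names(mean_r2)
  if (!setequal(chroms, names(roh_total_length)) ||
      !setequal(chroms, names(chrom_lengths))) {
    stop("chromosome sets differ between inputs")
  }
  x <- cbind(mean_r2 = mean_r2[chroms],
             roh = roh_total_length[chroms],
             len = chrom_lengths[chroms])
  one <- function(a, b, label) {
    ok <- stats::complete.cases(x[, a], x[, b])
    if (sum(ok) < 3L || stats::sd(x[ok, a]) == 0 || stats::sd(x[ok, b]) == 0) {
      return(data.frame(comparison = label, n = sum(ok), r = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok, a], x[ok, b])
    data.frame(comparison = label, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }
  rbind(one("mean_r2", "len", "mean_r2_vs_chrom_length"),
        one("roh", "len", "roh_length_vs_chrom_length"),
        one("mean_r2", "roh", "mean_r2_vs_roh_length"))
}

#' Average Ne trajectories across MAF datasets
#'
#' Aligns trajectories by bin (they must share the distance-bin grid) and
#' averages Ne per bin with equal weight per dataset, rounding as
#' configured. The reported generation is the unweighted mean of the
#' per-dataset generation values.
#'
#' @param trajectories Named list of trajectory data frames from
#'   [ne_trajectory()] (columns `t_generations`, `ne`).
#' @param digits Decimal places for the mean Ne column, default 0.
#' @return Data frame with `t_generations`, one `ne_<name>` column per
#'   input, and `mean_ne`.
#' @export
mean_trajectory <- function(trajectories, digits = 0) {
  stopifnot(length(trajectories) >= 1L)
  n_rows <- vapply(trajectories, nrow, integer(1))
  if (length(unique(n_rows)) != 1L) {
    stop("trajectories have different numbers of bins; grids differ")
  }
  t_mat <- vapply(trajectories, function(tr) tr$t_generations,
                  numeric(n_rows[1L]))
  t_mat <- matrix(t_mat, nrow = n_rows[1L])
  t_mean <- rowMeans(t_mat)
  rel_spread <- apply(t_mat, 1L, function(v) {
    if (all(is.na(v))) return(0)
    (max(v, na.rm = TRUE) - min(v, na.rm = TRUE)) / mean(v, na.rm = TRUE)
  })
  if (any(rel_spread > 0.5, na.rm = TRUE)) {
    stop("generation grids differ by more than 50% between trajectories")
  }
  ne_mat <- vapply(trajectories, function(tr) tr$ne, numeric(n_rows[1L]))
  ne_mat <- matrix(ne_mat, nrow = n_rows[1L])
  out <- data.frame(t_generations = t_mean)
  for (k in seq_along(trajectories)) {
    out[[paste0("ne_", names(trajectories)[k])]] <- ne_mat[, k]
  }
  out$mean_ne <- round(rowMeans(ne_mat), digits)
  out
}
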
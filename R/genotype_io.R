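#' Construct a genotype matrix
#'
#' The central data container: an `n_samples x n_markers` matrix of diploid
#' genotype calls coded as the count (0/1/2) of each marker's counted allele
#' (`allele_b`), with `NA` for missing, bound to a marker map.
#'
#' @param calls Integer matrix, samples in rows, markers in columns. Values
#'   must be 0, 1, 2 or `NA`.
#' @param map Data frame with columns `marker_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b`. One row per column of `calls`,
#'   sorted by chromosome then position.
#' @param samples Character vector of sample identifiers; defaults to the
#'   row names of `calls` or `"S1".."Sn"`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `map`, `samples`.
#' @seealso [read_ped_map()], [validate_genotypes()]
#' @export
genotype_matrix <- function(calls, map, samples = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) {
    samples <- rownames(calls)
    if (is.null(samples)) samples <- sprintf("S%d", seq_len(nrow(calls)))
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("marker_id", "chromosome", "position_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols) > 0L) {
    stop("map is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(map) != ncol(calls)) {
    stop("map has ", nrow(map), " markers but calls has ", ncol(calls),
         " columns")
  }
  if (length(samples) != nrow(calls)) {
    stop("length(samples) != nrow(calls)")
  }
  map$chromosome <- as.character(map$chromosome)
  map$position_bp <- as.integer(map$position_bp)
  rownames(calls) <- samples
  colnames(calls) <- map$marker_id
  structure(list(calls = calls, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$map), " markers on ",
      length(unique(x$map$chromosome)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Marker and sample counts of a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @return An integer count.
#' @export
n_markers <- function(g) nrow(g$map)

#' @rdname n_markers
#' @export
n_samples <- function(g) length(g$samples)

# Order markers by (chromosome, position); chromosomes sort numerically when
# all labels are numeric, lexicographically otherwise.
marker_order <- function(map) {
  chrom_num <- suppressWarnings(as.numeric(map$chromosome))
  if (anyNA(chrom_num)) {
    order(map$chromosome, map$position_bp)
  } else {
    order(chrom_num, map$position_bp)
  }
}

#' Subset a genotype matrix
#'
#' @param g A [genotype_matrix()].
#' @param samples,markers Integer or logical indices of samples/markers to
#'   keep (`NULL` keeps all). Marker map order is preserved.
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, markers = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(samples)) samples <- seq_along(g$samples)
  if (is.null(markers)) markers <- seq_len(n_markers(g))
  genotype_matrix(g$calls[samples, markers, drop = FALSE],
                  g$map[markers, , drop = FALSE],
                  g$samples[samples])
}

#' Keep only markers on a configured autosome set
#'
#' @param g A [genotype_matrix()].
#' @param autosomes Character vector of chromosome labels to retain;
#'   defaults to `"1".."29"`, the bovine autosomes.
#' @return A `genotype_matrix` restricted to those chromosomes.
#' @export
filter_autosomes <- function(g, autosomes = as.character(1:29)) {
  keep <- which(g$map$chromosome %in% autosomes)
  subset_genotypes(g, markers = keep)
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' Parses whitespace-delimited PED (6 leading columns, then two allele
#' tokens per marker; `"0"` = missing allele) and MAP (chromosome,
#' marker id, genetic position, bp position). Genotypes are coded as the
#' count of `allele_b`, which defaults to the lexicographically later of
#' the two observed alleles at each marker; `r2`, `|D'|` and homozygosity
#' are invariant under this orientation choice.
#'
#' Round-trip note: for a marker at which only one allele is observed the
#' orientation cannot be recovered from the file, so its dose reads back
#' as 0; supply `ref_alleles` to pin the counted allele and make
#' `read_ped_map(write_ped_map(g))` bit-exact on such markers.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @param ref_alleles Optional named character vector `marker_id -> allele`
#'   fixing which allele is counted.
#' @return A [genotype_matrix()] with markers sorted by
#'   (chromosome, position).
#' @export
read_ped_map <- function(ped_path, map_path, ref_alleles = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  n_tok <- lengths(map_tok)
  if (any(n_tok < 4L)) {
    stop("MAP line ", which(n_tok < 4L)[1L], " has fewer than 4 fields")
  }
  map <- data.frame(
    chromosome = vapply(map_tok, `[`, "", 1L),
    marker_id  = vapply(map_tok, `[`, "", 2L),
    position   = vapply(map_tok, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
  pos <- suppressWarnings(as.numeric(map$position))
  if (anyNA(pos)) {
    stop("MAP line ", which(is.na(pos))[1L], ": non-numeric position '",
         map$position[which(is.na(pos))[1L]], "'")
  }
  if (anyDuplicated(map$marker_id)) {
    stop("duplicate marker id in MAP: ",
         map$marker_id[anyDuplicated(map$marker_id)])
  }
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  a1 <- matrix("0", nrow = n, ncol = m)
  a2 <- matrix("0", nrow = n, ncol = m)
  samples <- character(n)
  for (k in seq_len(n)) {
    tok <- strsplit(trimws(ped_lines[k]), "[ \t]+")[[1L]]
    if (length(tok) != 6L + 2L * m) {
      stop("PED line ", k, " has ", length(tok), " fields, expected ",
           6L + 2L * m)
    }
    samples[k] <- tok[2L]
    gt <- tok[-(1:6)]
    a1[k, ] <- gt[seq(1L, 2L * m, by = 2L)]
    a2[k, ] <- gt[seq(2L, 2L * m, by = 2L)]
  }

  calls <- matrix(NA_integer_, nrow = n, ncol = m)
  allele_a <- character(m)
  allele_b <- character(m)
  for (j in seq_len(m)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(unique(obs[obs != "0"]))
    if (length(alleles) > 2L) {
      stop("marker ", map$marker_id[j], " has >2 alleles: ",
           paste(alleles, collapse = "/"))
    }
    ref <- NULL
    if (!is.null(ref_alleles) && map$marker_id[j] %in% names(ref_alleles)) {
      ref <- ref_alleles[[map$marker_id[j]]]
    }
    if (length(alleles) == 0L) {
      allele_a[j] <- NA_character_; allele_b[j] <- NA_character_
      next
    }
    b <- if (!is.null(ref)) ref else alleles[length(alleles)]
    a <- setdiff(alleles, b)
    allele_a[j] <- if (length(a) > 0L) a[1L] else NA_character_
    allele_b[j] <- b
    ok <- a1[, j] != "0" & a2[, j] != "0"
    calls[ok, j] <- (a1[ok, j] == b) + (a2[ok, j] == b)
  }

  full_map <- data.frame(
    marker_id = map$marker_id, chromosome = map$chromosome,
    position_bp = as.integer(pos), allele_a = allele_a, allele_b = allele_b,
    stringsAsFactors = FALSE
  )
  ord <- marker_order(full_map)
  genotype_matrix(calls[, ord, drop = FALSE],
                  full_map[ord, , drop = FALSE], samples)
}

#' Write genotypes to PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: missing calls become `"0 0"`, homozygotes
#' and heterozygotes are spelled with `allele_a`/`allele_b`. A marker whose
#' `allele_b` is `NA` (monomorphic) is written with `allele_a` only.
#'
#' @param g A [genotype_matrix()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `NULL`.
#' @export
write_ped_map <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- g$map
  map_out <- paste(map$chromosome, map$marker_id, 0L, map$position_bp)
  writeLines(map_out, map_path)

  m <- n_markers(g)
  n <- n_samples(g)
  a <- ifelse(is.na(map$allele_a), map$allele_b, map$allele_a)
  b <- ifelse(is.na(map$allele_b), map$allele_a, map$allele_b)
  ped_lines <- character(n)
  for (k in seq_len(n)) {
    calls <- g$calls[k, ]
    t1 <- ifelse(is.na(calls), "0", ifelse(calls >= 1L, b, a))
    t2 <- ifelse(is.na(calls), "0", ifelse(calls == 2L, b, a))
    ped_lines[k] <- paste(c(g$samples[k], g$samples[k], "0", "0", "0", "-9",
                            as.vector(rbind(t1, t2))), collapse = " ")
  }
  writeLines(ped_lines, ped_path)
  invisible(NULL)
}

#' Validate a genotype matrix
#'
#' Checks the container invariants and reports violations without
#' raising: out-of-range genotype codes, duplicate marker ids, duplicate
#' chromosome+position pairs, markers not sorted by position within a
#' chromosome, positions below 1.
#'
#' @param g A [genotype_matrix()].
#' @return A sorted character vector of findings; empty iff all
#'   invariants hold.
#' @export
validate_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  findings <- character(0)
  bad <- !is.na(g$calls) & !(g$calls %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    findings <- c(findings, sprintf(
      "out-of-range genotype code %d at sample '%s', marker '%s'",
      g$calls[bad][1L], g$samples[idx[1L]], g$map$marker_id[idx[2L]]))
  }
  dup_id <- unique(g$map$marker_id[duplicated(g$map$marker_id)])
  for (id in dup_id) {
    findings <- c(findings, sprintf("duplicate marker id '%s'", id))
  }
  key <- paste(g$map$chromosome, g$map$position_bp)
  dup_pos <- unique(key[duplicated(key)])
  for (kp in dup_pos) {
    findings <- c(findings, sprintf(
      "duplicate position: chromosome %s bp %s",
      sub(" .*", "", kp), sub(".* ", "", kp)))
  }
  if (any(g$map$position_bp < 1L, na.rm = TRUE)) {
    findings <- c(findings, "position_bp below 1")
  }
  for (chr in unique(g$map$chromosome)) {
    p <- g$map$position_bp[g$map$chromosome == chr]
    if (is.unsorted(p, strictly = FALSE)) {
      findings <- c(findings,
                    sprintf("markers unsorted on chromosome %s", chr))
    }
  }
  sort(findings)
}
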
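#' Convergent-transcription flags per gene
#'
#' A gene is flagged when more than `min_overlap` bp (strictly) of sense
#' and antisense transcription overlap within its body: some plus-strand
#' transcribed interval, intersected with a minus-strand interval,
#' intersected with the gene body, must exceed `min_overlap` bp.
#'
#' @param plus_intervals,minus_intervals Tibbles of transcribed intervals
#'   (`chrom`, `start`, `end`; 0-based half-open) or paths to stranded BED
#'   files (strand filtered from column 6 when both strands share a file).
#' @param gene_bodies Tibble (`chrom`, `start`, `end`, `name`) or BED path;
#'   `name` is the gene id.
#' @param min_overlap Overlap must be strictly greater than this (bp).
#' @return Tibble `gene`, `convt` (0/1), one row per gene body.
#' @export
convergent_transcription_flags <- function(plus_intervals, minus_intervals,
                                           gene_bodies, min_overlap = 100) {
  load_iv <- function(x, strand_filter = NULL) {
    if (is.character(x) && length(x) == 1) {
      b <- read_bed_intervals(x, min_cols = 3)
      if (!is.null(strand_filter) && any(!is.na(b$strand))) {
        b <- b[!is.na(b$strand) & b$strand == strand_filter, , drop = FALSE]
      }
      b
    } else {
      tibble::as_tibble(x)
    }
  }
  plus <- load_iv(plus_intervals, "+")
  minus <- load_iv(minus_intervals, "-")
  genes <- load_iv(gene_bodies)
  if (!"name" %in% names(genes) || anyNA(genes$name)) {
    genes$name <- paste0("gene", seq_len(nrow(genes)))
  }
  flags <- stats::setNames(rep(0L, nrow(genes)), genes$name)
  if (nrow(plus) > 0 && nrow(minus) > 0 && nrow(genes) > 0) {
    gr <- function(tb) GenomicRanges::GRanges(
      tb$chrom, IRanges::IRanges(start = tb$start + 1L, end = tb$end))
    gp <- gr(plus)
    gm <- gr(minus)
    gg <- gr(genes)
    ov <- GenomicRanges::findOverlaps(gp, gm)
    if (length(ov) > 0) {
      pieces <- GenomicRanges::pintersect(
        gp[S4Vectors::queryHits(ov)], gm[S4Vectors::subjectHits(ov)])
      ov2 <- GenomicRanges::findOverlaps(pieces, gg)
      if (length(ov2) > 0) {
        final <- GenomicRanges::pintersect(
          pieces[S4Vectors::queryHits(ov2)], gg[S4Vectors::subjectHits(ov2)])
        hit_genes <- genes$name[S4Vectors::subjectHits(ov2)][
          GenomicRanges::width(final) > min_overlap]
        flags[unique(hit_genes)] <- 1L
      }
    }
  }
  tibble::tibble(gene = names(flags), convt = unname(flags))
}

#' Filter a gene feature table for tree fitting
#'
#' Drops genes whose mutation frequency in the AID-null background exceeds
#' the cutoff (strictly), to avoid residual polymorphism or alignment
#' artifacts, and validates the feature columns: continuous features must
#' be nonnegative, binary marks in \{0, 1\}.
#'
#' @param table Gene feature tibble (see [simulate_feature_table()] for the
#'   expected columns).
#' @param background_freq_cutoff Exclusion threshold (default 5e-4).
#' @return Filtered tibble; errors if empty afterwards or if a required
#'   column is missing.
#' @export
prepare_features <- function(table, background_freq_cutoff = 5e-4) {
  continuous <- c("expression_tpm", "transcription_rate",
                  "polII_density", "spt5_density")
  binary <- c("med12", "h3k4me1", "h3k36me3", "h3k79me2",
              "superenhancer", "convt")
  required <- c("gene", continuous, binary, "background_freq")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(paste0("prepare_features: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n0 <- nrow(table)
  out <- table[table$background_freq <= background_freq_cutoff, ,
               drop = FALSE]
  inform(paste0("prepare_features: excluded ", n0 - nrow(out),
                " gene(s) with background frequency > ",
                format(background_freq_cutoff)))
  if (nrow(out) == 0) abort("prepare_features: no genes left after filter")
  for (col in continuous) {
    if (any(out[[col]] < 0)) {
      abort(paste0("prepare_features: negative values in ", col))
    }
  }
  for (col in binary) {
    if (!all(out[[col]] %in% c(0, 1))) {
      abort(paste0("prepare_features: non-binary values in ", col))
    }
  }
  out
}
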
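#' AID hotspot motif specification
#'
#' A motif is an IUPAC pattern together with the offset of the deaminated
#' cytosine within it. The canonical somatic-hypermutation hotspot is WRCY
#' (W = A/T, R = A/G, Y = C/T) with the deaminated C at offset 2; AGCTNT is
#' the extended hotspot with the same C offset.
#'
#' @param name Motif name used in outputs.
#' @param iupac Uppercase IUPAC pattern; position `deaminated_index` must be
#'   a literal `C`.
#' @param deaminated_index 0-based offset of the deaminated cytosine.
#' @return An object of class `motif_spec`.
#' @examples
#' motif_spec("WRCY", "WRCY", 2)
#' @export
motif_spec <- function(name, iupac, deaminated_index) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(iupac), length(iupac) == 1, nchar(iupac) >= 1)
  deaminated_index <- as.integer(deaminated_index)
  if (deaminated_index < 0 || deaminated_index >= nchar(iupac)) {
    abort("deaminated_index out of range for motif pattern")
  }
  if (substr(iupac, deaminated_index + 1, deaminated_index + 1) != "C") {
    abort(paste0("motif '", name, "': position ", deaminated_index,
                 " of pattern '", iupac, "' is not 'C'"))
  }
  # validates the alphabet
  iupac_to_regex(iupac)
  structure(list(name = name, iupac = iupac,
                 deaminated_index = deaminated_index),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("<motif_spec> ", x$name, ": ", x$iupac,
      " (deaminated C at offset ", x$deaminated_index, ")\n", sep = "")
  invisible(x)
}

#' Preset AID hotspot motifs
#'
#' Returns the built-in motif definitions: `WRC`, `WRCY`, `AGCTNT`, its
#' control `AGCTNV` (same AGCT core, any non-T two bases downstream), and the
#' eight concrete WRCY variants (`AACT`, `AGCT`, `TACT`, `TGCT`, `AACC`,
#' `AGCC`, `TACC`, `TGCC`). All have the deaminated C at offset 2.
#'
#' @param names Optional character vector selecting a subset.
#' @return Named list of [motif_spec()] objects.
#' @examples
#' preset_motifs(c("WRCY", "AGCTNT"))
#' @export
preset_motifs <- function(names = NULL) {
  wrcy_variants <- c("AACT", "AGCT", "TACT", "TGCT",
                     "AACC", "AGCC", "TACC", "TGCC")
  all <- c(
    list(
      WRC = motif_spec("WRC", "WRC", 2),
      WRCY = motif_spec("WRCY", "WRCY", 2),
      AGCTNT = motif_spec("AGCTNT", "AGCTNT", 2),
      AGCTNV = motif_spec("AGCTNV", "AGCTNV", 2)
    ),
    stats::setNames(
      lapply(wrcy_variants, function(v) motif_spec(v, v, 2)),
      wrcy_variants
    )
  )
  if (is.null(names)) return(all)
  missing <- setdiff(names, base::names(all))
  if (length(missing) > 0) {
    abort(paste0("unknown preset motif(s): ", paste(missing, collapse = ", ")))
  }
  all[names]
}

as_motif_list <- function(motifs) {
  if (inherits(motifs, "motif_spec")) return(list(motifs))
  if (!is.list(motifs) || !all(vapply(motifs, inherits, logical(1), "motif_spec"))) {
    abort("motifs must be a motif_spec or a list of motif_spec objects")
  }
  motifs
}

# All start positions (1-based) of overlapping regex matches in `sequence`.
overlapping_starts <- function(sequence, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan a sequence for hotspot motif instances on both strands
#'
#' Plus-strand instances are direct matches of the IUPAC pattern; minus-strand
#' instances are matches of the reverse complement of the pattern on the plus
#' strand (a deaminated C on the minus strand appears as a G on the plus
#' strand). Reported positions are 0-based plus-strand coordinates of the
#' deaminated base. Overlapping and nested matches are all reported; an `N`
#' in the sequence matches only motif letter `N`.
#'
#' @param sequence Uppercase DNA string over A/C/G/T/N.
#' @param motif A [motif_spec()].
#' @return Tibble with columns `position`, `strand`, `motif_name`.
#' @examples
#' scan_motif("AGCTAT", preset_motifs("WRCY")[[1]])
#' @export
scan_motif <- function(sequence, motif) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  motif <- as_motif_list(motif)[[1]]
  L <- nchar(motif$iupac)
  fwd <- overlapping_starts(sequence, iupac_to_regex(motif$iupac))
  rev <- overlapping_starts(sequence, iupac_to_regex(revcomp(motif$iupac)))
  tibble::tibble(
    position = c(fwd - 1L + motif$deaminated_index,
                 rev - 1L + (L - 1L - motif$deaminated_index)),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    motif_name = motif$name
  ) %>%
    dplyr::arrange(.data$position, .data$strand)
}

#' Annotate hotspot instances across target regions
#'
#' Applies [scan_motif()] for every motif to every region and returns the
#' union as a long table: one row per hotspot instance. A position inside
#' several instances appears once per (motif, strand) membership; downstream
#' denominators count each position once.
#'
#' @param regions Tibble of target regions (see [load_regions()]), with at
#'   least `region_id` and `sequence` columns.
#' @param motifs A [motif_spec()] or list of them, e.g. from
#'   [preset_motifs()].
#' @return Tibble with columns `region_id`, `position`, `strand`,
#'   `motif_name`.
#' @export
annotate_hotspots <- function(regions, motifs) {
  motifs <- as_motif_list(motifs)
  if (length(motifs) == 0 || nrow(regions) == 0) {
    return(tibble::tibble(region_id = character(), position = integer(),
                          strand = character(), motif_name = character()))
  }
  # gregexpr is vectorised over sequences; one call per motif x orientation
  scan_all <- function(regex, offset, strand, motif_name) {
    m <- gregexpr(paste0("(?=", regex, ")"), regions$sequence, perl = TRUE)
    starts <- lapply(m, function(x) if (x[1] == -1) integer(0) else as.integer(x))
    n_hits <- lengths(starts)
    tibble::tibble(
      region_id = rep(regions$region_id, n_hits),
      position = unlist(starts, use.names = FALSE) - 1L + offset,
      strand = strand,
      motif_name = motif_name
    )
  }
  purrr::map_dfr(motifs, function(mo) {
    L <- nchar(mo$iupac)
    dplyr::bind_rows(
      scan_all(iupac_to_regex(mo$iupac), mo$deaminated_index, "+", mo$name),
      scan_all(iupac_to_regex(revcomp(mo$iupac)),
               L - 1L - mo$deaminated_index, "-", mo$name)
    )
  }) %>%
    dplyr::arrange(.data$region_id, .data$position, .data$strand)
}

#' Write hotspot annotation as BED
#'
#' Emits one BED line per hotspot instance with 0-based half-open
#' single-base intervals and name `motif|strand`.
#'
#' @param hotspots Output of [annotate_hotspots()].
#' @param regions Regions table supplying `chrom` and `start` offsets.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hotspot_bed <- function(hotspots, regions, path) {
  joined <- dplyr::inner_join(
    hotspots,
    dplyr::select(regions, "region_id", "chrom", "start"),
    by = "region_id"
  )
  bed <- tibble::tibble(
    chrom = joined$chrom,
    start = joined$start + joined$position,
    end = joined$start + joined$position + 1L,
    name = paste0(joined$motif_name, "|", joined$strand)
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
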
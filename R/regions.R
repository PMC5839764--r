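#' Load capture regions from BED and FASTA
#'
#' Reads a BED file (>= 4 columns; the name column carries the region id)
#' and slices each region's sequence out of the FASTA contigs. Coordinates
#' are 0-based half-open, as in BED, and stay that way throughout the
#' package. Sequences are uppercased.
#'
#' @param bed_path Path to a BED file of capture intervals.
#' @param fasta_path Path to the FASTA file holding the contigs.
#' @return Tibble with columns `region_id`, `gene`, `chrom`, `start`, `end`,
#'   `sequence`. `gene` defaults to the region id; capture designs that tile
#'   one gene with several regions can overwrite it.
#' @export
load_regions <- function(bed_path, fasta_path) {
  contigs <- Biostrings::readDNAStringSet(fasta_path)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  bed <- read_bed_intervals(bed_path, min_cols = 4)
  if (nrow(bed) == 0) {
    return(tibble::tibble(region_id = character(), gene = character(),
                          chrom = character(), start = integer(),
                          end = integer(), sequence = character()))
  }
  seqs <- vapply(seq_len(nrow(bed)), function(i) {
    chrom <- bed$chrom[i]
    if (!chrom %in% names(contigs)) {
      abort(paste0("BED contig not present in FASTA: ", chrom))
    }
    clen <- Biostrings::width(contigs[chrom])
    if (bed$end[i] > clen) {
      abort(paste0("region ", bed$name[i], " [", bed$start[i], ",", bed$end[i],
                   ") exceeds contig ", chrom, " length ", clen))
    }
    toupper(as.character(Biostrings::subseq(contigs[[chrom]],
                                            start = bed$start[i] + 1L,
                                            end = bed$end[i])))
  }, character(1))
  tibble::tibble(
    region_id = bed$name,
    gene = bed$name,
    chrom = bed$chrom,
    start = bed$start,
    end = bed$end,
    sequence = seqs
  )
}

# Minimal BED reader: tab- or space-separated, no header, 0-based half-open.
# Validates per line and reports the first malformed line by number.
read_bed_intervals <- function(path, min_cols = 3) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          score = character(), strand = character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  out <- purrr::map_dfr(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < min_cols) {
      abort(paste0("malformed BED line ", i, ": expected >= ", min_cols,
                   " columns, got ", length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || end <= start) {
      abort(paste0("malformed BED line ", i,
                   ": start/end must be integers with end > start"))
    }
    tibble::tibble(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else NA_character_,
      score = if (length(f) >= 5) f[5] else NA_character_,
      strand = if (length(f) >= 6) f[6] else NA_character_
    )
  })
  out
}

#' Read a per-base count table
#'
#' The TSV schema is `region_id, pos, ref, depth, A, C, G, T` with `pos`
#' 0-based and region-local.
#'
#' @param path TSV file.
#' @return Tibble of site counts.
#' @export
read_counts_tsv <- function(path) {
  counts <- readr::read_tsv(path, col_types = readr::cols(
    region_id = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    depth = readr::col_integer(),
    A = readr::col_integer(), C = readr::col_integer(),
    G = readr::col_integer(), T = readr::col_integer()
  ))
  validate_counts(counts)
  counts
}

#' Write a per-base count table
#'
#' @param counts Site-count tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  validate_counts(counts)
  readr::write_tsv(counts[, c("region_id", "pos", "ref", "depth",
                              "A", "C", "G", "T")], path)
  invisible(path)
}

validate_counts <- function(counts) {
  required <- c("region_id", "pos", "ref", "depth", "A", "C", "G", "T")
  missing <- setdiff(required, names(counts))
  if (length(missing) > 0) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tot <- counts$A + counts$C + counts$G + counts$T
  if (any(tot != counts$depth)) {
    abort("count table invariant violated: A+C+G+T must equal depth")
  }
  invisible(counts)
}

#' Read a germline SNP mask (BED or VCF)
#'
#' Accepts a BED file (0-based half-open single-base intervals) or a VCF
#' (positions only; 1-based, converted to 0-based). Genomic coordinates are
#' mapped to region-local positions against `regions`; SNPs falling outside
#' every region are dropped.
#'
#' @param path BED or VCF file (uncompressed).
#' @param regions Regions table from [load_regions()].
#' @return Tibble with columns `region_id`, `pos` (region-local, 0-based).
#' @export
read_snp_mask <- function(path, regions) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) > 0 && startsWith(first, "##fileformat=VCF")) {
    lines <- readr::read_lines(path)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    snps <- tibble::tibble(
      chrom = vapply(fields, `[`, character(1), 1),
      gpos = vapply(fields, function(f) as.integer(f[2]), integer(1)) - 1L
    )
  } else {
    bed <- read_bed_intervals(path, min_cols = 3)
    snps <- tibble::tibble(chrom = bed$chrom, gpos = bed$start)
  }
  localize_positions(snps, regions)
}

# Map genomic (chrom, gpos 0-based) points into region-local coordinates.
localize_positions <- function(points, regions) {
  if (nrow(points) == 0 || nrow(regions) == 0) {
    return(tibble::tibble(region_id = character(), pos = integer()))
  }
  dplyr::inner_join(points, regions, by = "chrom",
                    relationship = "many-to-many") %>%
    dplyr::filter(.data$gpos >= .data$start, .data$gpos < .data$end) %>%
    dplyr::transmute(region_id = .data$region_id,
                     pos = as.integer(.data$gpos - .data$start)) %>%
    dplyr::distinct()
}
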
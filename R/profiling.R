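#' Remove germline SNP positions from a count table
#'
#' Drops rows at annotated SNP positions and, optionally, rows whose largest
#' non-reference allele fraction reaches `vaf_threshold` (a crude de-novo
#' polymorphism filter, disabled by default — the genotype contrast against
#' the AID-null control is the intended error control).
#'
#' @param counts Site-count tibble (`region_id`, `pos`, `ref`, `depth`,
#'   `A`, `C`, `G`, `T`).
#' @param snp_positions Tibble with `region_id` and `pos` columns (extra
#'   columns ignored), or NULL for no mask.
#' @param vaf_threshold Numeric in (0,1] or NULL (disabled).
#' @return Filtered count tibble; the number of removed rows is reported via
#'   `message()` and attached as attribute `n_masked`.
#' @export
mask_snps <- function(counts, snp_positions = NULL, vaf_threshold = NULL) {
  n0 <- nrow(counts)
  out <- counts
  if (!is.null(snp_positions) && nrow(snp_positions) > 0) {
    out <- dplyr::anti_join(out, snp_positions[, c("region_id", "pos")],
                            by = c("region_id", "pos"))
  }
  if (!is.null(vaf_threshold)) {
    m <- as.matrix(out[, c("A", "C", "G", "T")])
    m[cbind(seq_len(nrow(out)), match(out$ref, c("A", "C", "G", "T")))] <- 0L
    max_alt_frac <- ifelse(out$depth > 0,
                           apply(m, 1, max) / out$depth, 0)
    out <- out[max_alt_frac < vaf_threshold, , drop = FALSE]
  }
  n_masked <- n0 - nrow(out)
  inform(paste0("mask_snps: removed ", n_masked, " of ", n0, " positions"))
  attr(out, "n_masked") <- n_masked
  out
}

#' Tally substitution calls from a masked count table
#'
#' One row per (position, non-reference base) with at least `min_alt_count`
#' supporting calls. Substitutions are labelled `"C>T"` style; transitions
#' are C>T, T>C, G>A, A>G. `c_frame_strand` records the deaminated-cytosine
#' frame: `"+"` at reference C, `"-"` at reference G, NA otherwise.
#' Reference-N rows are skipped.
#'
#' @param counts SNP-masked site-count tibble.
#' @param min_alt_count Minimum supporting calls per substitution.
#' @return Tibble of mutation sites.
#' @export
tally_mutations <- function(counts, min_alt_count = 1) {
  bases <- c("A", "C", "G", "T")
  counts <- counts[counts$ref %in% bases, , drop = FALSE]
  long <- tidyr::pivot_longer(
    counts, cols = dplyr::all_of(bases),
    names_to = "alt", values_to = "alt_count")
  long <- long[long$alt != long$ref & long$alt_count >= min_alt_count, ,
               drop = FALSE]
  transitions <- c("C>T", "T>C", "G>A", "A>G")
  dplyr::transmute(
    long,
    region_id = .data$region_id,
    pos = .data$pos,
    ref = .data$ref,
    alt = .data$alt,
    alt_count = .data$alt_count,
    depth = .data$depth,
    change_label = paste0(.data$ref, ">", .data$alt),
    change_class = ifelse(.data$change_label %in% transitions,
                          "transition", "transversion"),
    c_frame_strand = dplyr::case_when(.data$ref == "C" ~ "+",
                                      .data$ref == "G" ~ "-",
                                      TRUE ~ NA_character_)
  )
}

#' Subtract the AID-null control frequency per site
#'
#' The mutation frequency observed in the AID-null control is subtracted
#' site by site and the result floored at zero, the background correction
#' applied before plotting and context analysis.
#'
#' @param case_freqs,control_freqs Tibbles with `region_id`, `pos`, `freq`
#'   (extra columns of `case_freqs` are carried through).
#' @return `case_freqs` with `freq` replaced by `max(case - control, 0)`.
#'   Sites absent from the control are treated as control 0 with a warning.
#' @export
subtract_control <- function(case_freqs, control_freqs) {
  if (is.null(control_freqs) || nrow(control_freqs) == 0) {
    return(case_freqs)
  }
  ctrl <- dplyr::select(control_freqs, "region_id", "pos",
                        ctrl_freq = "freq")
  joined <- dplyr::left_join(case_freqs, ctrl, by = c("region_id", "pos"))
  n_missing <- sum(is.na(joined$ctrl_freq))
  if (n_missing > 0) {
    warn(paste0("subtract_control: ", n_missing,
                " case site(s) absent from control; control taken as 0"))
    joined$ctrl_freq[is.na(joined$ctrl_freq)] <- 0
  }
  joined$freq <- pmax(joined$freq - joined$ctrl_freq, 0)
  dplyr::select(joined, -"ctrl_freq")
}

#' Per-site mutation frequencies from a count table
#'
#' `type = "total"` gives the summed non-reference fraction at every
#' position; `type = "ct"` gives the C>T fraction at reference-C positions
#' and the G>A fraction at reference-G positions (the transition signal in
#' the deaminated-C frame), other positions omitted.
#'
#' @param counts Site-count tibble.
#' @param type `"total"` or `"ct"`.
#' @return Tibble `region_id`, `pos`, `ref`, `depth`, `freq` (plus
#'   `c_frame_strand` for `type = "ct"`).
#' @export
site_frequencies <- function(counts, type = c("total", "ct")) {
  type <- match.arg(type)
  bases <- c("A", "C", "G", "T")
  if (type == "total") {
    m <- as.matrix(counts[, bases])
    ref_idx <- match(counts$ref, bases)
    ref_count <- m[cbind(seq_len(nrow(counts)),
                         ifelse(is.na(ref_idx), 1L, ref_idx))]
    # reference-N positions carry no substitution information
    ref_count[is.na(ref_idx)] <- counts$depth[is.na(ref_idx)]
    tibble::tibble(
      region_id = counts$region_id, pos = counts$pos, ref = counts$ref,
      depth = counts$depth,
      freq = ifelse(counts$depth > 0,
                    (counts$depth - ref_count) / counts$depth, 0)
    )
  } else {
    cg <- counts[counts$ref %in% c("C", "G"), , drop = FALSE]
    ev <- ifelse(cg$ref == "C", cg$T, cg$A)
    tibble::tibble(
      region_id = cg$region_id, pos = cg$pos, ref = cg$ref,
      depth = cg$depth,
      c_frame_strand = ifelse(cg$ref == "C", "+", "-"),
      freq = ifelse(cg$depth > 0, ev / cg$depth, 0)
    )
  }
}

#' Region-level mutation-frequency summary
#'
#' Implements the depth-weighted accounting behind the three mutation
#' frequencies: total (all substitution calls over all sequenced bases),
#' C/G (calls at C/G positions over sequenced C/G bases) and hotspot
#' (restricted to cytosines carrying a plus-frame hotspot instance and
#' guanines carrying a minus-frame instance). Numerators are read-level
#' call counts; denominators are summed depths, so frequencies are per
#' sequenced base. Positions with reference N are excluded from all terms;
#' a position inside several hotspot instances is counted once.
#'
#' @param sites Mutation sites from [tally_mutations()] on the same masked
#'   counts.
#' @param counts The masked site-count tibble.
#' @param annotation Hotspot annotation from [annotate_hotspots()] (use the
#'   WRCY-family presets for the canonical hotspot frequency).
#' @param clone_mode If TRUE, denominators are position counts instead of
#'   summed depth (Sanger-style data where each region is sequenced once
#'   per clone; pass per-clone aggregated counts).
#' @return One row per region with every accounting term, the derived
#'   frequencies `total_freq`, `cg_freq`, `hotspot_freq`, `ct_freq`,
#'   position-level terms for the positions-mode contrast, and a
#'   `flag_zero_denom` marker where a denominator was zero (frequency
#'   reported as 0).
#' @export
summarize_region <- function(sites, counts, annotation,
                             clone_mode = FALSE) {
  counts <- counts[counts$ref %in% c("A", "C", "G", "T"), , drop = FALSE]
  weight <- if (clone_mode) rep(1L, nrow(counts)) else counts$depth

  hot <- dplyr::distinct(annotation, .data$region_id, .data$position,
                         .data$strand)
  key_counts <- paste(counts$region_id, counts$pos)
  hot_c <- paste(hot$region_id[hot$strand == "+"],
                 hot$position[hot$strand == "+"])
  hot_g <- paste(hot$region_id[hot$strand == "-"],
                 hot$position[hot$strand == "-"])
  is_c <- counts$ref == "C"
  is_g <- counts$ref == "G"
  is_hc <- is_c & key_counts %in% hot_c
  is_hg <- is_g & key_counts %in% hot_g

  denom <- tibble::tibble(
    region_id = counts$region_id,
    w = weight,
    w_c = weight * is_c, w_g = weight * is_g,
    w_hc = weight * is_hc, w_hg = weight * is_hg,
    p_cg = as.integer(is_c | is_g)
  ) %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::summarise(
      total_sequenced_length = sum(.data$w),
      seq_length_cytosines = sum(.data$w_c),
      seq_length_guanines = sum(.data$w_g),
      seq_length_cytosines_hotspot = sum(.data$w_hc),
      seq_length_guanines_hotspot = sum(.data$w_hg),
      seq_positions_cg = sum(.data$p_cg),
      .groups = "drop"
    )

  if (nrow(sites) > 0) {
    skey <- paste(sites$region_id, sites$pos)
    s_hc <- sites$ref == "C" & skey %in% hot_c
    s_hg <- sites$ref == "G" & skey %in% hot_g
    ct <- (sites$change_label == "C>T") | (sites$change_label == "G>A")
    num <- tibble::tibble(
      region_id = sites$region_id,
      n_all = sites$alt_count,
      n_c = sites$alt_count * (sites$ref == "C"),
      n_g = sites$alt_count * (sites$ref == "G"),
      n_hc = sites$alt_count * s_hc,
      n_hg = sites$alt_count * s_hg,
      n_ct = sites$alt_count * ct,
      pos_key = paste(sites$region_id, sites$pos),
      is_cg_pos = sites$ref %in% c("C", "G") & ct
    ) %>%
      dplyr::group_by(.data$region_id) %>%
      dplyr::summarise(
        total_mutations = sum(.data$n_all),
        mutated_cytosines = sum(.data$n_c),
        mutated_guanines = sum(.data$n_g),
        mutated_cytosines_hotspot = sum(.data$n_hc),
        mutated_guanines_hotspot = sum(.data$n_hg),
        ct_transition_mutations = sum(.data$n_ct),
        mutated_positions_cg = dplyr::n_distinct(
          .data$pos_key[.data$is_cg_pos]),
        .groups = "drop"
      )
  } else {
    num <- tibble::tibble(region_id = character(), total_mutations = integer(),
                          mutated_cytosines = integer(),
                          mutated_guanines = integer(),
                          mutated_cytosines_hotspot = integer(),
                          mutated_guanines_hotspot = integer(),
                          ct_transition_mutations = integer(),
                          mutated_positions_cg = integer())
  }

  out <- dplyr::left_join(denom, num, by = "region_id") %>%
    dplyr::mutate(dplyr::across(
      c("total_mutations", "mutated_cytosines", "mutated_guanines",
        "mutated_cytosines_hotspot", "mutated_guanines_hotspot",
        "ct_transition_mutations", "mutated_positions_cg"),
      ~ tidyr::replace_na(.x, 0)
    ))
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  out %>%
    dplyr::mutate(
      total_freq = safe_div(.data$total_mutations,
                            .data$total_sequenced_length),
      cg_freq = safe_div(.data$mutated_cytosines + .data$mutated_guanines,
                         .data$seq_length_cytosines +
                           .data$seq_length_guanines),
      hotspot_freq = safe_div(
        .data$mutated_cytosines_hotspot + .data$mutated_guanines_hotspot,
        .data$seq_length_cytosines_hotspot +
          .data$seq_length_guanines_hotspot),
      ct_freq = safe_div(.data$ct_transition_mutations,
                         .data$seq_length_cytosines +
                           .data$seq_length_guanines),
      flag_zero_denom = .data$total_sequenced_length == 0 |
        (.data$seq_length_cytosines + .data$seq_length_guanines) == 0 |
        (.data$seq_length_cytosines_hotspot +
           .data$seq_length_guanines_hotspot) == 0
    )
}

#' Control-adjusted per-base mutation-frequency track
#'
#' Per position, the summed non-reference call fraction in the case minus
#' the same quantity in the AID-null control, floored at 0. Positions with
#' zero control depth take control frequency 0 and are flagged.
#'
#' @param case_counts,control_counts Site-count tibbles covering the same
#'   regions.
#' @return Tibble `region_id`, `pos`, `ref`, `freq_case`, `freq_control`,
#'   `adj_freq`, `flag_no_control`.
#' @export
per_base_profile <- function(case_counts, control_counts) {
  case_f <- site_frequencies(case_counts, "total")
  ctrl_f <- site_frequencies(control_counts, "total") %>%
    dplyr::select("region_id", "pos", ctrl_depth = "depth",
                  freq_control = "freq")
  dplyr::left_join(case_f, ctrl_f, by = c("region_id", "pos")) %>%
    dplyr::mutate(
      flag_no_control = is.na(.data$freq_control) | .data$ctrl_depth == 0,
      freq_control = dplyr::coalesce(.data$freq_control, 0),
      adj_freq = pmax(.data$freq - .data$freq_control, 0)
    ) %>%
    dplyr::select("region_id", "pos", "ref", freq_case = "freq",
                  "freq_control", "adj_freq", "flag_no_control")
}
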
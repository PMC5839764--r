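#' Extract sequence contexts of mutated cytosines
#'
#' Collects, for every C/G site whose control-adjusted C>T (G>A) transition
#' frequency reaches `threshold`, the flanking window of `w` nucleotides
#' per side in the deaminated-cytosine frame: minus-frame (reference G)
#' windows are reverse-complemented so the mutated cytosine is always
#' central and read 5'->3'. Windows truncated at region edges are dropped
#' and their count reported.
#'
#' @param site_freqs Adjusted per-site frequencies with columns
#'   `region_id`, `pos`, `c_frame_strand` (`"+"` at C, `"-"` at G) and
#'   `freq` (see [site_frequencies()] and [subtract_control()]).
#' @param regions Regions tibble supplying sequences.
#' @param threshold Minimum adjusted frequency (default 4e-3).
#' @param w Flank width per side (default 5; the 10-nucleotide window).
#' @return Tibble `region_id`, `pos`, `c_frame_strand`, `context`
#'   (length 2w+1, center `C`), `center_freq`.
#' @export
extract_contexts <- function(site_freqs, regions, threshold = 4e-3, w = 5) {
  hits <- site_freqs[site_freqs$freq >= threshold, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(tibble::tibble(region_id = character(), pos = integer(),
                          c_frame_strand = character(),
                          context = character(), center_freq = numeric()))
  }
  seq_map <- stats::setNames(regions$sequence, regions$region_id)
  len_map <- stats::setNames(nchar(regions$sequence), regions$region_id)
  hits$region_len <- unname(len_map[hits$region_id])
  full <- hits$pos - w >= 0 & hits$pos + w <= hits$region_len - 1
  n_trunc <- sum(!full)
  if (n_trunc > 0) {
    inform(paste0("extract_contexts: dropped ", n_trunc,
                  " window(s) truncated at region edges"))
  }
  hits <- hits[full, , drop = FALSE]
  ctx <- substr(seq_map[hits$region_id], hits$pos + 1 - w, hits$pos + 1 + w)
  minus <- hits$c_frame_strand == "-"
  ctx[minus] <- revcomp(ctx[minus])
  bad <- substr(ctx, w + 1, w + 1) != "C"
  if (any(bad)) {
    abort("extract_contexts: center base is not C in the deaminated frame")
  }
  tibble::tibble(region_id = hits$region_id, pos = hits$pos,
                 c_frame_strand = hits$c_frame_strand,
                 context = unname(ctx), center_freq = hits$freq)
}

#' Contexts of all cytosines in the analyzed regions
#'
#' The background for [position_enrichment()]: full windows around every C
#' (plus frame) and G (minus frame, reverse-complemented) regardless of
#' mutation status.
#'
#' @param regions Regions tibble.
#' @param w Flank width per side.
#' @return Context tibble as from [extract_contexts()] (`center_freq` NA).
#' @export
all_cytosine_contexts <- function(regions, w = 5) {
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    s <- regions$sequence[i]
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    pos <- which(chars == "C" | chars == "G") - 1L
    pos <- pos[pos - w >= 0 & pos + w <= length(chars) - 1]
    if (length(pos) == 0) return(NULL)
    strand <- ifelse(chars[pos + 1] == "C", "+", "-")
    ctx <- substr(rep(s, length(pos)), pos + 1 - w, pos + 1 + w)
    ctx[strand == "-"] <- revcomp(ctx[strand == "-"])
    tibble::tibble(region_id = regions$region_id[i], pos = pos,
                   c_frame_strand = strand, context = ctx,
                   center_freq = NA_real_)
  })
}

#' Positional base composition of context windows
#'
#' The logo matrix: percentage of each base at every position relative to
#' the mutated cytosine (position 0).
#'
#' @param contexts Context tibble from [extract_contexts()].
#' @return Tibble `position` (-w..w), `base`, `percentage`; percentages at
#'   each position sum to 100.
#' @export
position_composition <- function(contexts) {
  if (nrow(contexts) == 0) abort("position_composition: no contexts")
  L <- nchar(contexts$context[1])
  w <- (L - 1) %/% 2
  mat <- do.call(rbind, strsplit(contexts$context, "", fixed = TRUE))
  purrr::map_dfr(seq_len(L), function(j) {
    tab <- table(factor(mat[, j], levels = c("A", "C", "G", "T", "N")))
    tab <- tab[tab > 0 | names(tab) %in% c("A", "C", "G", "T")]
    tibble::tibble(position = j - 1L - w,
                   base = names(tab),
                   percentage = 100 * as.numeric(tab) / nrow(mat))
  })
}

#' Per-position nucleotide enrichment around mutated cytosines
#'
#' For every flank position and base, a one-tailed Fisher test of
#' over-representation in the mutated-cytosine contexts against the
#' contexts of all cytosines in the analyzed regions, Bonferroni-corrected
#' over the 4 x 2w tests.
#'
#' @param fg_contexts Foreground contexts ([extract_contexts()]).
#' @param bg_contexts Background contexts ([all_cytosine_contexts()]).
#' @param alpha Threshold on the adjusted p-value (default 1e-3).
#' @return Tibble `position`, `base`, `fg_with`, `fg_n`, `bg_with`, `bg_n`,
#'   `p`, `p_adj`, `significant`.
#' @export
position_enrichment <- function(fg_contexts, bg_contexts, alpha = 1e-3) {
  if (nrow(bg_contexts) < nrow(fg_contexts)) {
    abort("position_enrichment: background smaller than foreground")
  }
  L <- nchar(fg_contexts$context[1])
  w <- (L - 1) %/% 2
  fg <- do.call(rbind, strsplit(fg_contexts$context, "", fixed = TRUE))
  bg <- do.call(rbind, strsplit(bg_contexts$context, "", fixed = TRUE))
  cells <- tidyr::expand_grid(position = setdiff(-w:w, 0),
                              base = c("A", "C", "G", "T"))
  res <- purrr::pmap_dfr(cells, function(position, base) {
    j <- position + w + 1
    fg_with <- sum(fg[, j] == base)
    bg_with <- sum(bg[, j] == base)
    tibble::tibble(position = position, base = base,
                   fg_with = fg_with, fg_n = nrow(fg),
                   bg_with = bg_with, bg_n = nrow(bg),
                   p = fisher_one_tailed(fg_with, nrow(fg),
                                         bg_with, nrow(bg)))
  })
  res$p_adj <- bonferroni(res$p)
  res$significant <- res$p_adj <= alpha
  res
}

#' Per-motif mutability ranking
#'
#' Scans each motif over both strands of every region; every instance
#' contributes the adjusted frequency of its deaminated site (0 if the site
#' is absent from `site_freqs`, i.e. unmutated). Motifs are ranked by mean
#' per-site frequency.
#'
#' @param site_freqs Adjusted per-site frequency tibble (`region_id`,
#'   `pos`, `freq`).
#' @param regions Regions tibble.
#' @param motifs List of [motif_spec()] objects.
#' @return Tibble `motif_name`, `n_sites`, `mean_freq` (NA when a motif has
#'   no instances), `freqs` (list column of per-site values), ranked by
#'   mean descending.
#' @export
motif_mutability <- function(site_freqs, regions, motifs) {
  motifs <- as_motif_list(motifs)
  freq_key <- paste(site_freqs$region_id, site_freqs$pos)
  purrr::map_dfr(motifs, function(m) {
    inst <- annotate_hotspots(regions, list(m))
    if (nrow(inst) == 0) {
      return(tibble::tibble(motif_name = m$name, n_sites = 0L,
                            mean_freq = NA_real_, freqs = list(numeric(0))))
    }
    idx <- match(paste(inst$region_id, inst$position), freq_key)
    f <- ifelse(is.na(idx), 0, site_freqs$freq[idx])
    tibble::tibble(motif_name = m$name, n_sites = nrow(inst),
                   mean_freq = mean(f), freqs = list(f))
  }) %>%
    dplyr::arrange(dplyr::desc(.data$mean_freq))
}

#' Two-tailed Mann-Whitney U test
#'
#' Exact permutation p-value by full enumeration of group assignments when
#' the pooled sample size is at most `exact_max` (midranks for ties);
#' otherwise the normal approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @param exact_max Largest pooled size for exact enumeration.
#' @return One-row tibble `u_statistic` (for `x`), `p_value`, `method`.
#' @export
mann_whitney_two_tailed <- function(x, y, exact_max = 12) {
  if (length(x) == 0 || length(y) == 0) {
    abort("mann_whitney_two_tailed: both samples must be nonempty")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    idx_sets <- utils::combn(n1 + n2, n1, simplify = FALSE)
    u_all <- vapply(idx_sets, function(ix) {
      sum(r[ix]) - n1 * (n1 + 1) / 2
    }, numeric(1))
    eps <- 1e-9
    p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
    p <- min(p, 1)
    method <- "exact enumeration"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-abs(z)), 1)
    }
    method <- "normal approximation"
  }
  tibble::tibble(u_statistic = u_obs, p_value = p, method = method)
}

#' Random control motifs
#'
#' Draws `k` distinct random 4-mers (or `length`-mers) with the deaminated
#' C fixed at offset 2, excluding WRCY variants and AGCT-core motifs so the
#' controls carry no known hotspot signal.
#'
#' @param k Number of motifs.
#' @param length Motif length (>= 3; C at offset 2).
#' @param seed Seed.
#' @return List of [motif_spec()] objects.
#' @export
random_motifs <- function(k, length = 4, seed = 1) {
  stopifnot(k >= 1, length >= 3)
  bases <- c("A", "C", "G", "T")
  free <- setdiff(seq_len(length), 3)  # offset 2 is fixed to C
  grids <- rep(list(bases), base::length(free))
  combos <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  seqs <- apply(combos, 1, function(row) {
    s <- character(length)
    s[free] <- row
    s[3] <- "C"
    paste(s, collapse = "")
  })
  is_wrcy <- grepl("^[AT][AG]C[CT]", seqs)
  is_agct_core <- grepl("^AGCT", seqs)
  pool <- seqs[!is_wrcy & !is_agct_core]
  if (k > base::length(pool)) {
    abort(paste0("random_motifs: only ", base::length(pool),
                 " motifs available, requested ", k))
  }
  chosen <- with_private_seed(seed, sample(pool, k))
  lapply(chosen, function(s) motif_spec(s, s, 2))
}
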
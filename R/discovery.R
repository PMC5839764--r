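#' One-tailed Fisher exact test for case enrichment
#'
#' Exact hypergeometric upper-tail probability of observing at least
#' `m_case` mutation events among the case draws given the margins of the
#' 2x2 table `[m_case, n_case - m_case; m_ctrl, n_ctrl - m_ctrl]`
#' (alternative: case enriched). Vectorised over its arguments.
#'
#' @param m_case,n_case Events and exposure (sequenced bases) in the case.
#' @param m_ctrl,n_ctrl Events and exposure in the control.
#' @return P-values in (0, 1].
#' @export
fisher_one_tailed <- function(m_case, n_case, m_ctrl, n_ctrl) {
  if (any(m_case < 0 | m_ctrl < 0 | n_case < m_case | n_ctrl < m_ctrl)) {
    abort("fisher_one_tailed: need 0 <= m <= n for both groups")
  }
  if (any(n_case + n_ctrl == 0)) {
    abort("empty contingency")
  }
  # upper tail P(X >= m_case), X ~ Hypergeometric(K = m_case + m_ctrl,
  # N - K, drawn = n_case)
  stats::phyper(m_case - 1, m = m_case + m_ctrl,
                n = (n_case + n_ctrl) - (m_case + m_ctrl),
                k = n_case, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, order-preserving
#' with the input.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values.
#' @export
benjamini_hochberg <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Bonferroni adjusted p-values
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return `min(p * m, 1)` elementwise.
#' @export
bonferroni <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Call AID target regions against the AID-null control
#'
#' Per region, events are the C>T/G>A transition calls
#' (`ct_transition_mutations`) and exposure the depth-summed sequenced C/G
#' length; significance is a one-tailed Fisher test of case enrichment over
#' the AID-null control with Benjamini-Hochberg correction across all
#' tested regions. A positions-mode (distinct mutated C/G positions vs C/G
#' position counts) is available for sensitivity analysis.
#'
#' @param case_summaries,ctrl_summaries Region summaries from
#'   [summarize_region()] for the case genotype and the AID-null control.
#' @param alpha FDR threshold for the target flag.
#' @param mode `"reads"` (default, read-level events) or `"positions"`.
#' @return Tibble `region_id`, `m_case`, `n_case`, `m_ctrl`, `n_ctrl`,
#'   `p_value`, `q_value`, `is_target`, one row per region present in both
#'   inputs (missing regions are dropped with a warning).
#' @export
call_targets <- function(case_summaries, ctrl_summaries, alpha = 0.05,
                         mode = c("reads", "positions")) {
  mode <- match.arg(mode)
  only <- c(setdiff(case_summaries$region_id, ctrl_summaries$region_id),
            setdiff(ctrl_summaries$region_id, case_summaries$region_id))
  if (length(only) > 0) {
    warn(paste0("call_targets: ", length(only),
                " region(s) missing in one genotype were excluded"))
  }
  if (mode == "reads") {
    pick <- function(s) dplyr::transmute(
      s, region_id = .data$region_id,
      m = .data$ct_transition_mutations,
      n = .data$seq_length_cytosines + .data$seq_length_guanines)
  } else {
    pick <- function(s) dplyr::transmute(
      s, region_id = .data$region_id,
      m = .data$mutated_positions_cg,
      n = .data$seq_positions_cg)
  }
  joined <- dplyr::inner_join(pick(case_summaries), pick(ctrl_summaries),
                              by = "region_id",
                              suffix = c("_case", "_ctrl"))
  if (nrow(joined) == 0) {
    return(tibble::tibble(region_id = character(), m_case = numeric(),
                          n_case = numeric(), m_ctrl = numeric(),
                          n_ctrl = numeric(), p_value = numeric(),
                          q_value = numeric(), is_target = logical()))
  }
  p <- fisher_one_tailed(joined$m_case, joined$n_case,
                         joined$m_ctrl, joined$n_ctrl)
  q <- benjamini_hochberg(p)
  tibble::tibble(
    region_id = joined$region_id,
    m_case = joined$m_case, n_case = joined$n_case,
    m_ctrl = joined$m_ctrl, n_ctrl = joined$n_ctrl,
    p_value = p, q_value = q,
    is_target = q <= alpha
  )
}

#' Compare repair genotypes over target regions
#'
#' Builds the genotype-by-region matrix of control-adjusted total mutation
#' frequencies (the AID-null control frequency is subtracted per region and
#' floored at 0 before any comparison) and, where at least two replicates
#' per genotype are available, runs a two-tailed Welch t test per region
#' for every genotype pair.
#'
#' @param replicate_summaries Tibble with columns `genotype`, `replicate`,
#'   `region_id`, `total_freq` (one row per replicate x region; e.g. bind
#'   [summarize_region()] outputs per replicate).
#' @param ctrl_summaries AID-null control summaries (`region_id`,
#'   `total_freq`; replicates are averaged first if a `replicate` column is
#'   present).
#' @param alpha Significance level for the flags.
#' @return List with `freq_matrix` (tibble `genotype`, `region_id`,
#'   `adj_freq` averaged over replicates) and `tests` (tibble `region_id`,
#'   `genotype_a`, `genotype_b`, `p_value`, `significant`; empty with a
#'   warning when replicates are insufficient).
#' @export
compare_genotypes <- function(replicate_summaries, ctrl_summaries,
                              alpha = 0.05) {
  ctrl <- ctrl_summaries %>%
    dplyr::group_by(.data$region_id) %>%
    dplyr::summarise(ctrl_freq = mean(.data$total_freq), .groups = "drop")
  adj <- replicate_summaries %>%
    dplyr::left_join(ctrl, by = "region_id") %>%
    dplyr::mutate(ctrl_freq = dplyr::coalesce(.data$ctrl_freq, 0),
                  adj_freq = pmax(.data$total_freq - .data$ctrl_freq, 0))
  freq_matrix <- adj %>%
    dplyr::group_by(.data$genotype, .data$region_id) %>%
    dplyr::summarise(adj_freq = mean(.data$adj_freq), .groups = "drop")

  n_reps <- adj %>%
    dplyr::distinct(.data$genotype, .data$replicate) %>%
    dplyr::count(.data$genotype)
  genos <- n_reps$genotype[n_reps$n >= 2]
  if (length(genos) < 2) {
    warn("compare_genotypes: fewer than two genotypes with >= 2 replicates; tests skipped")
    tests <- tibble::tibble(region_id = character(),
                            genotype_a = character(),
                            genotype_b = character(),
                            p_value = numeric(), significant = logical())
    return(list(freq_matrix = freq_matrix, tests = tests))
  }
  pairs <- utils::combn(sort(genos), 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- adj[adj$genotype == pr[1], ]
    b <- adj[adj$genotype == pr[2], ]
    regions <- intersect(unique(a$region_id), unique(b$region_id))
    purrr::map_dfr(regions, function(r) {
      xa <- a$adj_freq[a$region_id == r]
      xb <- b$adj_freq[b$region_id == r]
      p <- if (stats::var(xa) == 0 && stats::var(xb) == 0) {
        if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      } else {
        stats::t.test(xa, xb, var.equal = FALSE)$p.value
      }
      tibble::tibble(region_id = r, genotype_a = pr[1], genotype_b = pr[2],
                     p_value = p, significant = p <= alpha)
    })
  })
  list(freq_matrix = freq_matrix, tests = tests)
}

#' Classify gene mutability
#'
#' Genes are split into highly mutated (targets in the top 20% by C>T
#' transition frequency, provided that frequency exceeds 3e-4), mutated
#' (remaining targets) and nonmutated (the rest).
#'
#' @param gene_ct_freqs Tibble `gene`, `ct_freq`.
#' @param target_flags Tibble `gene`, `is_target` (a gene is a target if
#'   any of its regions was called).
#' @param top_fraction Fraction of targets eligible for the top class.
#' @param freq_threshold Minimum C>T frequency for the top class.
#' @return Tibble `gene`, `class`, `ct_freq`.
#' @export
classify_mutability <- function(gene_ct_freqs, target_flags,
                                top_fraction = 0.2, freq_threshold = 3e-4) {
  d <- dplyr::left_join(gene_ct_freqs, target_flags, by = "gene") %>%
    dplyr::mutate(is_target = dplyr::coalesce(.data$is_target, FALSE))
  n_targets <- sum(d$is_target)
  n_top <- floor(top_fraction * n_targets)
  d$rank_among_targets <- NA_integer_
  if (n_targets > 0) {
    d$rank_among_targets[d$is_target] <-
      rank(-d$ct_freq[d$is_target], ties.method = "min")
  }
  dplyr::transmute(
    d,
    gene = .data$gene,
    class = dplyr::case_when(
      .data$is_target & .data$rank_among_targets <= n_top &
        .data$ct_freq > freq_threshold ~ "highly_mutated",
      .data$is_target ~ "mutated",
      TRUE ~ "nonmutated"
    ),
    ct_freq = .data$ct_freq
  )
}

#' Gene-set overlap enrichment
#'
#' Two-tailed Fisher exact test of the 2x2 table of target membership
#' against set membership over the gene universe, with the percentages the
#' figure-style reports print (rounded to 0.1).
#'
#' @param is_target Logical vector over the universe.
#' @param in_set Logical vector over the universe (same length).
#' @return One-row tibble: `n_targets`, `n_targets_in_set`,
#'   `proportion_in_targets`, `proportion_in_nontargets` (percent, 1
#'   decimal), `odds_ratio` (cross-product ratio), `two_tailed_fisher_p`.
#' @examples
#' gene_set_enrichment(rep(c(TRUE, FALSE), c(275, 1100)),
#'                     rep(c(TRUE, FALSE, TRUE, FALSE),
#'                         c(21, 254, 40, 1060)))
#' @export
gene_set_enrichment <- function(is_target, in_set) {
  if (length(is_target) == 0) abort("empty gene universe")
  stopifnot(length(is_target) == length(in_set),
            is.logical(is_target), is.logical(in_set))
  a <- sum(is_target & in_set)
  b <- sum(is_target & !in_set)
  c_ <- sum(!is_target & in_set)
  d <- sum(!is_target & !in_set)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  tibble::tibble(
    n_targets = a + b,
    n_targets_in_set = a,
    proportion_in_targets = round(100 * a / max(a + b, 1), 1),
    proportion_in_nontargets = round(100 * c_ / max(c_ + d, 1), 1),
    odds_ratio = or,
    two_tailed_fisher_p = p
  )
}
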
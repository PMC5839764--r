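# Independent brute-force oracles used to pin down expected values.

# IUPAC letter -> matched sequence letters, restated independently of the
# package internals. Sequence 'N' is matched only by motif letter 'N'.
oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N")
)
oracle_comp <- c(A = "T", C = "G", G = "C", T = "A", W = "W", S = "S",
                 R = "Y", Y = "R", K = "M", M = "K", B = "V", V = "B",
                 D = "H", H = "D", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(oracle_comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Sliding-window matcher over both strands; position = deaminated base on
# the plus strand. Window test is letter-by-letter set membership.
naive_scan <- function(sequence, iupac, dindex) {
  chars <- strsplit(sequence, "")[[1]]
  match_pattern <- function(pat) {
    pchars <- strsplit(pat, "")[[1]]
    L <- length(pchars)
    n <- length(chars)
    if (n < L) return(integer(0))
    starts <- seq_len(n - L + 1)
    ok <- rep(TRUE, length(starts))
    for (j in seq_len(L)) {
      ok <- ok & chars[starts + j - 1] %in% oracle_iupac[[pchars[j]]]
    }
    starts[ok]
  }
  L <- nchar(iupac)
  fwd <- match_pattern(iupac)
  rev <- match_pattern(oracle_revcomp(iupac))
  rbind(
    if (length(fwd)) data.frame(position = fwd - 1 + dindex, strand = "+"),
    if (length(rev)) data.frame(position = rev - 1 + (L - 1 - dindex),
                                strand = "-")
  )
}

# Hypergeometric upper tail by direct choose() summation.
oracle_hyper_tail <- function(m_case, n_case, m_ctrl, n_ctrl) {
  K <- m_case + m_ctrl
  N <- n_case + n_ctrl
  ks <- max(0, K - n_ctrl):min(K, n_case)
  probs <- exp(lchoose(K, ks) + lchoose(N - K, n_case - ks) -
                 lchoose(N, n_case))
  sum(probs[ks >= m_case])
}

# Naive step-up BH: sort ascending, adjust, enforce monotonicity, unsort.
naive_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact two-tailed Mann-Whitney by enumeration, with U computed by
# pairwise comparison counting (independent of the rank-sum formula).
naive_mw_exact <- function(x, y) {
  u_of <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- u_of(x, y)
  sets <- utils::combn(length(pooled), n1, simplify = FALSE)
  u_all <- vapply(sets, function(ix) {
    u_of(pooled[ix], pooled[-ix])
  }, numeric(1))
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# Random uppercase DNA string.
random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Tiny count-table builder: one region, given reference string, uniform
# depth, and a list of (pos, alt, count) substitutions.
toy_counts <- function(ref_seq, depth = 1000, subs = list(),
                       region_id = "r1") {
  chars <- strsplit(ref_seq, "")[[1]]
  n <- length(chars)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ref_idx <- match(chars, c("A", "C", "G", "T"))
  dep <- rep(as.integer(depth), n)
  for (s in subs) {
    counts[s$pos + 1, s$alt] <- counts[s$pos + 1, s$alt] + as.integer(s$count)
  }
  for (i in seq_len(n)) {
    if (!is.na(ref_idx[i])) {
      counts[i, ref_idx[i]] <- dep[i] - sum(counts[i, -ref_idx[i]])
    } else {
      counts[i, 1] <- dep[i] - sum(counts[i, -1])
    }
  }
  tibble::tibble(region_id = region_id, pos = 0:(n - 1), ref = chars,
                 depth = dep, A = counts[, "A"], C = counts[, "C"],
                 G = counts[, "G"], T = counts[, "T"])
}

# Brute-force per-read-call region summary used against summarize_region.
naive_summary <- function(sites, counts, annotation) {
  counts <- counts[counts$ref %in% c("A", "C", "G", "T"), ]
  hot_c <- annotation[annotation$strand == "+", ]
  hot_g <- annotation[annotation$strand == "-", ]
  is_hot_c <- function(rid, p) any(hot_c$region_id == rid & hot_c$position == p)
  is_hot_g <- function(rid, p) any(hot_g$region_id == rid & hot_g$position == p)
  out <- list()
  for (rid in unique(counts$region_id)) {
    cc <- counts[counts$region_id == rid, ]
    ss <- sites[sites$region_id == rid, ]
    terms <- c(total_mutations = 0, total_sequenced_length = 0,
               mutated_cytosines = 0, mutated_guanines = 0,
               seq_length_cytosines = 0, seq_length_guanines = 0,
               mutated_cytosines_hotspot = 0, mutated_guanines_hotspot = 0,
               seq_length_cytosines_hotspot = 0,
               seq_length_guanines_hotspot = 0,
               ct_transition_mutations = 0)
    for (i in seq_len(nrow(cc))) {
      d <- cc$depth[i]
      terms["total_sequenced_length"] <- terms["total_sequenced_length"] + d
      if (cc$ref[i] == "C") {
        terms["seq_length_cytosines"] <- terms["seq_length_cytosines"] + d
        if (is_hot_c(rid, cc$pos[i])) {
          terms["seq_length_cytosines_hotspot"] <-
            terms["seq_length_cytosines_hotspot"] + d
        }
      }
      if (cc$ref[i] == "G") {
        terms["seq_length_guanines"] <- terms["seq_length_guanines"] + d
        if (is_hot_g(rid, cc$pos[i])) {
          terms["seq_length_guanines_hotspot"] <-
            terms["seq_length_guanines_hotspot"] + d
        }
      }
    }
    for (i in seq_len(nrow(ss))) {
      k <- ss$alt_count[i]
      terms["total_mutations"] <- terms["total_mutations"] + k
      if (ss$ref[i] == "C") {
        terms["mutated_cytosines"] <- terms["mutated_cytosines"] + k
        if (is_hot_c(rid, ss$pos[i])) {
          terms["mutated_cytosines_hotspot"] <-
            terms["mutated_cytosines_hotspot"] + k
        }
        if (ss$alt[i] == "T") {
          terms["ct_transition_mutations"] <-
            terms["ct_transition_mutations"] + k
        }
      }
      if (ss$ref[i] == "G") {
        terms["mutated_guanines"] <- terms["mutated_guanines"] + k
        if (is_hot_g(rid, ss$pos[i])) {
          terms["mutated_guanines_hotspot"] <-
            terms["mutated_guanines_hotspot"] + k
        }
        if (ss$alt[i] == "A") {
          terms["ct_transition_mutations"] <-
            terms["ct_transition_mutations"] + k
        }
      }
    }
    out[[rid]] <- c(region_id = rid, as.list(terms))
  }
  dplyr::bind_rows(out)
}

# Shared small-scale discovery run used by several tests.
run_discovery <- function(seed, target_fraction = 0.05,
                          config = simulation_config(seed = seed)) {
  sim <- simulate_shm_experiment(config, target_fraction = target_fraction)
  wr <- annotate_hotspots(sim$regions, preset_motifs("WRCY"))
  summ <- lapply(sim$counts, function(cts) {
    m <- suppressMessages(mask_snps(cts, sim$snps))
    summarize_region(tally_mutations(m), m, wr)
  })
  calls <- call_targets(summ$UngMsh2_DKO, summ$Aicda_KO)
  list(sim = sim, summaries = summ, calls = calls,
       called = calls$region_id[calls$is_target])
}
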
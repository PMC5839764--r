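toy_region <- function(seq, id = "r1") {
  tibble::tibble(region_id = id, gene = id, chrom = "c", start = 0L,
                 end = nchar(seq), sequence = seq)
}

test_that("extract_contexts windows the deaminated-C frame", {
  #       0123456789012345
  seq <- "TTTTTCAAAAAGGGTT"
  regions <- toy_region(seq)
  freqs <- tibble::tibble(region_id = "r1", pos = c(5L, 11L),
                          c_frame_strand = c("+", "-"),
                          freq = c(5e-3, 6e-3))
  ctx <- extract_contexts(freqs, regions, w = 3)
  expect_equal(nrow(ctx), 2)
  expect_equal(ctx$context[ctx$pos == 5], "TTTCAAA")
  # minus-frame window is reverse-complemented: G at 11 flanked by
  # AAAG|GG -> revcomp("AAAGGGG"... ) reads in the C frame
  expect_equal(substr(ctx$context[ctx$pos == 11], 4, 4), "C")
  expect_equal(ctx$context[ctx$pos == 11], revcomp(substr(seq, 9, 15)))

  # below-threshold sites excluded
  low <- freqs
  low$freq <- c(3.9e-3, 1e-5)
  expect_equal(nrow(extract_contexts(low, regions, w = 3)), 0)

  # truncated windows dropped with a message
  edge <- tibble::tibble(region_id = "r1", pos = 5L,
                         c_frame_strand = "+", freq = 1)
  expect_message(out <- extract_contexts(edge, regions, w = 10),
                 "truncated")
  expect_equal(nrow(out), 0)
})

test_that("G-site contexts read in the AGCTNT frame after reverse complement", {
  # plus strand holds ANAGCT...: the minus-strand AGCTNT instance centers
  # on the plus-strand G
  seq <- "TTTANAGCTTTTT"
  regions <- toy_region(seq)
  hits <- scan_motif(seq, preset_motifs("AGCTNT")[[1]])
  expect_true("-" %in% hits$strand)
  p <- hits$position[hits$strand == "-"]
  freqs <- tibble::tibble(region_id = "r1", pos = p,
                          c_frame_strand = "-", freq = 5e-3)
  ctx <- extract_contexts(freqs, regions, w = 5)
  # the emitted window contains the motif in the deaminated-C frame
  expect_true(grepl("AGCT[ACGTN]T", substr(ctx$context, 4, 11)))
})

test_that("position_composition counts percentages per position", {
  ctx <- tibble::tibble(region_id = "r", pos = 1:2, c_frame_strand = "+",
                        context = c("AGCTT", "AGCTA"),
                        center_freq = 1)
  comp <- position_composition(ctx)
  p2 <- comp[comp$position == 2, ]
  expect_setequal(p2$base[p2$percentage == 50], c("T", "A"))
  p0 <- comp[comp$position == 0, ]
  expect_equal(p0$percentage[p0$base == "C"], 100)
  sums <- tapply(comp$percentage, comp$position, sum)
  expect_true(all(abs(sums - 100) < 0.1))

  single <- position_composition(ctx[1, ])
  expect_true(all(single$percentage %in% c(0, 100)))
  expect_error(position_composition(ctx[0, ]), "no contexts")
})

test_that("position_enrichment flags planted enrichment only", {
  withr::local_seed(2)
  make_ctx <- function(strings) {
    tibble::tibble(region_id = "r", pos = seq_along(strings),
                   c_frame_strand = "+", context = strings,
                   center_freq = NA_real_)
  }
  rand_ctx <- function(n) {
    vapply(seq_len(n), function(i) {
      s <- sample(c("A", "C", "G", "T"), 11, replace = TRUE)
      s[6] <- "C"
      paste(s, collapse = "")
    }, character(1))
  }
  bg <- make_ctx(rand_ctx(1000))
  fg_strings <- rand_ctx(50)
  substr(fg_strings, 9, 9) <- "T"  # +3 position forced to T
  fg <- make_ctx(fg_strings)
  enr <- position_enrichment(fg, bg)
  expect_equal(nrow(enr), 40)  # 4 bases x 10 flank positions, w = 5
  hit <- enr[enr$position == 3 & enr$base == "T", ]
  expect_true(hit$significant)

  # foreground drawn from the background distribution: nothing significant
  enr0 <- position_enrichment(make_ctx(rand_ctx(50)), bg)
  expect_false(any(enr0$significant))

  expect_error(position_enrichment(bg, fg), "background smaller")
})

test_that("motif_mutability ranks by mean per-site adjusted frequency", {
  seq <- "TTAGCTATTTAACTTT"
  regions <- toy_region(seq)
  motifs <- preset_motifs(c("AGCTNT", "AACT"))
  inst <- annotate_hotspots(regions, motifs)
  # give the AGCTNT site 4e-3 and leave the AACT site unmutated
  agct_pos <- inst$position[inst$motif_name == "AGCTNT"][1]
  freqs <- tibble::tibble(region_id = "r1", pos = agct_pos, freq = 4e-3)
  mm <- motif_mutability(freqs, regions, motifs)
  expect_equal(mm$motif_name[1], "AGCTNT")
  # two AGCTNT-context values {0, 4e-3} average to 2e-3 if two instances,
  # or equal 4e-3 for the single instance
  expect_equal(mm$mean_freq[1],
               mean(ifelse(is.na(match(
                 inst$position[inst$motif_name == "AGCTNT"], agct_pos)),
                 0, 4e-3)))

  # all sites at zero -> all means zero
  mm0 <- motif_mutability(freqs[0, ], regions, motifs)
  expect_true(all(mm0$mean_freq == 0))

  # motif with no instances is flagged with NA mean
  none <- motif_mutability(freqs, regions, preset_motifs("TGCC"))
  expect_equal(none$n_sites, 0)
  expect_true(is.na(none$mean_freq))
})

test_that("mann_whitney_two_tailed matches enumeration and wilcox.test", {
  expect_equal(mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(mann_whitney_two_tailed(1, 2)$p_value, 1)
  expect_equal(mann_whitney_two_tailed(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_error(mann_whitney_two_tailed(numeric(0), 1), "nonempty")

  withr::local_seed(14)
  for (rep in 1:30) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    got <- mann_whitney_two_tailed(x, y)
    expect_equal(got$p_value, naive_mw_exact(x, y), tolerance = 1e-12)
  }

  # large-sample path against the standard implementation
  withr::local_seed(15)
  x <- rnorm(40); y <- rnorm(35, 0.5)
  got <- mann_whitney_two_tailed(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(got$u_statistic, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("random_motifs excludes hotspot patterns and is reproducible", {
  m1 <- random_motifs(10, seed = 6)
  m2 <- random_motifs(10, seed = 6)
  expect_identical(lapply(m1, `[[`, "iupac"), lapply(m2, `[[`, "iupac"))
  seqs <- vapply(m1, `[[`, character(1), "iupac")
  expect_true(all(substr(seqs, 3, 3) == "C"))
  expect_false(any(grepl("^[AT][AG]C[CT]$", seqs)))
  expect_false(any(startsWith(seqs, "AGCT")))
  expect_equal(length(unique(seqs)), 10)
  expect_error(random_motifs(1000), "available")
})

test_that("composition is invariant under reverse-complementing the panel", {
  cfg <- simulation_config(n_regions = 10, region_length = 200, seed = 17)
  sim <- simulate_shm_experiment(cfg, target_fraction = 1)
  f_case <- site_frequencies(sim$counts$UngMsh2_DKO, "ct")
  f_ctrl <- dplyr::select(site_frequencies(sim$counts$Aicda_KO, "ct"),
                          "region_id", "pos", "freq")
  adj <- subtract_control(f_case, f_ctrl)
  ctx <- suppressMessages(extract_contexts(adj, sim$regions, threshold = 2e-3))
  comp <- position_composition(ctx)

  # reverse complement every region and remap sites: p -> L - 1 - p,
  # frame flipped
  L <- cfg$region_length
  rc_regions <- dplyr::mutate(sim$regions, sequence = revcomp(sequence))
  rc_adj <- dplyr::mutate(adj, pos = L - 1L - pos,
                          c_frame_strand = ifelse(c_frame_strand == "+",
                                                  "-", "+"))
  rc_ctx <- suppressMessages(
    extract_contexts(rc_adj, rc_regions, threshold = 2e-3))
  rc_comp <- position_composition(rc_ctx)
  expect_equal(nrow(ctx), nrow(rc_ctx))
  expect_equal(dplyr::arrange(comp, position, base),
               dplyr::arrange(rc_comp, position, base))
})
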
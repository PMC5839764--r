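test_that("mask_snps removes annotated and high-VAF positions", {
  cts <- toy_counts("ACGT", depth = 100,
                    subs = list(list(pos = 1, alt = "T", count = 50),
                                list(pos = 2, alt = "A", count = 5)))
  snps <- tibble::tibble(region_id = "r1", pos = 3L)
  out <- suppressMessages(mask_snps(cts, snps))
  expect_false(3 %in% out$pos)
  expect_equal(attr(out, "n_masked"), 1)

  # identity with empty mask and no threshold
  id <- suppressMessages(mask_snps(cts, NULL))
  expect_equal(nrow(id), nrow(cts))

  # VAF threshold removes the 50% site but keeps the 5% site
  vaf <- suppressMessages(mask_snps(cts, NULL, vaf_threshold = 0.2))
  expect_false(1 %in% vaf$pos)
  expect_true(2 %in% vaf$pos)
})

test_that("tally_mutations labels substitutions and the deaminated frame", {
  cts <- toy_counts("NCGA", depth = 1000,
                    subs = list(list(pos = 1, alt = "T", count = 4),
                                list(pos = 2, alt = "A", count = 3),
                                list(pos = 1, alt = "A", count = 2)))
  sites <- tally_mutations(cts, min_alt_count = 1)
  # reference-N rows are skipped
  expect_false(0 %in% sites$pos)
  ct <- sites[sites$pos == 1 & sites$alt == "T", ]
  expect_equal(ct$change_label, "C>T")
  expect_equal(ct$change_class, "transition")
  expect_equal(ct$c_frame_strand, "+")
  ga <- sites[sites$pos == 2, ]
  expect_equal(ga$change_label, "G>A")
  expect_equal(ga$c_frame_strand, "-")
  ca <- sites[sites$pos == 1 & sites$alt == "A", ]
  expect_equal(ca$change_class, "transversion")
  # min_alt_count filters
  expect_false(any(tally_mutations(cts, min_alt_count = 3)$alt_count < 3))
})

test_that("subtract_control floors at zero and tolerates missing sites", {
  case <- tibble::tibble(region_id = "r1", pos = c(0L, 1L, 2L),
                         freq = c(5e-3, 1e-4, 2e-3))
  ctrl <- tibble::tibble(region_id = "r1", pos = c(0L, 1L),
                         freq = c(1e-4, 5e-3))
  expect_warning(out <- subtract_control(case, ctrl), "absent from control")
  expect_equal(out$freq, c(4.9e-3, 0, 2e-3))
  # empty control is the identity
  expect_equal(subtract_control(case, NULL)$freq, case$freq)
})

test_that("summarize_region implements the printed frequency formulas", {
  # 3 C positions at depth 200 (600 C bases), 2 G positions at depth 200
  # (400 G bases), 3 C>T calls and 1 G>A call -> cg_freq = 4/1000
  cts <- toy_counts("CCCGG", depth = 200,
                    subs = list(list(pos = 0, alt = "T", count = 2),
                                list(pos = 1, alt = "T", count = 1),
                                list(pos = 3, alt = "A", count = 1)))
  sites <- tally_mutations(cts)
  empty_ann <- tibble::tibble(region_id = character(), position = integer(),
                              strand = character(), motif_name = character())
  s <- summarize_region(sites, cts, empty_ann)
  expect_equal(s$seq_length_cytosines, 600)
  expect_equal(s$seq_length_guanines, 400)
  expect_equal(s$cg_freq, 4 / 1000)
  expect_equal(s$ct_freq, 4 / 1000)
  expect_equal(s$total_freq, 4 / 1000)

  # no mutant calls -> all frequencies zero
  clean <- toy_counts("CCGG", depth = 100)
  s0 <- summarize_region(tally_mutations(clean), clean, empty_ann)
  expect_equal(s0$total_freq, 0)
  expect_equal(s0$cg_freq, 0)

  # hotspot restriction concentrates the same calls on fewer bases
  ann <- tibble::tibble(region_id = "r1", position = c(0L, 1L),
                        strand = "+", motif_name = "WRCY")
  s2 <- summarize_region(sites, cts, ann)
  expect_equal(s2$seq_length_cytosines_hotspot, 400)
  expect_equal(s2$hotspot_freq, 3 / 400)
  expect_gt(s2$hotspot_freq, s2$cg_freq)
})

test_that("summarize_region matches a brute-force enumeration on random tables", {
  withr::local_seed(33)
  for (rep in 1:10) {
    n <- sample(10:50, 1)
    seq <- random_dna(n)
    subs <- list()
    chars <- strsplit(seq, "")[[1]]
    for (k in seq_len(sample(3:8, 1))) {
      p <- sample(n, 1) - 1
      alt <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1]), 1)
      subs <- c(subs, list(list(pos = p, alt = alt, count = sample(1:5, 1))))
    }
    cts <- toy_counts(seq, depth = sample(50:500, 1), subs = subs)
    regions <- tibble::tibble(region_id = "r1", gene = "r1", chrom = "c",
                              start = 0L, end = n, sequence = seq)
    ann <- annotate_hotspots(regions, preset_motifs("WRCY"))
    sites <- tally_mutations(cts)
    got <- summarize_region(sites, cts, ann)
    exp <- naive_summary(sites, cts, ann)
    for (col in setdiff(names(exp), "region_id")) {
      expect_equal(got[[col]], as.numeric(exp[[col]]), info = col)
    }
  }
})

test_that("masking more positions never inflates terms; scaling leaves frequencies alone", {
  withr::local_seed(8)
  seq <- random_dna(60)
  chars <- strsplit(seq, "")[[1]]
  subs <- lapply(c(5, 12, 30), function(p) {
    list(pos = p, alt = sample(setdiff(c("A", "C", "G", "T"),
                                       chars[p + 1]), 1), count = 3)
  })
  cts <- toy_counts(seq, depth = 100, subs = subs)
  regions <- tibble::tibble(region_id = "r1", gene = "r1", chrom = "c",
                            start = 0L, end = 60L, sequence = seq)
  ann <- annotate_hotspots(regions, preset_motifs("WRCY"))

  base <- summarize_region(tally_mutations(cts), cts, ann)
  masked <- suppressMessages(
    mask_snps(cts, tibble::tibble(region_id = "r1", pos = c(5L, 30L))))
  after <- summarize_region(tally_mutations(masked), masked, ann)
  terms <- c("total_mutations", "total_sequenced_length",
             "mutated_cytosines", "mutated_guanines",
             "seq_length_cytosines", "seq_length_guanines",
             "ct_transition_mutations")
  for (t in terms) expect_lte(after[[t]], base[[t]])

  # uniform depth scaling: numerators and denominators scale together
  scaled <- cts
  for (b in c("A", "C", "G", "T")) scaled[[b]] <- scaled[[b]] * 7L
  scaled$depth <- scaled$depth * 7L
  s_scaled <- summarize_region(tally_mutations(scaled), scaled, ann)
  for (f in c("total_freq", "cg_freq", "hotspot_freq", "ct_freq")) {
    expect_equal(s_scaled[[f]], base[[f]])
  }
})

test_that("per_base_profile subtracts the control and highlights hotspots", {
  cts <- toy_counts("ACGT", depth = 100,
                    subs = list(list(pos = 1, alt = "T", count = 10)))
  # identical case and control -> all-zero track
  same <- per_base_profile(cts, cts)
  expect_true(all(same$adj_freq == 0))

  clean <- toy_counts("ACGT", depth = 100)
  only_case <- per_base_profile(cts, clean)
  expect_equal(sum(only_case$adj_freq > 0), 1)
  expect_equal(only_case$adj_freq[only_case$pos == 1], 0.1)

  # seeded double-knockout simulation: top-decile adjusted sites are
  # concentrated at annotated hotspot positions
  cfg <- simulation_config(n_regions = 40, seed = 9)
  sim <- simulate_shm_experiment(cfg, target_fraction = 1)
  prof <- per_base_profile(sim$counts$UngMsh2_DKO, sim$counts$Aicda_KO)
  nonzero <- prof[prof$adj_freq > 0, ]
  top <- nonzero[nonzero$adj_freq >=
                   quantile(nonzero$adj_freq, 0.9), ]
  hot <- unique(paste(sim$hotspots$region_id, sim$hotspots$position))
  expect_gte(mean(paste(top$region_id, top$pos) %in% hot), 0.7)
})
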
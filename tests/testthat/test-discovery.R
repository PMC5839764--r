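test_that("fisher_one_tailed equals the hypergeometric tail", {
  expect_equal(fisher_one_tailed(2, 2, 0, 2), 1 / 6)
  expect_equal(fisher_one_tailed(0, 1000, 5, 1000), 1)
  expect_equal(fisher_one_tailed(10, 1000, 1, 1000),
               oracle_hyper_tail(10, 1000, 1, 1000), tolerance = 1e-12)
  # cross-check against the conditional exact test
  expect_equal(fisher_one_tailed(10, 1000, 1, 1000),
               fisher.test(matrix(c(10, 990, 1, 999), 2, byrow = TRUE),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(fisher_one_tailed(0, 0, 0, 0), "empty contingency")
  expect_error(fisher_one_tailed(5, 3, 0, 10), "0 <= m <= n")

  withr::local_seed(10)
  for (rep in 1:200) {
    n1 <- sample(1:30, 1); n2 <- sample(1:30, 1)
    m1 <- sample(0:n1, 1); m2 <- sample(0:n2, 1)
    expect_equal(fisher_one_tailed(m1, n1, m2, n2),
                 oracle_hyper_tail(m1, n1, m2, n2), tolerance = 1e-10)
  }
})

test_that("benjamini_hochberg matches the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.05), 0.05)
  expect_equal(benjamini_hochberg(c(1e-5, 0.5)), c(2e-5, 0.5))

  withr::local_seed(4)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_equal(q, naive_bh(p))
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("bonferroni caps at one and handles the empty vector", {
  expect_equal(bonferroni(c(0.01, 0.2)), c(0.02, 0.4))
  expect_equal(bonferroni(c(0.9, 0.9)), c(1, 1))
  expect_equal(bonferroni(numeric(0)), numeric(0))
})

test_that("call_targets recovers planted targets and nothing else", {
  res <- run_discovery(seed = 1)
  expect_setequal(res$called, res$sim$target_ids)
  expect_true(all(res$calls$q_value >= res$calls$p_value))
  expect_true(all(res$calls$p_value > 0 & res$calls$p_value <= 1))

  # identical case and control tables -> zero targets; alpha 0 -> zero
  s <- res$summaries$Aicda_KO
  expect_equal(sum(call_targets(s, s)$is_target), 0)
  expect_equal(sum(call_targets(res$summaries$UngMsh2_DKO,
                                res$summaries$Aicda_KO,
                                alpha = 0)$is_target), 0)

  # region present in only one genotype is excluded with a warning
  expect_warning(call_targets(s[-1, ], s), "excluded")
})

test_that("positions-mode calling uses distinct mutated sites", {
  res <- run_discovery(seed = 3)
  pos_calls <- call_targets(res$summaries$UngMsh2_DKO,
                            res$summaries$Aicda_KO, mode = "positions")
  expect_true(all(pos_calls$m_case <= pos_calls$n_case))
  # deep planted signal should be recoverable in either mode
  expect_setequal(pos_calls$region_id[pos_calls$is_target],
                  res$sim$target_ids)
})

test_that("compare_genotypes adjusts, averages and tests replicates", {
  reps <- tidyr::expand_grid(genotype = c("A", "B"),
                             replicate = c(1L, 2L),
                             region_id = "g1")
  reps$total_freq <- c(5e-3, 6e-3, 1e-3, 1.2e-3)
  ctrl <- tibble::tibble(region_id = "g1", total_freq = 1e-4)
  out <- compare_genotypes(reps, ctrl)
  expect_equal(out$freq_matrix$adj_freq[out$freq_matrix$genotype == "A"],
               mean(c(5e-3, 6e-3)) - 1e-4)
  # Welch two-tailed t on the adjusted replicate frequencies
  expect_equal(out$tests$p_value,
               t.test(c(5e-3, 6e-3) - 1e-4, c(1e-3, 1.2e-3) - 1e-4,
                      var.equal = FALSE)$p.value)
  # with more replicates the separation is unambiguous
  reps4 <- tidyr::expand_grid(genotype = c("A", "B"),
                              replicate = 1:4, region_id = "g1")
  reps4$total_freq <- c(5e-3, 6e-3, 5.5e-3, 5.2e-3,
                        1e-3, 1.2e-3, 0.9e-3, 1.1e-3)
  out4 <- compare_genotypes(reps4, ctrl)
  expect_true(out4$tests$significant)

  # identical replicate sets -> nothing significant
  reps2 <- reps
  reps2$total_freq <- rep(c(2e-3, 3e-3), 2)
  out2 <- compare_genotypes(reps2, ctrl)
  expect_false(any(out2$tests$significant))

  # single replicate -> matrix only, warning
  expect_warning(
    out3 <- compare_genotypes(reps[reps$replicate == 1, ], ctrl),
    "tests skipped")
  expect_equal(nrow(out3$tests), 0)
  expect_equal(nrow(out3$freq_matrix), 2)
})

test_that("classify_mutability applies the top-20%/3e-4 rule", {
  freqs <- tibble::tibble(gene = paste0("g", 1:12),
                          ct_freq = c(seq(4e-4, 15e-4, length.out = 10),
                                      1e-5, 2e-5))
  flags <- tibble::tibble(gene = paste0("g", 1:12),
                          is_target = c(rep(TRUE, 10), FALSE, FALSE))
  cls <- classify_mutability(freqs, flags)
  expect_equal(sum(cls$class == "highly_mutated"), 2)
  expect_setequal(cls$gene[cls$class == "highly_mutated"], c("g9", "g10"))
  expect_equal(sum(cls$class == "mutated"), 8)
  expect_equal(sum(cls$class == "nonmutated"), 2)

  # a top-ranked target below the frequency threshold stays "mutated"
  low <- tibble::tibble(gene = paste0("g", 1:10),
                        ct_freq = seq(1e-5, 2e-4, length.out = 10))
  cls2 <- classify_mutability(low, dplyr::mutate(low[, "gene"],
                                                 is_target = TRUE))
  expect_false(any(cls2$class == "highly_mutated"))

  # no targets -> everything nonmutated
  cls3 <- classify_mutability(freqs,
                              dplyr::mutate(flags, is_target = FALSE))
  expect_true(all(cls3$class == "nonmutated"))
})

test_that("gene_set_enrichment reproduces proportions and exact p-values", {
  # 21 of 275 target genes annotated in the lymphoma set -> 7.6%
  res <- gene_set_enrichment(
    rep(c(TRUE, FALSE), c(275, 1100)),
    rep(c(TRUE, FALSE, TRUE, FALSE), c(21, 254, 40, 1060)))
  expect_equal(res$proportion_in_targets, 7.6)

  # identical rows -> odds ratio 1, p 1
  flat <- gene_set_enrichment(rep(c(TRUE, FALSE), each = 10),
                              rep(c(TRUE, FALSE, TRUE, FALSE),
                                  c(2, 8, 2, 8)))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$two_tailed_fisher_p, 1)

  # perfectly concentrated 5/5 table: p = 2/252 by enumeration
  conc <- gene_set_enrichment(rep(c(TRUE, FALSE), each = 5),
                              rep(c(TRUE, FALSE), each = 5))
  expect_equal(conc$two_tailed_fisher_p, 2 / 252, tolerance = 1e-12)

  expect_error(gene_set_enrichment(logical(0), logical(0)), "empty")
})
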
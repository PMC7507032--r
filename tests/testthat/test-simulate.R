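# Generators: determinism, planted-effect structure, degenerate inputs.

test_that("screen simulator is deterministic and validates its config", {
  cfg <- screen_sim_config(n_genes = 50, seed = 11)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a, b)
  expect_error(screen_sim_config(50, library_size = 0), "library_size")
  expect_error(screen_sim_config(50, nb_dispersion = -1), "nb_dispersion")
  expect_error(screen_sim_config(50, frac_essential = 0.7,
                                 frac_suppressor = 0.5), "<= 1")
})

test_that("planted dropout shows up as the expected CPM ratio vs neutral genes", {
  cfg <- screen_sim_config(n_genes = 500, frac_essential = 0.1,
                           frac_suppressor = 0, effect_log2fc = -2,
                           n_replicates_per_group = 3, seed = 1)
  sim <- simulate_screen(cfg)
  cpm <- cpm_normalize(sim$counts)
  grp <- sim$counts$samples$group
  lfc <- log2(rowMeans(cpm[, grp == "day4"]) + 0.5) -
         log2(rowMeans(cpm[, grp == "day0"]) + 0.5)
  cls <- sim$truth$gene_class[sim$library$gene]
  # compositional normalisation shifts all CPMs; the essential-vs-neutral
  # contrast recovers the planted factor
  delta <- median(lfc[cls == "essential"]) - median(lfc[cls == "neutral"])
  expect_lt(abs(delta - (-2)), 0.1)
})

test_that("null screen has exchangeable day0/day4 groups", {
  cfg <- screen_sim_config(n_genes = 200, frac_essential = 0,
                           frac_suppressor = 0, seed = 3)
  sim <- simulate_screen(cfg)
  res <- screen_genes(sim$counts, sim$library)
  # per-shRNA hit rate near nominal alpha, and essentially no gene calls
  expect_lt(mean(res$shrna_stats$p_value < 0.05), 0.08)
  expect_lt(nrow(res$genes), 5)
})

test_that("paired-expression simulator plants balanced DE and rejects n_pairs < 2", {
  pe <- simulate_paired_expression(300, n_pairs = 10, frac_de = 0.2, seed = 4)
  expect_equal(sum(pe$truth > 0), sum(pe$truth != 0) -
                 floor(sum(pe$truth != 0) / 2))
  expect_identical(pe, simulate_paired_expression(300, n_pairs = 10,
                                                  frac_de = 0.2, seed = 4))
  expect_error(simulate_paired_expression(10, n_pairs = 1), "n_pairs")
  pe2 <- simulate_paired_expression(10, gene_names = letters[1:10],
                                    de_genes_up = "a", de_genes_down = "b",
                                    seed = 1)
  expect_equal(unname(pe2$truth[c("a", "b", "c")]), c(1, -1, 0))
  expect_error(simulate_paired_expression(10, gene_names = letters[1:10],
                                          de_genes_up = "z"), "universe")
})

test_that("ranked-transcriptome simulator places the planted set at the bottom", {
  rt <- simulate_ranked_transcriptome(n_genes = 500, set_size = 40,
                                      planted_shift = -2, seed = 5)
  rm_ <- rank_metric(rt$expr, rt$sample_info$condition,
                     test = "kd", ref = "control")
  pos <- which(names(rm_) %in% rt$truth$planted_genes)
  # planted genes concentrate in the bottom tenth of the ranking
  expect_gt(median(pos), 0.9 * length(rm_))
  expect_error(simulate_ranked_transcriptome(n_genes = 50, set_size = 50),
               "smaller")
  expect_identical(rt, simulate_ranked_transcriptome(n_genes = 500,
                                                     set_size = 40,
                                                     planted_shift = -2,
                                                     seed = 5))
})

test_that("survival simulator respects censor_rate limits and hazard ratio", {
  all_cens <- simulate_survival_cohort(50, censor_rate = 1, seed = 6)
  expect_true(all(all_cens$event == 0))
  expect_true(all(km_estimate(all_cens)$survival == 1))
  none <- simulate_survival_cohort(50, censor_rate = 0, seed = 6)
  expect_true(all(none$event == 1))
  expect_error(simulate_survival_cohort(5), "n_patients")
  expect_error(simulate_survival_cohort(50, hazard_ratio = 0), "hazard_ratio")
  coh <- simulate_survival_cohort(400, hazard_ratio = 3, censor_rate = 0.2,
                                  seed = 7)
  med <- tapply(coh$time, coh$group, median)
  expect_lt(med[["high"]], med[["low"]])
})

test_that("correlated-pair simulator hits the requested correlation", {
  expect_error(simulate_correlated_pairs(rho = 1), "rho")
  expect_error(simulate_correlated_pairs(n = 2), "n")
  r <- vapply(1:40, function(s) {
    d <- simulate_correlated_pairs(n = 270, rho = 0.4, seed = s)
    cor(d$x, d$y)
  }, numeric(1))
  # Fisher-z 95% interval around rho = 0.4 at n = 270 is about [0.29, 0.50]
  expect_gte(mean(r > 0.29 & r < 0.50), 0.95)
  near <- simulate_correlated_pairs(n = 100, rho = 0.999, seed = 1)
  expect_gt(cor(near$x, near$y), 0.99)
})
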
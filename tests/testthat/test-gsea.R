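# Ranking metric, weighted-KS enrichment score, permutation significance.

test_that("rank_metric computes signal-to-noise with an SD floor", {
  expr <- rbind(g1 = c(10, 10.2, 9.8, 5, 5.1, 4.9),
                g2 = c(3, 3, 3, 3, 3, 3))
  cond <- rep(c("kd", "control"), each = 3)
  m <- rank_metric(expr, cond, test = "kd", ref = "control")
  mu1 <- mean(expr[1, 1:3]); mu2 <- mean(expr[1, 4:6])
  s1 <- max(sd(expr[1, 1:3]), 0.2 * abs(mu1))
  s2 <- max(sd(expr[1, 4:6]), 0.2 * abs(mu2))
  expect_equal(unname(m["g1"]), (mu1 - mu2) / (s1 + s2))
  expect_equal(unname(m["g2"]), 0)  # identical groups, zero-denominator guard
  expect_error(rank_metric(expr[, c(1, 4)], c("kd", "control")),
               "log2fc")
  m2 <- rank_metric(expr[, c(1, 4)], c("kd", "control"), method = "log2fc")
  expect_equal(unname(m2["g1"]), 5)
})

test_that("ties in the metric are ordered deterministically by symbol", {
  expr <- matrix(3, nrow = 4, ncol = 4,
                 dimnames = list(c("d", "b", "a", "c"), NULL))
  m <- rank_metric(expr, rep(c("kd", "control"), each = 2))
  expect_equal(names(m), c("a", "b", "c", "d"))
})

test_that("enrichment score equals the brute-force running sum", {
  set.seed(30)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    metric <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    names(metric) <- sprintf("g%03d", sample(n))
    set <- sample(names(metric), sample(2:(n - 2), 1))
    for (p in c(0, 1, 2)) {
      es <- enrichment_score(metric, set, p = p)
      expect_equal(es$es, es_oracle(metric, set, p = p), tolerance = 1e-12)
      expect_lte(abs(es$es), 1)
    }
  }
})

test_that("p = 0 reduces to the KS statistic on hit positions", {
  set.seed(31)
  for (i in 1:10) {
    n <- 60
    metric <- sort(rnorm(n), decreasing = TRUE)
    names(metric) <- sprintf("g%03d", 1:n)
    set <- sample(names(metric), 12)
    es <- enrichment_score(metric, set, p = 0)$es
    hit_pos <- which(names(metric) %in% set)
    miss_pos <- setdiff(1:n, hit_pos)
    ks <- suppressWarnings(ks.test(hit_pos, miss_pos)$statistic)
    expect_equal(abs(es), unname(ks), tolerance = 1e-12)
  }
})

test_that("degenerate sets are rejected and reversal negates the p=0 score", {
  metric <- setNames(sort(rnorm(20), decreasing = TRUE), letters[1:20])
  expect_error(enrichment_score(metric, "zzz"), "no overlap")
  expect_error(enrichment_score(metric, letters[1:20]), "whole ranked list")
  set <- c("a", "e", "f", "q")
  fwd <- enrichment_score(metric, set, p = 0)$es
  rev_metric <- rev(metric)
  bwd <- enrichment_score(rev_metric, set, p = 0)$es
  expect_equal(fwd, -bwd, tolerance = 1e-12)
})

test_that("leading edge contains the members driving the extremum", {
  metric <- setNames(seq(3, -3, length.out = 12), letters[1:12])
  top <- enrichment_score(metric, c("a", "b", "c"))
  expect_true(all(top$leading_edge %in% c("a", "b", "c")))
  expect_gt(top$es, 0)
  bottom <- enrichment_score(metric, c("j", "k", "l"))
  expect_lt(bottom$es, 0)
  expect_true(all(bottom$leading_edge %in% c("j", "k", "l")))
})

test_that("enrichment scores agree with fgsea on random instances", {
  skip_if_not_installed("fgsea")
  set.seed(32)
  metric <- sort(rnorm(100, sd = 2), decreasing = TRUE)
  names(metric) <- sprintf("g%03d", sample(100))
  sets <- list(s1 = sample(names(metric), 10),
               s2 = sample(names(metric), 25))
  for (nm in names(sets)) {
    ours <- enrichment_score(metric, sets[[nm]], p = 1)$es
    theirs <- fgsea::calcGseaStat(metric,
                                  which(names(metric) %in% sets[[nm]]),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("permutation significance is seed-deterministic and finds the planted set", {
  rt <- simulate_ranked_transcriptome(n_genes = 600, set_size = 40,
                                      planted_shift = -1.5, n_decoy_sets = 10,
                                      seed = 33)
  metric <- rank_metric(rt$expr, rt$sample_info$condition,
                        test = "kd", ref = "control")
  a <- permutation_significance(metric, rt$gene_sets, n_perm = 200, seed = 7)
  b <- permutation_significance(metric, rt$gene_sets, n_perm = 200, seed = 7)
  expect_identical(a, b)
  expect_equal(a$set[which.min(a$nes)], "planted")
  expect_lt(a$q_value[a$set == "planted"], 0.05)
  expect_error(permutation_significance(metric, rt$gene_sets, n_perm = 50),
               "n_perm")
})
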
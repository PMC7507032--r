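# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity from its definition, not from package internals.

# Benjamini-Hochberg step-up by the definition:
# q(i) = min_{j >= i} m * p_(j) / j, capped at 1, in the original order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- rev(cummin(rev(m * ps / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# Literal weighted-KS running sum, one step at a time.
es_oracle <- function(ranked, set, p = 1) {
  genes <- names(ranked)
  hit <- genes %in% set
  nh <- sum(hit)
  n <- length(genes)
  wh <- sum(abs(ranked[hit])^p)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(ranked[i])^p / wh else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Log-rank chi-square by direct O/E/V accumulation over pooled event times.
logrank_oracle <- function(time, event, group) {
  g1 <- unique(group)[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Exhaustive Youden scan over every midpoint threshold.
roc_oracle <- function(marker, outcome) {
  u <- sort(unique(marker))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (ct in cuts) {
    sens <- mean(marker[outcome == 1] > ct)
    spec <- mean(marker[outcome == 0] <= ct)
    y <- sens + spec - 1
    if (is.null(best) || y > best$youden) best <- list(cutoff = ct, youden = y)
  }
  best
}

# Literal application of the three screen filter criteria to a small count
# matrix, using stats::t.test per shRNA (independent of the vectorised path).
screen_oracle <- function(cm, lib, cpm_threshold = 25, p_threshold = 0.05,
                          min_shrnas = 3, pseudocount = 0.5) {
  m <- cm$counts
  cpm <- sweep(m, 2, colSums(m), "/") * 1e6
  i0 <- cm$samples$group == "day0"
  i4 <- cm$samples$group == "day4"
  l <- log2(cpm + pseudocount)
  pass <- character(0)
  gene_of <- character(0)
  for (i in seq_len(nrow(m))) {
    mean0 <- mean(cpm[i, i0])
    a <- l[i, i4]; b <- l[i, i0]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else .Machine$double.xmin
    } else stats::t.test(a, b)$p.value
    if (mean0 > cpm_threshold && p < p_threshold) {
      pass <- c(pass, rownames(m)[i])
      gene_of <- c(gene_of, lib$gene[lib$shrna_id == rownames(m)[i]])
    }
  }
  genes <- as.character(names(which(table(gene_of) >= min_shrnas)))
  list(passing_shrnas = sort(pass), genes = sort(genes))
}

# Small random screen fixture: a handful of genes, 2-4 shRNAs each, counts
# spanning the 25-CPM boundary region.
random_small_screen <- function(n_genes = 4, max_shrnas = 4, nrep = 3) {
  k <- sample(2:max_shrnas, n_genes, replace = TRUE)
  gene <- rep(sprintf("g%02d", seq_len(n_genes)), times = k)
  id <- paste0(gene, "_", unlist(lapply(k, seq_len)))
  n_sh <- length(id)
  mu <- exp(stats::runif(n_sh, log(2), log(2000)))
  fac <- sample(c(0.2, 0.5, 1, 1, 2), n_sh, replace = TRUE)
  m <- cbind(matrix(stats::rpois(n_sh * nrep, mu), n_sh),
             matrix(stats::rpois(n_sh * nrep, mu * fac), n_sh))
  dimnames(m) <- list(id, c(paste0("day0_r", 1:nrep), paste0("day4_r", 1:nrep)))
  storage.mode(m) <- "double"
  lib <- data.frame(shrna_id = id, gene = gene,
                    target_seq = rep("ACGTACGTACGTACGTACGTA", n_sh),
                    stringsAsFactors = FALSE)
  list(counts = count_matrix(m, rep(c("day0", "day4"), each = nrep)),
       library = lib)
}

# Binomial 99% acceptance band around a nominal rate.
binom_band <- function(alpha, n) {
  half <- stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / n)
  c(alpha - half, alpha + half)
}
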
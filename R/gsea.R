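# Gene set enrichment analysis of knockdown-vs-control transcriptomes:
# ranking metric, weighted Kolmogorov-Smirnov running-sum enrichment score,
# and gene-label permutation NES / nominal p / FDR q with leading edge.

#' Rank genes by a differential metric
#'
#' Signal-to-noise `(mu_test - mu_ref) / (sd_test + sd_ref)` with each
#' group's SD floored at `sd_floor_frac * |mu|` (the classic GSEA floor), or
#' the mean log2 difference. The result is sorted in descending metric
#' order; ties are resolved by lexicographic gene symbol so the ranking is
#' reproducible.
#'
#' @param expr Genes x samples matrix of log2 expression.
#' @param condition Character vector per sample column, with exactly two
#'   levels.
#' @param test,ref Which condition is the test (numerator) and which the
#'   reference; default: the first and second unique value of `condition`.
#' @param method `"signal2noise"` (needs >= 2 samples per group) or
#'   `"log2fc"`.
#' @param sd_floor_frac Fraction of `|mu|` used as the SD floor.
#' @return Named numeric vector of metric values, descending; names are gene
#'   symbols.
#' @export
rank_metric <- function(expr, condition, test = NULL, ref = NULL,
                        method = c("signal2noise", "log2fc"),
                        sd_floor_frac = 0.2) {
  method <- match.arg(method)
  condition <- as.character(condition)
  lv <- unique(condition)
  if (length(lv) != 2) fail("`condition` must have exactly two levels")
  if (is.null(test)) test <- lv[[1]]
  if (is.null(ref)) ref <- setdiff(lv, test)[[1]]
  it <- condition == test
  ir <- condition == ref
  if (method == "signal2noise" && (sum(it) < 2 || sum(ir) < 2))
    fail("signal2noise needs >= 2 samples per group; use method = 'log2fc'")
  mt <- rowMeans(expr[, it, drop = FALSE])
  mr <- rowMeans(expr[, ir, drop = FALSE])
  if (method == "signal2noise") {
    st <- pmax(sqrt(row_vars(expr[, it, drop = FALSE])), sd_floor_frac * abs(mt))
    sr <- pmax(sqrt(row_vars(expr[, ir, drop = FALSE])), sd_floor_frac * abs(mr))
    denom <- st + sr
    metric <- ifelse(denom == 0, 0, (mt - mr) / denom)
  } else {
    metric <- mt - mr
  }
  names(metric) <- rownames(expr)
  metric[order(-metric, names(metric))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list accumulating `|metric|^p / sum(|metric|^p over
#' hits)` at set members and `-1 / (N - N_hits)` at non-members; the
#' enrichment score is the signed extremum of the running sum. With
#' `p = 0` this reduces to the classic KS statistic on hit positions. The
#' leading edge contains the set members at or before the extremum
#' (positive ES) or at or after it (negative ES).
#'
#' @param ranked Named metric vector from [rank_metric()] (descending).
#' @param set Character vector of member gene symbols; its intersection with
#'   the ranked list must be non-empty and proper.
#' @param p Weighting exponent (default 1, classic weighted GSEA).
#' @return List with `es`, `running` (data frame `position`, `gene`, `hit`,
#'   `running_sum`) and `leading_edge`.
#' @export
enrichment_score <- function(ranked, set, p = 1) {
  genes <- names(ranked)
  hit <- genes %in% set
  n <- length(genes)
  nh <- sum(hit)
  if (nh == 0) fail("gene set has no overlap with the ranked list")
  if (nh == n) fail("gene set covers the whole ranked list (degenerate)")
  w <- abs(ranked)^p
  wh <- sum(w[hit])
  inc <- ifelse(hit, if (wh > 0) w / wh else 1 / nh, -1 / (n - nh))
  run <- cumsum(inc)
  peak <- which.max(abs(run))
  es <- run[[peak]]
  le <- if (es >= 0) genes[hit & seq_len(n) <= peak]
        else genes[hit & seq_len(n) >= peak]
  list(es = unname(es),
       running = data.frame(position = seq_len(n), gene = genes, hit = hit,
                            running_sum = unname(run),
                            stringsAsFactors = FALSE),
       leading_edge = le)
}

# Fast ES from sorted hit positions (used for the permutation null).
# `w` is |metric|^p over the whole ranked list of length n.
es_from_positions <- function(idx, w, n) {
  k <- length(idx)
  wh <- w[idx]
  cw <- cumsum(wh)
  W <- cw[[k]]
  miss <- (idx - seq_len(k)) / (n - k)
  if (W > 0) {
    at <- cw / W - miss
    before <- (cw - wh) / W - miss
  } else {
    at <- seq_len(k) / k - miss
    before <- (seq_len(k) - 1) / k - miss
  }
  v <- c(at, before)
  v[[which.max(abs(v))]]
}

#' Permutation significance for a gene-set collection
#'
#' For every set, a null distribution of enrichment scores is built from
#' `n_perm` random gene sets of matched size drawn from the ranked list
#' (gene-label permutation; knockdown designs rarely have enough replicates
#' for phenotype permutation). `NES = ES / mean(|null ES| of the same
#' sign)`; the nominal p is the add-one-corrected fraction of same-sign null
#' scores at least as extreme; the FDR q compares each set's NES with the
#' pooled sign-matched null NES distribution, GSEA-style. Results are
#' deterministic under a fixed seed.
#'
#' @param ranked Named metric vector from [rank_metric()].
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param n_perm Number of permutations, at least 100.
#' @param seed Integer seed.
#' @param p Weighting exponent passed to [enrichment_score()].
#' @return Data frame with one row per set: `set`, `size` (genes in the
#'   ranked list), `es`, `nes`, `p_value`, `q_value`, `leading_edge`
#'   (list column), `n_permutations`, `seed`.
#' @export
permutation_significance <- function(ranked, collection, n_perm = 1000,
                                     seed = 1, p = 1) {
  assert_scalar_number(n_perm, "n_perm", min = 100)
  if (is.null(names(collection)) || any(!nzchar(names(collection))))
    fail("every gene set in the collection must be named")
  n <- length(ranked)
  w <- abs(ranked)^p

  obs <- lapply(collection, function(s) enrichment_score(ranked, s, p = p))
  es <- vapply(obs, `[[`, numeric(1), "es")
  sizes <- vapply(collection, function(s) sum(names(ranked) %in% s), integer(1))

  null_by_size <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(i)
        es_from_positions(sort(sample.int(n, k)), w, n), numeric(1))
    }
    out
  })

  norm_mean <- function(x, positive) {
    m <- mean(abs(x[if (positive) x >= 0 else x < 0]))
    if (!is.finite(m) || m == 0) NA_real_ else m
  }
  nes <- numeric(length(es))
  pval <- numeric(length(es))
  null_nes_pos <- list()
  null_nes_neg <- list()
  for (i in seq_along(es)) {
    null <- null_by_size[[as.character(sizes[[i]])]]
    pos_m <- norm_mean(null, TRUE)
    neg_m <- norm_mean(null, FALSE)
    same <- if (es[[i]] >= 0) null[null >= 0] else null[null < 0]
    pval[[i]] <- (1 + sum(abs(same) >= abs(es[[i]]))) / (1 + length(same))
    nes[[i]] <- if (es[[i]] >= 0) es[[i]] / pos_m else es[[i]] / neg_m
    null_nes_pos[[i]] <- null[null >= 0] / pos_m
    null_nes_neg[[i]] <- null[null < 0] / neg_m
  }
  all_null_pos <- unlist(null_nes_pos)
  all_null_neg <- unlist(null_nes_neg)

  qval <- vapply(seq_along(nes), function(i) {
    if (is.na(nes[[i]])) return(NA_real_)
    if (nes[[i]] >= 0) {
      null_frac <- mean(all_null_pos >= nes[[i]])
      obs_frac <- mean(nes[nes >= 0 & !is.na(nes)] >= nes[[i]])
    } else {
      null_frac <- mean(all_null_neg <= nes[[i]])
      obs_frac <- mean(nes[nes < 0 & !is.na(nes)] <= nes[[i]])
    }
    if (obs_frac == 0) return(1)
    min(1, null_frac / obs_frac)
  }, numeric(1))

  out <- data.frame(set = names(collection), size = sizes, es = es,
                    nes = nes, p_value = pval, q_value = qval,
                    n_permutations = as.integer(n_perm),
                    seed = as.integer(seed),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$leading_edge <- I(lapply(obs, `[[`, "leading_edge"))
  out
}
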
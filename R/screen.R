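# Core dropout-screen statistics: CPM normalisation, per-shRNA day0-vs-day4
# testing, the three-criterion filter cascade, and gene-level aggregation.

#' Counts-per-million normalisation
#'
#' `cpm[i, s] = counts[i, s] / total[s] * 1e6`, so every sample column sums
#' to one million.
#'
#' @param counts A [count_matrix()] or a plain numeric count matrix.
#' @return Numeric CPM matrix with the same dimnames.
#' @export
cpm_normalize <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!is.matrix(m) || !is.numeric(m)) fail("`counts` must be numeric")
  totals <- colSums(m)
  zero <- which(totals == 0)
  if (length(zero) > 0)
    fail("sample '%s' has zero total counts", colnames(m)[zero[[1]]])
  sweep(m, 2, totals, "/") * 1e6
}

#' Per-shRNA day-0 vs day-4 test
#'
#' For each shRNA, computes the mean day-0 and day-4 CPM, the log2 fold
#' change of day-4 over day-0 on pseudocounted log2 CPM, and a two-sided
#' Welch t-test p-value over the log2-CPM replicate values. Both groups need
#' at least two replicates.
#'
#' Degenerate cases are resolved explicitly rather than returning `NaN`:
#' both groups zero-variance with equal means gives `p = 1`, `log2fc = 0`;
#' both zero-variance with unequal means gives the smallest representable
#' p-value and `zero_variance = TRUE`.
#'
#' @param cpm CPM matrix from [cpm_normalize()].
#' @param groups Character vector (`"day0"`/`"day4"`) per sample column, or a
#'   [count_matrix()] whose metadata supplies it.
#' @param pseudocount Added to CPM before taking log2 (default 0.5).
#' @param lib Optional library data frame; attaches a `gene` column.
#' @return Data frame with one row per shRNA: `shrna_id`, optional `gene`,
#'   `mean_cpm_day0`, `mean_cpm_day4`, `log2fc`, `p_value`, `zero_variance`.
#' @export
shrna_test <- function(cpm, groups, pseudocount = 0.5, lib = NULL) {
  if (inherits(groups, "count_matrix")) groups <- groups$samples$group
  groups <- as.character(groups)
  if (length(groups) != ncol(cpm))
    fail("`groups` must label every sample column")
  i0 <- groups == "day0"
  i4 <- groups == "day4"
  if (sum(i0) < 2 || sum(i4) < 2)
    fail("need at least 2 replicates in each of day0 and day4")
  assert_scalar_number(pseudocount, "pseudocount", min = 0)

  l <- log2(cpm + pseudocount)
  n0 <- sum(i0); n4 <- sum(i4)
  m0 <- rowMeans(l[, i0, drop = FALSE])
  m4 <- rowMeans(l[, i4, drop = FALSE])
  v0 <- row_vars(l[, i0, drop = FALSE])
  v4 <- row_vars(l[, i4, drop = FALSE])
  se2 <- v0 / n0 + v4 / n4
  lfc <- m4 - m0

  tstat <- lfc / sqrt(se2)
  df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v4 / n4)^2 / (n4 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  degen <- se2 == 0
  zero_var <- degen & lfc != 0
  p[degen & lfc == 0] <- 1
  lfc[degen & lfc == 0] <- 0
  p[zero_var] <- .Machine$double.xmin

  out <- data.frame(shrna_id = rownames(cpm),
                    mean_cpm_day0 = rowMeans(cpm[, i0, drop = FALSE]),
                    mean_cpm_day4 = rowMeans(cpm[, i4, drop = FALSE]),
                    log2fc = lfc, p_value = p, zero_variance = degen & lfc != 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(lib)) {
    idx <- match(out$shrna_id, lib$shrna_id)
    if (anyNA(idx)) fail("shRNA '%s' not present in the library",
                         out$shrna_id[which(is.na(idx))[1]])
    out$gene <- lib$gene[idx]
    out <- out[, c("shrna_id", "gene", setdiff(names(out),
                                               c("shrna_id", "gene")))]
  }
  out
}

#' Apply the abundance and significance filters to per-shRNA statistics
#'
#' An shRNA passes if and only if its mean day-0 CPM is strictly greater
#' than `cpm_threshold` (default 25 copies per million) and its p-value is
#' strictly below `p_threshold` (default 0.05). Boundary values are excluded
#' on both criteria.
#'
#' @param stats Data frame from [shrna_test()].
#' @param cpm_threshold Day-0 abundance threshold in CPM.
#' @param p_threshold Significance threshold.
#' @return The passing subset of `stats` with logical columns
#'   `passed_abundance` and `passed_test` attached; an attribute
#'   `filter_log` records survivor counts at each stage.
#' @export
filter_shrnas <- function(stats, cpm_threshold = 25, p_threshold = 0.05) {
  stats$passed_abundance <- stats$mean_cpm_day0 > cpm_threshold
  stats$passed_test <- stats$p_value < p_threshold
  keep <- stats$passed_abundance & stats$passed_test
  out <- stats[keep, , drop = FALSE]
  attr(out, "filter_log") <- c(n_input = nrow(stats),
                               n_passed_abundance = sum(stats$passed_abundance),
                               n_passed_test = sum(stats$passed_test),
                               n_passed_both = sum(keep))
  out
}

#' Aggregate passing shRNAs into gene-level screen calls
#'
#' A gene is reported when at least `min_shrnas` of its shRNAs survive the
#' abundance and significance filters. Its direction is the sign of the
#' median passing log2 fold change (`depleted` for negative: the gene's
#' knockdown reduced proliferation, i.e. the gene promotes growth;
#' `enriched` for positive). A gene whose median is exactly zero has no
#' direction and is dropped (and counted in the attached log). Evidence is
#' combined across passing shRNAs by Stouffer's method on one-sided p-values
#' oriented by the gene's direction.
#'
#' @param passing Data frame of passing shRNAs from [filter_shrnas()]; must
#'   carry a `gene` column.
#' @param min_shrnas Minimum number of passing shRNAs per reported gene
#'   (default 3).
#' @return Data frame with one row per reported gene: `gene`,
#'   `n_shrnas_passing`, `direction`, `median_log2fc`, `combined_p`.
#' @export
aggregate_genes <- function(passing, min_shrnas = 3) {
  if (is.null(passing$gene))
    fail("`passing` must have a `gene` column (run shrna_test with `lib`)")
  if (nrow(passing) == 0)
    return(data.frame(gene = character(), n_shrnas_passing = integer(),
                      direction = character(), median_log2fc = numeric(),
                      combined_p = numeric(), stringsAsFactors = FALSE))
  by_gene <- split(passing, passing$gene)
  n_tied <- 0L
  rows <- lapply(by_gene, function(d) {
    if (nrow(d) < min_shrnas) return(NULL)
    med <- stats::median(d$log2fc)
    if (med == 0) { n_tied <<- n_tied + 1L; return(NULL) }
    direction <- if (med < 0) "depleted" else "enriched"
    aligned <- if (direction == "depleted") d$log2fc < 0 else d$log2fc > 0
    p_one <- ifelse(aligned, d$p_value / 2, 1 - d$p_value / 2)
    p_one <- pmin(pmax(p_one, 1e-300), 1 - 1e-16)
    z <- stats::qnorm(p_one, lower.tail = FALSE)
    comb <- stats::pnorm(sum(z) / sqrt(length(z)), lower.tail = FALSE)
    data.frame(gene = d$gene[[1]], n_shrnas_passing = nrow(d),
               direction = direction, median_log2fc = med,
               combined_p = comb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) rownames(out) <- NULL
  if (is.null(out))
    out <- data.frame(gene = character(), n_shrnas_passing = integer(),
                      direction = character(), median_log2fc = numeric(),
                      combined_p = numeric(), stringsAsFactors = FALSE)
  attr(out, "n_zero_median_dropped") <- n_tied
  out
}

#' Run the full screen cascade on a count matrix
#'
#' Convenience composition of [cpm_normalize()], [shrna_test()],
#' [filter_shrnas()] and [aggregate_genes()].
#'
#' @param counts A [count_matrix()].
#' @param lib Library data frame mapping shRNAs to genes.
#' @inheritParams filter_shrnas
#' @inheritParams aggregate_genes
#' @inheritParams shrna_test
#' @return List with `shrna_stats` (all shRNAs), `passing` (filter
#'   survivors) and `genes` (gene-level calls).
#' @export
screen_genes <- function(counts, lib, cpm_threshold = 25, p_threshold = 0.05,
                         min_shrnas = 3, pseudocount = 0.5) {
  cpm <- cpm_normalize(counts)
  stats <- shrna_test(cpm, counts, pseudocount = pseudocount, lib = lib)
  passing <- filter_shrnas(stats, cpm_threshold, p_threshold)
  genes <- aggregate_genes(passing, min_shrnas)
  list(shrna_stats = stats, passing = passing, genes = genes)
}
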
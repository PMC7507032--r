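# Paired tumour/normal differential expression, BH-FDR, and set-overlap
# logic for comparing downregulated gene lists across knockdowns.

#' Paired tumour/normal differential expression
#'
#' Per gene, a two-sided paired t-test on the within-pair (tumour - normal)
#' differences of log2 expression; the reported `log2fc` is the mean paired
#' difference. q-values are Benjamini-Hochberg across all tested genes, and
#' genes are called `up`/`down` when `q < fdr_threshold` and
#' `|log2fc| >= lfc_threshold`, otherwise `ns`.
#'
#' A gene with zero variance of differences and zero mean difference gets
#' `p = 1`; zero variance with a non-zero mean gets the smallest
#' representable p-value.
#'
#' @param x Paired expression object (list with `expr` and `sample_info`, as
#'   from [simulate_paired_expression()] or [read_expression()]).
#' @param fdr_threshold BH-FDR threshold for calling (default 0.05).
#' @param lfc_threshold Minimum absolute log2 fold change for calling
#'   (default 1).
#' @return Data frame with `gene`, `log2fc`, `p_value`, `q_value`, `call`.
#' @export
paired_de <- function(x, fdr_threshold = 0.05, lfc_threshold = 1) {
  expr <- x$expr
  info <- x$sample_info
  it <- which(info$condition == "tumor")
  in_ <- which(info$condition == "normal")
  if (length(it) < 2 || length(it) != length(in_))
    fail("need at least 2 complete tumor/normal pairs")
  in_ <- in_[match(info$pair[it], info$pair[in_])]
  if (anyNA(in_)) fail("orphan pair label: every pair needs both conditions")

  d <- expr[, it, drop = FALSE] - expr[, in_, drop = FALSE]
  n <- ncol(d)
  m <- rowMeans(d)
  s2 <- row_vars(d)
  tstat <- m / sqrt(s2 / n)
  p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  p[s2 == 0 & m == 0] <- 1
  p[s2 == 0 & m != 0] <- .Machine$double.xmin
  q <- bh_fdr(p)
  call <- rep("ns", nrow(expr))
  call[q < fdr_threshold & m >= lfc_threshold] <- "up"
  call[q < fdr_threshold & m <= -lfc_threshold] <- "down"
  data.frame(gene = rownames(expr), log2fc = m, p_value = p, q_value = q,
             call = call, stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q(i) = min over j >= i of (m * p(j) / j)` on sorted p-values, capped at
#' 1, with the original input order restored.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    fail("all p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Overlap of two gene lists
#'
#' Exact set intersection after upper-casing symbols and dropping
#' duplicates.
#'
#' @param list_a,list_b Character vectors of gene symbols.
#' @return List with `n_a`, `n_b`, `n_overlap` and `members` (sorted
#'   intersection).
#' @export
overlap_sets <- function(list_a, list_b) {
  a <- unique(toupper(as.character(list_a)))
  b <- unique(toupper(as.character(list_b)))
  members <- sort(intersect(a, b))
  list(n_a = length(a), n_b = length(b), n_overlap = length(members),
       members = members)
}
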
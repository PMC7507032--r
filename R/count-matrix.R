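#' Construct an shRNA count matrix with sample metadata
#'
#' Container for the screen's sequencing counts: an shRNA-by-sample matrix of
#' non-negative integers plus, per sample, a group label (`"day0"` for the
#' post-selection baseline, `"day4"` for the proliferation endpoint) and a
#' replicate index.
#'
#' @param counts Numeric matrix of non-negative integer counts. Row names are
#'   shRNA identifiers, column names sample identifiers.
#' @param group Character vector of length `ncol(counts)` with values
#'   `"day0"` or `"day4"`.
#' @param replicate Optional integer vector of replicate indices per sample;
#'   defaults to a running index within each group.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (the matrix) and `samples` (a data frame with columns `sample`, `group`,
#'   `replicate`).
#' @examples
#' m <- matrix(c(10L, 90L, 12L, 88L), nrow = 2,
#'             dimnames = list(c("shA", "shB"), c("d0_1", "d4_1")))
#' cm <- count_matrix(m, group = c("day0", "day4"))
#' @export
count_matrix <- function(counts, group, replicate = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    fail("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    fail("`counts` must have row (shRNA) and column (sample) names")
  if (anyNA(counts)) fail("`counts` must not contain missing values")
  if (any(counts < 0)) fail("counts must be non-negative")
  if (any(counts != round(counts))) fail("counts must be integers")
  if (anyDuplicated(rownames(counts)))
    fail("duplicated shRNA id in counts: '%s'",
         rownames(counts)[anyDuplicated(rownames(counts))])
  group <- as.character(group)
  if (length(group) != ncol(counts))
    fail("`group` must have one label per sample column")
  bad <- setdiff(unique(group), c("day0", "day4"))
  if (length(bad) > 0)
    fail("unknown group label '%s' (expected day0/day4)", bad[[1]])
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(group), group, FUN = seq_along)
  }
  if (length(replicate) != ncol(counts))
    fail("`replicate` must have one entry per sample column")
  structure(
    list(counts = counts,
         samples = data.frame(sample = colnames(counts),
                              group = group,
                              replicate = as.integer(replicate),
                              stringsAsFactors = FALSE)),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d shRNAs x %d samples (%d day0, %d day4)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$samples$group == "day0"),
              sum(x$samples$group == "day4")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
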
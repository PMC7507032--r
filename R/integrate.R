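# Candidate selection: screen hits whose expression change in tumours is
# consistent with their screen phenotype, ranked by DE FDR.

#' Direction-consistent candidate genes
#'
#' A gene depleted in the dropout screen promoted proliferation; it is a
#' candidate when it is also upregulated in tumours. Conversely, a gene
#' enriched on knockdown (growth-inhibiting) is a candidate when
#' downregulated in tumours. All other combinations are dropped; genes
#' present in only one input are dropped silently but counted in the
#' attached log.
#'
#' @param screen Gene-level screen results from [aggregate_genes()]
#'   (columns `gene`, `direction`, `combined_p`, ...).
#' @param de DE results from [paired_de()] (columns `gene`, `log2fc`,
#'   `q_value`, `call`, ...).
#' @return Merged data frame of candidates, with a `merge_log` attribute
#'   recording how many genes were shared between the inputs.
#' @export
direction_consistent_candidates <- function(screen, de) {
  merged <- merge(screen, de, by = "gene",
                  suffixes = c("_screen", "_de"))
  keep <- (merged$direction == "depleted" & merged$call == "up") |
          (merged$direction == "enriched" & merged$call == "down")
  out <- merged[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "merge_log") <- c(n_screen = nrow(screen), n_de = nrow(de),
                              n_shared = nrow(merged),
                              n_consistent = nrow(out))
  out
}

#' Rank candidate genes
#'
#' Ascending sort by the chosen key (default the DE q-value, i.e. the
#' aberrant-expression FDR); ties broken by larger absolute DE log2 fold
#' change, then lexicographic gene symbol. Ranks are assigned 1..n.
#'
#' @param candidates Data frame from [direction_consistent_candidates()].
#' @param rank_by `"de"` (DE q-value), `"screen"` (screen combined p) or
#'   `"product"` (product of the two).
#' @return The candidate table sorted with an integer `rank` column.
#' @export
rank_candidates <- function(candidates, rank_by = c("de", "screen", "product")) {
  rank_by <- match.arg(rank_by)
  key <- switch(rank_by,
                de = candidates$q_value,
                screen = candidates$combined_p,
                product = candidates$q_value * candidates$combined_p)
  if (anyNA(key) || any(!is.finite(key)))
    fail("every candidate needs a finite ranking key (missing q_value?)")
  ord <- order(key, -abs(candidates$log2fc), candidates$gene)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
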
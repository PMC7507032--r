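# Readers/writers for the on-disk formats the pipeline touches, plus
# exact-match shRNA quantification from raw FASTQ reads. All readers reject
# malformed input rather than silently coercing it.

#' Read / write an shRNA library annotation
#'
#' The library is a tab-separated table with header columns `shrna_id`,
#' `gene`, `target_seq`; each shRNA maps to exactly one gene and its target
#' sequence is a non-empty string over A/C/G/T.
#'
#' @param path File path.
#' @return `read_library`: a data frame with the three columns above.
#' @export
read_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("shrna_id", "gene", "target_seq")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    fail("library file %s is missing column(s): %s", path,
         paste(missing, collapse = ", "))
  validate_library(df[need])
  df[need]
}

validate_library <- function(lib) {
  dup <- lib$shrna_id[duplicated(lib$shrna_id)]
  if (length(dup) > 0)
    fail("duplicated shrna_id '%s' (row %d)", dup[[1]],
         which(lib$shrna_id == dup[[1]])[2])
  bad <- grep("^[ACGT]+$", lib$target_seq, invert = TRUE)
  if (length(bad) > 0)
    fail("target_seq of '%s' (row %d) is not a non-empty A/C/G/T string",
         lib$shrna_id[bad[[1]]], bad[[1]])
  n_gene <- tapply(lib$gene, lib$shrna_id, function(g) length(unique(g)))
  if (any(n_gene > 1)) fail("an shRNA maps to more than one gene")
  invisible(lib)
}

#' @rdname read_library
#' @param lib Library data frame (`shrna_id`, `gene`, `target_seq`).
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an shRNA count matrix
#'
#' Counts are stored as a TSV whose first column is `shrna_id` and whose
#' remaining columns are samples named `<group>_r<replicate>` with group
#' `day0` or `day4` (e.g. `day0_r1`); the sample metadata round-trips
#' through the column names.
#'
#' @param path File path.
#' @return `read_counts`: a [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "shrna_id") fail("first column must be `shrna_id`")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$shrna_id
  if (!is.numeric(m)) fail("non-numeric count in %s", path)
  parsed <- regmatches(colnames(m),
                       regexec("^(day0|day4)_r([0-9]+)$", colnames(m)))
  bad <- which(lengths(parsed) == 0)
  if (length(bad) > 0)
    fail("sample name '%s' is not of the form day0_r<i>/day4_r<i>",
         colnames(m)[bad[[1]]])
  count_matrix(m,
               group = vapply(parsed, `[`, character(1), 2),
               replicate = as.integer(vapply(parsed, `[`, character(1), 3)))
}

#' @rdname read_counts
#' @param cm A [count_matrix()].
#' @export
write_counts <- function(cm, path) {
  if (!inherits(cm, "count_matrix")) fail("`cm` must be a count_matrix")
  m <- cm$counts
  colnames(m) <- paste0(cm$samples$group, "_r", cm$samples$replicate)
  df <- data.frame(shrna_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a paired tumour/normal expression matrix
#'
#' Expression is a TSV whose first column is `gene` and whose sample columns
#' are named `<condition>_<pair>` with condition `tumor` or `normal`; every
#' pair id must appear exactly once per condition.
#'
#' @param path File path.
#' @return `read_expression`: list with `expr` (matrix) and `sample_info`
#'   (data frame `sample`, `condition`, `pair`), the structure produced by
#'   [simulate_paired_expression()].
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "gene") fail("first column must be `gene`")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (!is.numeric(m) || anyNA(m)) fail("non-numeric or missing expression value")
  parsed <- regmatches(colnames(m),
                       regexec("^(tumor|normal)_(.+)$", colnames(m)))
  bad <- which(lengths(parsed) == 0)
  if (length(bad) > 0)
    fail("sample name '%s' is not of the form tumor_<pair>/normal_<pair>",
         colnames(m)[bad[[1]]])
  condition <- vapply(parsed, `[`, character(1), 2)
  pair <- vapply(parsed, `[`, character(1), 3)
  tab <- table(pair, condition)
  orphan <- rownames(tab)[rowSums(tab == 1) != 2]
  if (length(orphan) > 0)
    fail("pair '%s' lacks a complete tumor/normal couple", orphan[[1]])
  list(expr = m,
       sample_info = data.frame(sample = colnames(m), condition = condition,
                                pair = pair, stringsAsFactors = FALSE))
}

#' @rdname read_expression
#' @param x List with `expr` and `sample_info` as returned by
#'   [read_expression()] / [simulate_paired_expression()].
#' @export
write_expression <- function(x, path) {
  m <- x$expr
  colnames(m) <- paste0(x$sample_info$condition, "_", x$sample_info$pair)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write gene set collections in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path File path.
#' @return `read_gmt`: named list of character vectors of member genes, with
#'   a `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    fail("GMT line %d has no members (empty set)", short[[1]])
  nm <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nm)) fail("duplicated set name '%s'", nm[duplicated(nm)][1])
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  attr(sets, "description") <-
    stats::setNames(vapply(fields, `[`, character(1), 2), nm)
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors; optional `description`
#'   attribute.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    fail("every gene set must be named")
  if (any(lengths(sets) == 0)) fail("empty gene set not allowed")
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a survival table
#'
#' CSV with header columns `id`, `time` (non-negative), `event` (0/1),
#' `marker`, and optionally `group`. Missing values in required columns are
#' rejected.
#'
#' @param path File path.
#' @return `read_survival`: a data frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time", "event", "marker")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    fail("survival file is missing column(s): %s",
         paste(missing, collapse = ", "))
  if (anyNA(df[need])) fail("missing value in a required survival column")
  if (!all(df$event %in% c(0, 1))) fail("`event` must be 0 or 1")
  if (any(df$time < 0)) fail("`time` must be non-negative")
  df
}

#' @rdname read_survival
#' @param records Survival data frame.
#' @export
write_survival <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a simulation ground-truth ledger as JSON
#'
#' @param truth A list (e.g. the `truth` element of a simulator's output).
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors must become JSON objects, not nameless arrays
  objectify <- function(x) {
    if (is.list(x)) lapply(x, objectify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(objectify(truth), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Quantify shRNA abundance in raw reads by exact sequence match
#'
#' A read increments an shRNA's count if and only if the shRNA's target
#' sequence occurs as an exact substring of the read (sense strand; set
#' `revcomp = TRUE` to also search the reverse complement). Reads matching no
#' shRNA are unassigned; reads matching more than one are ambiguous and
#' assigned to none, so `assigned + unassigned + ambiguous = n_reads`.
#'
#' @param fastq_path Path to a FASTQ file (plain or gzip-compressed).
#' @param lib Library data frame (`shrna_id`, `gene`, `target_seq`).
#' @param revcomp Also match the reverse complement of each target sequence.
#' @return List with `counts` (named integer vector per shRNA), `n_reads`,
#'   `n_assigned`, `n_unassigned`, `n_ambiguous`.
#' @export
count_shrnas_from_fastq <- function(fastq_path, lib, revcomp = FALSE) {
  validate_library(lib)
  lines <- readLines(fastq_path)
  if (length(lines) %% 4 != 0)
    fail("malformed FASTQ %s: %d lines is not a multiple of 4",
         fastq_path, length(lines))
  n_reads <- length(lines) %/% 4
  for (i in seq_len(n_reads)) {
    block <- lines[(4 * i - 3):(4 * i)]
    if (!startsWith(block[1], "@") || !startsWith(block[3], "+") ||
        nchar(block[2]) != nchar(block[4]))
      fail("malformed FASTQ record %d in %s", i, fastq_path)
  }
  reads <- Biostrings::DNAStringSet(lines[seq(2, length(lines), by = 4)])

  hit <- vapply(lib$target_seq, function(s) {
    h <- Biostrings::vcountPattern(s, reads, fixed = TRUE) > 0
    if (revcomp) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
      h <- h | Biostrings::vcountPattern(rc, reads, fixed = TRUE) > 0
    }
    h
  }, logical(n_reads))
  hit <- matrix(hit, nrow = n_reads)  # guards n_reads <= 1 drop
  n_hits <- rowSums(hit)
  uniq <- n_hits == 1L
  counts <- stats::setNames(colSums(hit[uniq, , drop = FALSE]), lib$shrna_id)
  list(counts = as.integer(counts) |> stats::setNames(lib$shrna_id),
       n_reads = n_reads,
       n_assigned = sum(uniq),
       n_unassigned = sum(n_hits == 0L),
       n_ambiguous = sum(n_hits > 1L))
}
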
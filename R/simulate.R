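#' Configuration for the pooled shRNA screen simulator
#'
#' Defines the study conditions of a simulated dropout screen: a library of
#' `n_genes * shrnas_per_gene` shRNAs sequenced at day 0 (post-selection
#' baseline) and day 4 (proliferation endpoint). A fraction of genes is
#' essential (their knockdown reagents drop out by day 4) and a fraction acts
#' as growth suppressors (their reagents are enriched).
#'
#' Counts are negative binomial (gamma-Poisson) around library-size-scaled
#' per-shRNA abundances. Baseline abundances are log-normal across shRNAs, so
#' a realistic minority of shRNAs sits below the 25 counts-per-million
#' abundance filter.
#'
#' @param n_genes Number of genes in the library.
#' @param shrnas_per_gene shRNAs targeting each gene (default 5, the typical
#'   redundancy of genome-scale pooled libraries).
#' @param n_replicates_per_group Sequencing replicates per time point.
#' @param library_size Expected reads per sample.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param frac_essential,frac_suppressor Fractions of genes whose knockdown
#'   depletes / enriches by day 4. Must sum to at most 1.
#' @param effect_log2fc Mean day4-vs-day0 log2 change applied to essential
#'   genes' shRNA abundances (negative = dropout); suppressors receive the
#'   opposite sign.
#' @param baseline_sdlog Log-scale SD of the log-normal baseline abundances.
#' @param add_null_shrna If `TRUE`, the first shRNA of every affected gene
#'   carries no effect (an "off-target-like" reagent), exercising the
#'   3-concordant-shRNAs rule.
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical output.
#' @return An object of class `screen_sim_config`.
#' @seealso [simulate_screen()]
#' @export
screen_sim_config <- function(n_genes,
                              shrnas_per_gene = 5,
                              n_replicates_per_group = 3,
                              library_size = 1e7,
                              nb_dispersion = 0.05,
                              frac_essential = 0.1,
                              frac_suppressor = 0.05,
                              effect_log2fc = -2,
                              baseline_sdlog = 1.5,
                              add_null_shrna = FALSE,
                              seed = 1) {
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(shrnas_per_gene, "shrnas_per_gene", min = 1)
  assert_scalar_number(n_replicates_per_group, "n_replicates_per_group", min = 1)
  assert_scalar_number(library_size, "library_size", min = 0, strict_min = TRUE)
  assert_scalar_number(nb_dispersion, "nb_dispersion", min = 0, strict_min = TRUE)
  assert_scalar_number(frac_essential, "frac_essential", min = 0, max = 1)
  assert_scalar_number(frac_suppressor, "frac_suppressor", min = 0, max = 1)
  if (frac_essential + frac_suppressor > 1)
    fail("frac_essential + frac_suppressor must be <= 1")
  assert_scalar_number(effect_log2fc, "effect_log2fc")
  assert_scalar_number(baseline_sdlog, "baseline_sdlog", min = 0)
  structure(
    list(n_genes = as.integer(n_genes),
         shrnas_per_gene = as.integer(shrnas_per_gene),
         n_replicates_per_group = as.integer(n_replicates_per_group),
         library_size = library_size,
         nb_dispersion = nb_dispersion,
         frac_essential = frac_essential,
         frac_suppressor = frac_suppressor,
         effect_log2fc = effect_log2fc,
         baseline_sdlog = baseline_sdlog,
         add_null_shrna = isTRUE(add_null_shrna),
         seed = as.integer(seed)),
    class = "screen_sim_config")
}

#' Simulate a pooled shRNA dropout screen
#'
#' Draws a synthetic screen under a [screen_sim_config()]: a library
#' annotation (shRNA id, gene, random 21-nt target sequence), day-0/day-4
#' count matrices, and a ground-truth ledger classifying every gene as
#' `essential`, `suppressor` or `neutral`.
#'
#' Day-4 expected abundances of essential genes' shRNAs are multiplied by
#' `2^effect_log2fc` (suppressors by the reciprocal). Because sequencing is
#' compositional, raw day4/day0 CPM ratios of affected shRNAs converge to
#' `2^effect_log2fc` times the total-abundance ratio; effect-recovery checks
#' should therefore compare against neutral shRNAs (ratio of ratios).
#'
#' @param config A `screen_sim_config`.
#' @return A list with elements `library` (data frame: `shrna_id`, `gene`,
#'   `target_seq`), `counts` (a [count_matrix()]) and `truth` (list with
#'   `gene_class`, a named character vector, and the config).
#' @examples
#' sim <- simulate_screen(screen_sim_config(n_genes = 20, seed = 7))
#' table(sim$truth$gene_class)
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_sim_config"))
    fail("`config` must be created by screen_sim_config()")
  with_seed(config$seed, {
    n_genes <- config$n_genes
    k <- config$shrnas_per_gene
    genes <- sprintf("G%04d", seq_len(n_genes))

    n_ess <- round(config$frac_essential * n_genes)
    n_sup <- round(config$frac_suppressor * n_genes)
    cls <- rep("neutral", n_genes)
    idx <- sample.int(n_genes, n_ess + n_sup)
    cls[idx[seq_len(n_ess)]] <- "essential"
    if (n_sup > 0) cls[idx[n_ess + seq_len(n_sup)]] <- "suppressor"
    gene_class <- stats::setNames(cls, genes)

    shrna_gene <- rep(genes, each = k)
    shrna_id <- paste0(shrna_gene, "_sh", rep(seq_len(k), times = n_genes))
    n_sh <- length(shrna_id)
    target_seq <- vapply(seq_len(n_sh), function(i)
      paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
      character(1))

    w0 <- stats::rlnorm(n_sh, meanlog = 0, sdlog = config$baseline_sdlog)
    p0 <- w0 / sum(w0)

    fac <- rep(1, n_sh)
    fac[gene_class[shrna_gene] == "essential"] <- 2^config$effect_log2fc
    fac[gene_class[shrna_gene] == "suppressor"] <- 2^(-config$effect_log2fc)
    if (config$add_null_shrna) {
      first <- rep(seq_len(k), times = n_genes) == 1L
      fac[first & gene_class[shrna_gene] != "neutral"] <- 1
    }

    mu0 <- config$library_size * p0
    mu4 <- mu0 * fac
    nrep <- config$n_replicates_per_group
    size <- 1 / config$nb_dispersion

    draw <- function(mu) matrix(
      stats::rnbinom(n_sh * nrep, mu = rep(mu, nrep), size = size),
      nrow = n_sh, ncol = nrep)
    m <- cbind(draw(mu0), draw(mu4))
    dimnames(m) <- list(shrna_id,
                        c(paste0("day0_r", seq_len(nrep)),
                          paste0("day4_r", seq_len(nrep))))
    storage.mode(m) <- "double"

    lib <- data.frame(shrna_id = shrna_id, gene = shrna_gene,
                      target_seq = target_seq, stringsAsFactors = FALSE)
    cm <- count_matrix(m, group = rep(c("day0", "day4"), each = nrep),
                       replicate = rep(seq_len(nrep), times = 2))
    list(library = lib,
         counts = cm,
         truth = list(gene_class = gene_class,
                      shrna_effect_factor = stats::setNames(fac, shrna_id),
                      config = config))
  })
}

#' Simulate paired tumour/normal expression with planted DE genes
#'
#' Generates log2-scale expression for `n_pairs` matched tumour/normal sample
#' pairs (emulating a paired adenoma-vs-mucosa microarray comparison of 32
#' pairs). A fraction of genes is differentially expressed: shifted by
#' `de_log2fc` in tumours, with up/down signs balanced unless explicit gene
#' lists are supplied.
#'
#' @param n_genes Number of genes (ignored when `gene_names` is given).
#' @param n_pairs Number of tumour/normal pairs (default 32); must be >= 2.
#' @param frac_de Fraction of genes planted as DE (ignored when explicit
#'   `de_genes_up`/`de_genes_down` are given).
#' @param de_log2fc Absolute log2 shift applied to planted genes in tumours.
#' @param noise_sd Residual SD of each log2 measurement.
#' @param seed Integer seed.
#' @param gene_names Optional gene symbols (to share a gene universe with a
#'   screen simulation).
#' @param de_genes_up,de_genes_down Optional explicit planted up-/
#'   down-regulated gene sets (subsets of the gene universe).
#' @return List with `expr` (genes x 2*n_pairs matrix, columns named
#'   `tumor_P..`/`normal_P..`), `sample_info` (data frame: `sample`,
#'   `condition`, `pair`) and `truth` (named vector of true tumour-vs-normal
#'   log2 fold changes).
#' @export
simulate_paired_expression <- function(n_genes, n_pairs = 32, frac_de = 0.1,
                                       de_log2fc = 1, noise_sd = 0.2,
                                       seed = 1, gene_names = NULL,
                                       de_genes_up = NULL,
                                       de_genes_down = NULL) {
  if (!is.null(gene_names)) n_genes <- length(gene_names)
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(n_pairs, "n_pairs", min = 2)
  assert_scalar_number(frac_de, "frac_de", min = 0, max = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  n_genes <- as.integer(n_genes)
  n_pairs <- as.integer(n_pairs)
  genes <- if (is.null(gene_names)) sprintf("G%04d", seq_len(n_genes))
           else as.character(gene_names)

  with_seed(seed, {
    shift <- stats::setNames(rep(0, n_genes), genes)
    if (is.null(de_genes_up) && is.null(de_genes_down)) {
      n_de <- round(frac_de * n_genes)
      de <- sample(genes, n_de)
      half <- seq_len(floor(n_de / 2))
      shift[de] <- abs(de_log2fc)
      if (n_de > 0) shift[de[half]] <- -abs(de_log2fc)
    } else {
      if (length(intersect(de_genes_up, de_genes_down)) > 0)
        fail("a gene cannot be planted both up and down")
      missing <- setdiff(c(de_genes_up, de_genes_down), genes)
      if (length(missing) > 0)
        fail("planted DE gene not in gene universe: '%s'", missing[[1]])
      shift[de_genes_up] <- abs(de_log2fc)
      shift[de_genes_down] <- -abs(de_log2fc)
    }

    base <- stats::runif(n_genes, 4, 12)
    pair_eff <- matrix(stats::rnorm(n_genes * n_pairs, sd = 0.5),
                       nrow = n_genes)
    noise <- function() matrix(stats::rnorm(n_genes * n_pairs, sd = noise_sd),
                               nrow = n_genes)
    normal <- base + pair_eff + noise()
    tumor <- base + pair_eff + shift + noise()
    pair_ids <- sprintf("P%02d", seq_len(n_pairs))
    expr <- cbind(tumor, normal)
    dimnames(expr) <- list(genes, c(paste0("tumor_", pair_ids),
                                    paste0("normal_", pair_ids)))
    list(expr = expr,
         sample_info = data.frame(
           sample = colnames(expr),
           condition = rep(c("tumor", "normal"), each = n_pairs),
           pair = rep(pair_ids, times = 2),
           stringsAsFactors = FALSE),
         truth = shift)
  })
}

#' Simulate a knockdown transcriptome with one planted enriched gene set
#'
#' Generates a small knockdown-vs-control expression experiment in which the
#' members of one gene set receive a common (by default negative) expression
#' shift in the knockdown samples, plus a collection of decoy sets drawn
#' uniformly from the gene universe. Feeding the result through
#' [rank_metric()] and [permutation_significance()] should recover the
#' planted set as the most negatively enriched.
#'
#' @param n_genes Genes in the transcriptome.
#' @param set_size Size of the planted set; must be < `n_genes`.
#' @param planted_shift Log2 shift of planted genes in knockdown samples
#'   (negative = enriched among downregulated genes).
#' @param n_decoy_sets Number of uniformly drawn decoy sets.
#' @param decoy_size_range Inclusive size range for decoy sets.
#' @param n_per_group Samples per condition.
#' @param noise_sd Residual SD of each log2 measurement.
#' @param seed Integer seed.
#' @return List with `expr` (genes x samples), `sample_info` (`condition` =
#'   `kd`/`control`), `gene_sets` (named list of character vectors, planted
#'   set named `"planted"`), and `truth` (planted set name and members).
#' @export
simulate_ranked_transcriptome <- function(n_genes = 1000, set_size = 50,
                                          planted_shift = -1,
                                          n_decoy_sets = 20,
                                          decoy_size_range = c(15, 100),
                                          n_per_group = 3, noise_sd = 0.5,
                                          seed = 1) {
  assert_scalar_number(n_genes, "n_genes", min = 2)
  assert_scalar_number(set_size, "set_size", min = 1)
  if (set_size >= n_genes) fail("set_size must be smaller than n_genes")
  assert_scalar_number(n_per_group, "n_per_group", min = 2)
  n_genes <- as.integer(n_genes)
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    planted <- sort(sample(genes, set_size))
    sets <- list(planted = planted)
    for (i in seq_len(n_decoy_sets)) {
      sz <- sample(seq(decoy_size_range[1], decoy_size_range[2]), 1)
      sets[[sprintf("decoy%02d", i)]] <- sort(sample(genes, sz))
    }
    shift <- stats::setNames(rep(0, n_genes), genes)
    shift[planted] <- planted_shift
    base <- stats::runif(n_genes, 4, 12)
    noise <- function() matrix(
      stats::rnorm(n_genes * n_per_group, sd = noise_sd), nrow = n_genes)
    kd <- base + shift + noise()
    ctrl <- base + noise()
    expr <- cbind(kd, ctrl)
    dimnames(expr) <- list(genes, c(paste0("kd_", seq_len(n_per_group)),
                                    paste0("control_", seq_len(n_per_group))))
    list(expr = expr,
         sample_info = data.frame(
           sample = colnames(expr),
           condition = rep(c("kd", "control"), each = n_per_group),
           stringsAsFactors = FALSE),
         gene_sets = sets,
         truth = list(planted_set = "planted", planted_genes = planted,
                      planted_shift = planted_shift))
  })
}

#' Simulate a survival cohort with a marker-dependent hazard
#'
#' Event times are exponential with hazard `baseline_hazard` for marker-low
#' patients and `baseline_hazard * hazard_ratio` for marker-high patients
#' (high = continuous marker above the population median). Censoring times
#' are independent exponentials with a single cohort-wide rate (censoring is
#' non-informative), calibrated against the mean event hazard so the
#' expected censored fraction is `censor_rate` (exactly so when
#' `hazard_ratio = 1`); `censor_rate = 1` marks every record censored.
#'
#' @param n_patients Cohort size; must be >= 10.
#' @param hazard_ratio Hazard ratio of marker-high vs marker-low; must be > 0.
#' @param censor_rate Expected fraction of censored records in `[0, 1]`.
#' @param baseline_hazard Events per month in the marker-low group.
#' @param seed Integer seed.
#' @return Data frame with columns `id`, `time` (months), `event` (0/1),
#'   `marker`, `group` (`"high"`/`"low"`).
#' @export
simulate_survival_cohort <- function(n_patients, hazard_ratio = 3,
                                     censor_rate = 0.2,
                                     baseline_hazard = 0.05, seed = 1) {
  assert_scalar_number(n_patients, "n_patients", min = 10)
  assert_scalar_number(hazard_ratio, "hazard_ratio", min = 0, strict_min = TRUE)
  assert_scalar_number(censor_rate, "censor_rate", min = 0, max = 1)
  assert_scalar_number(baseline_hazard, "baseline_hazard", min = 0,
                       strict_min = TRUE)
  n <- as.integer(n_patients)
  with_seed(seed, {
    marker <- stats::rnorm(n)
    high <- marker > stats::median(marker)
    lambda <- baseline_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- stats::rexp(n, rate = lambda)
    if (censor_rate >= 1) {
      time <- t_event
      event <- rep(0L, n)
    } else if (censor_rate == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      lambda_c <- mean(lambda) * censor_rate / (1 - censor_rate)
      t_cens <- stats::rexp(n, rate = lambda_c)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    }
    data.frame(id = sprintf("PT%03d", seq_len(n)),
               time = time, event = event, marker = marker,
               group = ifelse(high, "high", "low"),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a bivariate-normal expression pair with known correlation
#'
#' @param n Number of observations (default 270, a typical tumour-cohort
#'   size for expression correlation); must be >= 3.
#' @param rho Population Pearson correlation, strictly between -1 and 1.
#' @param seed Integer seed.
#' @return Data frame with columns `x` and `y`.
#' @export
simulate_correlated_pairs <- function(n = 270, rho = 0.4, seed = 1) {
  assert_scalar_number(n, "n", min = 3)
  assert_scalar_number(rho, "rho")
  if (abs(rho) >= 1) fail("`rho` must satisfy -1 < rho < 1")
  n <- as.integer(n)
  with_seed(seed, {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    data.frame(x = x, y = y)
  })
}
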
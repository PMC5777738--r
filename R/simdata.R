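#' Configure a synthetic polysome-profiling experiment
#'
#' Builds and validates the parameter set for [simulate_experiment()]. The
#' default design mirrors a two-cell-line polysome-profiling screen: cells
#' cultured in normoxia (`N`, the control), hypoxia (`H`), an mTOR inhibitor
#' (`PP`) or both (`HPP`), each profiled in a total-mRNA pool (`T`) and a
#' polysome-bound pool (`P`) with `replicates` libraries per condition.
#'
#' Genes fall into four regulation classes relative to the control:
#' \describe{
#'   \item{null}{no change in either pool.}
#'   \item{transcriptional}{the same log2 shift in both pools (mRNA level
#'     changes, translation follows).}
#'   \item{translational}{a shift in the polysomal pool only (ribosome
#'     loading changes at constant mRNA).}
#'   \item{buffered}{a transcriptional shift exactly compensated in the
#'     polysomal pool, so P stays flat while T moves.}
#' }
#'
#' @param n_genes number of genes.
#' @param cell_lines character vector of cell-line labels.
#' @param treatments character vector of treatment labels; the first is the
#'   control every other treatment is contrasted against.
#' @param replicates libraries per (cell line, treatment, pool); at least 2.
#' @param class_proportions named non-negative fractions over
#'   `c("null", "transcriptional", "translational", "buffered")` summing to 1.
#' @param effect_size_log2 positive magnitude (log2 units) of planted effects;
#'   each regulated gene receives a random sign.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters (natural
#'   log) of per-gene relative abundance.
#' @param dispersion negative-binomial dispersion phi >= 0 under the
#'   variance = mean + phi * mean^2 parameterization; 0 gives Poisson counts.
#' @param dispersion_trend optional `c(phi0, phi1)` making the per-observation
#'   dispersion phi0 + phi1 / mean, a decreasing mean-dispersion trend.
#' @param polysome_loading_logit_sd spread (logit scale) of the per-gene
#'   baseline polysome-loading fraction around 0.5.
#' @param library_size_mean,library_size_cv mean and coefficient of variation
#'   of per-sample sequencing depth (log-normal; cv 0 gives constant depth).
#' @param seed integer seed; identical configurations generate bit-identical
#'   experiments.
#'
#' @return a validated list of class `"sim_config"`.
#' @seealso [simulate_experiment()]
#' @export
sim_config <- function(n_genes = 10000L,
                       cell_lines = c("MCF10A", "MDAMB231"),
                       treatments = c("N", "H", "PP", "HPP"),
                       replicates = 2L,
                       class_proportions = c(null = 0.7,
                                             transcriptional = 0.1,
                                             translational = 0.1,
                                             buffered = 0.1),
                       effect_size_log2 = 1,
                       baseline_log_mean = 4,
                       baseline_log_sd = 1,
                       dispersion = 0.1,
                       dispersion_trend = NULL,
                       polysome_loading_logit_sd = 0.5,
                       library_size_mean = 2e6,
                       library_size_cv = 0.1,
                       seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  replicates <- check_count(replicates, "replicates", min = 2L)
  if (!is.character(cell_lines) || length(cell_lines) < 1L ||
      anyDuplicated(cell_lines))
    stopf("'cell_lines' must be distinct labels")
  if (!is.character(treatments) || length(treatments) < 2L ||
      anyDuplicated(treatments))
    stopf("'treatments' must be >= 2 distinct labels (control first)")
  classes <- c("null", "transcriptional", "translational", "buffered")
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% classes))
    stopf("'class_proportions' must be named over {%s}",
          paste(classes, collapse = ", "))
  p <- stats::setNames(numeric(4), classes)
  p[names(class_proportions)] <- class_proportions
  if (any(p < 0)) stopf("'class_proportions' must be non-negative")
  if (abs(sum(p) - 1) > 1e-12) stopf("'class_proportions' must sum to 1")
  check_number(effect_size_log2, "effect_size_log2", min = 0, strict_min = TRUE)
  check_number(baseline_log_sd, "baseline_log_sd", min = 0)
  check_number(dispersion, "dispersion", min = 0)
  if (!is.null(dispersion_trend)) {
    if (!is.numeric(dispersion_trend) || length(dispersion_trend) != 2L ||
        any(dispersion_trend < 0))
      stopf("'dispersion_trend' must be non-negative c(phi0, phi1)")
  }
  check_number(polysome_loading_logit_sd, "polysome_loading_logit_sd", min = 0)
  check_number(library_size_mean, "library_size_mean", min = 0,
               strict_min = TRUE)
  check_number(library_size_cv, "library_size_cv", min = 0)
  seed <- check_count(seed, "seed", min = -.Machine$integer.max)
  structure(list(n_genes = n_genes, cell_lines = cell_lines,
                 treatments = treatments, replicates = replicates,
                 class_proportions = p, effect_size_log2 = effect_size_log2,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd, dispersion = dispersion,
                 dispersion_trend = dispersion_trend,
                 polysome_loading_logit_sd = polysome_loading_logit_sd,
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv, seed = seed),
            class = "sim_config")
}

#' Simulate a polysome-profiling count experiment with known regulation
#'
#' Generative model, per gene g: relative abundance
#' `a_g ~ LogNormal(baseline_log_mean, baseline_log_sd)`; baseline polysome
#' loading fraction `r_g` logistic-normal around 0.5 with spread
#' `polysome_loading_logit_sd`. Under treatment c the expected relative
#' abundance is proportional to `a_g * 2^t_gc` in the total pool and
#' `a_g * r_g * 2^(t_gc + d_gc)` in the polysomal pool, where `t` and `d` are
#' the planted transcriptional and translational log2 effects. Each sample's
#' expectation vector is renormalized to sum to 1 (sequencing measures
#' relative, compositional abundance) and multiplied by that sample's library
#' size; counts are negative-binomial with dispersion phi via a Gamma-Poisson
#' mixture, collapsing exactly to Poisson at phi = 0.
#'
#' @param config a [sim_config()].
#' @return a list of class `"sim_experiment"` with elements `counts` (integer
#'   gene-by-sample matrix), `design` (sample sheet data.frame), `truth`
#'   (per-gene class plus `t_<treatment>`/`d_<treatment>` effect columns for
#'   each non-control treatment) and `config`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_genes = 200, cell_lines = "A",
#'                                       treatments = c("N", "H"),
#'                                       library_size_mean = 1e5, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    stopf("'config' must come from sim_config()")
  with_seed(config$seed, .simulate_experiment(config))
}

.simulate_experiment <- function(cf) {
  n <- cf$n_genes
  classes <- names(cf$class_proportions)
  gene_id <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))
  cls <- sample(classes, n, replace = TRUE, prob = cf$class_proportions)
  sign <- sample(c(-1, 1), n, replace = TRUE)
  eff <- cf$effect_size_log2 * sign
  t_g <- ifelse(cls %in% c("transcriptional", "buffered"), eff, 0)
  d_g <- ifelse(cls == "translational", eff,
                ifelse(cls == "buffered", -eff, 0))

  a <- stats::rlnorm(n, cf$baseline_log_mean, cf$baseline_log_sd)
  r <- stats::plogis(stats::rnorm(n, 0, cf$polysome_loading_logit_sd))

  design <- expand.grid(replicate = seq_len(cf$replicates),
                        pool = c("T", "P"),
                        treatment = cf$treatments,
                        cell_line = cf$cell_lines,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("cell_line", "treatment", "pool", "replicate")]
  design$sample_id <- with(design,
                           paste(cell_line, treatment, pool, replicate,
                                 sep = "_"))
  design <- design[, c("sample_id", "cell_line", "treatment", "pool",
                       "replicate")]
  ns <- nrow(design)

  if (cf$library_size_cv > 0) {
    sdlog <- sqrt(log1p(cf$library_size_cv^2))
    lib <- stats::rlnorm(ns, log(cf$library_size_mean) - sdlog^2 / 2, sdlog)
  } else lib <- rep(cf$library_size_mean, ns)

  counts <- matrix(0L, n, ns, dimnames = list(gene_id, design$sample_id))
  control <- cf$treatments[1L]
  for (s in seq_len(ns)) {
    trt <- design$treatment[s]
    tt <- if (trt == control) 0 else t_g
    dd <- if (trt == control) 0 else d_g
    q <- if (design$pool[s] == "T") a * 2^tt else a * r * 2^(tt + dd)
    mu <- lib[s] * q / sum(q)
    phi <- if (is.null(cf$dispersion_trend)) rep(cf$dispersion, n) else
      cf$dispersion_trend[1L] + cf$dispersion_trend[2L] / pmax(mu, 1e-8)
    lambda <- if (all(phi == 0)) mu else {
      out <- mu
      nb <- phi > 0
      out[nb] <- stats::rgamma(sum(nb), shape = 1 / phi[nb],
                               rate = 1 / (phi[nb] * mu[nb]))
      out
    }
    counts[, s] <- stats::rpois(n, lambda)
  }

  truth <- data.frame(gene_id = gene_id, class = cls,
                      stringsAsFactors = FALSE)
  for (trt in cf$treatments[-1L]) {
    truth[[paste0("t_", trt)]] <- t_g
    truth[[paste0("d_", trt)]] <- d_g
  }
  structure(list(counts = counts, design = design, truth = truth,
                 config = cf),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d genes x %d samples (%d cell line(s), %d treatments, 2 pools, %d replicates)\n",
              nrow(x$counts), ncol(x$counts), length(x$config$cell_lines),
              length(x$config$treatments), x$config$replicates))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulated experiment to tab-separated files
#'
#' Writes `counts.tsv`, `design.tsv` and `truth.tsv` under `dir`; the first
#' two round-trip through [read_counts()] and [read_design()].
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_sim_experiment <- function(sim, dir) {
  if (!inherits(sim, "sim_experiment")) stopf("'sim' is not a sim_experiment")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.tsv", "design.tsv", "truth.tsv"))
  write_counts(sim$counts, paths[1L])
  write_design(sim$design, paths[2L])
  utils::write.table(sim$truth, paths[3L], sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(paths)
}
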
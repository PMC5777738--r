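# Whole-pipeline orchestration: filter -> TMM -> per-contrast DE ->
# polysome-significance gate -> Te -> z -> translational calls -> four-way
# classes -> set intersections -> enrichment -> PCA, from a single validated
# configuration, with a hash manifest for end-to-end reproducibility.

#' Build and validate a pipeline configuration
#'
#' Accepts either explicit arguments or `yaml = "config.yml"` holding the
#' same keys. Every referenced path must exist at validation time; numeric
#' parameters are range-checked before any computation runs.
#'
#' @param counts path to a count matrix (tab-separated).
#' @param design path to a sample sheet.
#' @param outdir output directory.
#' @param gmt optional GMT gene-set file; enrichment is skipped when absent.
#' @param control control treatment label (default `"N"`).
#' @param fdr_thresholds either one value in (0, 1] for every cell line or a
#'   named vector/list per cell line, e.g. `c(MCF10A = 0.05, MDAMB231 =
#'   0.10)` following the convention of a stricter cut for the non-tumoural
#'   line.
#' @param min_cpm,min_samples expression-filter parameters
#'   ([filter_low_expression()]).
#' @param trim_m,trim_a TMM trim fractions ([tmm_factors()]).
#' @param prior_count fold-change prior ([test_contrast()]).
#' @param te_mode `"ratio"` or `"difference"` ([compute_te()]).
#' @param z_threshold translational z threshold (default 1.5).
#' @param enrich_p,enrich_fdr enrichment thresholds ([overrepresentation()]).
#' @param pca_scale scale genes to unit variance in PCA (default off).
#' @param seed global seed (the pipeline itself is deterministic; the seed
#'   is recorded and set for forward compatibility).
#' @param yaml optional path to a YAML file supplying any of the above.
#' @return a validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, outdir = NULL,
                            gmt = NULL, control = "N",
                            fdr_thresholds = 0.05, min_cpm = 1.0,
                            min_samples = NULL, trim_m = 0.30,
                            trim_a = 0.05, prior_count = 0.5,
                            te_mode = c("ratio", "difference"),
                            z_threshold = 1.5, enrich_p = 0.03,
                            enrich_fdr = 0.05, pca_scale = FALSE,
                            seed = 1L, yaml = NULL) {
  te_mode <- match.arg(te_mode)
  cfg <- list(counts = counts, design = design, outdir = outdir, gmt = gmt,
              control = control, fdr_thresholds = fdr_thresholds,
              min_cpm = min_cpm, min_samples = min_samples, trim_m = trim_m,
              trim_a = trim_a, prior_count = prior_count, te_mode = te_mode,
              z_threshold = z_threshold, enrich_p = enrich_p,
              enrich_fdr = enrich_fdr, pca_scale = pca_scale, seed = seed)
  if (!is.null(yaml)) {
    if (!file.exists(yaml)) stopf("config file not found: %s", yaml)
    over <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stopf("unknown config key(s): %s",
                               paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  for (p in c("counts", "design")) {
    if (is.null(cfg[[p]])) stopf("config is missing required path '%s'", p)
    if (!file.exists(cfg[[p]])) stopf("'%s' path does not exist: %s", p,
                                      cfg[[p]])
  }
  if (is.null(cfg$outdir)) stopf("config is missing required path 'outdir'")
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
    stopf("'gmt' path does not exist: %s", cfg$gmt)
  thr <- unlist(cfg$fdr_thresholds)
  if (any(thr <= 0 | thr > 1))
    stopf("FDR threshold(s) must be in (0, 1]; got %s",
          paste(thr[thr <= 0 | thr > 1], collapse = ", "))
  check_number(cfg$z_threshold, "z_threshold", min = 0, strict_min = TRUE)
  check_number(cfg$min_cpm, "min_cpm", min = 0)
  check_number(cfg$enrich_p, "enrich_p", min = 0, strict_min = TRUE)
  check_number(cfg$enrich_fdr, "enrich_fdr", min = 0, strict_min = TRUE)
  cfg$seed <- check_count(cfg$seed, "seed", min = -.Machine$integer.max)
  structure(cfg, class = "pipeline_config")
}

.fdr_for <- function(cfg, cell_line) {
  thr <- unlist(cfg$fdr_thresholds)
  if (length(thr) == 1L && is.null(names(thr))) return(thr)
  if (!is.null(names(thr)) && cell_line %in% names(thr))
    return(thr[[cell_line]])
  if (length(thr) == 1L) return(thr[[1L]])
  stopf("no FDR threshold configured for cell line '%s'", cell_line)
}

#' Run the full translatome pipeline
#'
#' Executes every stage in order, writes all result tables under
#' `config$outdir`, and finishes with `manifest.json`: the fully resolved
#' configuration plus an MD5 content hash per output file. Identical inputs
#' and configuration produce a byte-identical manifest (timestamps go only
#' to `run.log`, which is not hashed). Any stage failure aborts with the
#' stage name.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("'config' must come from pipeline_config()")
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  cat(sprintf("[%s] pipeline start\n", format(Sys.time())), file = logfile)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    cat(sprintf("[%s] %-12s %.2fs\n", format(Sys.time()), name,
                as.numeric(difftime(Sys.time(), st, units = "secs"))),
        file = logfile, append = TRUE)
    res
  }
  set.seed(config$seed)
  outputs <- character(0)
  emit <- function(rel, writer) {
    path <- file.path(outdir, rel)
    dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
    writer(path)
    outputs <<- c(outputs, rel)
    path
  }
  write_tsv <- function(df) function(path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")

  counts <- stage("read", {
    cts <- read_counts(config$counts)
    des <- read_design(config$design)
    list(counts = cts, design = match_design(cts, des))
  })
  design <- counts$design; counts <- counts$counts

  filtered <- stage("filter", filter_low_expression(counts, design,
                                                    min_cpm = config$min_cpm,
                                                    min_samples =
                                                      config$min_samples))
  emit("filtered_counts.tsv", function(p) write_counts(filtered, p))

  factors <- stage("normalize", tmm_factors(filtered, trim_m = config$trim_m,
                                            trim_a = config$trim_a))
  emit("norm_factors.tsv", write_tsv(data.frame(
    sample_id = names(factors$factors), factor = factors$factors,
    lib_size = factors$lib_sizes[names(factors$factors)],
    reference = factors$reference, row.names = NULL)))

  logcpm <- cpm(filtered, factors, prior = 0.5, log_scale = TRUE)
  dispersions <- stage("dispersion",
                       estimate_dispersions(filtered, design, factors))
  emit("dispersions.tsv", write_tsv(data.frame(
    gene_id = names(dispersions$per_gene),
    dispersion = dispersions$per_gene, common = dispersions$common,
    row.names = NULL)))

  cell_lines <- unique(design$cell_line)
  treatments <- setdiff(unique(design$treatment), config$control)
  de <- stage("de", {
    res <- list()
    for (cl in cell_lines) for (pool in c("T", "P")) for (trt in treatments) {
      d <- test_contrast(filtered, design, factors, dispersions, cl, pool,
                         trt, control = config$control,
                         prior_count = config$prior_count)
      res[[paste(cl, pool, trt, sep = "_")]] <- d
      emit(sprintf("de/%s_%s_%s.tsv", cl, pool, trt), write_tsv(d))
    }
    res
  })

  te_tables <- stage("te", {
    res <- list()
    for (cl in cell_lines) for (trt in treatments) {
      de_p <- de[[paste(cl, "P", trt, sep = "_")]]
      de_t <- de[[paste(cl, "T", trt, sep = "_")]]
      thr <- .fdr_for(config, cl)
      selected <- select_polysome_significant(de_p, thr)
      key <- paste(cl, trt, sep = "_")
      if (length(selected) >= 2L) {
        te <- compute_te(de_p, de_t, selected, mode = config$te_mode)
        if (sum(is.na(te$call) | te$call != "excluded") >= 2L) {
          te <- zscore_te(te)
          te <- classify_translational(te, config$z_threshold)
        }
        res[[key]] <- te
        emit(sprintf("te/%s.tsv", key), write_tsv(te))
      } else {
        res[[key]] <- NULL
        cat(sprintf("[%s] te: %s has %d selected gene(s); skipped\n",
                    format(Sys.time()), key, length(selected)),
            file = logfile, append = TRUE)
      }
    }
    res
  })

  classes <- stage("classify", {
    res <- list()
    for (cl in cell_lines) for (trt in treatments) {
      key <- paste(cl, trt, sep = "_")
      te <- te_tables[[key]]
      if (is.null(te))
        te <- structure(data.frame(gene_id = character(0), z = numeric(0)),
                        class = c("te_table", "data.frame"))
      cw <- classify_four_way(de[[paste(cl, "T", trt, sep = "_")]],
                              de[[paste(cl, "P", trt, sep = "_")]],
                              te, .fdr_for(config, cl), config$z_threshold)
      res[[key]] <- cw
      emit(sprintf("classes/%s.tsv", key), write_tsv(cw))
    }
    res
  })

  stage("intersect", {
    if (length(cell_lines) >= 2L && length(cell_lines) <= 4L) {
      for (trt in treatments) for (dir in c("up", "down")) {
        sets <- lapply(cell_lines, function(cl) {
          d <- de[[paste(cl, "T", trt, sep = "_")]]
          thr <- .fdr_for(config, cl)
          if (dir == "up") d$gene_id[d$fdr < thr & d$log2FC > 0]
          else d$gene_id[d$fdr < thr & d$log2FC < 0]
        })
        names(sets) <- cell_lines
        if (sum(lengths(sets) > 0) >= 1L) {
          v <- intersect_sets(sets)
          emit(sprintf("venn/%s_transcriptional_%s.txt", trt, dir),
               function(p) write_venn(v, p))
        }
      }
    }
    if (length(treatments) >= 2L && length(treatments) <= 4L) {
      for (cl in cell_lines) {
        sets <- lapply(treatments, function(trt) {
          te <- te_tables[[paste(cl, trt, sep = "_")]]
          if (is.null(te) || !"call" %in% names(te)) character(0)
          else te$gene_id[!is.na(te$call) & te$call == "activated"]
        })
        names(sets) <- treatments
        v <- intersect_sets(sets)
        emit(sprintf("venn/%s_te_activated.txt", cl),
             function(p) write_venn(v, p))
      }
    }
    NULL
  })

  if (!is.null(config$gmt)) stage("enrich", {
    sets <- read_gmt(config$gmt)
    universe <- rownames(filtered)
    for (cl in cell_lines) for (trt in treatments) {
      key <- paste(cl, trt, sep = "_")
      queries <- list(
        transcriptional_up = {
          d <- de[[paste(cl, "T", trt, sep = "_")]]
          d$gene_id[d$fdr < .fdr_for(config, cl) & d$log2FC > 0]
        },
        te_activated = {
          te <- te_tables[[key]]
          if (is.null(te) || !"call" %in% names(te)) character(0)
          else te$gene_id[!is.na(te$call) & te$call == "activated"]
        })
      for (qn in names(queries)) {
        q <- intersect(queries[[qn]], universe)
        if (length(q) == 0L) next
        tab <- suppressMessages(
          overrepresentation(q, universe, sets,
                             p_threshold = config$enrich_p,
                             fdr_threshold = config$enrich_fdr))
        emit(sprintf("enrich/%s_%s.tsv", key, qn), write_tsv(tab))
      }
    }
    NULL
  })

  stage("pca", {
    fit <- pca_samples(logcpm, scale. = config$pca_scale,
                       k = min(10L, ncol(logcpm) - 1L))
    emit("pca/coordinates.tsv", write_tsv(data.frame(
      sample_id = rownames(fit$coordinates), fit$coordinates,
      check.names = FALSE, row.names = NULL)))
    emit("pca/variance.tsv", write_tsv(data.frame(
      component = paste0("PC", seq_along(fit$variance_fraction)),
      variance_fraction = fit$variance_fraction, row.names = NULL)))
    for (cl in cell_lines) {
      ids <- design$sample_id[design$cell_line == cl]
      if (length(ids) < 3L) next
      sub <- pca_samples(logcpm, scale. = config$pca_scale,
                         k = min(5L, length(ids) - 1L), samples = ids)
      emit(sprintf("pca/coordinates_%s.tsv", cl), write_tsv(data.frame(
        sample_id = rownames(sub$coordinates), sub$coordinates,
        check.names = FALSE, row.names = NULL)))
    }
    NULL
  })

  manifest <- stage("manifest", {
    outputs <- sort(outputs)
    hashes <- as.character(tools::md5sum(file.path(outdir, outputs)))
    cfg_echo <- unclass(config)
    cfg_echo$min_samples <- if (is.null(cfg_echo$min_samples)) "auto" else
      cfg_echo$min_samples
    cfg_echo$gmt <- if (is.null(cfg_echo$gmt)) "none" else cfg_echo$gmt
    man <- list(config = cfg_echo,
                outputs = data.frame(path = outputs, md5 = hashes,
                                     stringsAsFactors = FALSE))
    jsonlite::write_json(man, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    man
  })
  cat(sprintf("[%s] pipeline done (%.2fs)\n", format(Sys.time()),
              as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      file = logfile, append = TRUE)
  invisible(manifest)
}
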
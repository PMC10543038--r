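#' Pipeline configuration
#'
#' Exactly one of `input_paths` (a list with `vcf`, `sample_sheet`,
#' `annotations`, and optionally `reference_vcf` + `reference_labels`) or
#' `simulation` (a [simulation_config()]) must be supplied. All stage
#' thresholds live here so no analysis constant is hard-coded in the
#' pipeline.
#'
#' @param input_paths Named list of input file paths, or `NULL`.
#' @param simulation A [simulation_config()], or `NULL`.
#' @param thresholds A [qc_thresholds()].
#' @param k_use MDS components for ancestry assignment.
#' @param n_components MDS components as association covariates.
#' @param p_report Association reporting threshold.
#' @param route Rare-variant qualification route.
#' @param trap_min TRaP threshold for splice variants.
#' @param cadd_revel_mode `"or"` or `"and"` for the seqr route.
#' @param symptom_map Rating rescale table (length 5).
#' @param burden_method Burden p-value method.
#' @param weights_beta Burden weight parameters (`NULL` = flat).
#' @param ref_n_per_pop Synthetic reference-panel size per population.
#' @param seed Seed for any stochastic stage (defaults to the simulation
#'   seed when simulating).
#' @param output_dir Optional directory; when set, [run_pipeline()]
#'   writes every result table there as TSV.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, simulation = NULL,
                            thresholds = qc_thresholds(),
                            k_use = 3L, n_components = 2L, p_report = 0.01,
                            route = "seqr", trap_min = 0.1,
                            cadd_revel_mode = "or",
                            symptom_map = c(0, 4, 6, 8, 10),
                            burden_method = "liu",
                            weights_beta = c(1, 25),
                            ref_n_per_pop = 40L,
                            seed = NULL, output_dir = NULL) {
  if (is.null(input_paths) == is.null(simulation))
    stop("exactly one of input_paths and simulation must be supplied")
  if (is.null(seed)) seed <- if (!is.null(simulation)) simulation$seed else 1L
  structure(as.list(environment()), class = "pipeline_config")
}

.write_stage_tsv <- function(x, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  flat <- x
  for (col in names(flat))
    if (is.list(flat[[col]]))
      flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ";")
  utils::write.table(flat, file.path(dir, paste0(name, ".tsv")), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}

#' Run the full candidate-gene analysis pipeline
#'
#' Stage order: acquire data (simulate or read), common-stage QC,
#' identity-by-state MDS ancestry, overall + per-subtype association,
#' rare-stage QC and qualification, monogenic and oligogenic screening,
#' and the per-gene burden test. Identical config and seed give an
#' identical bundle. A stage failure halts with the stage name and
#' cause.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_bundle` with one element per stage
#'   plus a `decision_log` of every configurable choice used.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  bundle <- list()

  data <- run_stage("input", {
    if (!is.null(config$simulation)) {
      cohort <- simulate_cohort(config$simulation)
      ref <- simulate_reference_panel(cohort, config$ref_n_per_pop)
      list(samples = cohort$samples, gm = cohort$matrix,
           annotations = cohort$annotations, ledger = cohort$ledger,
           ref_gm = ref$matrix, ref_labels = ref$labels)
    } else {
      p <- config$input_paths
      gm <- read_vcf(p$vcf)
      list(samples = read_sample_sheet(p$sample_sheet), gm = gm,
           annotations = read_annotations(p$annotations,
                                          gm$variants$variant_id),
           ledger = NULL,
           ref_gm = if (!is.null(p$reference_vcf)) read_vcf(p$reference_vcf),
           ref_labels = if (!is.null(p$reference_labels))
             tibble::as_tibble(.read_tsv(p$reference_labels)))
    }
  })
  bundle$samples <- data$samples
  bundle$summary <- run_stage("cohort_summary", cohort_summary(data$samples))

  qc <- run_stage("qc_common",
                  apply_qc(data$gm, config$thresholds, stage = "common"))
  bundle$qc_log <- qc$log
  bundle$common_matrix <- qc$matrix

  bundle$ancestry <- run_stage("ancestry", {
    if (is.null(data$ref_gm) || is.null(data$ref_labels)) NULL
    else run_ancestry(qc$matrix, data$samples, data$ref_gm,
                      data$ref_labels, k_use = config$k_use)
  })

  covariates <- run_stage("covariates",
                          encode_covariates(data$samples, bundle$ancestry))
  bundle$association <- run_stage("association",
    run_association_scan(qc$matrix, data$samples, covariates,
                         p_report = config$p_report,
                         n_components = config$n_components))
  bundle$subtype_association <- run_stage("subtype_association", {
    subs <- intersect(c("IBS-C", "IBS-D", "IBS-M", "IBS-U"),
                      unique(data$samples$subtype))
    purrr::map_dfr(subs, function(st)
      subtype_scan(qc$matrix, data$samples, st, covariates,
                   p_report = config$p_report,
                   n_components = config$n_components))
  })

  rare <- run_stage("qc_rare",
                    apply_qc(data$gm, config$thresholds, stage = "rare",
                             annotations = data$annotations))
  bundle$rare_log <- rare$log
  qual <- run_stage("qualification",
    qualify_rare_variant(data$annotations, route = config$route,
                         trap_min = config$trap_min,
                         cadd_revel_mode = config$cadd_revel_mode))
  bundle$qualification <- qual
  qual_ids <- qual$variant_id[qual$qualifies]

  bundle$monogenic <- run_stage("monogenic", {
    genes <- sort(unique(stats::na.omit(rare$matrix$variants$gene)))
    purrr::map_dfr(genes, function(g)
      detect_monogenic(rare$matrix, data$samples, qual_ids, g))
  })
  bundle$oligogenic <- run_stage("oligogenic",
    detect_oligogenic(rare$matrix, data$samples, qual_ids))
  bundle$carriers <- run_stage("carriers",
    summarize_carriers(dplyr::bind_rows(bundle$monogenic,
                                        bundle$oligogenic[!bundle$oligogenic$is_control, ]),
                       data$samples, data$annotations,
                       map = config$symptom_map))

  bundle$burden <- run_stage("burden",
    run_burden(data$gm, data$samples, data$annotations,
               covariates = covariates, method = config$burden_method,
               weights_beta = config$weights_beta, route = config$route))

  bundle$ledger <- data$ledger
  bundle$decision_log <- tibble::tibble(
    option = c("hwe_p_min", "maf_min", "call_rate_min", "ld_r2_max",
               "ld_window", "ld_step", "allelic_ratio_min", "k_use",
               "n_components", "p_report", "route", "trap_min",
               "cadd_revel_mode", "symptom_map", "burden_method",
               "weights_beta", "seed"),
    value = c(config$thresholds$hwe_p_min, config$thresholds$maf_min,
              config$thresholds$call_rate_min, config$thresholds$ld_r2_max,
              config$thresholds$ld_window, config$thresholds$ld_step,
              config$thresholds$allelic_ratio_min, config$k_use,
              config$n_components, config$p_report, config$route,
              config$trap_min, config$cadd_revel_mode,
              paste(config$symptom_map, collapse = ","),
              config$burden_method,
              paste(config$weights_beta, collapse = ","), config$seed))
  class(bundle) <- "pipeline_bundle"

  if (!is.null(config$output_dir)) {
    for (nm in c("summary", "qc_log", "association", "subtype_association",
                 "rare_log", "qualification", "monogenic", "oligogenic",
                 "carriers", "burden", "decision_log")) {
      if (!is.null(bundle[[nm]]) && is.data.frame(bundle[[nm]]))
        .write_stage_tsv(bundle[[nm]], config$output_dir, nm)
    }
    if (!is.null(bundle$ancestry))
      .write_stage_tsv(bundle$ancestry$components, config$output_dir,
                       "mds_components")
  }
  bundle
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat("<pipeline_bundle>\n")
  for (nm in names(x))
    if (is.data.frame(x[[nm]]))
      cat(sprintf("  %-20s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' @method glance pipeline_bundle
#' @export
glance.pipeline_bundle <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_common_variants = ncol(x$common_matrix$dosage),
    n_flagged = sum(x$association$flagged, na.rm = TRUE),
    n_monogenic = nrow(x$monogenic),
    n_oligogenic = nrow(x$oligogenic),
    min_burden_p = suppressWarnings(min(x$burden$p, na.rm = TRUE)),
    ancestry_concordance = if (is.null(x$ancestry)) NA_real_
                           else x$ancestry$concordance
  )
}

.fmt_table <- function(df, max_rows = 25L) {
  if (is.null(df) || !is.data.frame(df) || nrow(df) == 0L)
    return("  (no rows)")
  flat <- df
  for (col in names(flat)) {
    if (is.list(flat[[col]]))
      flat[[col]] <- vapply(flat[[col]], paste, "", collapse = ";")
    if (is.numeric(flat[[col]])) flat[[col]] <- signif(flat[[col]], 4)
  }
  shown <- utils::head(flat, max_rows)
  out <- utils::capture.output(print(as.data.frame(shown), row.names = FALSE))
  if (nrow(flat) > max_rows)
    out <- c(out, sprintf("  ... %d more rows", nrow(flat) - max_rows))
  paste0("  ", out)
}

#' Render a human-readable analysis report
#'
#' Plain-text report with the demographic summary, flagged associations
#' (with genotype-count tables), candidate inheritance tables, the
#' burden table, and the full decision log. Missing stages are noted
#' rather than failing.
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @param path Optional file to write the report to.
#' @return Character vector of report lines, invisibly when `path` is
#'   given.
#' @export
generate_report <- function(bundle, path = NULL) {
  sec <- function(title, body) c(paste0("== ", title, " =="), body, "")
  missing_note <- function(nm) sprintf("  stage '%s' missing from bundle", nm)
  lines <- c("Candidate-gene panel analysis report",
             strrep("=", 40), "")
  lines <- c(lines, sec("Cohort demographics",
                        if (is.null(bundle$summary)) missing_note("summary")
                        else .fmt_table(bundle$summary, 40L)))
  assoc_body <- if (is.null(bundle$association)) missing_note("association")
  else {
    flagged <- dplyr::filter(tibble::as_tibble(bundle$association),
                             .data$flagged %in% TRUE)
    if (nrow(flagged) == 0L) "  no variants below the reporting threshold"
    else .fmt_table(dplyr::select(flagged, "variant_id", "model", "n_cases",
                                  "n_controls", "aOR", "ci_low", "ci_high",
                                  "p"))
  }
  lines <- c(lines, sec("Common-variant associations (flagged)", assoc_body))
  lines <- c(lines, sec("Subtype associations (flagged)",
                        if (is.null(bundle$subtype_association))
                          missing_note("subtype_association")
                        else {
                          fl <- dplyr::filter(bundle$subtype_association,
                                              .data$flagged %in% TRUE)
                          if (nrow(fl) == 0L) "  none flagged"
                          else .fmt_table(dplyr::select(fl, "variant_id",
                                                        "model", "aOR", "p"))
                        }))
  lines <- c(lines, sec("Candidate inheritance events",
                        if (is.null(bundle$carriers)) missing_note("carriers")
                        else .fmt_table(bundle$carriers, 40L)))
  lines <- c(lines, sec("Rare-variant burden",
                        if (is.null(bundle$burden)) missing_note("burden")
                        else .fmt_table(bundle$burden, 30L)))
  lines <- c(lines, sec("Decision log",
                        if (is.null(bundle$decision_log))
                          missing_note("decision_log")
                        else .fmt_table(bundle$decision_log, 30L)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
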
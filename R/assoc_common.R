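# Internal logistic fit: IRLS via stats::glm.fit with Wald inference on
# the last column of X (the dosage term).
.logit_fit <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 50L))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, length(beta)) else sqrt(diag(cov))
  j <- length(beta)
  separated <- is.na(se[j]) || !fit$converged ||
    abs(beta[j]) > 10 || se[j] > 20
  list(beta = unname(beta[j]), se = unname(se[j]), converged = !separated)
}

#' Additive logistic association fit for one variant
#'
#' Maximum-likelihood logistic regression of case status on the
#' minor-allele dosage plus covariates, fitted by iteratively reweighted
#' least squares. Reports the per-allele log-odds, Wald 95% CI
#' `exp(beta +/- 1.96 SE)`, and a convergence flag; complete or
#' quasi-complete separation yields `converged = FALSE` rather than a
#' silently unstable estimate.
#'
#' @param dosage Minor-allele dosage vector (0/1/2, `NA` dropped).
#' @param phenotype 0/1 vector (1 = case), same length.
#' @param covariates Optional numeric matrix/data frame of covariates
#'   (rows aligned with `dosage`).
#' @param variant_id,model Labels carried into the result row.
#' @return One-row tibble: `variant_id`, `model`, `n_cases`,
#'   `n_controls`, `beta`, `se`, `aOR`, `ci_low`, `ci_high`, `p`,
#'   `covariates`, `converged`.
#' @export
fit_additive_logistic <- function(dosage, phenotype, covariates = NULL,
                                  variant_id = NA_character_,
                                  model = "overall") {
  stopifnot(length(dosage) == length(phenotype))
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  ok <- !is.na(dosage) & !is.na(phenotype)
  if (!is.null(cov_m)) ok <- ok & stats::complete.cases(cov_m)
  d <- dosage[ok]; y <- phenotype[ok]
  if (sum(y == 1) < 1L || sum(y == 0) < 1L)
    stop("need at least one case and one control")
  X <- cbind(`(Intercept)` = 1, if (!is.null(cov_m)) cov_m[ok, , drop = FALSE],
             dosage = d)
  f <- .logit_fit(X, y)
  z <- f$beta / f$se
  tibble::tibble(
    variant_id = variant_id, model = model,
    n_cases = sum(y == 1), n_controls = sum(y == 0),
    beta = f$beta, se = f$se, aOR = exp(f$beta),
    ci_low = exp(f$beta - 1.96 * f$se), ci_high = exp(f$beta + 1.96 * f$se),
    p = 2 * stats::pnorm(-abs(z)),
    covariates = paste(colnames(cov_m) %||% character(), collapse = ","),
    converged = f$converged
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recode dosages so they count the cohort-pooled minor allele.
.minor_code <- function(dosage) {
  f <- mean(dosage, na.rm = TRUE) / 2
  if (!is.na(f) && f > 0.5) 2L - dosage else dosage
}

#' Per-variant association scan
#'
#' Fits every variant with the additive logistic model (dosage coded as
#' the cohort-pooled minor allele), orders results by p-value, flags the
#' subset with `p < p_report`, and re-fits the flagged variants with the
#' extended covariate set (up to six MDS components) as a sensitivity
#' analysis when those columns are available.
#'
#' @param gm `genotype_matrix` of QC-passed common variants.
#' @param samples Sample tibble (`status` defines the phenotype).
#' @param covariates Tibble with `sample_id` plus numeric covariate
#'   columns (typically `sex` and `C1`, `C2`; `C3`-`C6` enable the
#'   sensitivity refit).
#' @param p_report Reporting threshold (default 0.01).
#' @param n_components Number of MDS components in the primary model
#'   (default 2).
#' @return Tibble of association rows (class `ibs_assoc_scan`), flagged
#'   rows first; sensitivity refits carry model `"overall_6mds"`.
#' @export
run_association_scan <- function(gm, samples, covariates = NULL,
                                 p_report = 0.01, n_components = 2L) {
  if (ncol(gm$dosage) == 0L) {
    return(structure(tibble::tibble(), class = c("ibs_assoc_scan", "tbl_df",
                                                 "tbl", "data.frame")))
  }
  y <- as.integer(samples$status[match(rownames(gm$dosage), samples$sample_id)] == "case")
  cov_m <- .covariate_matrix(covariates, rownames(gm$dosage),
                             n_components = n_components)
  res <- purrr::map_dfr(seq_len(ncol(gm$dosage)), function(j) {
    d <- .minor_code(gm$dosage[, j])
    if (all(is.na(d)) || stats::var(d, na.rm = TRUE) == 0) return(NULL)
    fit_additive_logistic(d, y, cov_m, gm$variants$variant_id[j], "overall")
  })
  if (nrow(res) == 0L)
    return(structure(res, class = c("ibs_assoc_scan", class(res))))
  res <- dplyr::arrange(res, .data$p)
  res$flagged <- res$p < p_report
  extra <- .covariate_matrix(covariates, rownames(gm$dosage), n_components = 6L)
  if (!is.null(extra) && !identical(colnames(extra), colnames(cov_m)) &&
      any(res$flagged)) {
    sens <- purrr::map_dfr(res$variant_id[res$flagged], function(v) {
      j <- match(v, gm$variants$variant_id)
      fit_additive_logistic(.minor_code(gm$dosage[, j]), y, extra, v,
                            "overall_6mds")
    })
    sens$flagged <- NA
    res <- dplyr::bind_rows(res, sens)
  }
  structure(res, class = c("ibs_assoc_scan", class(res)))
}

# Align a covariate tibble (sample_id + numeric columns) to sample order,
# keeping sex plus the first n_components MDS columns present.
.covariate_matrix <- function(covariates, sample_ids, n_components = 2L) {
  if (is.null(covariates)) return(NULL)
  m <- covariates[match(sample_ids, covariates$sample_id), , drop = FALSE]
  comp_cols <- grep("^C[0-9]+$", names(m), value = TRUE)
  comp_cols <- comp_cols[order(as.integer(sub("C", "", comp_cols)))]
  comp_cols <- utils::head(comp_cols, n_components)
  keep <- c(intersect("sex", names(m)), comp_cols)
  if (length(keep) == 0L) return(NULL)
  as.matrix(m[, keep, drop = FALSE])
}

#' Encode sample covariates for association models
#'
#' Sex is encoded 0/1 with female = 1; samples with unknown sex get `NA`
#' and are dropped from fits. MDS components are joined when an
#' `ancestry_result` is supplied.
#'
#' @param samples Sample tibble.
#' @param ancestry Optional `ancestry_result` from [run_ancestry()].
#' @return Tibble `sample_id`, `sex`, and `C1..Ck` when available.
#' @export
encode_covariates <- function(samples, ancestry = NULL) {
  out <- tibble::tibble(
    sample_id = samples$sample_id,
    sex = dplyr::case_when(samples$sex == "female" ~ 1,
                           samples$sex == "male" ~ 0,
                           TRUE ~ NA_real_)
  )
  if (!is.null(ancestry)) {
    comp <- ancestry$components |>
      dplyr::filter(.data$role == "cohort") |>
      dplyr::select("sample_id", dplyr::matches("^C[0-9]+$"))
    out <- dplyr::left_join(out, comp, by = "sample_id")
  }
  out
}

#' Subtype-stratified association scan
#'
#' Cases are restricted to one IBS subtype; all controls are retained and
#' cases of other subtypes are excluded. Variants monomorphic within the
#' stratum are skipped with a log entry (attribute `skipped`).
#'
#' @param gm `genotype_matrix` of QC-passed common variants.
#' @param samples Sample tibble.
#' @param subtype One of `"IBS-C"`, `"IBS-D"`, `"IBS-M"`, `"IBS-U"`.
#' @inheritParams run_association_scan
#' @return Tibble of association rows with `model = subtype`.
#' @export
subtype_scan <- function(gm, samples, subtype, covariates = NULL,
                         p_report = 0.01, n_components = 2L) {
  stopifnot(subtype %in% c("IBS-C", "IBS-D", "IBS-M", "IBS-U"))
  keep <- samples$status == "control" |
    (samples$status == "case" & samples$subtype == subtype)
  if (sum(samples$status == "case" & samples$subtype == subtype) == 0L)
    stop("no cases of subtype ", subtype)
  sub_samples <- samples[keep, , drop = FALSE]
  gm2 <- gm_subset(gm, samples = intersect(rownames(gm$dosage),
                                           sub_samples$sample_id))
  y <- as.integer(sub_samples$status[match(rownames(gm2$dosage),
                                           sub_samples$sample_id)] == "case")
  cov_m <- .covariate_matrix(covariates, rownames(gm2$dosage),
                             n_components = n_components)
  skipped <- character()
  res <- purrr::map_dfr(seq_len(ncol(gm2$dosage)), function(j) {
    d <- .minor_code(gm2$dosage[, j])
    if (all(is.na(d)) || stats::var(d, na.rm = TRUE) == 0) {
      skipped <<- c(skipped, gm2$variants$variant_id[j])
      return(NULL)
    }
    fit_additive_logistic(d, y, cov_m, gm2$variants$variant_id[j], subtype)
  })
  if (nrow(res)) {
    res <- dplyr::arrange(res, .data$p)
    res$flagged <- res$p < p_report
  }
  attr(res, "skipped") <- skipped
  res
}

#' Genotype-class count table for one variant
#'
#' Counts of homozygous-major, heterozygous and homozygous-minor calls
#' (labelled with the actual alleles) per group, net of missing calls.
#'
#' @param gm `genotype_matrix`.
#' @param samples Sample tibble.
#' @param variant_id Variant to tabulate.
#' @param grouping Sample column to group by (default `"status"`).
#' @return Tibble `variant_id`, `genotype`, one count column per group.
#' @export
genotype_count_table <- function(gm, samples, variant_id,
                                 grouping = "status") {
  j <- match(variant_id, gm$variants$variant_id)
  if (is.na(j)) stop("unknown variant: ", variant_id)
  ref <- gm$variants$ref[j]; alt <- gm$variants$alt[j]
  d <- gm$dosage[, j]
  grp <- samples[[grouping]][match(rownames(gm$dosage), samples$sample_id)]
  labels <- c(paste(ref, ref, sep = "/"), paste(ref, alt, sep = "/"),
              paste(alt, alt, sep = "/"))
  tab <- table(factor(labels[d + 1L], levels = labels),
               factor(grp), useNA = "no")
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "genotype")
  dplyr::bind_cols(tibble::tibble(variant_id = variant_id), out)
}

#' Allelic odds ratio from a 2x2 allele-count table
#'
#' Cross-product odds ratio with the Haldane-Anscombe 0.5 continuity
#' correction when any cell is zero, and the Woolf (log) 95% CI.
#'
#' @param table 2x2 numeric matrix: rows = allele (minor, major),
#'   columns = group (case, control).
#' @return A list with `or`, `ci_low`, `ci_high`.
#' @export
allelic_odds_ratio <- function(table) {
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in allele-count table")
  t2 <- if (any(table == 0)) table + 0.5 else table
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  list(or = or, ci_low = or * exp(-1.96 * se), ci_high = or * exp(1.96 * se))
}

#' Genomic inflation factor
#'
#' Lambda is the median of the observed one-degree chi-square statistics
#' (from the p-values) divided by the null median.
#'
#' @param p_values Numeric vector of p-values (at least 10).
#' @return Lambda.
#' @export
genomic_inflation <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) < 10L) stop("need at least 10 p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy ibs_assoc_scan
#' @export
tidy.ibs_assoc_scan <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::transmute(.data$variant_id, .data$model, term = "dosage",
                     estimate = .data$beta, std.error = .data$se,
                     p.value = .data$p)
}

#' @method glance ibs_assoc_scan
#' @export
glance.ibs_assoc_scan <- function(x, ...) {
  primary <- dplyr::filter(tibble::as_tibble(x), .data$model == "overall")
  tibble::tibble(
    n_variants = nrow(primary),
    n_flagged = sum(primary$flagged, na.rm = TRUE),
    lambda = if (nrow(primary) >= 10) genomic_inflation(primary$p) else NA_real_
  )
}

#' QQ plot input / figure for an association scan
#'
#' @param object An `ibs_assoc_scan`.
#' @param ... Unused.
#' @return A ggplot of observed vs expected -log10 p.
#' @method autoplot ibs_assoc_scan
#' @export
autoplot.ibs_assoc_scan <- function(object, ...) {
  primary <- dplyr::filter(tibble::as_tibble(object), .data$model == "overall")
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(nrow(primary))),
    observed = -log10(sort(primary$p))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "expected -log10(p)", y = "observed -log10(p)") +
    ggplot2::theme_minimal()
}
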
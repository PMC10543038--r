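#' Identity-by-state distance matrix
#'
#' For each pair of samples the distance is `1 - mean(shared fraction)`
#' over jointly non-missing variants, where the per-variant shared-allele
#' fraction is `1 - |d_i - d_j| / 2`. Computed with indicator-matrix
#' algebra so cohort-scale inputs stay fast.
#'
#' @param gm A `genotype_matrix` (typically after common-stage QC).
#' @return A symmetric numeric matrix with zero diagonal, sample ids as
#'   dimnames.
#' @export
ibs_distance_matrix <- function(gm) {
  d <- gm$dosage
  if (nrow(d) < 2L) stop("need at least two samples")
  A0 <- (!is.na(d) & d == 0L) * 1
  A1 <- (!is.na(d) & d == 1L) * 1
  A2 <- (!is.na(d) & d == 2L) * 1
  N <- (!is.na(d)) * 1
  shared_n <- tcrossprod(N)                     # jointly non-missing counts
  absdiff <- tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1) +
    2 * (tcrossprod(A0, A2) + tcrossprod(A2, A0))
  if (any(shared_n[upper.tri(shared_n)] == 0)) {
    idx <- which(shared_n == 0 & upper.tri(shared_n), arr.ind = TRUE)[1, ]
    stop("no jointly non-missing variants for pair ",
         rownames(d)[idx[1]], " / ", rownames(d)[idx[2]])
  }
  dist <- absdiff / (2 * shared_n)
  diag(dist) <- 0
  dimnames(dist) <- list(rownames(d), rownames(d))
  (dist + t(dist)) / 2
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, takes the top `k`
#' eigenpairs, and scales eigenvectors by root-eigenvalue. Components are
#' ordered by decreasing eigenvalue and each component's sign is fixed so
#' that its largest-magnitude loading is positive, making output
#' deterministic across platforms.
#'
#' @param dist Symmetric distance matrix.
#' @param k Number of components (must be <= n - 1).
#' @return A list with `points` (n x k matrix, columns `C1..Ck`) and
#'   `eigenvalues`.
#' @export
classical_mds <- function(dist, k = 10L) {
  n <- nrow(dist)
  if (k > n - 1L) stop("k must be at most n - 1")
  # cmdscale warns when fewer than k positive eigenvalues exist (degenerate
  # geometry); we pad those components with zeros below instead
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(dist), k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(pts) || ncol(pts) < k) {
    # degenerate geometry (e.g., all-zero distances): pad with zeros
    pad <- matrix(0, n, k - ncol(pts))
    pts <- cbind(pts, pad)
  }
  for (j in seq_len(ncol(pts))) {
    i_max <- which.max(abs(pts[, j]))
    if (length(i_max) && pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("C", seq_len(ncol(pts)))
  rownames(pts) <- rownames(dist)
  list(points = pts, eigenvalues = fit$eig[seq_len(k)])
}

#' Assign samples to the nearest superpopulation
#'
#' Distances are Euclidean, over the first `k_use` MDS components, from
#' each sample to the centroid of each reference superpopulation group.
#' Assignment is the argmin; exact ties go to the lexicographically first
#' label and are flagged.
#'
#' @param components Matrix of MDS components for the samples to assign
#'   (rows named by sample id).
#' @param reference Named list mapping superpopulation label (`AFR`,
#'   `AMR`, `EAS`, `EUR`, `SAS`) to a matrix of reference-member
#'   components on the same coordinate system.
#' @param k_use Number of leading components used (default 3).
#' @return A tibble: `sample_id`, `assigned_superpop`, `tie`, and one
#'   `dist_<POP>` column per superpopulation.
#' @export
assign_superpopulation <- function(components, reference, k_use = 3L) {
  labs <- sort(names(reference))
  if (length(labs) == 0L) stop("empty reference panel")
  for (l in labs) {
    if (is.null(reference[[l]]) || nrow(reference[[l]]) == 0L)
      stop("empty reference group: ", l)
  }
  k_use <- min(k_use, ncol(components))
  cent <- t(vapply(labs, function(l)
    colMeans(reference[[l]][, seq_len(k_use), drop = FALSE]), numeric(k_use)))
  x <- components[, seq_len(k_use), drop = FALSE]
  d2 <- outer(rowSums(x^2), rep(1, length(labs))) -
    2 * x %*% t(cent) + outer(rep(1, nrow(x)), rowSums(cent^2))
  d <- sqrt(pmax(d2, 0))
  colnames(d) <- labs
  best <- apply(d, 1L, function(r) labs[which.min(r)])
  tie <- apply(d, 1L, function(r) sum(abs(r - min(r)) < 1e-12) > 1L)
  out <- tibble::tibble(sample_id = rownames(components),
                        assigned_superpop = unname(best), tie = unname(tie))
  dd <- tibble::as_tibble(d)
  names(dd) <- paste0("dist_", labs)
  dplyr::bind_cols(out, dd)
}

# Self-reported ethnicity -> acceptable superpopulation labels
.ethnicity_superpop_map <- list(
  "Native American/Alaska Native" = "EAS",
  "Asian" = c("EAS", "SAS"),
  "Black" = "AFR",
  "Hispanic/Latino" = "AMR",
  "Native Hawaiian/Pacific Islander" = "EAS",
  "White" = "EUR"
)

#' Concordance of genetic ancestry with self-reported ethnicity
#'
#' Self-reported labels map to superpopulations (Native American/Alaska
#' Native and Native Hawaiian/Pacific Islander to EAS; Asian to EAS or
#' SAS, either counting as concordant; Black to AFR; Hispanic/Latino to
#' AMR; White to EUR). Samples reporting Multiple/Other or nothing are
#' excluded from the denominator.
#'
#' @param assignments Tibble from [assign_superpopulation()].
#' @param samples Sample tibble with `sample_id` and `ethnicity`.
#' @return Concordance as a percentage (0-100).
#' @export
ethnicity_concordance <- function(assignments, samples) {
  joined <- dplyr::inner_join(assignments, samples[, c("sample_id", "ethnicity")],
                              by = "sample_id")
  evaluable <- joined |>
    dplyr::filter(!is.na(.data$ethnicity),
                  .data$ethnicity %in% names(.ethnicity_superpop_map))
  if (nrow(evaluable) == 0L) stop("no evaluable samples for concordance")
  ok <- purrr::map2_lgl(evaluable$ethnicity, evaluable$assigned_superpop,
                        function(e, a) a %in% .ethnicity_superpop_map[[e]])
  100 * mean(ok)
}

#' Run the full ancestry stage
#'
#' Merges the cohort with a labelled reference panel, computes the IBS
#' distance matrix and classical MDS jointly (not by projection), assigns
#' every cohort sample to its nearest superpopulation centroid over the
#' first `k_use` components, and evaluates self-report concordance.
#'
#' @param gm Cohort `genotype_matrix` after common-stage QC.
#' @param samples Cohort sample tibble.
#' @param ref_gm Reference-panel `genotype_matrix` on the same variants.
#' @param ref_labels Tibble `sample_id`, `superpop` for the reference.
#' @param k Components to compute (default 10).
#' @param k_use Components used for assignment (default 3).
#' @return A list of class `ancestry_result`: `components` (tibble),
#'   `assignments`, `concordance`, `eigenvalues`.
#' @export
run_ancestry <- function(gm, samples, ref_gm, ref_labels, k = 10L, k_use = 3L) {
  shared <- intersect(gm$variants$variant_id, ref_gm$variants$variant_id)
  if (length(shared) < 2L) stop("cohort and reference share too few variants")
  gm2 <- gm_subset(gm, variants = shared)
  ref2 <- gm_subset(ref_gm, variants = shared)
  dos <- rbind(gm2$dosage, ref2$dosage)
  merged <- genotype_matrix(dos, gm2$variants)
  dist <- ibs_distance_matrix(merged)
  k <- min(k, nrow(dist) - 1L)
  mds <- classical_mds(dist, k = k)
  is_ref <- rownames(mds$points) %in% ref_labels$sample_id
  ref_pts <- mds$points[is_ref, , drop = FALSE]
  pops <- ref_labels$superpop[match(rownames(ref_pts), ref_labels$sample_id)]
  reference <- split.data.frame(ref_pts, pops)
  cohort_pts <- mds$points[!is_ref, , drop = FALSE]
  assignments <- assign_superpopulation(cohort_pts, reference, k_use = k_use)
  conc <- tryCatch(ethnicity_concordance(assignments, samples),
                   error = function(e) NA_real_)
  comp <- tibble::as_tibble(mds$points)
  comp$sample_id <- rownames(mds$points)
  comp$role <- ifelse(is_ref, "reference", "cohort")
  comp$superpop <- ifelse(is_ref, pops[match(comp$sample_id, rownames(ref_pts))],
                          assignments$assigned_superpop[match(comp$sample_id,
                                                              assignments$sample_id)])
  structure(list(components = dplyr::relocate(comp, "sample_id", "role", "superpop"),
                 assignments = assignments, concordance = conc,
                 eigenvalues = mds$eigenvalues),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat(sprintf("<ancestry_result> %d samples (%d cohort), concordance %s\n",
              nrow(x$components), sum(x$components$role == "cohort"),
              if (is.na(x$concordance)) "not evaluable"
              else sprintf("%.1f%%", x$concordance)))
  invisible(x)
}

#' Scatter plot of the first two MDS components
#'
#' @param object An `ancestry_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ancestry_result
#' @export
autoplot.ancestry_result <- function(object, ...) {
  ggplot2::ggplot(object$components,
                  ggplot2::aes(x = .data$C1, y = .data$C2,
                               colour = .data$superpop,
                               shape = .data$role)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "C1", y = "C2", colour = "superpopulation",
                  shape = NULL) +
    ggplot2::theme_minimal()
}
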
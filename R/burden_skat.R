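#' Logistic null model for the burden test
#'
#' Fits case status on covariates only (genotypes excluded) and returns
#' the pieces the variance-component score test needs.
#'
#' @param phenotype 0/1 vector (1 = case).
#' @param covariates Optional numeric matrix/data frame (no intercept
#'   column; one is added).
#' @return List of class `skat_null`: `X`, `y`, `mu` (fitted
#'   probabilities), `residuals` (`y - mu`), `v` (`mu (1 - mu)`).
#' @export
fit_null_model <- function(phenotype, covariates = NULL) {
  y <- as.numeric(phenotype)
  if (sum(y == 1) < 1L || sum(y == 0) < 1L)
    stop("need at least one case and one control")
  X <- cbind(`(Intercept)` = rep(1, length(y)),
             if (!is.null(covariates)) as.matrix(covariates))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 50L)))
  mu <- fit$fitted.values
  structure(list(X = X, y = y, mu = mu, residuals = y - mu,
                 v = mu * (1 - mu)),
            class = "skat_null")
}

# Liu-Tang-Zhang moment-matching survival probability for a positive
# linear combination of chi-square(1) variables.
.p_liu <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- c2^3 / c3^2
  }
  mu_x <- l + delta; sigma_x <- sqrt(2) * sqrt(l + 2 * delta)
  t_star <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta,
                lower.tail = FALSE)
}

# Davies-style exact tail probability by numerical inversion of the
# characteristic function (Imhof's integral).
.p_davies <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(integrand, lower = 0, upper = Inf,
                     subdivisions = 2000L, rel.tol = 1e-9)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  min(max(0.5 + val / pi, 1e-12), 1)
}

#' SKAT-style variance-component score test
#'
#' With residuals `r = y - mu` from the null logistic fit, genotype
#' matrix `G` and diagonal weights `W`, the score statistic is
#' `Q = r' G W^2 G' r` (weighted linear kernel). Its null distribution is
#' the usual mixture of one-degree chi-squares with eigenvalues from the
#' projected weighted kernel `W G' P0 G W`,
#' `P0 = V - V X (X' V X)^{-1} X' V`; the p-value comes from Liu
#' moment-matching by default, an exact characteristic-function inversion
#' (`"davies"`), or phenotype permutation (`"permutation"`, which refits
#' the null per replicate).
#'
#' @param G Samples-by-markers dosage matrix (no missing values; impute
#'   first). At least one polymorphic column.
#' @param weights Per-marker weights (default: all 1).
#' @param null A `skat_null` from [fit_null_model()].
#' @param method `"liu"`, `"davies"` or `"permutation"`.
#' @param n_perm Permutation count for the permutation method.
#' @return One-row tibble: `Q`, `p`, `method`, `n_snvs`.
#' @export
skat_test <- function(G, weights = NULL, null, method = c("liu", "davies",
                                                          "permutation"),
                      n_perm = 1000L) {
  method <- match.arg(method)
  G <- as.matrix(G)
  poly <- apply(G, 2L, function(g) stats::var(g) > 0)
  if (!any(poly)) stop("all markers monomorphic")
  G <- G[, poly, drop = FALSE]
  w <- if (is.null(weights)) rep(1, ncol(G)) else weights[poly]
  r <- null$residuals
  s <- drop(crossprod(G, r)) * w
  Q <- sum(s^2)
  if (method == "permutation") {
    qs <- vapply(seq_len(n_perm), function(b) {
      yb <- sample(null$y)
      nb <- fit_null_model(yb, if (ncol(null$X) > 1L)
        null$X[, -1L, drop = FALSE] else NULL)
      sum((drop(crossprod(G, nb$residuals)) * w)^2)
    }, 1)
    p <- (1 + sum(qs >= Q)) / (n_perm + 1)
  } else {
    V <- null$v
    GX <- G * V                          # V G
    XtVX <- crossprod(null$X * sqrt(V))
    B <- crossprod(null$X * V, G)        # X' V G
    K <- crossprod(G * sqrt(V)) - t(B) %*% solve(XtVX, B)
    K <- (t(K) + K) / 2 * outer(w, w)
    lambda <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    lambda <- lambda[lambda > max(lambda) * 1e-10]
    p <- if (method == "liu") .p_liu(Q, lambda) else {
      pd <- .p_davies(Q, lambda)
      if (is.na(pd)) .p_liu(Q, lambda) else pd
    }
  }
  tibble::tibble(Q = Q, p = min(max(p, .Machine$double.xmin), 1),
                 method = method, n_snvs = ncol(G))
}

# Mean-impute missing dosages (to twice the cohort alternate frequency).
.impute_dosage <- function(G) {
  for (j in seq_len(ncol(G))) {
    m <- is.na(G[, j])
    if (any(m)) G[m, j] <- mean(G[!m, j])
  }
  G
}

#' Per-gene rare-variant burden tests over three marker sets
#'
#' For each gene the test runs on: `full` (all panel variants in the
#' gene), `rare` (cohort MAF <= 0.05) and `deleterious` (rare variants
#' passing [qualify_rare_variant()]). Default weights are the Beta(1, 25)
#' density of the cohort MAF, the canonical rare-variant upweighting; the
#' covariates default to those of the common-variant model.
#'
#' @param gm `genotype_matrix`.
#' @param samples Sample tibble.
#' @param annotations Annotation tibble (for qualification).
#' @param genes Genes to test (default: all genes present).
#' @param covariates Covariate tibble as in [run_association_scan()].
#' @param weights_beta Beta density parameters for MAF weights; `NULL`
#'   for flat weights.
#' @param method p-value method passed to [skat_test()].
#' @param route Qualification route for the deleterious set.
#' @return Tibble of class `ibs_burden`: `gene`, `marker_set`, `n_snvs`,
#'   `Q`, `p`, `method`.
#' @export
run_burden <- function(gm, samples, annotations = NULL, genes = NULL,
                       covariates = NULL, weights_beta = c(1, 25),
                       method = "liu", route = "seqr") {
  y <- as.integer(samples$status[match(rownames(gm$dosage),
                                       samples$sample_id)] == "case")
  cov_m <- .covariate_matrix(covariates, rownames(gm$dosage),
                             n_components = 2L)
  if (!is.null(cov_m)) {
    ok <- stats::complete.cases(cov_m)
  } else ok <- rep(TRUE, length(y))
  null <- fit_null_model(y[ok], if (is.null(cov_m)) NULL
                         else cov_m[ok, , drop = FALSE])
  if (is.null(genes))
    genes <- sort(unique(stats::na.omit(gm$variants$gene)))
  qual <- if (!is.null(annotations))
    qualify_rare_variant(annotations, route = route) else NULL
  rows <- purrr::map_dfr(genes, function(g) {
    vids_full <- gm$variants$variant_id[gm$variants$gene %in% g]
    maf <- vapply(vids_full, function(v) {
      d <- gm$dosage[ok, match(v, gm$variants$variant_id)]
      if (all(is.na(d))) NA_real_ else compute_maf(d)
    }, 1)
    sets <- list(
      full = vids_full,
      rare = vids_full[!is.na(maf) & maf <= 0.05],
      deleterious = if (is.null(qual)) character() else
        intersect(vids_full[!is.na(maf) & maf <= 0.05],
                  qual$variant_id[qual$qualifies])
    )
    purrr::imap_dfr(sets, function(vids, set_name) {
      base <- tibble::tibble(gene = g, marker_set = set_name,
                             n_snvs = length(vids), Q = NA_real_,
                             p = NA_real_, method = method)
      if (length(vids) == 0L) return(base)
      G <- .impute_dosage(gm$dosage[ok, match(vids, gm$variants$variant_id),
                                    drop = FALSE])
      if (!any(apply(G, 2L, function(x) stats::var(x) > 0))) {
        base$n_snvs <- ncol(G)
        return(base)
      }
      w <- if (is.null(weights_beta)) NULL else {
        mafs <- pmin(pmax(colMeans(G) / 2, 1e-6), 1 - 1e-6)
        mafs <- pmin(mafs, 1 - mafs)
        stats::dbeta(mafs, weights_beta[1], weights_beta[2])
      }
      out <- skat_test(G, w, null, method = method)
      # n_snvs reports the marker-set cardinality (monomorphic members
      # contribute nothing to Q but belong to the set)
      tibble::tibble(gene = g, marker_set = set_name, n_snvs = length(vids),
                     Q = out$Q, p = out$p, method = out$method)
    })
  })
  structure(rows, class = c("ibs_burden", class(rows)))
}

#' @method tidy ibs_burden
#' @export
tidy.ibs_burden <- function(x, ...) tibble::as_tibble(x)

#' @method glance ibs_burden
#' @export
glance.ibs_burden <- function(x, ...) {
  tibble::tibble(n_genes = length(unique(x$gene)),
                 min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
                 any_significant = any(x$p < 0.05, na.rm = TRUE))
}
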
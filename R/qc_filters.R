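#' Quality-control thresholds
#'
#' Defaults reproduce the common candidate-gene QC cascade: exact
#' Hardy-Weinberg test at p < 1e-6, cohort minor allele frequency >= 0.01,
#' per-variant call rate > 0.95, and greedy windowed LD pruning at
#' r^2 < 0.2 in windows of 50 variants sliding by 5. The allelic-ratio
#' threshold (70:30) gates individual genotype calls in the rare-variant
#' stage.
#'
#' @param hwe_p_min Minimum HWE exact p-value to retain a variant.
#' @param maf_min Minimum cohort minor allele frequency (common stage).
#' @param call_rate_min Minimum per-variant call rate (exclusive bound).
#' @param ld_r2_max Pairwise r-squared at or above which the
#'   later-positioned variant of a pair is pruned.
#' @param ld_window Window size in number of variants.
#' @param ld_step Slide step in number of variants.
#' @param allelic_ratio_min Minimum minor-read fraction for a heterozygous
#'   call to pass the allelic-balance check.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-6, maf_min = 0.01,
                          call_rate_min = 0.95, ld_r2_max = 0.2,
                          ld_window = 50L, ld_step = 5L,
                          allelic_ratio_min = 0.30) {
  stopifnot(hwe_p_min > 0, hwe_p_min <= 1, maf_min > 0, maf_min <= 1,
            call_rate_min > 0, call_rate_min <= 1,
            ld_r2_max > 0, ld_r2_max <= 1,
            allelic_ratio_min > 0, allelic_ratio_min <= 1,
            ld_step <= ld_window)
  structure(list(hwe_p_min = hwe_p_min, maf_min = maf_min,
                 call_rate_min = call_rate_min, ld_r2_max = ld_r2_max,
                 ld_window = as.integer(ld_window), ld_step = as.integer(ld_step),
                 allelic_ratio_min = allelic_ratio_min),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test: given the observed allele counts, the
#' p-value is the sum of the probabilities of all heterozygote counts (of
#' matching parity) whose conditional probability does not exceed that of
#' the observed configuration. Probabilities are evaluated with a stable
#' recurrence over heterozygote counts; not a mid-p variant.
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts.
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) stop("all genotype counts are zero")
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  probs <- .hwe_het_distribution(n, n_rare)
  het_obs <- n_het
  # het counts share the parity of the rare allele count
  idx_obs <- (het_obs - n_rare %% 2L) / 2L + 1L
  p_obs <- probs[idx_obs]
  p <- sum(probs[probs <= p_obs * (1 + 1e-9)])
  min(1, p)
}

# Conditional distribution of the heterozygote count given n diploids and
# n_rare copies of the rarer allele, via the standard recurrence
#   P(h-2)/P(h) = h(h-1) / (4 (hom_r+1)(hom_c+1))
# evaluated from the mid-range mode outward, then normalized.
.hwe_het_distribution <- function(n, n_rare) {
  if (n_rare == 0L) return(1)
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  m <- length(hets)
  lw <- numeric(m)
  for (k in 2:max(2L, m)) {
    if (m < 2L) break
    h <- hets[k]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    # ratio P(h)/P(h-2)
    lw[k] <- lw[k - 1L] + log(4 * (hom_r + 1) * (hom_c + 1)) - log(h * (h - 1))
  }
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Cohort minor allele frequency from dosages
#'
#' @param dosages Integer vector of alternate-allele dosages (0/1/2, `NA`
#'   for missing).
#' @return `min(f, 1 - f)` of the alternate-allele frequency over
#'   non-missing calls.
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("all dosages missing")
  f <- sum(d) / (2 * length(d))
  min(f, 1 - f)
}

#' Per-variant call rate
#' @param dosages Dosage vector.
#' @return Fraction of non-missing calls.
#' @export
call_rate <- function(dosages) {
  if (length(dosages) == 0L) stop("empty dosage vector")
  mean(!is.na(dosages))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors over jointly
#' non-missing samples.
#'
#' @param dosages_a,dosages_b Dosage vectors of equal length.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (length(a) < 2L || stats::var(a) == 0 || stats::var(b) == 0)
    stop("LD undefined: a vector is constant on the joint support")
  stats::cor(a, b)^2
}

#' Greedy windowed LD pruning
#'
#' Within each window of `ld_window` position-consecutive retained
#' variants, any pair with r^2 at or above `ld_r2_max` loses its
#' later-positioned member; the window slides by `ld_step`. Sweeps are
#' repeated until no further variant is removed, so the result is a fixed
#' point: pruning the output changes nothing.
#'
#' @param gm A `genotype_matrix` with position-sorted variants.
#' @param thresholds A [qc_thresholds()] object.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(gm, thresholds = qc_thresholds()) {
  vt <- gm$variants
  keep <- vt$variant_id
  repeat {
    removed <- FALSE
    idx <- match(keep, vt$variant_id)
    n <- length(idx)
    alive <- rep(TRUE, n)
    starts <- if (n <= thresholds$ld_window) 1L else
      unique(c(seq(1L, n - thresholds$ld_window + 1L, by = thresholds$ld_step),
               n - thresholds$ld_window + 1L))
    for (s in starts) {
      win <- s:min(s + thresholds$ld_window - 1L, n)
      win <- win[alive[win]]
      if (length(win) < 2L) next
      for (ii in seq_along(win)) {
        i <- win[ii]
        if (!alive[i]) next
        for (jj in seq_along(win)) {
          if (jj <= ii) next
          j <- win[jj]
          if (!alive[j]) next
          r2 <- tryCatch(ld_r2(gm$dosage[, idx[i]], gm$dosage[, idx[j]]),
                         error = function(e) NA_real_)
          if (!is.na(r2) && r2 >= thresholds$ld_r2_max) {
            alive[j] <- FALSE  # later-positioned member removed
            removed <- TRUE
          }
        }
      }
    }
    keep <- keep[alive]
    if (!removed) break
  }
  keep
}

#' Allelic-balance check for a single genotype call
#'
#' Heterozygous calls pass when the alternate-read fraction lies within
#' \[`allelic_ratio_min`, `1 - allelic_ratio_min`\] (boundaries inclusive,
#' the 70:30 rule); homozygous calls pass when the fraction is consistent
#' with the called genotype at the same threshold.
#'
#' @param ad_ref,ad_alt Reference / alternate read counts for the call.
#' @param dosage The called dosage (0, 1 or 2).
#' @param allelic_ratio_min Minor-read fraction threshold.
#' @return `TRUE` if the call passes; zero total depth fails with a
#'   `missing_depth` attribute.
#' @export
allelic_ratio_pass <- function(ad_ref, ad_alt, dosage,
                               allelic_ratio_min = 0.30) {
  if (is.na(ad_ref) || is.na(ad_alt) || (ad_ref + ad_alt) == 0)
    return(structure(FALSE, missing_depth = TRUE))
  fa <- ad_alt / (ad_ref + ad_alt)
  if (is.na(dosage)) return(structure(FALSE, missing_depth = TRUE))
  if (dosage == 1L) fa >= allelic_ratio_min && fa <= 1 - allelic_ratio_min
  else if (dosage == 2L) fa >= 1 - allelic_ratio_min
  else fa <= allelic_ratio_min
}

#' Apply the QC cascade
#'
#' The `common` stage removes, in order: multiallelic-origin records,
#' variants failing the HWE exact test (p < `hwe_p_min`), variants with
#' MAF below `maf_min`, variants with call rate at or below
#' `call_rate_min`, and finally LD-pruned variants. The `rare` stage masks
#' genotype calls failing the allelic-balance check (they become missing)
#' and restricts to variants with gnomAD MAF < 0.01 (cohort MAF when no
#' annotation is supplied). Every removal is logged with the first failing
#' filter.
#'
#' @param gm A `genotype_matrix`.
#' @param thresholds A [qc_thresholds()] object.
#' @param stage `"common"` or `"rare"`.
#' @param annotations Optional annotation tibble (used by the rare stage
#'   for gnomAD frequencies).
#' @return A list with elements `matrix` (the filtered `genotype_matrix`)
#'   and `log` (tibble `variant_id`, `stage`, `filter`, `value`,
#'   `threshold`).
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds(),
                     stage = c("common", "rare"), annotations = NULL) {
  stage <- match.arg(stage)
  log <- tibble::tibble(variant_id = character(), stage = character(),
                        filter = character(), value = numeric(),
                        threshold = numeric())
  note <- function(ids, filt, val, thr) {
    dplyr::bind_rows(log, tibble::tibble(
      variant_id = ids, stage = stage, filter = filt,
      value = val, threshold = thr))
  }
  if (stage == "common") {
    vt <- gm$variants
    drop <- vt$variant_id[vt$multiallelic %in% TRUE]
    log <- note(drop, "multiallelic", NA_real_, NA_real_)
    keep <- setdiff(vt$variant_id, drop)
    gm <- gm_subset(gm, variants = keep)

    hwe_p <- apply(gm$dosage, 2L, function(d) {
      d <- d[!is.na(d)]
      if (length(d) == 0L) return(NA_real_)
      hwe_exact_test(sum(d == 0L), sum(d == 1L), sum(d == 2L))
    })
    bad <- !is.na(hwe_p) & hwe_p < thresholds$hwe_p_min
    log <- note(gm$variants$variant_id[bad], "hwe", hwe_p[bad], thresholds$hwe_p_min)
    gm <- gm_subset(gm, variants = gm$variants$variant_id[!bad])

    maf <- apply(gm$dosage, 2L, function(d)
      if (all(is.na(d))) NA_real_ else compute_maf(d))
    bad <- is.na(maf) | maf < thresholds$maf_min
    log <- note(gm$variants$variant_id[bad], "maf", maf[bad], thresholds$maf_min)
    gm <- gm_subset(gm, variants = gm$variants$variant_id[!bad])

    cr <- apply(gm$dosage, 2L, call_rate)
    bad <- cr <= thresholds$call_rate_min
    log <- note(gm$variants$variant_id[bad], "call_rate", cr[bad], thresholds$call_rate_min)
    gm <- gm_subset(gm, variants = gm$variants$variant_id[!bad])

    kept <- ld_prune(gm, thresholds)
    pruned <- setdiff(gm$variants$variant_id, kept)
    log <- note(pruned, "ld_prune", NA_real_, thresholds$ld_r2_max)
    gm <- gm_subset(gm, variants = kept)
  } else {
    if (!is.null(gm$ad_ref)) {
      dos <- gm$dosage
      tot <- gm$ad_ref + gm$ad_alt
      fa <- gm$ad_alt / tot
      bad_het <- !is.na(dos) & dos == 1L & !is.na(fa) &
        (fa < thresholds$allelic_ratio_min | fa > 1 - thresholds$allelic_ratio_min)
      bad_hom2 <- !is.na(dos) & dos == 2L & !is.na(fa) & fa < 1 - thresholds$allelic_ratio_min
      bad_hom0 <- !is.na(dos) & dos == 0L & !is.na(fa) & fa > thresholds$allelic_ratio_min
      dos[bad_het | bad_hom2 | bad_hom0] <- NA_integer_
      gm$dosage <- dos
      n_masked <- colSums(bad_het | bad_hom2 | bad_hom0)
      masked <- gm$variants$variant_id[n_masked > 0]
      log <- note(masked, "allelic_ratio_mask", n_masked[n_masked > 0],
                  thresholds$allelic_ratio_min)
    }
    if (!is.null(annotations) && "gnomad_maf" %in% names(annotations)) {
      maf <- annotations$gnomad_maf[match(gm$variants$variant_id,
                                          annotations$variant_id)]
    } else {
      maf <- apply(gm$dosage, 2L, function(d)
        if (all(is.na(d))) NA_real_ else compute_maf(d))
    }
    bad <- is.na(maf) | maf >= 0.01
    log <- note(gm$variants$variant_id[bad], "gnomad_maf", maf[bad], 0.01)
    gm <- gm_subset(gm, variants = gm$variants$variant_id[!bad])
  }
  list(matrix = gm, log = log)
}
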
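#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the package's analyses target: a
#' 687-case / 439-control cohort, predominantly female, drawn from five
#' continental populations dominated by EUR, with 1,449 common variants
#' (the scale of a QC-filtered candidate-gene panel) plus per-gene rare
#' variants, Balding-Nichols population divergence, a logistic
#' disease model with optional planted per-allele odds ratios, and
#' planted biallelic / digenic carriers with shifted symptom ratings.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_cases,n_controls Cohort sizes (defaults 687 / 439).
#' @param populations Named numeric vector of superpopulation
#'   proportions (must sum to 1).
#' @param fst Balding-Nichols divergence parameter in \[0, 1).
#' @param n_common_variants Number of common variants.
#' @param ancestral_maf_range Interval for ancestral common-variant MAFs.
#' @param planted_effects Tibble `index` (into the common variants),
#'   `or` (per-allele odds ratio > 0); `NULL` for a null cohort.
#' @param sex_log_odds Additive log-odds of case status for females.
#' @param prob_female Cohort female fraction.
#' @param n_rare_per_gene Background rare variants per panel gene.
#' @param n_event_slots_per_gene Initially monomorphic rare-variant slots
#'   per gene reserved for planted inheritance events.
#' @param planted_monogenic Tibble `gene`, `n_case_carriers`,
#'   `n_control_carriers`.
#' @param planted_digenic Tibble `gene_a`, `gene_b`, `n_case_carriers`.
#' @param symptom_shift Upward shift (0-4 scale, clamped) applied to
#'   planted carriers' symptom ratings.
#' @param depth_mean Mean sequencing depth for simulated allele depths.
#' @param het_balance_sd Spread of the heterozygous allele balance around
#'   0.5.
#' @param p_damaging_call Probability that each damage/conservation
#'   annotation of a deleterious-labelled variant exceeds its threshold.
#' @param annotation_missingness Probability that an individual
#'   annotation call is missing.
#' @param simulate_depths Whether to simulate per-call allele depths.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_cases = 687L, n_controls = 439L,
                              populations = c(AFR = 0.05, AMR = 0.09,
                                              EAS = 0.02, EUR = 0.82,
                                              SAS = 0.02),
                              fst = 0.1,
                              n_common_variants = 1449L,
                              ancestral_maf_range = c(0.05, 0.5),
                              planted_effects = NULL,
                              sex_log_odds = 0.27,
                              prob_female = 0.745,
                              n_rare_per_gene = 30L,
                              n_event_slots_per_gene = 6L,
                              planted_monogenic = NULL,
                              planted_digenic = NULL,
                              symptom_shift = 2L,
                              depth_mean = 60,
                              het_balance_sd = 0.05,
                              p_damaging_call = 1,
                              annotation_missingness = 0,
                              simulate_depths = TRUE) {
  stopifnot(abs(sum(populations) - 1) < 1e-8, fst >= 0, fst < 1,
            ancestral_maf_range[1] > 0, ancestral_maf_range[2] <= 0.5)
  if (!is.null(planted_effects)) stopifnot(all(planted_effects$or > 0))
  structure(as.list(environment()), class = "simulation_config")
}

# Deterministic per-stage sub-seeds so stages can rerun in isolation.
.sub_seed <- function(seed, offset) (as.integer(seed) + offset * 10007L) %% .Machine$integer.max

# Scatter k positions per gene across the panel, sorted within gene.
.simulate_positions <- function(n_by_gene) {
  panel <- panel_genes()
  purrr::map_dfr(names(n_by_gene), function(g) {
    row <- panel[panel$gene == g, ]
    k <- n_by_gene[[g]]
    tibble::tibble(gene = g, chrom = row$chrom,
                   pos = sort(sample(seq(row$start, row$end), k)))
  })
}

#' Simulate a structured case-control cohort
#'
#' Common-variant allele frequencies follow a Balding-Nichols model:
#' population-specific frequencies are Beta-distributed around an
#' ancestral frequency with divergence `fst`, and genotypes are
#' Hardy-Weinberg within population. Case/control status comes from a
#' logistic model combining planted per-allele effects and the sex
#' effect, with cases and controls sampled to the exact configured
#' counts (retrospective design, so planted odds ratios are recoverable
#' by logistic regression). Rare background variants and reserved event
#' slots are generated per panel gene. When the config plants
#' inheritance events and annotations, those stages run too.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort`: `samples`, `variants`,
#'   `matrix` (a `genotype_matrix`), `annotations`, `ledger` (planted
#'   events), `pop_freqs` (variants x populations frequency matrix).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.sub_seed(config$seed, 1L))
  pops <- names(config$populations)
  panel <- panel_genes()

  # ---- variant table -------------------------------------------------
  n_cv <- config$n_common_variants
  common_by_gene <- table(sample(panel$gene, n_cv, replace = TRUE,
                                 prob = (panel$end - panel$start) /
                                   sum(panel$end - panel$start)))
  vt_common <- .simulate_positions(as.list(common_by_gene))
  vt_common$class <- "common"
  n_bg <- stats::setNames(rep(config$n_rare_per_gene, nrow(panel)), panel$gene)
  vt_rare <- .simulate_positions(as.list(n_bg))
  vt_rare$class <- "rare_background"
  n_ev <- stats::setNames(rep(config$n_event_slots_per_gene, nrow(panel)),
                          panel$gene)
  vt_event <- .simulate_positions(as.list(n_ev))
  vt_event$class <- "event_slot"
  vt <- dplyr::bind_rows(vt_common, vt_rare, vt_event)
  # avoid coincident positions across classes
  vt <- vt[!duplicated(vt[, c("chrom", "pos")]), ]
  bases <- c("A", "C", "G", "T")
  vt$ref <- sample(bases, nrow(vt), replace = TRUE)
  vt$alt <- vapply(vt$ref, function(r) sample(setdiff(bases, r), 1L), "")
  ord <- order(suppressWarnings(as.integer(vt$chrom)), vt$pos)
  vt <- vt[ord, ]
  vt$variant_id <- paste(vt$chrom, vt$pos, vt$ref, vt$alt, sep = ":")
  vt$multiallelic <- FALSE
  vt$consequence <- dplyr::case_when(
    vt$class == "event_slot" ~ sample(c("missense", "splice_region"),
                                      nrow(vt), TRUE, prob = c(0.8, 0.2)),
    vt$class == "rare_background" ~ sample(c("missense", "synonymous",
                                             "intronic"), nrow(vt), TRUE,
                                           prob = c(0.4, 0.3, 0.3)),
    TRUE ~ sample(c("intronic", "synonymous", "UTR", "missense"),
                  nrow(vt), TRUE, prob = c(0.6, 0.2, 0.1, 0.1))
  )
  vt$label <- ifelse(vt$class == "event_slot", "deleterious", "benign")

  # ---- allele frequencies -------------------------------------------
  m <- nrow(vt)
  anc <- numeric(m)
  is_common <- vt$class == "common"
  anc[is_common] <- stats::runif(sum(is_common),
                                 config$ancestral_maf_range[1],
                                 config$ancestral_maf_range[2])
  anc[vt$class == "rare_background"] <-
    stats::runif(sum(vt$class == "rare_background"), 5e-4, 4e-3)
  anc[vt$class == "event_slot"] <- 0    # planted carriers only
  pop_freqs <- matrix(rep(anc, length(pops)), ncol = length(pops),
                      dimnames = list(vt$variant_id, pops))
  if (config$fst > 0) {
    a <- anc[is_common] * (1 - config$fst) / config$fst
    b <- (1 - anc[is_common]) * (1 - config$fst) / config$fst
    for (p in pops)
      pop_freqs[is_common, p] <- stats::rbeta(sum(is_common), a, b)
  }

  # ---- individuals: sample to exact case/control counts --------------
  eff <- rep(0, m)
  if (!is.null(config$planted_effects)) {
    idx_common <- which(is_common)
    eff[idx_common[config$planted_effects$index]] <-
      log(config$planted_effects$or)
  }
  need_cases <- config$n_cases; need_controls <- config$n_controls
  got <- list()
  batch <- ceiling((need_cases + need_controls) * 1.5)
  tries <- 0L
  while ((need_cases > 0L || need_controls > 0L) && tries < 30L) {
    tries <- tries + 1L
    pop_i <- sample(pops, batch, replace = TRUE, prob = config$populations)
    female <- stats::rbinom(batch, 1L, config$prob_female)
    pmat <- t(pop_freqs[, pop_i, drop = FALSE])          # batch x m
    dos <- matrix(stats::rbinom(batch * m, 2L, as.vector(pmat)),
                  nrow = batch)
    lp <- drop(dos %*% eff) + config$sex_log_odds * female
    status <- stats::rbinom(batch, 1L, stats::plogis(lp))
    take_case <- which(status == 1L)[seq_len(min(need_cases, sum(status == 1L)))]
    take_ctrl <- which(status == 0L)[seq_len(min(need_controls, sum(status == 0L)))]
    keep <- c(take_case, take_ctrl)
    got[[tries]] <- list(dos = dos[keep, , drop = FALSE],
                         pop = pop_i[keep], female = female[keep],
                         status = status[keep])
    need_cases <- need_cases - length(take_case)
    need_controls <- need_controls - length(take_ctrl)
  }
  if (need_cases > 0L || need_controls > 0L)
    stop("could not reach the configured case/control counts; ",
         "check the disease model parameters")
  dos <- do.call(rbind, lapply(got, `[[`, "dos"))
  pop <- unlist(lapply(got, `[[`, "pop"))
  female <- unlist(lapply(got, `[[`, "female"))
  status <- unlist(lapply(got, `[[`, "status"))
  ord2 <- order(-status)   # cases first, then controls
  dos <- dos[ord2, , drop = FALSE]
  pop <- pop[ord2]; female <- female[ord2]; status <- status[ord2]
  n <- nrow(dos)
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(dos) <- sample_ids
  storage.mode(dos) <- "integer"

  # ---- sample sheet --------------------------------------------------
  subtype <- rep("none", n)
  is_case <- status == 1L
  subtype[is_case] <- sample(c("IBS-C", "IBS-D", "IBS-M", "IBS-U", "none"),
                             sum(is_case), replace = TRUE,
                             prob = c(124, 206, 47, 186, 124) / 687)
  eth_map <- c(AFR = "Black", AMR = "Hispanic/Latino", EAS = "Asian",
               EUR = "White", SAS = "Asian")
  ethnicity <- unname(eth_map[pop])
  scramble <- stats::runif(n)
  ethnicity[scramble < 0.05] <- "unreported"
  ethnicity[scramble >= 0.05 & scramble < 0.09] <- "Multiple/Other"
  rate <- function(p_case) {
    r <- integer(n)
    r[is_case] <- sample(0:4, sum(is_case), TRUE, prob = p_case)
    r[!is_case] <- sample(0:4, sum(!is_case), TRUE,
                          prob = c(0.7, 0.2, 0.07, 0.02, 0.01))
    r
  }
  samples <- tibble::tibble(
    sample_id = sample_ids,
    status = ifelse(is_case, "case", "control"),
    subtype = subtype,
    sex = ifelse(female == 1L, "female", "male"),
    age = sample(7:83, n, replace = TRUE),
    site = sample(c("TCH", "UNC", "UW"), n, TRUE, prob = c(359, 470, 297) / 1126),
    ethnicity = ethnicity,
    population = pop,
    pain = rate(c(0.15, 0.2, 0.3, 0.25, 0.1)),
    diarrhea = rate(c(0.3, 0.2, 0.25, 0.15, 0.1)),
    constipation = rate(c(0.3, 0.2, 0.25, 0.15, 0.1)),
    bloating = rate(c(0.2, 0.2, 0.3, 0.2, 0.1))
  )

  vt2 <- tibble::as_tibble(vt[, c("variant_id", "chrom", "pos", "ref", "alt",
                                  "gene", "consequence", "multiallelic",
                                  "class", "label")])
  gm <- genotype_matrix(dos, vt2)

  out <- list(samples = samples, variants = vt2, matrix = gm,
              annotations = NULL,
              ledger = tibble::tibble(sample_id = character(),
                                      pattern = character(),
                                      genes = character(),
                                      variant_ids = character(),
                                      is_control = logical()),
              pop_freqs = pop_freqs, config = config)
  class(out) <- "synthetic_cohort"

  if (!is.null(config$planted_monogenic) || !is.null(config$planted_digenic)) {
    out <- plant_inheritance_events(out, config)
  }
  if (config$simulate_depths) out$matrix <- .simulate_depths(out$matrix, config)
  out$annotations <- simulate_annotations(out$variants, config)
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%d cases), %d variants, %d planted events\n",
              nrow(x$samples), sum(x$samples$status == "case"),
              nrow(x$variants), nrow(x$ledger)))
  invisible(x)
}

#' Plant monogenic and digenic inheritance events
#'
#' Monogenic events give a chosen case two qualifying heterozygous rare
#' variants in one gene (controls receive events only where configured);
#' digenic events give one qualifying variant in each of two genes.
#' Planted carriers' symptom ratings are shifted upward by
#' `symptom_shift` (clamped to 4). The returned ledger records ground
#' truth for every planted event.
#'
#' @param cohort A `synthetic_cohort` (or list with `matrix`, `samples`,
#'   `variants`, `ledger`).
#' @param config The [simulation_config()].
#' @return The cohort with updated genotypes, symptoms and ledger.
#' @export
plant_inheritance_events <- function(cohort, config) {
  set.seed(.sub_seed(config$seed, 2L))
  gm <- cohort$matrix
  samples <- cohort$samples
  vt <- cohort$variants
  ledger <- cohort$ledger
  slots <- split(vt$variant_id[vt$class == "event_slot"],
                 vt$gene[vt$class == "event_slot"])
  used_slots <- character()
  used_samples <- character()
  pick_slots <- function(gene, k) {
    if (!gene %in% names(slots)) stop("gene absent from panel: ", gene)
    avail <- setdiff(slots[[gene]], used_slots)
    if (length(avail) < k) stop("not enough event slots in gene ", gene)
    out <- avail[seq_len(k)]
    used_slots <<- c(used_slots, out)
    out
  }
  pick_samples <- function(status, k) {
    pool <- setdiff(samples$sample_id[samples$status == status], used_samples)
    if (length(pool) < k)
      stop("infeasible carrier counts: ", k, " ", status,
           " carriers requested but only ", length(pool), " available")
    out <- sample(pool, k)
    used_samples <<- c(used_samples, out)
    out
  }
  shift_symptoms <- function(ids) {
    for (s in c("pain", "diarrhea", "constipation", "bloating")) {
      i <- samples$sample_id %in% ids
      samples[[s]][i] <<- pmin(samples[[s]][i] + config$symptom_shift, 4L)
    }
  }
  add <- function(ids, pattern, genes, vids, is_control) {
    ledger <<- dplyr::bind_rows(ledger, tibble::tibble(
      sample_id = ids, pattern = pattern,
      genes = paste(sort(genes), collapse = "+"),
      variant_ids = paste(vids, collapse = ";"),
      is_control = is_control))
  }
  mono <- config$planted_monogenic
  if (!is.null(mono)) {
    for (i in seq_len(nrow(mono))) {
      g <- mono$gene[i]
      vids <- pick_slots(g, 2L)
      jj <- match(vids, gm$variants$variant_id)
      if (mono$n_case_carriers[i] > 0L) {
        ids <- pick_samples("case", mono$n_case_carriers[i])
        gm$dosage[ids, jj] <- 1L
        shift_symptoms(ids)
        add(ids, "monogenic", g, vids, FALSE)
      }
      nctrl <- if ("n_control_carriers" %in% names(mono))
        mono$n_control_carriers[i] else 0L
      if (!is.na(nctrl) && nctrl > 0L) {
        ids <- pick_samples("control", nctrl)
        gm$dosage[ids, jj] <- 1L
        add(ids, "monogenic", g, vids, TRUE)
      }
    }
  }
  dig <- config$planted_digenic
  if (!is.null(dig)) {
    for (i in seq_len(nrow(dig))) {
      va <- pick_slots(dig$gene_a[i], 1L)
      vb <- pick_slots(dig$gene_b[i], 1L)
      jj <- match(c(va, vb), gm$variants$variant_id)
      ids <- pick_samples("case", dig$n_case_carriers[i])
      gm$dosage[ids, jj] <- 1L
      shift_symptoms(ids)
      add(ids, "digenic", c(dig$gene_a[i], dig$gene_b[i]), c(va, vb), FALSE)
    }
  }
  cohort$matrix <- gm
  cohort$samples <- samples
  cohort$ledger <- ledger
  cohort
}

# Per-call allele depths: total depth Poisson, alternate reads binomial
# around a genotype-dependent allele balance.
.simulate_depths <- function(gm, config) {
  set.seed(.sub_seed(config$seed, 3L))
  d <- gm$dosage
  n <- length(d)
  tot <- matrix(stats::rpois(n, config$depth_mean), nrow = nrow(d))
  tot[tot == 0L] <- 1L
  bal <- matrix(0.005, nrow(d), ncol(d))
  het <- !is.na(d) & d == 1L
  bal[het] <- pmin(pmax(stats::rnorm(sum(het), 0.5, config$het_balance_sd),
                        0.05), 0.95)
  bal[!is.na(d) & d == 2L] <- 0.995
  alt <- matrix(stats::rbinom(n, as.vector(tot), as.vector(bal)),
                nrow = nrow(d))
  alt[is.na(d)] <- NA_integer_
  ref <- tot - alt
  ref[is.na(d)] <- NA_integer_
  dimnames(ref) <- dimnames(alt) <- dimnames(d)
  genotype_matrix(d, gm$variants, ref, alt)
}

#' Simulate per-variant annotations from ground-truth labels
#'
#' Deleterious-labelled variants draw CADD, REVEL, TRaP, categorical
#' damage calls and conservation metrics above the qualification
#' thresholds (each with probability `p_damaging_call`; at the default of
#' 1 the construction guarantees CADD > 12 and at least four damaging
#' votes). Benign variants draw below the thresholds, with at most two
#' damaging categorical calls so their damage score stays at or under
#' 0.5. Individual calls are set missing with probability
#' `annotation_missingness`.
#'
#' @param variants Variant tibble with `label` (benign / deleterious) and
#'   `class` columns from [simulate_cohort()].
#' @param config The [simulation_config()].
#' @return An annotation tibble.
#' @export
simulate_annotations <- function(variants, config) {
  set.seed(.sub_seed(config$seed, 4L))
  m <- nrow(variants)
  del <- variants$label == "deleterious"
  p_hit <- config$p_damaging_call
  draw_cat <- function() {
    out <- character(m)
    hit <- del & stats::runif(m) < p_hit
    out[hit] <- sample(c("damaging", "probably damaging",
                         "possibly damaging", "disease causing"),
                       sum(hit), TRUE)
    out[!hit] <- sample(c("tolerated", "benign", "neutral"),
                        sum(!hit), TRUE)
    # cap benign variants at 2 damaging calls overall (handled by caller)
    out
  }
  cats <- replicate(5L, draw_cat(), simplify = FALSE)
  # benign variants: keep at most 2 damaging categorical calls
  dmg_mat <- vapply(cats, .is_damaging_call, logical(m))
  over <- which(!del & rowSums(dmg_mat) > 2L)
  for (i in over) {
    hits <- which(dmg_mat[i, ])
    for (k in hits[-seq_len(2L)]) cats[[k]][i] <- "tolerated"
  }
  runi <- function(lo, hi) stats::runif(m, lo, hi)
  ann <- tibble::tibble(
    variant_id = variants$variant_id,
    gene = variants$gene,
    consequence = variants$consequence,
    gnomad_maf = dplyr::case_when(
      variants$class == "common" ~ pmin(runi(0.01, 0.5), 0.5),
      variants$class == "rare_background" ~ runi(1e-4, 9e-3),
      TRUE ~ runi(1e-5, 4e-3)
    ),
    cadd = ifelse(del, runi(15, 35), runi(0, 8)),
    revel = ifelse(del, runi(0.35, 0.95), runi(0, 0.2)),
    trap = ifelse(del, runi(0.12, 0.4), runi(0, 0.08)),
    sift = cats[[1]], polyphen2 = cats[[2]], lrt = cats[[3]],
    fathmm = cats[[4]], provean = cats[[5]],
    gerp = ifelse(del & stats::runif(m) < p_hit, runi(4.5, 6), runi(-2, 4)),
    phylop = ifelse(del & stats::runif(m) < p_hit, runi(1.7, 8), runi(-1, 1.5)),
    siphy = ifelse(del & stats::runif(m) < p_hit, runi(12.5, 20), runi(0, 11)),
    phastcons = ifelse(del & stats::runif(m) < p_hit, runi(0.55, 1), runi(0, 0.45)),
    clinvar = NA_character_
  )
  ann$revel[ann$consequence %in% c("splice_region", "intronic")] <- NA_real_
  if (config$annotation_missingness > 0) {
    for (col in c("sift", "polyphen2", "lrt", "fathmm", "provean",
                  "gerp", "phylop", "siphy", "phastcons")) {
      drop <- stats::runif(m) < config$annotation_missingness
      ann[[col]][drop] <- NA
    }
  }
  ann
}

#' Simulate a labelled reference panel on the cohort's common variants
#'
#' Draws `n_per_pop` individuals per superpopulation from the same
#' Balding-Nichols population frequencies used for the cohort, so the
#' panel clusters with it under joint MDS.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_per_pop Reference individuals per superpopulation.
#' @return List with `matrix` (a `genotype_matrix`) and `labels` (tibble
#'   `sample_id`, `superpop`).
#' @export
simulate_reference_panel <- function(cohort, n_per_pop = 40L) {
  config <- cohort$config
  set.seed(.sub_seed(config$seed, 5L))
  pf <- cohort$pop_freqs
  common <- cohort$variants$variant_id[cohort$variants$class == "common"]
  pf <- pf[common, , drop = FALSE]
  pops <- colnames(pf)
  dos <- do.call(rbind, lapply(pops, function(p) {
    matrix(stats::rbinom(n_per_pop * nrow(pf), 2L, rep(pf[, p], each = n_per_pop)),
           nrow = n_per_pop)
  }))
  ids <- paste0("REF_", rep(pops, each = n_per_pop), "_",
                seq_len(n_per_pop))
  rownames(dos) <- ids
  storage.mode(dos) <- "integer"
  vt <- cohort$variants[match(common, cohort$variants$variant_id), ]
  list(matrix = genotype_matrix(dos, vt),
       labels = tibble::tibble(sample_id = ids,
                               superpop = rep(pops, each = n_per_pop)))
}
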
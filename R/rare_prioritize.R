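# Categorical calls that count as a "damaging" vote, after normalising
# case and separators.
.damaging_calls <- c("damaging", "possibly damaging", "probably damaging",
                     "disease causing")

.is_damaging_call <- function(x) {
  x <- tolower(gsub("[_-]", " ", trimws(as.character(x))))
  !is.na(x) & x %in% .damaging_calls
}

#' Damage prediction score (voting matrix)
#'
#' Six assessments can vote: CADD (votes when the score exceeds 12) and
#' the five categorical algorithms SIFT, PolyPhen2, LRT, FATHMM and
#' PROVEAN (vote on a damaging-type call: "damaging", "possibly
#' damaging", "probably damaging" or "disease causing"). The score is the
#' damaging fraction among available (non-missing) assessments, reported
#' to two decimals.
#'
#' @param annotations Annotation tibble (rows are variants).
#' @param cadd_vote_min CADD threshold for a vote (strictly greater).
#' @return Tibble `variant_id`, `damage_score`, `damage_votes`,
#'   `damage_available`.
#' @export
damage_prediction_score <- function(annotations, cadd_vote_min = 12) {
  cat_cols <- c("sift", "polyphen2", "lrt", "fathmm", "provean")
  votes <- (!is.na(annotations$cadd) & annotations$cadd > cadd_vote_min) * 1L
  avail <- (!is.na(annotations$cadd)) * 1L
  for (col in cat_cols) {
    v <- annotations[[col]]
    votes <- votes + .is_damaging_call(v)
    avail <- avail + !is.na(v)
  }
  tibble::tibble(
    variant_id = annotations$variant_id,
    damage_score = ifelse(avail > 0, round(votes / avail, 2), NA_real_),
    damage_votes = as.integer(votes),
    damage_available = as.integer(avail)
  )
}

#' Conservation prediction score (voting matrix)
#'
#' Four conservation metrics vote with strict thresholds: SiPhy > 12,
#' GERP > 4.4, phyloP > 1.6 and phastCons > 0.5. The score is the
#' conserved fraction among available metrics, to two decimals.
#'
#' @param annotations Annotation tibble.
#' @return Tibble `variant_id`, `conservation_score`,
#'   `conservation_votes`, `conservation_available`.
#' @export
conservation_prediction_score <- function(annotations) {
  thr <- c(siphy = 12, gerp = 4.4, phylop = 1.6, phastcons = 0.5)
  votes <- avail <- rep(0L, nrow(annotations))
  for (col in names(thr)) {
    v <- annotations[[col]]
    votes <- votes + as.integer(!is.na(v) & v > thr[[col]])
    avail <- avail + as.integer(!is.na(v))
  }
  tibble::tibble(
    variant_id = annotations$variant_id,
    conservation_score = ifelse(avail > 0, round(votes / avail, 2), NA_real_),
    conservation_votes = votes,
    conservation_available = avail
  )
}

#' Combined voting-score matrix with deleteriousness classification
#'
#' A variant is damaging when strictly more than three of the six damage
#' assessments vote (i.e. >= 4 votes) and conserved when at least two of
#' the four conservation metrics vote; with missing assessments the same
#' absolute cutoffs apply.
#'
#' @param annotations Annotation tibble.
#' @return Tibble joining both score matrices plus `is_damaging`,
#'   `is_conserved`.
#' @export
score_matrix <- function(annotations) {
  dmg <- damage_prediction_score(annotations)
  cons <- conservation_prediction_score(annotations)
  out <- dplyr::inner_join(dmg, cons, by = "variant_id")
  cls <- classify_deleterious(out$damage_votes, out$conservation_votes)
  out$is_damaging <- cls$is_damaging
  out$is_conserved <- cls$is_conserved
  out
}

#' Classify votes into damaging / conserved calls
#'
#' @param damage_votes,conservation_votes Integer vote counts.
#' @return List of logical vectors `is_damaging` (votes >= 4 of 6) and
#'   `is_conserved` (votes >= 2 of 4).
#' @export
classify_deleterious <- function(damage_votes, conservation_votes) {
  list(is_damaging = damage_votes >= 4L,
       is_conserved = conservation_votes >= 2L)
}

#' Qualify rare variants for inheritance screening
#'
#' Two routes. The `matrix` route requires a non-synonymous (missense or
#' splice-region) consequence, gnomAD MAF < 0.01, and both voting-matrix
#' classifications (damaging and conserved). The `seqr` route requires a
#' non-synonymous consequence and MAF <= 0.05, then for missense variants
#' CADD >= 10 or REVEL >= 0.3 (disjunctive by default; conjunctive via
#' `cadd_revel_mode = "and"`), and for splice-region variants (REVEL
#' undefined) CADD >= 10 or TRaP >= `trap_min`. Every failed criterion is
#' recorded.
#'
#' @param annotations Annotation tibble (must include `consequence` and
#'   `gnomad_maf`).
#' @param route `"matrix"` or `"seqr"`.
#' @param trap_min TRaP threshold for splice-region variants (default 0.1).
#' @param cadd_revel_mode `"or"` (default) or `"and"`.
#' @return Tibble `variant_id`, `qualifies`, `reasons` (semicolon-joined
#'   failed criteria; empty when qualifying).
#' @export
qualify_rare_variant <- function(annotations, route = c("seqr", "matrix"),
                                 trap_min = 0.1,
                                 cadd_revel_mode = c("or", "and")) {
  route <- match.arg(route)
  cadd_revel_mode <- match.arg(cadd_revel_mode)
  n <- nrow(annotations)
  fails <- vector("list", n)
  add_fail <- function(cond, why) {
    for (i in which(cond)) fails[[i]] <<- c(fails[[i]], why)
  }
  cons <- annotations$consequence
  nonsyn <- !is.na(cons) & cons %in% c("missense", "splice_region")
  add_fail(!nonsyn, "consequence_not_nonsynonymous")
  maf <- annotations$gnomad_maf
  if (route == "matrix") {
    add_fail(is.na(maf) | maf >= 0.01, "maf_not_rare_lt_0.01")
    sm <- score_matrix(annotations)
    add_fail(!sm$is_damaging %in% TRUE, "not_damaging_by_vote_matrix")
    add_fail(!sm$is_conserved %in% TRUE, "not_conserved_by_vote_matrix")
  } else {
    add_fail(is.na(maf) | maf > 0.05, "maf_above_0.05")
    cadd_ok <- !is.na(annotations$cadd) & annotations$cadd >= 10
    revel_ok <- !is.na(annotations$revel) & annotations$revel >= 0.3
    trap_ok <- !is.na(annotations$trap) & annotations$trap >= trap_min
    is_mis <- !is.na(cons) & cons == "missense"
    is_spl <- !is.na(cons) & cons != "missense"
    score_ok <- rep(FALSE, n)
    score_ok[is_mis] <- if (cadd_revel_mode == "or")
      (cadd_ok | revel_ok)[is_mis] else (cadd_ok & revel_ok)[is_mis]
    score_ok[is_spl] <- (cadd_ok | trap_ok)[is_spl]
    add_fail(is_mis & !score_ok, "deleteriousness_below_cadd_revel")
    add_fail(is_spl & !score_ok, "deleteriousness_below_cadd_trap")
  }
  tibble::tibble(
    variant_id = annotations$variant_id,
    qualifies = lengths(fails) == 0L,
    reasons = vapply(fails, function(f) paste(f, collapse = ";"), "")
  )
}

# Per-sample biallelic status within one gene over a variant set:
# >= 2 qualifying heterozygous calls or >= 1 qualifying homozygous-alt.
.biallelic_samples <- function(gm, variant_ids) {
  sub <- gm$dosage[, gm$variants$variant_id %in% variant_ids, drop = FALSE]
  n_het <- rowSums(sub == 1L, na.rm = TRUE)
  n_hom <- rowSums(sub == 2L, na.rm = TRUE)
  rownames(sub)[n_het >= 2L | n_hom >= 1L]
}

#' Detect candidate monogenic (biallelic) inheritance in one gene
#'
#' A case is a candidate when it carries at least two qualifying
#' heterozygous variants in the gene, or one qualifying homozygous
#' alternate variant. The event is retained only if no control satisfies
#' the same biallelic condition over the same variant set (the
#' case-exclusivity rule). Phase is not inferred: all co-occurring pairs
#' are treated as potentially compound heterozygous.
#'
#' @param gm `genotype_matrix` (rare stage: allelic-balance masked).
#' @param samples Sample tibble.
#' @param qualifying Character vector of qualifying variant ids.
#' @param gene Gene symbol to screen.
#' @return Tibble of events: `sample_id`, `pattern`, `genes`,
#'   `variant_ids` (list-column), `case_exclusive`, `is_control`.
#' @export
detect_monogenic <- function(gm, samples, qualifying, gene) {
  vids <- gm$variants$variant_id[gm$variants$gene %in% gene &
                                   gm$variants$variant_id %in% qualifying]
  empty <- tibble::tibble(sample_id = character(), pattern = character(),
                          genes = list(), variant_ids = list(),
                          case_exclusive = logical(), is_control = logical())
  if (length(vids) == 0L) return(empty)
  cases <- samples$sample_id[samples$status == "case"]
  controls <- samples$sample_id[samples$status == "control"]
  hits <- .biallelic_samples(gm, vids)
  case_hits <- intersect(hits, cases)
  if (length(case_hits) == 0L) return(empty)
  rows <- purrr::map_dfr(case_hits, function(s) {
    d <- gm$dosage[s, match(vids, gm$variants$variant_id)]
    carried <- vids[!is.na(d) & d >= 1L]
    # controls biallelic over this case's variant set suppress the event
    ctrl_biallelic <- intersect(.biallelic_samples(gm, carried), controls)
    if (length(ctrl_biallelic) > 0L) return(NULL)
    tibble::tibble(sample_id = s, pattern = "monogenic",
                   genes = list(gene), variant_ids = list(carried),
                   case_exclusive = TRUE, is_control = FALSE)
  })
  if (nrow(rows) == 0L) empty else rows
}

#' Detect digenic / oligogenic qualifying-variant combinations
#'
#' Emits an event for every sample (cases and controls; control events
#' are flagged, not suppressed) whose qualifying variants span at least
#' two genes. Events are tiered: `known` when all genes are established
#' enzyme-deficiency genes, `candidate` when a candidate gene (by default
#' MGAM or SLC5A2) is involved.
#'
#' @param gm `genotype_matrix`.
#' @param samples Sample tibble.
#' @param qualifying Qualifying variant ids (seqr route).
#' @param known_genes Established disease genes.
#' @param candidate_genes Candidate disease genes.
#' @return Tibble of events with `pattern` (`digenic`/`oligogenic`),
#'   `tier`, `genes`, `variant_ids`, `case_exclusive`, `is_control`.
#' @export
detect_oligogenic <- function(gm, samples, qualifying,
                              known_genes = c("SI", "LCT", "TREH", "SLC5A1",
                                              "SLC2A5", "ALDOB"),
                              candidate_genes = c("MGAM", "SLC5A2")) {
  vids <- gm$variants$variant_id[gm$variants$variant_id %in% qualifying]
  empty <- tibble::tibble(sample_id = character(), pattern = character(),
                          tier = character(), genes = list(),
                          variant_ids = list(), case_exclusive = logical(),
                          is_control = logical())
  if (length(vids) < 2L) return(empty)
  idx <- match(vids, gm$variants$variant_id)
  genes <- gm$variants$gene[idx]
  sub <- gm$dosage[, idx, drop = FALSE]
  carrier <- !is.na(sub) & sub >= 1L
  rows <- purrr::map_dfr(rownames(sub), function(s) {
    carried <- vids[carrier[s, ]]
    g <- unique(genes[carrier[s, ]])
    g <- g[!is.na(g)]
    if (length(g) < 2L) return(NULL)
    st <- samples$status[match(s, samples$sample_id)]
    tibble::tibble(
      sample_id = s,
      pattern = if (length(g) == 2L) "digenic" else "oligogenic",
      tier = if (any(g %in% candidate_genes)) "candidate" else "known",
      genes = list(sort(g)), variant_ids = list(carried),
      case_exclusive = NA, is_control = identical(st, "control")
    )
  })
  if (nrow(rows) == 0L) return(empty)
  # case-exclusivity is reported, not enforced: a gene-set seen in any
  # control marks all events sharing that gene set
  key <- vapply(rows$genes, paste, "", collapse = "+")
  ctrl_keys <- unique(key[rows$is_control])
  rows$case_exclusive <- !(key %in% ctrl_keys)
  rows
}

#' Rescale a 0-4 Rome symptom rating to the 0-10 reporting scale
#'
#' Monotone mapping table with fixed endpoints (0 maps to 0, 4 to 10);
#' the default intermediate scores are 4, 6 and 8.
#'
#' @param rating Integer vector of ratings in 0-4 (`NA` passes through).
#' @param map Numeric vector of length 5: scores for ratings 0..4.
#' @return Numeric vector on the 0-10 scale.
#' @export
rescale_symptom <- function(rating, map = c(0, 4, 6, 8, 10)) {
  stopifnot(length(map) == 5L, map[1] == 0, map[5] == 10,
            !is.unsorted(map))
  bad <- !is.na(rating) & !(rating %in% 0:4)
  if (any(bad)) stop("symptom rating outside 0-4: ",
                     paste(unique(rating[bad]), collapse = ", "))
  out <- rep(NA_real_, length(rating))
  ok <- !is.na(rating)
  out[ok] <- map[rating[ok] + 1L]
  out
}

#' Carrier report rows for inheritance events
#'
#' One row per event variant, joining sample symptoms (rescaled to 0-10;
#' only symptoms above the reporting floor are listed) and variant
#' annotations, in the layout of a clinical candidate table.
#'
#' @param events Event tibble from [detect_monogenic()] /
#'   [detect_oligogenic()].
#' @param samples Sample tibble.
#' @param annotations Annotation tibble.
#' @param symptom_floor Report symptoms with rescaled score strictly
#'   above this (default 0).
#' @param map Symptom rescaling table passed to [rescale_symptom()].
#' @return Tibble `sample_id`, `pattern`, `symptoms`, `variant_id`,
#'   `gene`, `trap`, `cadd`, `revel`, `clinvar`.
#' @export
summarize_carriers <- function(events, samples, annotations,
                               symptom_floor = 0, map = c(0, 4, 6, 8, 10)) {
  if (nrow(events) == 0L)
    return(tibble::tibble(sample_id = character(), pattern = character(),
                          symptoms = character(), variant_id = character(),
                          gene = character(), trap = numeric(),
                          cadd = numeric(), revel = numeric(),
                          clinvar = character()))
  symptom_string <- function(s) {
    row <- samples[samples$sample_id == s, , drop = FALSE]
    if (nrow(row) == 0L) return(NA_character_)
    parts <- purrr::map_chr(c("pain", "diarrhea", "constipation", "bloating"),
                            function(sym) {
      sc <- rescale_symptom(row[[sym]], map)
      if (is.na(sc) || sc <= symptom_floor) return(NA_character_)
      cap <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
      sprintf("%s (%g/10)", cap, sc)
    })
    paste(stats::na.omit(parts), collapse = " ")
  }
  purrr::pmap_dfr(events, function(sample_id, variant_ids, pattern, ...) {
    syms <- symptom_string(sample_id)
    ann <- annotations[match(variant_ids, annotations$variant_id), , drop = FALSE]
    tibble::tibble(
      sample_id = sample_id, pattern = pattern, symptoms = syms,
      variant_id = variant_ids,
      gene = if ("gene" %in% names(ann)) ann$gene else NA_character_,
      trap = if ("trap" %in% names(ann)) ann$trap else NA_real_,
      cadd = if ("cadd" %in% names(ann)) ann$cadd else NA_real_,
      revel = if ("revel" %in% names(ann)) ann$revel else NA_real_,
      clinvar = if ("clinvar" %in% names(ann)) as.character(ann$clinvar)
                else NA_character_
    )
  })
}
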
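#' Carbohydrate-digestion candidate gene panel
#'
#' The seven targeted genes with their approximate genomic spans (1-based,
#' inclusive, GRCh37 coordinates). Spans are generous so that every targeted
#' exonic/intronic variant position falls inside its gene.
#'
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
panel_genes <- function() {
  tibble::tribble(
    ~gene,     ~chrom, ~start,      ~end,
    "SLC2A5",  "1",    9090000L,    9150000L,
    "LCT",     "2",    136540000L,  136600000L,
    "SI",      "3",    164690000L,  164800000L,
    "MGAM",    "7",    141600000L,  141810000L,
    "ALDOB",   "9",    104180000L,  104200000L,
    "TREH",    "11",   118520000L,  118560000L,
    "SLC5A1",  "22",   32430000L,   32510000L
  )
}

# Controlled vocabularies for the sample sheet
.statuses  <- c("case", "control")
.subtypes  <- c("IBS-C", "IBS-D", "IBS-M", "IBS-U", "none")
.sexes     <- c("female", "male", "unknown")
.ethnicities <- c(
  "Native American/Alaska Native", "Asian", "Black", "Hispanic/Latino",
  "Native Hawaiian/Pacific Islander", "White", "Multiple/Other", "unreported"
)
.symptoms  <- c("pain", "diarrhea", "constipation", "bloating")

#' Construct a genotype matrix object
#'
#' A light container for a samples-by-variants dosage matrix (counts of the
#' alternate allele: 0, 1, 2, or `NA` for missing calls) plus optional
#' per-call allele depths and the variant table.
#'
#' @param dosage Integer matrix, samples in rows, variants in columns.
#'   Rownames are sample ids, colnames variant ids.
#' @param variants Tibble with one row per column of `dosage`: `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `multiallelic`.
#' @param ad_ref,ad_alt Optional integer matrices of reference / alternate
#'   read depths, same shape as `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, ad_ref = NULL, ad_alt = NULL) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (!is.null(ad_ref)) stopifnot(all(dim(ad_ref) == dim(dosage)))
  if (!is.null(ad_alt)) stopifnot(all(dim(ad_alt) == dim(dosage)))
  bad <- stats::na.omit(unique(as.vector(dosage)))
  if (!all(bad %in% 0:2)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage))) stop("dosage must carry sample ids as rownames")
  colnames(dosage) <- variants$variant_id
  if (!is.null(ad_ref)) dimnames(ad_ref) <- dimnames(dosage)
  if (!is.null(ad_alt)) dimnames(ad_alt) <- dimnames(dosage)
  structure(
    list(dosage = dosage, variants = tibble::as_tibble(variants),
         ad_ref = ad_ref, ad_alt = ad_alt),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%s allele depths)\n",
              nrow(x$dosage), ncol(x$dosage),
              if (is.null(x$ad_ref)) "without" else "with"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by sample ids and/or variant ids
#'
#' @param gm A `genotype_matrix`.
#' @param samples,variants Character vectors of ids to keep (default: all).
#' @return A `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(gm$dosage)) else match(samples, rownames(gm$dosage))
  vi <- if (is.null(variants)) seq_len(ncol(gm$dosage)) else match(variants, gm$variants$variant_id)
  if (anyNA(si)) stop("unknown sample id(s): ", paste(samples[is.na(si)], collapse = ", "))
  if (anyNA(vi)) stop("unknown variant id(s): ", paste(variants[is.na(vi)], collapse = ", "))
  genotype_matrix(
    gm$dosage[si, vi, drop = FALSE], gm$variants[vi, , drop = FALSE],
    if (!is.null(gm$ad_ref)) gm$ad_ref[si, vi, drop = FALSE],
    if (!is.null(gm$ad_alt)) gm$ad_alt[si, vi, drop = FALSE]
  )
}

.assign_gene <- function(chrom, pos, panel = panel_genes()) {
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(panel))) {
    hit <- chrom == panel$chrom[i] & pos >= panel$start[i] & pos <= panel$end[i]
    out[hit] <- panel$gene[i]
  }
  out
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.2 file with GT (and optionally AD) FORMAT fields.
#' Multiallelic records are split into one biallelic record per alternate
#' allele; the split records are flagged (`multiallelic = TRUE`) so QC can
#' remove them. Missing or half-missing genotype calls become missing
#' dosages. Output variant order is deterministic: chromosome, position,
#' then alternate allele.
#'
#' @param path Path to a VCF file (plain text).
#' @return A `genotype_matrix`; its `variants` tibble is the variant table.
#' @export
read_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("VCF '", path, "' contains no variant records")
  gt_raw <- vcf@gt
  # depending on vcfR version the FORMAT column sits in @fix or in @gt
  if ("FORMAT" %in% colnames(fix)) {
    fmt <- fix$FORMAT
    calls <- gt_raw
  } else {
    fmt <- gt_raw[, 1]
    calls <- gt_raw[, -1, drop = FALSE]
  }
  if (is.null(calls) || ncol(calls) < 1L)
    stop("empty cohort: VCF '", path, "' has zero sample columns")
  sample_ids <- colnames(calls)
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE), function(f) match("GT", f), 1L)
  ad_idx <- vapply(strsplit(fmt, ":", fixed = TRUE), function(f) match("AD", f), 1L)
  if (anyNA(gt_idx)) stop("malformed VCF: record without GT at line(s) ",
                          paste(which(is.na(gt_idx)), collapse = ","))
  n_rec <- nrow(fix)

  rows <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    fields <- strsplit(calls[r, ], ":", fixed = TRUE)
    gts <- vapply(fields, `[`, "", gt_idx[r])
    ads <- if (!is.na(ad_idx[r])) vapply(fields, function(f) {
      if (length(f) >= ad_idx[r]) f[ad_idx[r]] else NA_character_
    }, "") else rep(NA_character_, length(fields))
    al <- strsplit(gts, "[/|]")
    ad_split <- strsplit(ads, ",", fixed = TRUE)
    per_alt <- vector("list", length(alts))
    for (j in seq_along(alts)) {
      dos <- vapply(al, function(a) {
        if (length(a) != 2L || any(a == ".") || any(a == "")) return(NA_integer_)
        sum(a == as.character(j))
      }, 1L)
      adr <- vapply(ad_split, function(a) {
        if (length(a) < j + 1L || any(a == ".")) return(NA_integer_)
        as.integer(a[1L])
      }, 1L)
      ada <- vapply(ad_split, function(a) {
        if (length(a) < j + 1L || any(a == ".")) return(NA_integer_)
        as.integer(a[j + 1L])
      }, 1L)
      id <- fix$ID[r]
      vid <- if (length(alts) > 1L || is.na(id) || id == ".")
        paste(fix$CHROM[r], fix$POS[r], fix$REF[r], alts[j], sep = ":") else id
      per_alt[[j]] <- list(
        variant_id = vid, chrom = fix$CHROM[r], pos = as.integer(fix$POS[r]),
        ref = fix$REF[r], alt = alts[j], multiallelic = length(alts) > 1L,
        dosage = dos, ad_ref = adr, ad_alt = ada
      )
    }
    rows[[r]] <- per_alt
  }
  rows <- unlist(rows, recursive = FALSE)
  vt <- tibble::tibble(
    variant_id = vapply(rows, `[[`, "", "variant_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    pos = vapply(rows, `[[`, 1L, "pos"),
    ref = vapply(rows, `[[`, "", "ref"),
    alt = vapply(rows, `[[`, "", "alt"),
    multiallelic = vapply(rows, `[[`, TRUE, "multiallelic")
  )
  ord <- order(suppressWarnings(as.integer(vt$chrom)), vt$chrom, vt$pos, vt$alt)
  vt <- vt[ord, ]
  vt$gene <- .assign_gene(vt$chrom, vt$pos)
  vt$consequence <- NA_character_
  dos <- do.call(cbind, lapply(rows[ord], `[[`, "dosage"))
  adr <- do.call(cbind, lapply(rows[ord], `[[`, "ad_ref"))
  ada <- do.call(cbind, lapply(rows[ord], `[[`, "ad_alt"))
  rownames(dos) <- rownames(adr) <- rownames(ada) <- sample_ids
  if (all(is.na(adr))) adr <- ada <- NULL
  genotype_matrix(dos, vt, adr, ada)
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT (and AD when depths are present). One biallelic record per
#' variant; previously split multiallelic records are written as separate
#' biallelic lines.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  vt <- gm$variants
  has_ad <- !is.null(gm$ad_ref)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ad) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "FORMAT",
            rownames(gm$dosage)), collapse = "\t")
  )
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gm$dosage + 1L], nrow = nrow(gm$dosage))
  gt_str[is.na(gm$dosage)] <- "./."
  if (has_ad) {
    ad_str <- matrix(paste0(gm$ad_ref, ",", gm$ad_alt), nrow = nrow(gm$dosage))
    ad_str[is.na(gm$ad_ref) | is.na(gm$ad_alt)] <- ".,."
    gt_str <- matrix(paste(gt_str, ad_str, sep = ":"), nrow = nrow(gm$dosage))
  }
  lines <- vapply(seq_len(nrow(vt)), function(j) {
    paste(c(vt$chrom[j], vt$pos[j], vt$variant_id[j], vt$ref[j], vt$alt[j],
            ".", "PASS", if (has_ad) "GT:AD" else "GT", gt_str[, j]),
          collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), check.names = FALSE)
}

#' Read a cohort sample sheet
#'
#' Tab-separated with header columns `sample_id`, `status`, `subtype`,
#' `sex`, `age`, `site`, `ethnicity`, `pain`, `diarrhea`, `constipation`,
#' `bloating`. Symptom ratings are on the 0-4 Rome questionnaire scale or
#' missing. Unknown category strings and out-of-range ratings are rejected
#' rather than coerced; a subtype on a control is an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble of sample records.
#' @export
read_sample_sheet <- function(path) {
  df <- .read_tsv(path)
  validate_samples(tibble::as_tibble(df))
}

#' Validate a sample-record tibble against the cohort data model
#'
#' @param samples A tibble with the sample-sheet columns.
#' @return The validated tibble (symptom columns as integer).
#' @export
validate_samples <- function(samples) {
  need <- c("sample_id", "status", "subtype", "sex", "age", "site",
            "ethnicity", .symptoms)
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  samples$subtype[is.na(samples$subtype)] <- "none"
  chk <- function(x, vocab, what) {
    bad <- setdiff(unique(stats::na.omit(x)), vocab)
    if (length(bad)) stop("unknown ", what, " value(s): ", paste(bad, collapse = ", "))
  }
  chk(samples$status, .statuses, "status")
  chk(samples$subtype, .subtypes, "subtype")
  chk(samples$sex, .sexes, "sex")
  chk(samples$ethnicity, .ethnicities, "ethnicity")
  bad_sub <- samples$status == "control" & samples$subtype != "none"
  if (any(bad_sub))
    stop("control sample(s) carry an IBS subtype: ",
         paste(samples$sample_id[bad_sub], collapse = ", "))
  for (s in .symptoms) {
    v <- samples[[s]]
    if (!all(is.na(v) | (v %in% 0:4)))
      stop("symptom rating '", s, "' outside 0-4 for sample(s): ",
           paste(samples$sample_id[!(is.na(v) | v %in% 0:4)], collapse = ", "))
    samples[[s]] <- as.integer(v)
  }
  tibble::as_tibble(samples)
}

#' Write a sample sheet as TSV
#' @param samples Sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' Tab-separated, keyed by `variant_id`, with pathogenicity and conservation
#' annotations: `gene`, `consequence`, `gnomad_maf`, `cadd`, `revel`,
#' `trap`, categorical damage calls (`sift`, `polyphen2`, `lrt`, `fathmm`,
#' `provean`), conservation scores (`gerp`, `phylop`, `siphy`, `phastcons`)
#' and `clinvar`. Missing fields stay missing (no imputation). Scores with
#' documented ranges are validated: `revel`, `trap`, `gnomad_maf` and
#' `phastcons` must lie in \[0, 1\].
#'
#' @param path Path to the TSV file.
#' @param known_variants Optional character vector; annotations for variants
#'   outside it trigger a warning (they are kept).
#' @return A tibble of annotation records.
#' @export
read_annotations <- function(path, known_variants = NULL) {
  ann <- tibble::as_tibble(.read_tsv(path))
  validate_annotations(ann, known_variants)
}

#' Validate an annotation tibble
#' @inheritParams read_annotations
#' @param annotations A tibble with the annotation columns.
#' @return The validated tibble.
#' @export
validate_annotations <- function(annotations, known_variants = NULL) {
  if (!"variant_id" %in% names(annotations)) stop("annotations lack variant_id")
  for (col in c("gnomad_maf", "revel", "trap", "phastcons")) {
    if (col %in% names(annotations)) {
      v <- annotations[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        stop(col, " outside [0,1] for variant(s): ",
             paste(annotations$variant_id[!is.na(v) & (v < 0 | v > 1)], collapse = ", "))
    }
  }
  if (!is.null(known_variants)) {
    unk <- setdiff(annotations$variant_id, known_variants)
    if (length(unk))
      warning("annotations for unknown variant(s): ", paste(unk, collapse = ", "))
  }
  tibble::as_tibble(annotations)
}

#' Write an annotation table as TSV
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Demographic summary of a cohort
#'
#' Counts and column percentages by case/control status for sex, ethnicity
#' and site, plus overall totals, in the layout of a standard "Table 1".
#' Percentages are rounded to one decimal.
#'
#' @param samples Sample tibble (as from [read_sample_sheet()]).
#' @return A tibble with columns `category`, `level`, `n_case`, `pct_case`,
#'   `n_control`, `pct_control`, `n_overall`, `pct_overall`.
#' @export
cohort_summary <- function(samples) {
  if (is.null(samples) || nrow(samples) == 0L) stop("empty cohort")
  samples <- validate_samples(samples)
  n_case <- sum(samples$status == "case")
  n_ctrl <- sum(samples$status == "control")
  n_all <- nrow(samples)
  blocks <- lapply(c("sex", "ethnicity", "site"), function(var) {
    tab <- samples |>
      dplyr::count(level = as.character(.data[[var]]), .data$status) |>
      tidyr::pivot_wider(names_from = "status", values_from = "n", values_fill = 0L)
    if (!"case" %in% names(tab)) tab$case <- 0L
    if (!"control" %in% names(tab)) tab$control <- 0L
    tibble::tibble(
      category = var, level = tab$level,
      n_case = tab$case, pct_case = round(100 * tab$case / n_case, 1),
      n_control = tab$control, pct_control = round(100 * tab$control / n_ctrl, 1),
      n_overall = tab$case + tab$control,
      pct_overall = round(100 * (tab$case + tab$control) / n_all, 1)
    )
  })
  totals <- tibble::tibble(
    category = "total", level = "all",
    n_case = n_case, pct_case = round(100 * n_case / n_all, 1),
    n_control = n_ctrl, pct_control = round(100 * n_ctrl / n_all, 1),
    n_overall = n_all, pct_overall = 100
  )
  dplyr::bind_rows(dplyr::bind_rows(blocks), totals)
}
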
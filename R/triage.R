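origin_levels <- function() {
  c("CH_RELATED", "TUMOR_DERIVED_CONCORDANT", "UNKNOWN_PLASMA_ONLY",
    "TUMOR_ONLY")
}

variant_key_cols <- function() c("chrom", "pos", "ref", "alt")

#' Classify a variant's origin from compartment co-detection
#'
#' Implements the triage rule for matched tumor / PBC / plasma sequencing:
#' detection in peripheral blood cells marks a variant as CH-related
#' regardless of tumor status (PBC precedence); otherwise detection in both
#' tumor and plasma marks it tumor-derived concordant; plasma-exclusive
#' variants have unknown origin; the remainder are tumor-only. Vectorized
#' over the three logical flags.
#'
#' @param in_tumor,in_pbc,in_plasma logical vectors (recycled to a common
#'   length): was the variant detected in that compartment?
#' @return factor with levels `CH_RELATED`, `TUMOR_DERIVED_CONCORDANT`,
#'   `UNKNOWN_PLASMA_ONLY`, `TUMOR_ONLY`.
#' @export
#' @examples
#' classify_origin(in_tumor = FALSE, in_pbc = TRUE, in_plasma = TRUE)
classify_origin <- function(in_tumor, in_pbc, in_plasma) {
  n <- max(length(in_tumor), length(in_pbc), length(in_plasma))
  in_tumor <- rep_len(as.logical(in_tumor), n)
  in_pbc <- rep_len(as.logical(in_pbc), n)
  in_plasma <- rep_len(as.logical(in_plasma), n)
  if (anyNA(in_tumor) || anyNA(in_pbc) || anyNA(in_plasma)) {
    stop("detection flags must not be NA")
  }
  if (any(!(in_tumor | in_pbc | in_plasma))) {
    stop("a variant must be detected in at least one compartment")
  }
  out <- ifelse(in_pbc, "CH_RELATED",
         ifelse(in_tumor & in_plasma, "TUMOR_DERIVED_CONCORDANT",
         ifelse(in_plasma, "UNKNOWN_PLASMA_ONLY", "TUMOR_ONLY")))
  factor(out, levels = origin_levels())
}

normalize_callset <- function(calls, patient_id) {
  if (is.null(calls)) calls <- data.table::data.table()
  calls <- data.table::as.data.table(calls)
  if (nrow(calls) == 0L) {
    return(data.table::data.table(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene = character(), aa_change = character(),
      vaf_pct = numeric()
    ))
  }
  miss <- setdiff(c(variant_key_cols(), "vaf_pct"), names(calls))
  if (length(miss)) {
    stop("call set is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if ("patient" %in% names(calls) && !is.null(patient_id)) {
    pats <- unique(stats::na.omit(calls$patient))
    if (length(pats) && !all(pats == patient_id)) {
      stop("call set patient id(s) ", paste(pats, collapse = ","),
           " do not match triage patient ", patient_id)
    }
  }
  if (!"gene" %in% names(calls)) calls[, gene := NA_character_]
  if (!"aa_change" %in% names(calls)) calls[, aa_change := NA_character_]
  out <- calls[, .(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   gene, aa_change, vaf_pct = as.numeric(vaf_pct))]
  if (anyDuplicated(out, by = variant_key_cols())) {
    stop("call set contains more than one call for the same variant key")
  }
  out
}

#' Triage one patient's matched compartments
#'
#' Labels every variant seen in any of the three baseline call sets (tumor
#' tissue, PBC, preoperative plasma) via [classify_origin()] and attaches the
#' per-compartment VAFs; an absent compartment is recorded as not detected
#' (rendered "N.D" in tables).
#'
#' @param tumor,pbc,plasma call sets for one patient (data.frames with at
#'   least `chrom`, `pos`, `ref`, `alt`, `vaf_pct`; `NULL` or empty allowed).
#'   The plasma set must be the preoperative baseline.
#' @param patient_id patient identifier; checked against any `patient` column
#'   present in the call sets.
#' @param stage tumor stage, one of "I","II","III","IV" (optional, used by
#'   [detection_rate()]).
#' @param age age in years at baseline (optional, used by
#'   [ch_prevalence_by_age()]).
#' @return An object of class `patient_triage`: a list with `patient_id`,
#'   `stage`, `age` and a `variants` data.table holding the variant keys,
#'   per-compartment VAFs (`vaf_tumor`, `vaf_pbc`, `vaf_plasma`, NA when not
#'   detected), detection flags and the `origin` label.
#' @export
triage_patient <- function(tumor = NULL, pbc = NULL, plasma = NULL,
                           patient_id = NA_character_, stage = NA_character_,
                           age = NA_real_) {
  tumor <- normalize_callset(tumor, patient_id)
  pbc <- normalize_callset(pbc, patient_id)
  plasma <- normalize_callset(plasma, patient_id)
  keyc <- variant_key_cols()
  keys <- unique(data.table::rbindlist(list(
    tumor[, c(keyc, "gene", "aa_change"), with = FALSE],
    pbc[, c(keyc, "gene", "aa_change"), with = FALSE],
    plasma[, c(keyc, "gene", "aa_change"), with = FALSE]
  )), by = keyc)
  if (nrow(keys) == 0L) {
    variants <- data.table::data.table(
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), gene = character(), aa_change = character(),
      vaf_tumor = numeric(), vaf_pbc = numeric(), vaf_plasma = numeric(),
      in_tumor = logical(), in_pbc = logical(), in_plasma = logical(),
      origin = factor(character(), levels = origin_levels())
    )
  } else {
    add_vaf <- function(keys, set, col) {
      m <- merge(keys, set[, c(keyc, "vaf_pct"), with = FALSE],
                 by = keyc, all.x = TRUE, sort = FALSE)
      data.table::setnames(m, "vaf_pct", col)
      m
    }
    variants <- add_vaf(keys, tumor, "vaf_tumor")
    variants <- add_vaf(variants, pbc, "vaf_pbc")
    variants <- add_vaf(variants, plasma, "vaf_plasma")
    variants[, `:=`(in_tumor = !is.na(vaf_tumor),
                    in_pbc = !is.na(vaf_pbc),
                    in_plasma = !is.na(vaf_plasma))]
    variants[, origin := classify_origin(in_tumor, in_pbc, in_plasma)]
    data.table::setorder(variants, chrom, pos, alt)
  }
  structure(list(patient_id = patient_id, stage = stage, age = age,
                 variants = variants[]),
            class = "patient_triage")
}

#' @export
print.patient_triage <- function(x, ...) {
  cat(sprintf("Patient %s (stage %s, age %s): %d variant(s)\n",
              x$patient_id, x$stage, x$age, nrow(x$variants)))
  if (nrow(x$variants)) print(x$variants)
  invisible(x)
}

#' Bundle per-patient triages into a cohort
#'
#' @param triages list of `patient_triage` objects.
#' @return object of class `cohort_triage` (a named list of patients).
#' @export
as_cohort <- function(triages) {
  if (inherits(triages, "patient_triage")) triages <- list(triages)
  ok <- vapply(triages, inherits, logical(1), "patient_triage")
  if (!all(ok)) stop("all elements must be patient_triage objects")
  ids <- vapply(triages, function(p) as.character(p$patient_id), character(1))
  if (anyDuplicated(stats::na.omit(ids))) {
    stop("duplicated patient_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(triages) <- ids
  structure(triages, class = "cohort_triage")
}

cohort_variants <- function(cohort) {
  if (inherits(cohort, "patient_triage")) cohort <- as_cohort(list(cohort))
  if (!inherits(cohort, "cohort_triage")) {
    stop("expected a cohort_triage (see as_cohort())")
  }
  data.table::rbindlist(lapply(cohort, function(p) {
    v <- data.table::copy(p$variants)
    v[, `:=`(patient = p$patient_id, stage = p$stage, age = p$age)]
    v
  }))
}

#' Cohort concordance and origin partition
#'
#' Counts variants per origin label across a triaged cohort (each
#' patient-variant pair counted once) and derives the partition statistics:
#' tumor total, plasma total, concordant count (detected in both tumor and
#' plasma regardless of origin), and percentages of the plasma total for the
#' tumor-derived, CH-related and unknown fractions.
#'
#' @param cohort a `cohort_triage`.
#' @return object of class `cohort_summary` (a list of counts and
#'   percentages; see fields in the printed output).
#' @export
concordance <- function(cohort) {
  v <- cohort_variants(cohort)
  n_patients <- length(cohort)
  if (n_patients < 1L) stop("concordance requires at least one patient")
  lab <- table(v$origin)
  ch_plasma <- sum(v$origin == "CH_RELATED" & v$in_plasma)
  ch_tumor <- sum(v$origin == "CH_RELATED" & v$in_tumor)
  ch_both <- sum(v$origin == "CH_RELATED" & v$in_tumor & v$in_plasma)
  out <- list(
    n_patients = n_patients,
    tumor_total = sum(v$in_tumor),
    plasma_total = sum(v$in_plasma),
    concordant_count = sum(v$in_tumor & v$in_plasma),
    plasma_exclusive = sum(v$in_plasma & !v$in_tumor),
    counts = as.list(lab),
    ch_plasma_detected = ch_plasma,
    ch_tumor_detected = ch_tumor,
    ch_tumor_and_plasma = ch_both,
    n_patients_with_ch = length(unique(v[origin == "CH_RELATED"]$patient)),
    n_patients_concordant =
      length(unique(v[in_tumor & in_plasma]$patient)),
    n_patients_no_variant =
      n_patients - length(unique(v$patient[v$in_tumor | v$in_plasma]))
  )
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  out$pct_tumor_also_plasma <- pct(out$concordant_count, out$tumor_total)
  out$pct_plasma_tumor_derived <-
    pct(lab[["TUMOR_DERIVED_CONCORDANT"]], out$plasma_total)
  out$pct_plasma_ch_related <- pct(ch_plasma, out$plasma_total)
  out$pct_plasma_unknown <-
    pct(lab[["UNKNOWN_PLASMA_ONLY"]], out$plasma_total)
  out$pct_plasma_exclusive <- pct(out$plasma_exclusive, out$plasma_total)
  out$pct_patients_with_ch <- pct(out$n_patients_with_ch, n_patients)
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patient(s)\n", x$n_patients))
  cat(sprintf("  tumor mutations: %d; plasma mutations: %d\n",
              x$tumor_total, x$plasma_total))
  cat(sprintf("  concordant (tumor & plasma): %d (%.1f%% of tumor)\n",
              x$concordant_count, x$pct_tumor_also_plasma))
  cat(sprintf("  plasma partition: %d tumor-derived (%.0f%%), %d CH-related (%.0f%%), %d unknown (%.0f%%)\n",
              x$counts$TUMOR_DERIVED_CONCORDANT, x$pct_plasma_tumor_derived,
              x$ch_plasma_detected, x$pct_plasma_ch_related,
              x$counts$UNKNOWN_PLASMA_ONLY, x$pct_plasma_unknown))
  cat(sprintf("  patients with >=1 CH-related mutation: %d (%.0f%%)\n",
              x$n_patients_with_ch, x$pct_patients_with_ch))
  invisible(x)
}

stage_group_members <- function(stage_group) {
  switch(stage_group,
         "I-II" = c("I", "II"),
         "III-IV" = c("III", "IV"),
         stop("unknown stage group: ", stage_group))
}

#' Plasma ctDNA detection rate by stage group
#'
#' Percent of patients in a stage group with at least one preoperative plasma
#' variant. With `exclude_ch = TRUE`, CH-related variants are removed before
#' the at-least-one test, mimicking triage-aware detection; a patient whose
#' only plasma variant is CH-related then counts as undetected.
#'
#' @param cohort a `cohort_triage`; every patient must carry a stage.
#' @param stage_group `"I-II"` or `"III-IV"`.
#' @param exclude_ch drop CH-related variants before testing detection?
#' @return percent (full precision; round for display).
#' @export
detection_rate <- function(cohort, stage_group = c("I-II", "III-IV"),
                           exclude_ch = FALSE) {
  stage_group <- match.arg(stage_group)
  stages <- vapply(cohort, function(p) as.character(p$stage), character(1))
  if (anyNA(stages)) stop("every patient must have a stage")
  keep <- stages %in% stage_group_members(stage_group)
  if (!any(keep)) stop("no patients in stage group ", stage_group)
  detected <- vapply(cohort[keep], function(p) {
    v <- p$variants
    if (exclude_ch) v <- v[origin != "CH_RELATED"]
    any(v$in_plasma)
  }, logical(1))
  100 * mean(detected)
}

#' Percent of patients with a monitorable marker
#'
#' A patient is monitorable when at least one variant is detected in tumor
#' tissue or preoperative plasma; with `exclude_ch = TRUE` (default)
#' CH-related variants never count as monitorable markers.
#'
#' @inheritParams detection_rate
#' @return percent (full precision).
#' @export
monitorable_rate <- function(cohort, exclude_ch = TRUE) {
  if (length(cohort) == 0L) stop("monitorable_rate requires a non-empty cohort")
  ok <- vapply(cohort, function(p) {
    v <- p$variants
    if (exclude_ch) v <- v[origin != "CH_RELATED"]
    any(v$in_tumor | v$in_plasma)
  }, logical(1))
  100 * mean(ok)
}
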
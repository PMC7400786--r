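#' Track baseline plasma markers across postoperative samples
#'
#' Builds one trajectory per baseline (preoperative) plasma variant, matching
#' postoperative plasma calls by exact variant key (chrom, pos, ref, alt).
#' Variants appearing only postoperatively are reported separately as
#' *emergent* and carry origin `UNKNOWN_PLASMA_ONLY`; the baseline origin
#' labels of tracked markers are fixed at baseline and never re-evaluated.
#'
#' @param baseline a `patient_triage` (the preoperative triage).
#' @param postop_sets list of postoperative plasma samples, each a list with
#'   elements `timepoint` (label), `months` (months from surgery, strictly
#'   increasing across samples) and `calls` (data.frame, possibly empty, with
#'   `chrom`, `pos`, `ref`, `alt`, `vaf_pct`).
#' @return object of class `marker_trajectories`: `patient_id`, a
#'   `timepoints` table, and `data` in long format (one row per variant and
#'   timepoint with `vaf_pct`, NA when not detected, plus `detected`,
#'   `origin`, `emergent`). The baseline appears as timepoint "preop" at
#'   month 0.
#' @export
track_markers <- function(baseline, postop_sets = list()) {
  if (!inherits(baseline, "patient_triage")) {
    stop("baseline must be a patient_triage")
  }
  months <- vapply(postop_sets, function(s) as.numeric(s$months), numeric(1))
  if (length(months) > 1L && any(diff(months) <= 0)) {
    stop("postoperative timepoints must be strictly increasing in months")
  }
  if (length(months) && any(months <= 0)) {
    stop("postoperative months_from_surgery must be positive")
  }
  keyc <- variant_key_cols()
  bv <- baseline$variants[in_plasma == TRUE,
                          c(keyc, "gene", "origin", "vaf_plasma"),
                          with = FALSE]
  labels <- vapply(postop_sets, function(s) {
    if (is.null(s$timepoint)) NA_character_ else as.character(s$timepoint)
  }, character(1))
  labels[is.na(labels)] <- paste0("postop", seq_along(labels)[is.na(labels)])
  rows <- list(data.table::data.table(
    bv[, keyc, with = FALSE], gene = bv$gene, origin = bv$origin,
    emergent = FALSE, timepoint = "preop", months = 0,
    vaf_pct = bv$vaf_plasma
  ))
  emergent_keys <- data.table::data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), gene = character()
  )
  for (i in seq_along(postop_sets)) {
    calls <- normalize_callset(postop_sets[[i]]$calls, baseline$patient_id)
    m <- merge(bv[, c(keyc, "gene", "origin"), with = FALSE],
               calls[, c(keyc, "vaf_pct"), with = FALSE],
               by = keyc, all.x = TRUE, sort = FALSE)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      m[, keyc, with = FALSE], gene = m$gene, origin = m$origin,
      emergent = FALSE, timepoint = labels[i], months = months[i],
      vaf_pct = m$vaf_pct
    )
    em <- calls[!bv, on = keyc]
    if (nrow(em)) {
      emergent_keys <- unique(data.table::rbindlist(list(
        emergent_keys, em[, c(keyc, "gene"), with = FALSE])), by = keyc)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        em[, keyc, with = FALSE], gene = em$gene,
        origin = factor("UNKNOWN_PLASMA_ONLY", levels = origin_levels()),
        emergent = TRUE, timepoint = labels[i], months = months[i],
        vaf_pct = em$vaf_pct
      )
    }
  }
  dat <- data.table::rbindlist(rows)
  dat[, detected := !is.na(vaf_pct)]
  structure(list(
    patient_id = baseline$patient_id,
    timepoints = data.table::data.table(
      timepoint = c("preop", labels), months = c(0, months)),
    data = dat[]
  ), class = "marker_trajectories")
}

#' Interpret marker trajectories for residual disease
#'
#' Computes the two residual-disease readings of a longitudinal plasma
#' series and flags their disagreement. The naive reading ignores variant
#' origin: any baseline plasma variant redetected postoperatively signals
#' residual disease. The CH-aware reading only counts tumor-derived markers
#' (and, by default, plasma-exclusive variants of unknown origin), so a
#' persistent CH clone no longer masquerades as residual disease.
#'
#' @param traj a `marker_trajectories` object from [track_markers()].
#' @param count_emergent should variants first seen postoperatively count
#'   towards the residual-disease flags? Default FALSE.
#' @param count_unknown should baseline plasma variants of unknown origin
#'   count towards the CH-aware flag? Default TRUE (they may be tumor-derived).
#' @return object of class `monitoring_report` with logical flags
#'   `residual_disease_naive`, `residual_disease_ch_aware`,
#'   `ch_persistence`, `discordance_warning`, and the trajectories.
#'   CH-aware detection is always a filter of the naive one, never an
#'   addition.
#' @export
interpret_trajectories <- function(traj, count_emergent = FALSE,
                                   count_unknown = TRUE) {
  if (!inherits(traj, "marker_trajectories")) {
    stop("expected a marker_trajectories object (see track_markers())")
  }
  post <- traj$data[months > 0]
  eligible <- post[emergent == FALSE | count_emergent]
  naive <- any(eligible$detected)
  ch_origins <- "TUMOR_DERIVED_CONCORDANT"
  if (count_unknown) ch_origins <- c(ch_origins, "UNKNOWN_PLASMA_ONLY")
  ch_aware <- any(eligible$detected & eligible$origin %in% ch_origins)
  ch_persistence <- any(post$detected & post$origin == "CH_RELATED")
  structure(list(
    patient_id = traj$patient_id,
    residual_disease_naive = naive,
    residual_disease_ch_aware = ch_aware,
    ch_persistence = ch_persistence,
    discordance_warning = naive != ch_aware,
    count_emergent = count_emergent,
    count_unknown = count_unknown,
    trajectories = traj
  ), class = "monitoring_report")
}

#' @export
print.monitoring_report <- function(x, ...) {
  cat(sprintf("Monitoring report, patient %s\n", x$patient_id))
  cat(sprintf("  residual disease (naive, origin-blind): %s\n",
              x$residual_disease_naive))
  cat(sprintf("  residual disease (CH-aware):            %s\n",
              x$residual_disease_ch_aware))
  cat(sprintf("  CH persistence: %s\n", x$ch_persistence))
  if (isTRUE(x$discordance_warning)) {
    cat("  WARNING: naive reading disagrees with CH-aware reading;\n",
        "  persistent CH variant(s) would be misread as residual disease\n")
  }
  invisible(x)
}
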
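#' Simulation configuration for a matched three-compartment cohort
#'
#' Bundles every knob of the synthetic cohort generator. Defaults encode the
#' study design the package targets: 38 colorectal-cancer patients aged
#' 42-88, CH prevalence rising with age (logistic in age, ~30% of the cohort
#' overall and ~80% above age 80), CH clones at 0.05-1.5% VAF (log-uniform)
#' almost always in TP53 and occasionally GNAS, tumor clones drawn from the
#' observed mutation gene spectrum (TP53 46%, KRAS 19%, PIK3CA 11%, APC 10%,
#' remainder spread over minor genes), and per-compartment molecular depths
#' of 2048x (tumor), 2581x (PBC) and 4004x (plasma).
#'
#' Compartment mixing: a tumor clone with tissue VAF v appears in plasma at
#' `plasma_tumor_fraction[stage] * v`; a CH clone with PBC VAF w appears in
#' tumor tissue at `tumor_leukocyte_infiltration * w` (leukocytes are a
#' minority of tumor cells, so CH VAFs are suppressed in tissue) and in
#' plasma at `leukocyte_plasma_share * w` (cfDNA is predominantly
#' hematopoietic, so plasma CH VAFs overlap plasma ctDNA VAFs).
#'
#' @param seed integer seed controlling the whole cohort (mandatory for
#'   reproducibility).
#' @param n_patients cohort size.
#' @param age_range inclusive age range in years, sampled uniformly.
#' @param stage_probs named probabilities over stages I-IV.
#' @param ch_age_midpoint,ch_age_slope logistic parameters: P(>=1 CH clone) =
#'   plogis(slope * (age - midpoint)).
#' @param ch_vaf_range CH clone VAF range in percent, log-uniform.
#' @param ch_gene_weights sampling weights over CH-capable genes.
#' @param tumor_gene_freqs gene spectrum of tumor mutations (normalized to a
#'   sampling distribution).
#' @param mean_tumor_clones,max_tumor_clones tumor clone count per patient ~
#'   min(Poisson(mean), max).
#' @param tumor_clone_vaf_range tumor clone VAF range in tissue, percent,
#'   log-uniform.
#' @param plasma_tumor_fraction named per-stage shedding factor mapping
#'   tissue VAF to plasma VAF.
#' @param tumor_leukocyte_infiltration leukocyte fraction of tumor tissue.
#' @param leukocyte_plasma_share hematopoietic share scaling CH VAF from PBC
#'   to plasma.
#' @param molecular_depth named target molecular depths (functional families
#'   per locus) per compartment.
#' @param family_size_mean mean reads per family; sizes ~ 1 + Poisson(mean-1).
#' @param per_read_error_rate substitution probability per read.
#' @param postop_scenario `"cured"` (tumor clones vanish from postoperative
#'   plasma), `"residual"` (they persist) or `"relapse_at_t"` (they reappear
#'   from `relapse_at` months). CH clones persist in all scenarios.
#' @param relapse_at months from surgery at which tumor clones reappear
#'   (scenario `"relapse_at_t"` only).
#' @param postop_months postoperative sampling times in months.
#' @param postop_patients which patients get postoperative plasma samples in
#'   [simulate_cohort()]: `"ch"` (those with a CH clone, the monitored subset),
#'   `"all"`, or `"none"`.
#' @param panel panel definition (see [default_panel()]).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 38L,
                       age_range = c(42L, 88L),
                       stage_probs = c(I = 0.26, II = 0.26, III = 0.40,
                                       IV = 0.08),
                       ch_age_midpoint = 73,
                       ch_age_slope = 1 / 9,
                       ch_vaf_range = c(0.05, 1.5),
                       ch_gene_weights = c(TP53 = 10, GNAS = 1),
                       tumor_gene_freqs = c(TP53 = 0.46, KRAS = 0.19,
                                            PIK3CA = 0.11, APC = 0.10,
                                            BRAF = 0.05, EGFR = 0.03,
                                            FBXW7 = 0.03, SMAD4 = 0.03),
                       mean_tumor_clones = 2,
                       max_tumor_clones = 5L,
                       tumor_clone_vaf_range = c(5, 40),
                       plasma_tumor_fraction = c(I = 0.005, II = 0.015,
                                                 III = 0.08, IV = 0.2),
                       tumor_leukocyte_infiltration = 0.5,
                       leukocyte_plasma_share = 1.0,
                       molecular_depth = c(tumor = 2048, pbc = 2581,
                                           plasma = 4004),
                       family_size_mean = 6,
                       per_read_error_rate = 0.001,
                       postop_scenario = c("cured", "residual",
                                           "relapse_at_t"),
                       relapse_at = NA_real_,
                       postop_months = c(7.5, 10, 12.5),
                       postop_patients = c("ch", "all", "none"),
                       panel = default_panel()) {
  postop_scenario <- match.arg(postop_scenario)
  postop_patients <- match.arg(postop_patients)
  panel <- validate_panel(panel)
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_patients >= 0L,
    length(age_range) == 2L, age_range[1] <= age_range[2],
    all(stage_probs >= 0), sum(stage_probs) > 0,
    all(c("I", "II", "III", "IV") %in% names(stage_probs)),
    length(ch_vaf_range) == 2L, all(ch_vaf_range > 0),
    ch_vaf_range[1] <= ch_vaf_range[2],
    all(tumor_clone_vaf_range > 0),
    all(plasma_tumor_fraction >= 0), all(plasma_tumor_fraction <= 1),
    tumor_leukocyte_infiltration >= 0, tumor_leukocyte_infiltration <= 1,
    leukocyte_plasma_share >= 0,
    all(molecular_depth >= 1),
    all(c("tumor", "pbc", "plasma") %in% names(molecular_depth)),
    family_size_mean >= 1,
    per_read_error_rate >= 0, per_read_error_rate <= 1
  )
  if (postop_scenario == "relapse_at_t" && !is.finite(relapse_at)) {
    stop("scenario 'relapse_at_t' requires a finite relapse_at (months)")
  }
  miss <- setdiff(names(ch_gene_weights), panel$gene)
  if (length(miss)) stop("CH gene(s) not on the panel: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(names(tumor_gene_freqs), panel$gene)
  if (length(miss)) stop("tumor gene(s) not on the panel: ",
                         paste(miss, collapse = ", "))
  structure(list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    age_range = age_range, stage_probs = stage_probs / sum(stage_probs),
    ch_age_midpoint = ch_age_midpoint, ch_age_slope = ch_age_slope,
    ch_vaf_range = ch_vaf_range, ch_gene_weights = ch_gene_weights,
    tumor_gene_freqs = tumor_gene_freqs / sum(tumor_gene_freqs),
    mean_tumor_clones = mean_tumor_clones,
    max_tumor_clones = as.integer(max_tumor_clones),
    tumor_clone_vaf_range = tumor_clone_vaf_range,
    plasma_tumor_fraction = plasma_tumor_fraction,
    tumor_leukocyte_infiltration = tumor_leukocyte_infiltration,
    leukocyte_plasma_share = leukocyte_plasma_share,
    molecular_depth = molecular_depth,
    family_size_mean = family_size_mean,
    per_read_error_rate = per_read_error_rate,
    postop_scenario = postop_scenario, relapse_at = relapse_at,
    postop_months = postop_months, postop_patients = postop_patients,
    panel = panel
  ), class = "sim_config")
}

rlogunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Simulate one patient's ground truth
#'
#' Draws age, stage, CH clone (presence ~ Bernoulli(logistic(age)), VAF
#' log-uniform) and tumor clones (count ~ capped Poisson, genes from the
#' mutation spectrum, distinct loci), then derives the expected alternate
#' molecule fraction of every clone in every compartment. Uses the ambient
#' RNG stream; seed via `set.seed()` or use [simulate_truth()].
#'
#' @param config a `sim_config`.
#' @param patient_id identifier attached to the truth records.
#' @return list with `patient` (one-row data.table: id, age, stage, clone
#'   counts) and `clones` (per clone: locus, alleles, source "ch"/"tumor",
#'   source VAF percent, and expected fractions `frac_tumor`, `frac_pbc`,
#'   `frac_plasma` on the 0-1 scale).
#' @export
simulate_patient <- function(config, patient_id = "P001") {
  stopifnot(inherits(config, "sim_config"))
  panel <- config$panel
  age <- sample(seq(config$age_range[1], config$age_range[2]), 1L)
  stage <- sample(names(config$stage_probs), 1L, prob = config$stage_probs)
  clones <- list()
  used_loci <- character()

  # clonal hematopoiesis: 0 or 1 clone, probability rising with age
  p_ch <- stats::plogis(config$ch_age_slope * (age - config$ch_age_midpoint))
  if (runif(1) < p_ch) {
    g <- sample(names(config$ch_gene_weights), 1L,
                prob = config$ch_gene_weights)
    locus <- panel[gene == g][sample(.N, 1L)]
    v <- rlogunif(1, config$ch_vaf_range[1], config$ch_vaf_range[2])
    clones[[length(clones) + 1L]] <- data.table::data.table(
      locus_id = locus$locus_id, gene = g, chrom = locus$chrom,
      pos = locus$pos, ref = locus$ref,
      alt = sample(setdiff(c("A", "C", "G", "T"), locus$ref), 1L),
      source = "ch", vaf_source_pct = v
    )
    used_loci <- locus$locus_id
  }

  # tumor clones: capped Poisson count, genes by mutation spectrum
  k <- min(rpois(1L, config$mean_tumor_clones), config$max_tumor_clones)
  if (k > 0L) {
    genes <- sample(names(config$tumor_gene_freqs), k, replace = TRUE,
                    prob = config$tumor_gene_freqs)
    for (g in genes) {
      avail <- panel[gene == g & !(locus_id %in% used_loci)]
      if (nrow(avail) == 0L) next  # gene's loci exhausted; drop the clone
      locus <- avail[sample(.N, 1L)]
      used_loci <- c(used_loci, locus$locus_id)
      v <- rlogunif(1, config$tumor_clone_vaf_range[1],
                    config$tumor_clone_vaf_range[2])
      clones[[length(clones) + 1L]] <- data.table::data.table(
        locus_id = locus$locus_id, gene = g, chrom = locus$chrom,
        pos = locus$pos, ref = locus$ref,
        alt = sample(setdiff(c("A", "C", "G", "T"), locus$ref), 1L),
        source = "tumor", vaf_source_pct = v
      )
    }
  }
  clones <- if (length(clones)) data.table::rbindlist(clones) else
    data.table::data.table(
      locus_id = character(), gene = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      source = character(), vaf_source_pct = numeric()
    )
  shed <- config$plasma_tumor_fraction[[stage]]
  if (nrow(clones)) {
    clones[, `:=`(
      frac_tumor = data.table::fifelse(
        source == "tumor", vaf_source_pct,
        config$tumor_leukocyte_infiltration * vaf_source_pct) / 100,
      frac_pbc = data.table::fifelse(source == "ch", vaf_source_pct, 0) / 100,
      frac_plasma = data.table::fifelse(
        source == "tumor", shed * vaf_source_pct,
        config$leukocyte_plasma_share * vaf_source_pct) / 100
    )]
  } else {
    clones[, `:=`(frac_tumor = numeric(), frac_pbc = numeric(),
                  frac_plasma = numeric())]
  }
  clones[, patient_id := patient_id]
  list(
    patient = data.table::data.table(
      patient_id = patient_id, age = age, stage = stage,
      n_ch_clones = sum(clones$source == "ch"),
      n_tumor_clones = sum(clones$source == "tumor")
    ),
    clones = clones[]
  )
}

#' Simulate a cohort's ground truth (no reads)
#'
#' Seeds the RNG from `config$seed` and applies [simulate_patient()] across
#' the cohort. Identical config and seed give identical truth.
#'
#' @param config a `sim_config`.
#' @return object of class `sim_truth`: `patients` and `clones` tables plus
#'   the config.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  per <- lapply(ids, function(id) simulate_patient(config, id))
  structure(list(
    patients = data.table::rbindlist(lapply(per, `[[`, "patient")),
    clones = data.table::rbindlist(lapply(per, `[[`, "clones")),
    config = config
  ), class = "sim_truth")
}

# expected plasma fraction of each clone at a postoperative time
plasma_fraction_at <- function(clones, config, months) {
  if (months == 0) return(clones$frac_plasma)
  tumor_on <- switch(config$postop_scenario,
    cured = FALSE,
    residual = TRUE,
    relapse_at_t = months >= config$relapse_at
  )
  data.table::fifelse(clones$source == "ch", clones$frac_plasma,
                      if (tumor_on) clones$frac_plasma else 0)
}

compartment_fractions <- function(truth, pid, compartment, months) {
  cl <- truth$clones[truth$clones[["patient_id"]] == pid, ]
  f <- switch(compartment,
    tumor = cl$frac_tumor,
    pbc = cl$frac_pbc,
    plasma = plasma_fraction_at(cl, truth$config, months),
    stop("unknown compartment: ", compartment)
  )
  list(clones = cl, frac = f)
}

#' Emit UMI-tagged reads for one sample
#'
#' Realizes one compartment/timepoint of a patient as tagged reads: per
#' panel locus the number of molecular families is Poisson(target molecular
#' depth), family sizes are 1 + Poisson(mean - 1), each family's source
#' molecule carries the clone's alternate allele with probability equal to
#' that clone's expected compartment fraction, every read copies its
#' molecule's allele, and sequencing error substitutes a uniformly chosen
#' wrong base per read with probability `per_read_error_rate`. UMIs never
#' collide between families. Tumor and PBC exist at surgery only
#' (months = 0); plasma at any timepoint, with postoperative tumor-clone
#' fractions governed by the configured scenario (CH fractions persist).
#'
#' Uses the ambient RNG stream; [simulate_cohort()] seeds one stream per
#' sample for order-independent determinism.
#'
#' @param truth a `sim_truth`.
#' @param patient_id which patient.
#' @param compartment `"tumor"`, `"pbc"` or `"plasma"`.
#' @param months months from surgery (0 = at surgery / preoperative).
#' @param config overrides `truth$config` if supplied.
#' @return `data.table` of tagged reads (`locus_id`, `umi`, `allele`).
#' @export
emit_reads <- function(truth, patient_id, compartment, months = 0,
                       config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (compartment %in% c("tumor", "pbc") && months != 0) {
    stop("tumor and PBC samples exist only at surgery (months = 0)")
  }
  if (!patient_id %in% truth$patients$patient_id) {
    stop("unknown patient: ", patient_id)
  }
  cf <- compartment_fractions(truth, patient_id, compartment, months)
  panel <- config$panel
  depth <- config$molecular_depth[[compartment]]
  nloc <- nrow(panel)
  nfam <- rpois(nloc, depth)
  tot <- sum(nfam)
  if (tot == 0L) {
    return(data.table::data.table(locus_id = character(), umi = character(),
                                  allele = character()))
  }
  loc_idx <- rep.int(seq_len(nloc), nfam)
  # per-family alternate fraction and allele (0 / NA at clone-free loci)
  frac_by_locus <- numeric(nloc)
  alt_by_locus <- rep(NA_character_, nloc)
  if (nrow(cf$clones)) {
    m <- match(cf$clones$locus_id, panel$locus_id)
    frac_by_locus[m] <- cf$frac
    alt_by_locus[m] <- cf$clones$alt
  }
  is_alt <- runif(tot) < frac_by_locus[loc_idx]
  mol <- ifelse(is_alt, alt_by_locus[loc_idx], panel$ref[loc_idx])
  sizes <- 1L + rpois(tot, config$family_size_mean - 1)
  ridx <- rep.int(seq_len(tot), sizes)
  allele <- mol[ridx]
  if (config$per_read_error_rate > 0) {
    err <- which(runif(length(allele)) < config$per_read_error_rate)
    if (length(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- match(allele[err], bases)
      step <- sample.int(3L, length(err), replace = TRUE)
      allele[err] <- bases[((cur - 1L + step) %% 4L) + 1L]
    }
  }
  data.table::data.table(
    locus_id = panel$locus_id[loc_idx][ridx],
    umi = paste0("U", ridx),
    allele = allele
  )
}

cohort_sample_plan <- function(truth) {
  config <- truth$config
  pats <- truth$patients
  if (nrow(pats) == 0L) {
    return(data.table::data.table(
      patient_id = character(), compartment = character(),
      timepoint = character(), months = numeric()
    ))
  }
  plans <- lapply(seq_len(nrow(pats)), function(i) {
    pid <- pats$patient_id[i]
    base <- data.table::data.table(
      patient_id = pid,
      compartment = c("tumor", "pbc", "plasma"),
      timepoint = "preop", months = 0
    )
    monitored <- switch(config$postop_patients,
      all = TRUE,
      none = FALSE,
      ch = pats$n_ch_clones[i] > 0L
    )
    if (monitored && length(config$postop_months)) {
      post <- data.table::data.table(
        patient_id = pid, compartment = "plasma",
        timepoint = sprintf("postop%d", seq_along(config$postop_months)),
        months = config$postop_months
      )
      base <- data.table::rbindlist(list(base, post))
    }
    base
  })
  data.table::rbindlist(plans)
}

sample_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
}

#' Simulate a full matched cohort as tagged-read data
#'
#' Generates ground truth with [simulate_truth()], then realizes every
#' sample in the plan (tumor, PBC and preoperative plasma for all patients;
#' postoperative plasma per `config$postop_patients`) with [emit_reads()].
#' Each sample gets its own derived RNG seed, so output is byte-identical
#' for identical config and seed regardless of processing order.
#'
#' @param config a `sim_config`.
#' @param out_dir if given, tagged reads are written as one TSV per sample
#'   together with `panel.tsv`, `truth.json` and `manifest.tsv`, and only
#'   the manifest and truth are returned; existing files are never
#'   overwritten (path collisions are an error). If `NULL`, reads are
#'   returned in memory (only sensible for small configs).
#' @param callback optional `function(reads, meta)` invoked per sample in
#'   place of storage; use for streaming large cohorts through the caller.
#' @return list with `truth`, `manifest`, and (when neither `out_dir` nor
#'   `callback` is given) `reads`, a named list of tagged-read tables.
#' @export
simulate_cohort <- function(config, out_dir = NULL, callback = NULL) {
  truth <- simulate_truth(config)
  plan <- cohort_sample_plan(truth)
  plan[, file := sprintf("%s_%s_%s.tsv", patient_id, compartment, timepoint)]
  if (anyDuplicated(plan$file)) stop("output path collision in sample plan")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    targets <- c(file.path(out_dir, plan$file),
                 file.path(out_dir, c("panel.tsv", "truth.json",
                                      "manifest.tsv")))
    clash <- targets[file.exists(targets)]
    if (length(clash)) {
      stop("refusing to overwrite existing file(s): ",
           paste(basename(clash), collapse = ", "))
    }
  }
  reads_out <- if (is.null(out_dir) && is.null(callback)) list() else NULL
  for (i in seq_len(nrow(plan))) {
    set.seed(sample_seed(config$seed, i))
    rd <- emit_reads(truth, plan$patient_id[i], plan$compartment[i],
                     plan$months[i])
    meta <- plan[i]
    if (!is.null(out_dir)) {
      data.table::fwrite(rd, file.path(out_dir, plan$file[i]), sep = "\t")
    } else if (!is.null(callback)) {
      callback(rd, meta)
    } else {
      reads_out[[plan$file[i]]] <- rd
    }
  }
  if (!is.null(out_dir)) {
    write_panel(config$panel, file.path(out_dir, "panel.tsv"))
    jsonlite::write_json(
      list(patients = truth$patients, clones = truth$clones,
           seed = config$seed),
      file.path(out_dir, "truth.json"), dataframe = "rows", digits = NA)
    data.table::fwrite(plan, file.path(out_dir, "manifest.tsv"), sep = "\t")
  }
  out <- list(truth = truth, manifest = plan[])
  if (!is.null(reads_out)) out$reads <- reads_out
  out
}

#' Simulate a cohort and run the caller over every sample
#'
#' Streaming convenience wrapper: each sample's reads are generated, called
#' with [call_sample()] and discarded, keeping memory flat at ultradeep
#' depths.
#'
#' @param config a `sim_config`.
#' @param min_family_reads,min_alt_families caller thresholds.
#' @param keep_depths also collect per-sample depth metrics?
#' @return list with `calls` (all samples stacked, with `patient`,
#'   `compartment`, `timepoint`, `months` columns), `truth`, and optionally
#'   `depths`.
#' @export
simulate_and_call <- function(config, min_family_reads = 3L,
                              min_alt_families = 2L, keep_depths = FALSE) {
  calls <- list()
  depths <- list()
  truth_env <- new.env()
  res <- simulate_cohort(config, callback = function(rd, meta) {
    cs <- call_sample(rd, config$panel, min_family_reads, min_alt_families,
                      compartment = meta$compartment,
                      timepoint = meta$timepoint,
                      patient = meta$patient_id)
    cc <- cs$calls
    cc[, months := meta$months]
    calls[[length(calls) + 1L]] <<- cc
    if (keep_depths) {
      dd <- cs$depths
      dd[, `:=`(patient = meta$patient_id, compartment = meta$compartment,
                timepoint = meta$timepoint)]
      depths[[length(depths) + 1L]] <<- dd
    }
  })
  out <- list(
    calls = if (length(calls)) data.table::rbindlist(calls) else
      data.table::data.table(),
    truth = res$truth
  )
  if (keep_depths) out$depths <- data.table::rbindlist(depths)
  out
}

#' Fast family-level cohort simulation (no reads)
#'
#' Shortcut used by statistical property checks that need hundreds of
#' replicates: per sample and locus the functional-family count is
#' Poisson(depth) and the alternate-family count binomial in the clone's
#' compartment fraction, i.e. the caller's sampling distribution at zero
#' read error. Read-level effects (family-size filtering, consensus errors)
#' are bypassed; the read-level path is validated separately.
#'
#' @inheritParams simulate_and_call
#' @return list with `calls` and `truth` shaped like [simulate_and_call()].
#' @export
simulate_calls <- function(config, min_alt_families = 2L) {
  truth <- simulate_truth(config)
  plan <- cohort_sample_plan(truth)
  panel <- config$panel
  out <- list()
  for (i in seq_len(nrow(plan))) {
    set.seed(sample_seed(config$seed, i))
    cf <- compartment_fractions(truth, plan$patient_id[i],
                                plan$compartment[i], plan$months[i])
    if (!nrow(cf$clones)) next
    depth <- config$molecular_depth[[plan$compartment[i]]]
    tot <- rpois(nrow(cf$clones), depth)
    altn <- rbinom(nrow(cf$clones), tot, cf$frac)
    keep <- altn >= min_alt_families
    if (!any(keep)) next
    cl <- cf$clones[keep]
    out[[length(out) + 1L]] <- data.table::data.table(
      patient = plan$patient_id[i], compartment = plan$compartment[i],
      timepoint = plan$timepoint[i], months = plan$months[i],
      locus_id = cl$locus_id, chrom = cl$chrom, pos = cl$pos,
      ref = cl$ref, alt = cl$alt, gene = cl$gene,
      alt_families = altn[keep], total_functional_families = tot[keep],
      vaf_pct = 100 * altn[keep] / tot[keep],
      read_depth = NA_integer_
    )
  }
  list(
    calls = if (length(out)) data.table::rbindlist(out) else
      data.table::data.table(),
    truth = truth
  )
}

#' Triage a cohort from a stacked call table
#'
#' Splits a call table (e.g. from [simulate_and_call()] or
#' [read_variant_table()]) by patient and compartment, takes the
#' preoperative plasma timepoint as baseline, and runs [triage_patient()]
#' per patient.
#'
#' @param calls call table with `patient`, `compartment`, `timepoint`
#'   columns in addition to the variant fields.
#' @param patients data.frame with `patient_id` and optional `stage`, `age`;
#'   patients absent from `calls` get empty triages.
#' @return a `cohort_triage`.
#' @export
triage_cohort <- function(calls, patients) {
  calls <- data.table::as.data.table(calls)
  patients <- data.table::as.data.table(patients)
  if (!"patient_id" %in% names(patients)) {
    stop("patients table is missing required column: patient_id")
  }
  if (!"stage" %in% names(patients)) patients[, stage := NA_character_]
  if (!"age" %in% names(patients)) patients[, age := NA_real_]
  triages <- lapply(seq_len(nrow(patients)), function(i) {
    pid <- patients$patient_id[i]
    pc <- if (nrow(calls)) calls[patient == pid] else calls
    pick <- function(comp) {
      if (nrow(pc) == 0L) return(NULL)
      x <- pc[compartment == comp]
      if (comp == "plasma" && "timepoint" %in% names(x)) {
        x <- x[timepoint == "preop" | is.na(timepoint)]
      }
      if (nrow(x)) x else NULL
    }
    triage_patient(tumor = pick("tumor"), pbc = pick("pbc"),
                   plasma = pick("plasma"), patient_id = pid,
                   stage = patients$stage[i], age = patients$age[i])
  })
  as_cohort(triages)
}
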
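# truth object with hand-set compartment fractions, for targeted read tests
fake_truth <- function(cfg, clones) {
  structure(list(
    patients = data.table::data.table(
      patient_id = "P001", age = 60L, stage = "II",
      n_ch_clones = sum(clones$source == "ch"),
      n_tumor_clones = sum(clones$source == "tumor")),
    clones = clones, config = cfg
  ), class = "sim_truth")
}

small_cfg <- function(...) {
  sim_config(seed = 1, n_patients = 2,
             molecular_depth = c(tumor = 150, pbc = 150, plasma = 200),
             postop_patients = "none", ...)
}

test_that("fixed seed reproduces the cohort byte for byte", {
  a <- simulate_cohort(small_cfg())
  b <- simulate_cohort(small_cfg())
  expect_equal(a$truth$clones, b$truth$clones)
  expect_identical(a$reads, b$reads)
  expect_equal(a$manifest, b$manifest)
})

test_that("zero CH probability yields no CH clones", {
  cfg <- small_cfg(ch_age_midpoint = 1e4)  # logistic ~ 0 over all ages
  truth <- simulate_truth(cfg)
  expect_equal(sum(truth$clones$source == "ch"), 0L)
})

test_that("error 0 with no clones emits only reference reads and no calls", {
  cfg <- small_cfg(ch_age_midpoint = 1e4, mean_tumor_clones = 0,
                   per_read_error_rate = 0)
  res <- simulate_cohort(cfg)
  panel <- cfg$panel
  for (nm in names(res$reads)) {
    rd <- res$reads[[nm]]
    ref <- panel$ref[match(rd$locus_id, panel$locus_id)]
    expect_true(all(rd$allele == ref), info = nm)
    expect_equal(nrow(call_sample(rd, panel)$calls), 0L, info = nm)
  }
})

test_that("caller recovers a 50% alt fraction within binomial limits", {
  cfg <- sim_config(seed = 3, n_patients = 1,
                    molecular_depth = c(tumor = 2000, pbc = 100,
                                        plasma = 100),
                    per_read_error_rate = 0)
  clones <- data.table::data.table(
    locus_id = "KRAS_G12", gene = "KRAS", chrom = "chr12", pos = 25398284L,
    ref = "C", alt = "T", source = "tumor", vaf_source_pct = 50,
    frac_tumor = 0.5, frac_pbc = 0, frac_plasma = 0.5, patient_id = "P001")
  truth <- fake_truth(cfg, clones)
  set.seed(99)
  rd <- emit_reads(truth, "P001", "tumor")
  call <- call_sample(rd, cfg$panel)$calls
  expect_equal(nrow(call), 1L)
  n <- call$total_functional_families
  half_width <- 100 * stats::qnorm(0.995) * sqrt(0.25 / n)
  expect_lt(abs(call$vaf_pct - 50), half_width)
})

test_that("scenario 'cured': postop plasma keeps CH, drops tumor clones", {
  cfg <- sim_config(seed = 4, n_patients = 1, per_read_error_rate = 0,
                    molecular_depth = c(tumor = 100, pbc = 100,
                                        plasma = 1500),
                    postop_scenario = "cured")
  clones <- data.table::data.table(
    locus_id = c("TP53_C238S", "KRAS_G12"), gene = c("TP53", "KRAS"),
    chrom = c("chr17", "chr12"), pos = c(7577568L, 25398284L),
    ref = c("C", "C"), alt = c("G", "T"), source = c("ch", "tumor"),
    vaf_source_pct = c(1.0, 20), frac_tumor = c(0.005, 0.2),
    frac_pbc = c(0.01, 0), frac_plasma = c(0.01, 0.002),
    patient_id = "P001")
  truth <- fake_truth(cfg, clones)
  set.seed(77)
  post <- emit_reads(truth, "P001", "plasma", months = 10)
  expect_gt(sum(post$allele == "G" & post$locus_id == "TP53_C238S"), 0)
  expect_equal(sum(post$allele == "T" & post$locus_id == "KRAS_G12"), 0L)

  # 'relapse_at_t' restores the tumor clone from t onward
  cfg2 <- sim_config(seed = 4, n_patients = 1, per_read_error_rate = 0,
                     molecular_depth = c(tumor = 100, pbc = 100,
                                         plasma = 1500),
                     postop_scenario = "relapse_at_t", relapse_at = 9)
  truth2 <- fake_truth(cfg2, clones)
  set.seed(78)
  before <- emit_reads(truth2, "P001", "plasma", months = 6)
  after <- emit_reads(truth2, "P001", "plasma", months = 12)
  expect_equal(sum(before$allele == "T" & before$locus_id == "KRAS_G12"), 0L)
  expect_gt(sum(after$allele == "T" & after$locus_id == "KRAS_G12"), 0)
})

test_that("simulated plasma reaches the target molecular depth within 5%", {
  cfg <- sim_config(seed = 12, n_patients = 1, postop_patients = "none")
  truth <- simulate_truth(cfg)
  set.seed(12)
  rd <- emit_reads(truth, "P001", "plasma")
  d <- call_sample(rd, cfg$panel)$depths
  expect_lt(abs(median(d$molecular_depth) - 4004) / 4004, 0.05)
  expect_true(all(d$molecular_depth <= d$sequencing_depth))
})

test_that("tumor and PBC samples exist only at surgery", {
  truth <- simulate_truth(small_cfg())
  expect_error(emit_reads(truth, "P001", "tumor", months = 3), "surgery")
  expect_error(emit_reads(truth, "NOPE", "plasma"), "unknown patient")
})

test_that("empty cohort gives an empty manifest and a valid truth", {
  res <- simulate_cohort(sim_config(seed = 5, n_patients = 0))
  expect_equal(nrow(res$manifest), 0L)
  expect_equal(nrow(res$truth$patients), 0L)
})

test_that("cohort written to disk round-trips through the caller", {
  dir <- file.path(tempdir(), "simrt")
  unlink(dir, recursive = TRUE)
  cfg <- small_cfg()
  res <- simulate_cohort(cfg, out_dir = dir)
  man <- data.table::fread(file.path(dir, "manifest.tsv"))
  expect_equal(nrow(man), 6L)  # 2 patients x 3 compartments
  expect_true(file.exists(file.path(dir, "panel.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))

  direct <- simulate_and_call(cfg)
  panel <- read_panel(file.path(dir, "panel.tsv"))
  from_disk <- data.table::rbindlist(lapply(seq_len(nrow(man)), function(i) {
    rd <- read_tagged_reads(file.path(dir, man$file[i]))
    call_sample(rd, panel, compartment = man$compartment[i],
                timepoint = man$timepoint[i],
                patient = man$patient_id[i])$calls
  }))
  expect_equal(from_disk[order(patient, compartment, chrom, pos)]$vaf_pct,
               direct$calls[order(patient, compartment, chrom, pos)]$vaf_pct)

  # collision protection: never overwrite an existing dataset
  expect_error(simulate_cohort(cfg, out_dir = dir), "refusing to overwrite")
})

test_that("postop sampling plan follows the postop_patients policy", {
  cfg <- sim_config(seed = 6, n_patients = 6,
                    molecular_depth = c(tumor = 50, pbc = 50, plasma = 50),
                    postop_patients = "ch")
  truth <- simulate_truth(cfg)
  plan <- chtriage:::cohort_sample_plan(truth)
  ch_pat <- truth$patients[truth$patients$n_ch_clones > 0]$patient_id
  post <- plan[plan$months > 0]
  expect_setequal(unique(post$patient_id), ch_pat)
  expect_equal(sort(unique(post$months)), c(7.5, 10, 12.5))
})

test_that("family-level fast path matches the read-level caller statistically", {
  # same config through both paths; compare the per-variant VAF estimates
  cfg <- sim_config(seed = 8, n_patients = 3, per_read_error_rate = 0,
                    postop_patients = "none",
                    molecular_depth = c(tumor = 800, pbc = 800, plasma = 800))
  fast <- simulate_calls(cfg)
  slow <- simulate_and_call(cfg)
  truth <- fast$truth
  # every tumor clone (tissue VAF >= 5%) must be called in tumor by both
  tc <- truth$clones[truth$clones$source == "tumor"]
  for (i in seq_len(nrow(tc))) {
    for (calls in list(fast$calls, slow$calls)) {
      hit <- calls[calls$patient == tc$patient_id[i] &
                     calls$compartment == "tumor" &
                     calls$locus_id == tc$locus_id[i], ]
      expect_equal(nrow(hit), 1L)
      # molecular-depth binomial sampling: ~5 sigma tolerance
      p <- tc$frac_tumor[i]
      sigma <- 100 * sqrt(p * (1 - p) / hit$total_functional_families)
      expect_lt(abs(hit$vaf_pct - 100 * p), 5 * sigma + 1e-9)
    }
  }
})
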
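test_that("rank-sum matches its exact enumeration examples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$u_statistic, 0)
  expect_equal(r$p_value, 0.10)
  expect_equal(r$method, "exact")

  # identical multisets: U = n^2/2, p essentially 1
  r <- rank_sum_test(c(2, 4, 7, 7), c(2, 4, 7, 7))
  expect_equal(r$u_statistic, 16 / 2)
  expect_gte(r$p_value, 0.99)

  # smallest valid input
  r <- rank_sum_test(1, 2)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1)

  expect_error(rank_sum_test(numeric(), 1), "non-empty")
})

test_that("rank-sum agrees with the independent enumeration oracle", {
  set.seed(606)
  for (i in 1:30) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- sample(1:8, na, replace = TRUE)  # ties likely
    b <- sample(1:8, nb, replace = TRUE)
    got <- rank_sum_test(a, b)
    want <- oracle_rank_sum(a, b)
    expect_equal(got$u_statistic, want$u)
    expect_equal(got$p_value, want$p)
  }
})

test_that("rank-sum agrees with stats::wilcox.test on tie-free data", {
  set.seed(707)
  for (i in 1:20) {
    a <- sample(1:1000, sample(2:8, 1))
    b <- sample(2000:3000, sample(2:8, 1))  # disjoint: no ties
    got <- rank_sum_test(a, b)
    want <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE,
                                                correct = FALSE))
    expect_equal(got$u_statistic, unname(want$statistic))
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
})

test_that("exact and approximate branches agree at the crossover size", {
  # n = 9 per group: the smallest case routed to the approximation
  set.seed(808)
  for (i in 1:20) {
    a <- rnorm(9); b <- rnorm(9, mean = runif(1, -1, 1))
    pe <- rank_sum_test(a, b, exact = TRUE, max_enumeration = 5e6)$p_value
    pa <- rank_sum_test(a, b)$p_value
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("rank-sum invariances: group swap and location shift", {
  set.seed(909)
  for (i in 1:20) {
    na <- sample(2:7, 1); nb <- sample(2:7, 1)
    a <- sample(1:10, na, replace = TRUE)
    b <- sample(1:10, nb, replace = TRUE)
    r1 <- rank_sum_test(a, b)
    r2 <- rank_sum_test(b, a)
    expect_equal(r2$u_statistic, na * nb - r1$u_statistic)
    expect_equal(r2$p_value, r1$p_value)
    r3 <- rank_sum_test(a + 17.3, b + 17.3)
    expect_equal(r3$u_statistic, r1$u_statistic)
    expect_equal(r3$p_value, r1$p_value)
  }
})

make_vaf_cohort <- function(td_tumor, ch_pbc, ch_tumor = NULL,
                            ch_plasma = NULL, td_plasma = NULL) {
  triages <- list()
  for (i in seq_along(td_tumor)) {
    triages[[length(triages) + 1]] <- triage_patient(
      tumor = data.frame(chrom = "chr1", pos = i, ref = "A", alt = "T",
                         vaf_pct = td_tumor[i]),
      plasma = if (!is.null(td_plasma))
        data.frame(chrom = "chr1", pos = i, ref = "A", alt = "T",
                   vaf_pct = td_plasma[i]),
      patient_id = paste0("T", i))
  }
  for (i in seq_along(ch_pbc)) {
    key <- data.frame(chrom = "chr2", pos = i, ref = "C", alt = "G")
    triages[[length(triages) + 1]] <- triage_patient(
      pbc = transform(key, vaf_pct = ch_pbc[i]),
      tumor = if (!is.null(ch_tumor))
        transform(key, vaf_pct = ch_tumor[i]),
      plasma = if (!is.null(ch_plasma))
        transform(key, vaf_pct = ch_plasma[i]),
      patient_id = paste0("C", i))
  }
  as_cohort(triages)
}

test_that("VAF comparison separates suppressed CH in tumor tissue", {
  co <- make_vaf_cohort(td_tumor = c(25, 30, 40, 18, 22),
                        ch_pbc = c(0.5, 0.3, 0.8),
                        ch_tumor = c(0.2, 0.15, 0.4))
  cmp <- compare_vaf_by_origin(co, "tumor")
  expect_equal(cmp$n_a, 5L)
  expect_equal(cmp$n_b, 3L)
  expect_true(cmp$significant)
  expect_gt(cmp$mean_a, cmp$mean_b)
})

test_that("plasma comparison excludes unknown-origin variants", {
  co <- make_vaf_cohort(td_tumor = c(25, 30), td_plasma = c(0.4, 0.6),
                        ch_pbc = c(0.5, 0.3), ch_plasma = c(0.45, 0.55))
  # add a plasma-exclusive (unknown) variant that must not enter the test
  co2 <- as_cohort(c(unclass(co), list(
    triage_patient(plasma = data.frame(chrom = "chr9", pos = 1, ref = "A",
                                       alt = "T", vaf_pct = 99),
                   patient_id = "U1"))))
  cmp <- compare_vaf_by_origin(co2, "plasma")
  expect_equal(cmp$n_a + cmp$n_b, 4L)
  expect_false(99 %in% c(cmp$values_a, cmp$values_b))
  expect_false(cmp$significant)
})

test_that("two singleton groups still get an exact test", {
  co <- make_vaf_cohort(td_tumor = 30, ch_pbc = 0.5, ch_tumor = 0.2)
  cmp <- compare_vaf_by_origin(co, "tumor")
  expect_equal(cmp$method, "exact")
  expect_equal(cmp$p_value, 1)
})

test_that("empty comparison groups are rejected with a diagnostic", {
  co <- make_vaf_cohort(td_tumor = c(25, 30), ch_pbc = numeric())
  expect_error(compare_vaf_by_origin(co, "tumor"), "CH-related")
})

test_that("age-binned CH prevalence reports per-decade fractions", {
  mk <- function(id, age, ch) triage_patient(
    pbc = if (ch) mk_calls(100), patient_id = id, age = age)
  co <- as_cohort(list(
    mk("P1", 82, TRUE), mk("P2", 85, TRUE),           # [80,90): 100%
    mk("P3", 55, FALSE), mk("P4", 58, TRUE),          # [50,60): 50%
    mk("P5", 44, FALSE)                               # [40,50): 0%
  ))
  ap <- ch_prevalence_by_age(co)
  tab <- ap$table
  expect_equal(sum(tab$n_patients), 5L)
  expect_equal(tab$prevalence_pct[tab$bin == "[80,90)"], 100)
  expect_equal(tab$prevalence_pct[tab$bin == "[50,60)"], 50)
  expect_equal(tab$prevalence_pct[tab$bin == "[40,50)"], 0)
  # [60,70) and [70,80) exist but are empty: n 0, prevalence undefined
  expect_true(all(c("[60,70)", "[70,80)") %in% tab$bin))
  expect_true(all(is.na(tab$prevalence_pct[tab$n_patients == 0])))
})

test_that("patients with missing age are excluded with a warning", {
  co <- as_cohort(list(
    triage_patient(pbc = mk_calls(100), patient_id = "P1", age = 81),
    triage_patient(patient_id = "P2")
  ))
  expect_warning(ap <- ch_prevalence_by_age(co), "missing age")
  expect_equal(sum(ap$table$n_patients), 1L)
})

test_that("simulator's logistic age curve is recovered at n = 500", {
  cfg <- sim_config(seed = 9090, n_patients = 500, ch_age_midpoint = 80,
                    ch_age_slope = 0.5)
  truth <- simulate_truth(cfg)
  # perfect-detection cohort straight from truth: in_pbc = has a CH clone
  triages <- lapply(seq_len(nrow(truth$patients)), function(i) {
    p <- truth$patients[i]
    triage_patient(pbc = if (p$n_ch_clones > 0) mk_calls(100),
                   patient_id = p$patient_id, age = p$age)
  })
  ap <- ch_prevalence_by_age(as_cohort(triages))
  tab <- ap$table[ap$table$n_patients >= 20, ]
  ages <- truth$patients$age
  for (j in seq_len(nrow(tab))) {
    sel <- ages >= tab$age_lo[j] & ages < tab$age_hi[j]
    expected <- mean(stats::plogis(0.5 * (ages[sel] - 80)))
    ci <- stats::binom.test(tab$n_with_pbc_variant[j],
                            tab$n_patients[j])$conf.int
    expect_true(expected >= ci[1] && expected <= ci[2],
                info = tab$bin[j])
  }
  # the high-age regime: most patients above 80 carry a CH clone
  old <- truth$patients[ages > 80]
  expect_gte(mean(old$n_ch_clones > 0), 0.7)
})
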
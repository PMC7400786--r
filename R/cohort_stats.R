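#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U with midrank handling of ties. For small groups
#' (min group size <= 8, and as long as the enumeration stays below
#' `max_enumeration` subsets) the permutation distribution of U is
#' enumerated exactly; otherwise the normal approximation with tie-corrected
#' variance and a continuity correction is used. The U statistic reported is
#' for the first group: `U = sum(ranks_a) - n_a (n_a + 1) / 2`.
#'
#' @param values_a,values_b numeric vectors, both non-empty.
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) picks by group size.
#' @param max_enumeration cap on the number of enumerated rank subsets.
#' @return list with `u_statistic`, `p_value`, `n_a`, `n_b`, `method`
#'   ("exact" or "normal_approx").
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.10
rank_sum_test <- function(values_a, values_b, exact = NULL,
                          max_enumeration = 1e6) {
  values_a <- as.numeric(values_a)
  values_b <- as.numeric(values_b)
  n_a <- length(values_a)
  n_b <- length(values_b)
  if (n_a == 0L || n_b == 0L) {
    stop("rank_sum_test requires two non-empty groups (n_a = ", n_a,
         ", n_b = ", n_b, ")")
  }
  if (anyNA(values_a) || anyNA(values_b)) stop("values must not contain NA")
  pooled <- c(values_a, values_b)
  r <- rank(pooled)  # midranks
  n <- n_a + n_b
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (is.null(exact)) {
    exact <- min(n_a, n_b) <= 8L && choose(n, n_a) <= max_enumeration
  }
  if (exact && choose(n, n_a) > max_enumeration) {
    warning("enumeration too large; falling back to normal approximation")
    exact <- FALSE
  }
  if (exact) {
    idx <- utils::combn(n, n_a)
    rdist <- colSums(matrix(r[idx], nrow = n_a))
    udist <- rdist - n_a * (n_a + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(udist <= u + eps), mean(udist >= u - eps))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n_a * n_b / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- u - mu
      z <- (d - sign(d) * 0.5) / sqrt(sigma2)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  list(u_statistic = u, p_value = p, n_a = n_a, n_b = n_b, method = method)
}

#' Compare VAF of tumor-derived vs CH-related mutations
#'
#' Rank-sum comparison of variant allele frequencies between tumor-derived
#' and CH-related mutations within one compartment of a triaged cohort. In
#' tumor tissue the tumor-derived group pools concordant and tumor-only
#' variants; in plasma it is the concordant (tumor-derived) group only and
#' variants of unknown origin are excluded. Although the underlying test
#' compares distributions by ranks, group means are reported alongside for
#' display.
#'
#' @param cohort a `cohort_triage`.
#' @param compartment `"tumor"` or `"plasma"`.
#' @param alpha significance level (default 0.05).
#' @return object of class `vaf_group_comparison`: group labels, values,
#'   sizes, means, `u_statistic`, `p_value`, `significant`.
#' @export
compare_vaf_by_origin <- function(cohort, compartment = c("tumor", "plasma"),
                                  alpha = 0.05) {
  compartment <- match.arg(compartment)
  v <- cohort_variants(cohort)
  if (compartment == "tumor") {
    v <- v[in_tumor == TRUE]
    td <- v[origin %in% c("TUMOR_DERIVED_CONCORDANT", "TUMOR_ONLY")]$vaf_tumor
    ch <- v[origin == "CH_RELATED"]$vaf_tumor
  } else {
    v <- v[in_plasma == TRUE & origin != "UNKNOWN_PLASMA_ONLY"]
    td <- v[origin == "TUMOR_DERIVED_CONCORDANT"]$vaf_plasma
    ch <- v[origin == "CH_RELATED"]$vaf_plasma
  }
  if (length(td) == 0L) {
    stop("no tumor-derived mutations with a ", compartment,
         " VAF; cannot compare groups")
  }
  if (length(ch) == 0L) {
    stop("no CH-related mutations with a ", compartment,
         " VAF; cannot compare groups")
  }
  res <- rank_sum_test(td, ch)
  structure(list(
    compartment = compartment,
    group_a_label = "tumor_derived", group_b_label = "ch_related",
    values_a = td, values_b = ch,
    n_a = res$n_a, n_b = res$n_b,
    mean_a = mean(td), mean_b = mean(ch),
    u_statistic = res$u_statistic, p_value = res$p_value,
    method = res$method,
    alpha = alpha, significant = res$p_value < alpha
  ), class = "vaf_group_comparison")
}

#' @export
print.vaf_group_comparison <- function(x, ...) {
  cat(sprintf(
    "VAF comparison (%s compartment): %s (n=%d, mean %.2f%%) vs %s (n=%d, mean %.2f%%)\n",
    x$compartment, x$group_a_label, x$n_a, x$mean_a,
    x$group_b_label, x$n_b, x$mean_b))
  cat(sprintf("  Mann-Whitney U = %.1f, two-sided P = %.4g (%s), %s at alpha %.2f\n",
              x$u_statistic, x$p_value, x$method,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  invisible(x)
}

#' CH prevalence by age bin
#'
#' Fraction of patients carrying at least one PBC-detected (CH-related)
#' variant, per age bin of `bin_width_years` (decades by default). Patients
#' with missing age are excluded from all denominators with a warning.
#'
#' @param cohort a `cohort_triage` with ages.
#' @param bin_width_years bin width in years (default 10).
#' @return object of class `age_prevalence`: a data.table with `age_lo`,
#'   `age_hi`, `bin` label, `n_patients`, `n_with_pbc_variant`,
#'   `prevalence_pct` (NA for empty bins).
#' @export
ch_prevalence_by_age <- function(cohort, bin_width_years = 10) {
  if (bin_width_years <= 0) stop("bin_width_years must be positive")
  ages <- vapply(cohort, function(p) as.numeric(p$age), numeric(1))
  has_ch <- vapply(cohort, function(p) any(p$variants$in_pbc), logical(1))
  if (anyNA(ages)) {
    warning(sum(is.na(ages)), " patient(s) with missing age excluded")
    has_ch <- has_ch[!is.na(ages)]
    ages <- ages[!is.na(ages)]
  }
  if (!length(ages)) stop("no patients with a known age")
  lo <- floor(min(ages) / bin_width_years) * bin_width_years
  hi <- ceiling((max(ages) + 1) / bin_width_years) * bin_width_years
  edges <- seq(lo, hi, by = bin_width_years)
  bin <- findInterval(ages, edges, rightmost.closed = FALSE)
  tab <- data.table::data.table(
    age_lo = edges[-length(edges)],
    age_hi = edges[-1]
  )
  tab[, bin := sprintf("[%g,%g)", age_lo, age_hi)]
  cnt <- data.table::data.table(idx = bin, ch = has_ch)[
    , .(n_patients = .N, n_with_pbc_variant = sum(ch)), by = idx]
  tab[, `:=`(n_patients = 0L, n_with_pbc_variant = 0L)]
  tab[cnt$idx, `:=`(n_patients = cnt$n_patients,
                    n_with_pbc_variant = cnt$n_with_pbc_variant)]
  tab[, prevalence_pct := data.table::fifelse(
    n_patients > 0, 100 * n_with_pbc_variant / n_patients, NA_real_)]
  structure(list(table = tab[], bin_width_years = bin_width_years,
                 n_total = length(ages)),
            class = "age_prevalence")
}

#' @export
print.age_prevalence <- function(x, ...) {
  cat(sprintf("CH prevalence by age (%g-year bins, n = %d)\n",
              x$bin_width_years, x$n_total))
  print(x$table)
  invisible(x)
}
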
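#' Group UMI-tagged reads into molecular families
#'
#' Reads sharing a (locus, molecular barcode) pair derive from one original
#' template molecule and form a molecular family, the unit of error-corrected
#' evidence for ultradeep amplicon sequencing. Grouping only tallies reads;
#' consensus alleles and the functional-family flag are assigned afterwards by
#' [consensus_and_filter()].
#'
#' @param reads data.frame of tagged reads with columns `locus_id`, `umi`,
#'   `allele` (one row per sequenced read).
#' @param panel panel definition (see [default_panel()]); reads at loci not in
#'   the panel are rejected.
#' @return `data.table` with one row per (locus_id, umi) family: `read_count`,
#'   the modal allele and its count (`top_allele`, `top_count`), and
#'   `consensus_allele`/`functional` set to `NA` pending evaluation.
#' @seealso [consensus_and_filter()], [call_variants()], [compute_depths()]
#' @export
group_families <- function(reads, panel) {
  panel <- validate_panel(panel)
  reads <- data.table::as.data.table(reads)
  need <- c("locus_id", "umi", "allele")
  miss <- setdiff(need, names(reads))
  if (length(miss)) {
    stop("tagged reads are missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(reads) == 0L) {
    return(data.table::data.table(
      locus_id = character(), umi = character(), read_count = integer(),
      top_allele = character(), top_count = integer(),
      consensus_allele = character(), functional = logical()
    ))
  }
  if (any(!nzchar(reads$umi))) stop("tagged reads carry empty UMIs")
  if (any(!nzchar(reads$allele))) stop("tagged reads carry empty alleles")
  unknown <- setdiff(unique(reads$locus_id), panel$locus_id)
  if (length(unknown)) {
    stop("reads reference loci not in the panel: ",
         paste(unknown, collapse = ", "))
  }
  tab <- reads[, .N, by = .(locus_id, umi, allele)]
  fam <- tab[, .(
    read_count = sum(N),
    top_allele = allele[which.max(N)],
    top_count  = max(N)
  ), by = .(locus_id, umi)]
  fam[, `:=`(consensus_allele = NA_character_, functional = NA)]
  fam[]
}

#' Assign consensus alleles and the functional-family filter
#'
#' A family's consensus allele is the allele carried by a strict majority
#' (> 50%) of its reads; families with no strict majority are discarded.
#' A family is *functional* when it has at least `min_family_reads` reads
#' (default 3) and a non-discarded consensus. Only functional families enter
#' variant calling and molecular depth.
#'
#' @param families output of [group_families()].
#' @param min_family_reads minimum reads per functional family (default 3).
#' @return The family table with `consensus_allele` (`"discarded"` when no
#'   strict majority exists) and `functional` filled in.
#' @export
consensus_and_filter <- function(families, min_family_reads = 3L) {
  if (min_family_reads < 1L) stop("min_family_reads must be >= 1")
  fam <- data.table::as.data.table(families)
  if (nrow(fam) == 0L) return(fam[])
  fam <- data.table::copy(fam)
  fam[, consensus_allele := data.table::fifelse(
    2L * top_count > read_count, top_allele, "discarded")]
  fam[, functional := read_count >= min_family_reads &
        consensus_allele != "discarded"]
  fam[]
}

#' Call variants from functional molecular families
#'
#' One call is emitted per locus and non-reference consensus allele supported
#' by at least `min_alt_families` functional families (default 2, the
#' supporting-family threshold for SNV/MNP/INDEL calls). The variant allele
#' frequency is family-based: `vaf_pct = alt_families /
#' total_functional_families * 100`, i.e. the fraction of original molecules
#' carrying the alternate allele.
#'
#' @param families families with consensus evaluated
#'   (see [consensus_and_filter()]).
#' @param panel panel definition supplying `chrom`, `pos`, `ref`, `gene`.
#' @param min_alt_families minimum supporting families per call (default 2).
#' @param compartment,timepoint,patient optional labels attached to the calls.
#' @param reads optional tagged-read table; when given, per-locus read counts
#'   are attached as `read_depth`.
#' @return `data.table` of calls with columns `patient`, `compartment`,
#'   `timepoint`, `locus_id`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `alt_families`, `total_functional_families`, `vaf_pct`, `read_depth`.
#'   Zero functional families at a locus yields no call there (not an error).
#' @export
call_variants <- function(families, panel, min_alt_families = 2L,
                          compartment = NA_character_,
                          timepoint = NA_character_,
                          patient = NA_character_,
                          reads = NULL) {
  panel <- validate_panel(panel)
  if (min_alt_families < 1L) stop("min_alt_families must be >= 1")
  fam <- data.table::as.data.table(families)
  empty <- data.table::data.table(
    patient = character(), compartment = character(), timepoint = character(),
    locus_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), gene = character(),
    alt_families = integer(), total_functional_families = integer(),
    vaf_pct = numeric(), read_depth = integer()
  )
  if (nrow(fam) == 0L) return(empty)
  if (anyNA(fam$functional)) {
    stop("families have not been evaluated; run consensus_and_filter() first")
  }
  fun <- fam[functional == TRUE]
  if (nrow(fun) == 0L) return(empty)
  fun <- merge(fun, panel[, .(locus_id, chrom, pos, ref, gene)],
               by = "locus_id")
  tot <- fun[, .(total_functional_families = .N), by = locus_id]
  altt <- fun[consensus_allele != ref,
              .(alt_families = .N),
              by = .(locus_id, chrom, pos, ref, gene,
                     alt = consensus_allele)]
  altt <- altt[alt_families >= min_alt_families]
  if (nrow(altt) == 0L) return(empty)
  calls <- merge(altt, tot, by = "locus_id")
  calls[, vaf_pct := 100 * alt_families / total_functional_families]
  if (!is.null(reads)) {
    rd <- data.table::as.data.table(reads)[, .(read_depth = .N), by = locus_id]
    calls <- merge(calls, rd, by = "locus_id", all.x = TRUE)
    calls[is.na(read_depth), read_depth := 0L]
  } else {
    calls[, read_depth := NA_integer_]
  }
  calls[, `:=`(patient = patient, compartment = compartment,
               timepoint = timepoint)]
  data.table::setcolorder(calls, names(empty))
  data.table::setorder(calls, chrom, pos, alt)
  calls[]
}

#' Per-locus sequencing and molecular depth
#'
#' Sequencing depth is the raw read count at a locus; molecular depth is the
#' number of functional families, i.e. the effective number of original
#' molecules observed after error correction. Every panel locus is reported,
#' with (0, 0) where no read was seen.
#'
#' @inheritParams call_variants
#' @param reads tagged-read table (may be empty).
#' @return `data.table` with `locus_id`, `sequencing_depth`,
#'   `molecular_depth`.
#' @export
compute_depths <- function(reads, families, panel) {
  panel <- validate_panel(panel)
  reads <- data.table::as.data.table(reads)
  fam <- data.table::as.data.table(families)
  if (nrow(fam) > 0L && anyNA(fam$functional)) {
    stop("families have not been evaluated; run consensus_and_filter() first")
  }
  out <- panel[, .(locus_id)]
  sd <- if (nrow(reads)) reads[, .(sequencing_depth = .N), by = locus_id] else
    data.table::data.table(locus_id = character(), sequencing_depth = integer())
  md <- if (nrow(fam)) fam[functional == TRUE, .(molecular_depth = .N),
                           by = locus_id] else
    data.table::data.table(locus_id = character(), molecular_depth = integer())
  out <- merge(out, sd, by = "locus_id", all.x = TRUE)
  out <- merge(out, md, by = "locus_id", all.x = TRUE)
  out[is.na(sequencing_depth), sequencing_depth := 0L]
  out[is.na(molecular_depth), molecular_depth := 0L]
  out[]
}

#' One-call wrapper: tagged reads to variant calls and depths
#'
#' Convenience pipeline for a single sample: group families, evaluate
#' consensus with the functional-family threshold, call variants with the
#' supporting-family threshold, and compute depth metrics.
#'
#' @inheritParams group_families
#' @inheritParams consensus_and_filter
#' @inheritParams call_variants
#' @return list with elements `calls`, `depths`, `families`.
#' @export
call_sample <- function(reads, panel, min_family_reads = 3L,
                        min_alt_families = 2L,
                        compartment = NA_character_,
                        timepoint = NA_character_,
                        patient = NA_character_) {
  fam <- group_families(reads, panel)
  fam <- consensus_and_filter(fam, min_family_reads)
  calls <- call_variants(fam, panel, min_alt_families,
                         compartment = compartment, timepoint = timepoint,
                         patient = patient, reads = reads)
  depths <- compute_depths(reads, fam, panel)
  list(calls = calls, depths = depths, families = fam)
}
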
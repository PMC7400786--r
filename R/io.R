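ND <- "N.D"

fread_checked <- function(path, required, colClasses = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = colClasses, na.strings = NULL)
  miss <- setdiff(required, names(dt))
  if (length(miss)) {
    stop("'", basename(path), "' is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  dt
}

# parse a numeric column that may contain the "N.D" token; errors carry the
# 1-based data line number (header is line 1)
parse_vaf_column <- function(x, col, path) {
  x <- as.character(x)
  nd <- x %in% c(ND, "ND", "NA", "")
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !nd)
  if (length(bad)) {
    stop("'", basename(path), "' line ", bad[1] + 1L, ": ", col,
         " value '", x[bad[1]], "' is not a number (use \"", ND,
         "\" for not detected)")
  }
  out[nd] <- NA_real_
  out
}

#' Read and write the pipeline's TSV formats
#'
#' Tagged reads: `locus_id  umi  allele`, one row per read. Panel:
#' `locus_id  chrom  pos  ref  gene`. Variant calls:
#' `patient  compartment  timepoint  chrom  pos  ref  alt  gene  vaf_pct
#' alt_families  total_families  read_depth` with `vaf_pct` printed with two
#' decimals. All writers and readers round-trip.
#'
#' @param path file path.
#' @return the corresponding `data.table` (readers) or `path`, invisibly
#'   (writers).
#' @name read_tagged_reads
#' @export
read_tagged_reads <- function(path) {
  dt <- fread_checked(path, c("locus_id", "umi", "allele"))
  dt[, .(locus_id = as.character(locus_id), umi = as.character(umi),
         allele = as.character(allele))]
}

# split "chr17:7577568" / "C/G" columns into the variant key
parse_locus_genotype <- function(dt) {
  if (nrow(dt) == 0L) {
    dt[, `:=`(chrom = character(), pos = integer(), ref = character(),
              alt = character())]
    return(dt)
  }
  loc <- data.table::tstrsplit(dt$locus, ":", fixed = TRUE)
  gt <- data.table::tstrsplit(dt$genotype, "/", fixed = TRUE)
  dt[, `:=`(chrom = loc[[1]], pos = as.integer(loc[[2]]),
            ref = gt[[1]], alt = gt[[2]])]
  dt
}

#' @rdname read_tagged_reads
#' @param reads tagged-read table.
#' @export
write_tagged_reads <- function(reads, path) {
  reads <- data.table::as.data.table(reads)
  data.table::fwrite(reads[, .(locus_id, umi, allele)], path, sep = "\t")
  invisible(path)
}

#' @rdname read_tagged_reads
#' @param calls variant-call table (see [call_variants()]).
#' @export
write_variant_table <- function(calls, path) {
  calls <- data.table::as.data.table(calls)
  out <- calls[, .(
    patient, compartment, timepoint, chrom, pos, ref, alt, gene,
    vaf_pct = sprintf("%.2f", vaf_pct),
    alt_families,
    total_families = total_functional_families,
    read_depth
  )]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname read_tagged_reads
#' @export
read_variant_table <- function(path) {
  need <- c("patient", "compartment", "timepoint", "chrom", "pos", "ref",
            "alt", "gene", "vaf_pct", "alt_families", "total_families",
            "read_depth")
  dt <- fread_checked(path, need, colClasses = list(character = "vaf_pct"))
  dt[, vaf_pct := parse_vaf_column(vaf_pct, "vaf_pct", path)]
  data.table::setnames(dt, "total_families", "total_functional_families")
  dt[]
}

variant_type <- function(ref, alt) {
  data.table::fifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
  data.table::fifelse(nchar(ref) == nchar(alt), "MNP", "INDEL"))
}

#' Read the packaged PBC-detected (CH) mutation fixture
#'
#' The package ships a small TSV listing the CH-related mutations of a
#' 38-patient colorectal-cancer cohort: one row per PBC-detected mutation
#' with its VAF in PBCs, tumor tissue and preoperative plasma ("N.D" = not
#' detected). The same columns are produced by [write_triage_table()].
#'
#' @param path defaults to the packaged fixture.
#' @return `data.table` with patient, parsed variant key (`chrom`, `pos`,
#'   `ref`, `alt`), `type`, `gene`, `aa_change` and numeric `vaf_pbc`,
#'   `vaf_tumor`, `vaf_plasma` (NA when not detected).
#' @export
read_table1_fixture <- function(path = system.file(
  "extdata", "pbc_ch_mutations.tsv", package = "chtriage")) {
  need <- c("patient", "locus", "genotype", "type", "gene", "aa_change",
            "vaf_pbc", "vaf_tumor", "vaf_plasma")
  dt <- fread_checked(path, need,
                      colClasses = list(character = c("vaf_pbc", "vaf_tumor",
                                                      "vaf_plasma")))
  dt <- parse_locus_genotype(dt)
  for (col in c("vaf_pbc", "vaf_tumor", "vaf_plasma")) {
    data.table::set(dt, j = col,
                    value = parse_vaf_column(dt[[col]], col, path))
  }
  dt[]
}

#' Triage the packaged CH mutation fixture
#'
#' Builds a `cohort_triage` from [read_table1_fixture()]: each fixture row
#' becomes one PBC-detected variant of its patient, with tumor and plasma
#' detection given by the non-missing VAF columns. `n_patients` pads the
#' cohort with variant-free patients so cohort-level rates use the full
#' cohort denominator.
#'
#' @param fixture table as returned by [read_table1_fixture()].
#' @param n_patients total cohort size (default: only the fixture's
#'   patients).
#' @return a `cohort_triage`.
#' @export
triage_table1 <- function(fixture = read_table1_fixture(),
                          n_patients = NULL) {
  fixture <- data.table::as.data.table(fixture)
  triages <- lapply(split(fixture, by = "patient"), function(rows) {
    mk <- function(v) {
      rows[!is.na(rows[[v]]),
           .(chrom, pos, ref, alt, gene, aa_change,
             vaf_pct = rows[[v]][!is.na(rows[[v]])])]
    }
    triage_patient(tumor = mk("vaf_tumor"), pbc = mk("vaf_pbc"),
                   plasma = mk("vaf_plasma"),
                   patient_id = rows$patient[1])
  })
  if (!is.null(n_patients)) {
    extra <- n_patients - length(triages)
    if (extra < 0) stop("n_patients smaller than patients in fixture")
    for (i in seq_len(extra)) {
      pid <- sprintf("PAD%02d", i)
      triages[[pid]] <- triage_patient(patient_id = pid)
    }
  }
  as_cohort(unname(triages))
}

#' Write / read a per-patient triage table
#'
#' Human-readable summary mirroring the CH mutation fixture layout, one row
#' per variant: `patient locus genotype type gene aa_change vaf_pbc
#' vaf_tumor vaf_plasma origin`, plus `stage` and `age` when known; absent
#' VAFs are rendered "N.D".
#'
#' @param cohort a `cohort_triage` (or single `patient_triage`).
#' @param path file path.
#' @return `path` invisibly ([write_triage_table()]) or a `cohort_triage`
#'   ([read_triage_table()]).
#' @export
write_triage_table <- function(cohort, path) {
  v <- cohort_variants(cohort)
  fmt <- function(x) data.table::fifelse(is.na(x), ND, sprintf("%.2f", x))
  out <- v[, .(
    patient,
    locus = paste0(chrom, ":", pos),
    genotype = paste0(ref, "/", alt),
    type = variant_type(ref, alt),
    gene, aa_change,
    vaf_pbc = fmt(vaf_pbc), vaf_tumor = fmt(vaf_tumor),
    vaf_plasma = fmt(vaf_plasma),
    origin = as.character(origin), stage, age
  )]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_triage_table
#' @export
read_triage_table <- function(path) {
  need <- c("patient", "locus", "genotype", "type", "gene", "aa_change",
            "vaf_pbc", "vaf_tumor", "vaf_plasma")
  dt <- fread_checked(path, need,
                      colClasses = list(character = c("vaf_pbc", "vaf_tumor",
                                                      "vaf_plasma")))
  dt <- parse_locus_genotype(dt)
  for (col in c("vaf_pbc", "vaf_tumor", "vaf_plasma")) {
    data.table::set(dt, j = col,
                    value = parse_vaf_column(dt[[col]], col, path))
  }
  triages <- lapply(split(dt, by = "patient"), function(rows) {
    mk <- function(v) {
      rows[!is.na(rows[[v]]),
           .(chrom, pos, ref, alt, gene, aa_change,
             vaf_pct = rows[[v]][!is.na(rows[[v]])])]
    }
    triage_patient(
      tumor = mk("vaf_tumor"), pbc = mk("vaf_pbc"), plasma = mk("vaf_plasma"),
      patient_id = rows$patient[1],
      stage = if ("stage" %in% names(rows)) rows$stage[1] else NA_character_,
      age = if ("age" %in% names(rows)) rows$age[1] else NA_real_
    )
  })
  as_cohort(unname(triages))
}

#' Write a cohort summary as JSON
#'
#' @param summary a `cohort_summary` from [concordance()].
#' @param path file path.
#' @export
write_cohort_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

vcf_info_header <- c(
  '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Variant origin label">',
  '##INFO=<ID=VAF_PCT,Number=1,Type=Float,Description="Family-based variant allele frequency, percent">',
  '##INFO=<ID=ALT_FAM,Number=1,Type=Integer,Description="Alternate-supporting functional families">',
  '##INFO=<ID=TOT_FAM,Number=1,Type=Integer,Description="Total functional families">',
  '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">'
)

#' Write variant calls as minimal VCF 4.2
#'
#' One record per call, sorted by (chrom, pos), with the origin label and
#' family counts in INFO (`ORIGIN`, `VAF_PCT`, `ALT_FAM`, `TOT_FAM`,
#' `GENE`). An empty call set produces a header-only VCF.
#'
#' @param calls table with `chrom`, `pos`, `ref`, `alt` and optionally
#'   `vaf_pct`, `alt_families`, `total_functional_families`, `gene`,
#'   `origin`.
#' @param path output path.
#' @export
write_vcf <- function(calls, path) {
  calls <- data.table::as.data.table(calls)
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=chtriage-", utils::packageVersion("chtriage")),
           vcf_info_header,
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  for (col in c("vaf_pct", "alt_families", "total_functional_families",
                "gene", "origin")) {
    if (!col %in% names(calls)) calls[, (col) := NA]
  }
  data.table::setorder(calls, chrom, pos, alt)
  info <- apply(calls, 1L, function(r) {
    kv <- c(
      if (!is.na(r[["origin"]])) paste0("ORIGIN=", r[["origin"]]),
      if (!is.na(r[["vaf_pct"]]))
        paste0("VAF_PCT=", format(as.numeric(r[["vaf_pct"]]),
                                  scientific = FALSE)),
      if (!is.na(r[["alt_families"]]))
        paste0("ALT_FAM=", as.integer(r[["alt_families"]])),
      if (!is.na(r[["total_functional_families"]]))
        paste0("TOT_FAM=", as.integer(r[["total_functional_families"]])),
      if (!is.na(r[["gene"]])) paste0("GENE=", r[["gene"]])
    )
    if (length(kv)) paste(kv, collapse = ";") else "."
  })
  rec <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
               "PASS", info, sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a minimal VCF written by [write_vcf()]
#'
#' Parses the fixed columns and the INFO keys this package writes. Not a
#' general-purpose VCF reader; use VariantAnnotation for foreign files.
#'
#' @param path VCF path.
#' @return `data.table` with `chrom`, `pos`, `ref`, `alt`, `vaf_pct`,
#'   `alt_families`, `total_functional_families`, `gene`, `origin`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  empty <- data.table::data.table(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), vaf_pct = numeric(), alt_families = integer(),
    total_functional_families = integer(), gene = character(),
    origin = character()
  )
  if (!length(body)) return(empty)
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- rep(NA_character_, length(info))
    hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="),
                                             info))) > 0
    out[hit] <- sub(paste0("^;?", key, "="), "", m)
    out
  }
  info <- f[[8]]
  data.table::data.table(
    chrom = f[[1]], pos = as.integer(f[[2]]), ref = f[[4]], alt = f[[5]],
    vaf_pct = as.numeric(info_get(info, "VAF_PCT")),
    alt_families = as.integer(info_get(info, "ALT_FAM")),
    total_functional_families = as.integer(info_get(info, "TOT_FAM")),
    gene = info_get(info, "GENE"),
    origin = info_get(info, "ORIGIN")
  )
}
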
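#' Built-in hotspot SNV panel
#'
#' A compact pan-cancer hotspot panel used by the simulator and the examples:
#' one locus per hotspot position across nine genes recurrently mutated in
#' colorectal cancer, including the TP53 and GNAS positions at which
#' clonal-hematopoiesis (CH) mutations are observed in PBC DNA. Coordinates
#' are treated as opaque labels; no genome build is assumed.
#'
#' @return A `data.table` with columns `locus_id`, `chrom`, `pos`, `ref`,
#'   `gene`, one row per panel locus. `locus_id` is unique.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  p <- data.table::data.table(rbind(
    c("TP53_C238S",   "chr17", 7577568L,  "C", "TP53"),
    c("TP53_R249M",   "chr17", 7577535L,  "C", "TP53"),
    c("TP53_R273H",   "chr17", 7577120L,  "C", "TP53"),
    c("TP53_R273C",   "chr17", 7577121L,  "G", "TP53"),
    c("TP53_K132Q",   "chr17", 7578536L,  "T", "TP53"),
    c("TP53_R282W",   "chr17", 7577094L,  "G", "TP53"),
    c("TP53_R158H",   "chr17", 7578457L,  "C", "TP53"),
    c("TP53_R196X",   "chr17", 7578263L,  "G", "TP53"),
    c("TP53_M237I",   "chr17", 7577570L,  "C", "TP53"),
    c("TP53_C176Y",   "chr17", 7578403L,  "C", "TP53"),
    c("TP53_Y220C",   "chr17", 7578190L,  "T", "TP53"),
    c("TP53_R175H",   "chr17", 7578406L,  "C", "TP53"),
    c("TP53_R248Q",   "chr17", 7577538L,  "C", "TP53"),
    c("TP53_G245S",   "chr17", 7577548L,  "C", "TP53"),
    c("GNAS_R201C",   "chr20", 57484420L, "C", "GNAS"),
    c("GNAS_R201H",   "chr20", 57484421L, "G", "GNAS"),
    c("KRAS_G12",     "chr12", 25398284L, "C", "KRAS"),
    c("KRAS_G13",     "chr12", 25398281L, "C", "KRAS"),
    c("KRAS_Q61",     "chr12", 25380275L, "T", "KRAS"),
    c("KRAS_A146",    "chr12", 25378562L, "C", "KRAS"),
    c("PIK3CA_E542K", "chr3",  178936082L, "G", "PIK3CA"),
    c("PIK3CA_E545K", "chr3",  178936091L, "G", "PIK3CA"),
    c("PIK3CA_H1047R","chr3",  178952085L, "A", "PIK3CA"),
    c("APC_R1450X",   "chr5",  112175639L, "C", "APC"),
    c("APC_R876X",    "chr5",  112154737L, "C", "APC"),
    c("APC_R213X",    "chr5",  112128143L, "C", "APC"),
    c("BRAF_V600E",   "chr7",  140453136L, "A", "BRAF"),
    c("EGFR_L858R",   "chr7",  55259515L,  "T", "EGFR"),
    c("FBXW7_R465C",  "chr4",  153249385L, "C", "FBXW7"),
    c("SMAD4_R361H",  "chr18", 48604676L,  "G", "SMAD4")
  ))
  data.table::setnames(p, c("locus_id", "chrom", "pos", "ref", "gene"))
  p[, pos := as.integer(pos)]
  validate_panel(p)
}

#' Validate a panel definition
#'
#' Checks the invariants of a panel table: required columns, unique
#' `locus_id`, positive 1-based positions, non-empty reference alleles.
#'
#' @param panel data.frame with columns `locus_id`, `chrom`, `pos`, `ref`,
#'   `gene`.
#' @return The panel as a keyed `data.table` (invisibly usable downstream).
#' @export
validate_panel <- function(panel) {
  panel <- data.table::as.data.table(panel)
  need <- c("locus_id", "chrom", "pos", "ref", "gene")
  miss <- setdiff(need, names(panel))
  if (length(miss)) {
    stop("panel is missing required column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(panel$locus_id)) {
    stop("panel locus_id values must be unique; duplicated: ",
         paste(unique(panel$locus_id[duplicated(panel$locus_id)]), collapse = ", "))
  }
  if (any(panel$pos < 1L)) stop("panel positions must be >= 1")
  if (any(!nzchar(panel$ref))) stop("panel ref alleles must be non-empty")
  data.table::setkeyv(panel, "locus_id")
  panel[]
}

#' @rdname read_tagged_reads
#' @export
read_panel <- function(path) {
  panel <- fread_checked(path, c("locus_id", "chrom", "pos", "ref", "gene"))
  validate_panel(panel)
}

#' @rdname read_tagged_reads
#' @param panel panel table as returned by [default_panel()].
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  data.table::fwrite(panel, path, sep = "\t")
  invisible(path)
}
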
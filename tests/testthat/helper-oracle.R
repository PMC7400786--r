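# Independent brute-force oracle for the UMI caller: plain-R enumeration of
# (locus, UMI) groups, strict-majority votes and threshold checks. Kept free
# of the package's grouping machinery on purpose.

oracle_call <- function(reads, panel, min_family_reads = 3,
                        min_alt_families = 2) {
  reads <- as.data.frame(reads)
  panel <- as.data.frame(panel)
  calls <- list()
  mol_depth <- stats::setNames(integer(nrow(panel)), panel$locus_id)
  seq_depth <- stats::setNames(integer(nrow(panel)), panel$locus_id)
  for (li in seq_len(nrow(panel))) {
    lid <- panel$locus_id[li]
    r <- reads[reads$locus_id == lid, , drop = FALSE]
    seq_depth[lid] <- nrow(r)
    if (!nrow(r)) next
    consensus <- character()
    for (u in unique(r$umi)) {
      a <- r$allele[r$umi == u]
      tab <- table(a)
      top <- names(tab)[which.max(tab)]
      has_majority <- 2 * max(tab) > length(a)
      if (has_majority && length(a) >= min_family_reads) {
        consensus <- c(consensus, top)
      }
    }
    mol_depth[lid] <- length(consensus)
    for (al in unique(consensus)) {
      if (al == panel$ref[li]) next
      n <- sum(consensus == al)
      if (n >= min_alt_families) {
        calls[[length(calls) + 1]] <- data.frame(
          locus_id = lid, alt = al, alt_families = n,
          total_functional_families = length(consensus),
          vaf_pct = 100 * n / length(consensus),
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(locus_id = character(), alt = character(),
               alt_families = integer(),
               total_functional_families = integer(), vaf_pct = numeric())
  calls <- calls[order(calls$locus_id, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, molecular_depth = mol_depth,
       sequencing_depth = seq_depth)
}

# independent exact Mann-Whitney oracle: full enumeration of rank subsets
oracle_rank_sum <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a); n <- length(r)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  subsets <- utils::combn(n, na)
  u_all <- apply(subsets, 2, function(ix) sum(r[ix])) - na * (na + 1) / 2
  p <- 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9))
  list(u = u_obs, p = min(1, p))
}

toy_panel <- function(n_loci = 5) {
  data.frame(
    locus_id = paste0("L", seq_len(n_loci)),
    chrom = "chr1",
    pos = seq_len(n_loci) * 100L,
    ref = rep(c("A", "C", "G", "T"), length.out = n_loci),
    gene = rep(c("G1", "G2"), length.out = n_loci),
    stringsAsFactors = FALSE
  )
}

random_reads <- function(n_reads, panel, n_umis = 6,
                         alleles = c("A", "C", "G", "T")) {
  data.frame(
    locus_id = sample(panel$locus_id, n_reads, replace = TRUE),
    umi = sample(paste0("u", seq_len(n_umis)), n_reads, replace = TRUE),
    allele = sample(alleles, n_reads, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# minimal call-set constructor for triage tests
mk_calls <- function(keys, vaf = 1, gene = "TP53") {
  if (length(keys) == 0) return(NULL)
  data.frame(
    chrom = "chr17", pos = as.integer(keys), ref = "C", alt = "T",
    gene = gene, vaf_pct = rep_len(vaf, length(keys)),
    stringsAsFactors = FALSE
  )
}
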
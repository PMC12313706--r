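# CDS assembly, filtering, codon counting, positional GC statistics, RSCU and
# Wright's effective number of codons (ENC).
#
# All statistics use translation table 11 and the following exclusion sets:
#   GC1/GC2/GC3   - stop codons excluded
#   P1/P2/P3/P12  - ATG, ATA, TGG and stops excluded
#   A3s/T3s/C3s/G3s - ATG, ATT, ATC, ATA, TGG and stops excluded
#   GC3s          - third positions of synonymous codons (Met, Trp, stops excluded)

#' Construct a coding sequence
#' @param gene_name gene symbol
#' @param species_label organism or record label
#' @param dna in-frame coding-strand DNA string
#' @param provenance optional list (record id, segments)
#' @param is_trans_spliced logical
#' @return object of class `coding_sequence`
#' @export
coding_sequence <- function(gene_name, species_label = "", dna,
                            provenance = NULL, is_trans_spliced = FALSE) {
  structure(
    list(gene_name = gene_name, species_label = species_label, dna = dna,
         length_bp = nchar(dna), provenance = provenance,
         is_trans_spliced = isTRUE(is_trans_spliced)),
    class = "coding_sequence")
}

#' Assemble coding sequences from a record's CDS features
#'
#' One coding sequence per CDS feature, extracted on the coding strand.
#' Genes duplicated by the inverted repeat (same gene name, identical
#' sequence) are reduced to a single copy so duplicate data is not
#' double-weighted downstream. Trans-spliced genes are assembled per their
#' annotation and tagged.
#'
#' @param record a [plastome_record()]
#' @return list of [coding_sequence()] objects
#' @export
assemble_cds <- function(record) {
  cds_feats <- Filter(function(f) f$feature_kind == "CDS", record$features)
  out <- list()
  seen <- character(0)
  for (f in cds_feats) {
    dna <- extract_feature_sequence(record, f)
    key <- paste(f$gene_name, dna, sep = "\r")
    if (key %in% seen) next  # IR-duplicated copy
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- coding_sequence(
      gene_name = f$gene_name, species_label = record$organism, dna = dna,
      provenance = list(record = record$identifier, segments = f$segments),
      is_trans_spliced = f$is_trans_spliced)
  }
  out
}

VALID_STOPS <- c("TAA", "TAG", "TGA")

#' Filter coding sequences for codon-usage analysis
#'
#' Retains CDS that are at least `min_len` bp, a multiple of 3, begin with a
#' valid start codon, end with a stop codon, and contain no internal stops.
#' Trans-spliced genes are rejected (their assembled frame depends on
#' annotation conventions). Every rejection carries a reason; the first
#' failing rule in the order trans_spliced, duplicate_ir_copy, too_short,
#' not_triplet, bad_start, no_stop, internal_stop is reported.
#'
#' @param cds_list list of [coding_sequence()] objects
#' @param min_len minimum length in bp (default 300)
#' @param start_policy "table11" accepts ATG/GTG/TTG starts; "atg_only"
#'   accepts ATG alone
#' @return list with elements `retained` (coding sequences) and `rejected`
#'   (data.frame gene_name, reason)
#' @export
filter_cds <- function(cds_list, min_len = 300L,
                       start_policy = c("table11", "atg_only")) {
  start_policy <- match.arg(start_policy)
  starts_ok <- if (start_policy == "table11") c("ATG", "GTG", "TTG") else "ATG"
  retained <- list()
  rej <- list()
  seen <- character(0)
  for (cs in cds_list) {
    reason <- NULL
    dna <- cs$dna
    key <- paste(cs$gene_name, dna, sep = "\r")
    if (cs$is_trans_spliced) reason <- "trans_spliced"
    else if (key %in% seen) reason <- "duplicate_ir_copy"
    else if (cs$length_bp < min_len) reason <- "too_short"
    else if (cs$length_bp %% 3L != 0L) reason <- "not_triplet"
    else if (!substr(dna, 1L, 3L) %in% starts_ok) reason <- "bad_start"
    else {
      cods <- split_codons(dna)
      last <- cods[length(cods)]
      if (!last %in% VALID_STOPS) reason <- "no_stop"
      else if (any(cods[-length(cods)] %in% VALID_STOPS)) reason <- "internal_stop"
    }
    if (is.null(reason)) {
      seen <- c(seen, key)
      retained[[length(retained) + 1L]] <- cs
    } else {
      rej[[length(rej) + 1L]] <- data.frame(gene_name = cs$gene_name,
                                            reason = reason)
    }
  }
  list(retained = retained,
       rejected = if (length(rej)) do.call(rbind, rej)
                  else data.frame(gene_name = character(0), reason = character(0)))
}

#' Count codons in one or several coding sequences
#'
#' Counts non-overlapping triplets over the full in-frame sequence (including
#' any terminal stop); codons containing N are skipped and tallied separately.
#'
#' @param cds_set a [coding_sequence()] or list of them
#' @param pool if TRUE, one pooled table; if FALSE, a list of per-gene tables
#' @return a `codon_usage_table` (counts over the 64 codons, `n_codons`,
#'   `n_skipped`), or a named list of them when `pool = FALSE`
#' @export
codon_counts <- function(cds_set, pool = TRUE) {
  if (inherits(cds_set, "coding_sequence")) cds_set <- list(cds_set)
  one <- function(cs) {
    cods <- split_codons(cs$dna)
    keep <- !grepl("N", cods, fixed = TRUE)
    counts <- table(factor(cods[keep], levels = all_codons()))
    structure(list(counts = as.integer(counts), codons = all_codons(),
                   n_codons = sum(keep), n_skipped = sum(!keep)),
              class = "codon_usage_table")
  }
  if (!pool) {
    out <- lapply(cds_set, one)
    names(out) <- vapply(cds_set, `[[`, character(1), "gene_name")
    return(out)
  }
  tabs <- lapply(cds_set, one)
  structure(list(
    counts = Reduce(`+`, lapply(tabs, `[[`, "counts")),
    codons = all_codons(),
    n_codons = sum(vapply(tabs, `[[`, integer(1), "n_codons")),
    n_skipped = sum(vapply(tabs, `[[`, integer(1), "n_skipped"))),
    class = "codon_usage_table")
}

table_counts <- function(table) stats::setNames(table$counts, table$codons)

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count over its synonymous
#' family (equivalently k * X / sum(X) for a family of size k). Stop codons
#' are excluded; Met and Trp are reported as 1.0 by convention; a family with
#' zero total yields NA for all its members.
#'
#' @param table a `codon_usage_table`
#' @return named numeric vector over the 61 sense codons
#' @export
rscu <- function(table) {
  counts <- table_counts(table)
  code <- codon_table()
  sense <- names(code)[code != "*"]
  out <- stats::setNames(rep(NA_real_, length(sense)), sense)
  for (aa in unique(code[sense])) {
    fam <- sense[code[sense] == aa]
    k <- length(fam)
    if (k == 1L) { out[fam] <- 1.0; next }
    tot <- sum(counts[fam])
    if (tot == 0) next
    out[fam] <- counts[fam] * k / tot
  }
  out
}

#' Wright's effective number of codons (ENC)
#'
#' Per amino-acid family with n observed codons and usage frequencies p_i,
#' the homozygosity estimate is F = (n * sum(p_i^2) - 1) / (n - 1). Families
#' with n < 2 or F <= 0 are dropped; class means over families of degeneracy
#' 2 (9 families), 3 (Ile), 4 (5 families) and 6 (Leu, Ser, Arg) give
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. A missing 3-fold class is imputed as
#' the mean of the 2- and 4-fold means; a missing 2-, 4- or 6-fold class
#' yields NA. Values are capped at 61.
#'
#' @param table a `codon_usage_table` for one gene
#' @return ENC in [20, 61], or NA when undefined
#' @export
enc <- function(table) {
  counts <- table_counts(table)
  code <- codon_table()
  sense <- names(code)[code != "*"]
  fam_of <- split(sense, code[sense])
  f_hat <- numeric(0); degree <- integer(0)
  for (aa in names(fam_of)) {
    fam <- fam_of[[aa]]
    k <- length(fam)
    if (k == 1L) next
    n <- sum(counts[fam])
    if (n < 2) next
    p <- counts[fam] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    f_hat <- c(f_hat, f); degree <- c(degree, k)
  }
  fbar <- function(k) if (any(degree == k)) mean(f_hat[degree == k]) else NA_real_
  f2 <- fbar(2L); f3 <- fbar(3L); f4 <- fbar(4L); f6 <- fbar(6L)
  if (is.na(f2) || is.na(f4) || is.na(f6)) return(NA_real_)
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  min(61, 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6)
}

# helper: per-position GC fraction over a set of codon counts
positional_fraction <- function(counts, codons, pos, bases = c("G", "C")) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  hit <- substr(codons, pos, pos) %in% bases
  sum(counts[hit]) / n
}

#' Per-gene codon-position statistics
#'
#' Computes GC1/GC2/GC3 (percent), P1/P2/P3/P12, A3s/T3s/C3s/G3s, GC3s
#' (fractions) and ENC for one coding sequence, each over its own codon
#' exclusion set (see the module header). The terminal stop codon is removed
#' before counting. A statistic whose eligible codon set is empty is NA.
#'
#' @param cds a [coding_sequence()]
#' @return one-row data.frame of class `gene_cub_metrics`
#' @export
gene_cub_metrics <- function(cds) {
  cods <- split_codons(cds$dna)
  if (length(cods) && cods[length(cods)] %in% VALID_STOPS) {
    cods <- cods[-length(cods)]
  }
  cods <- cods[!grepl("N", cods, fixed = TRUE)]
  counts <- table(factor(cods, levels = all_codons()))
  counts <- stats::setNames(as.integer(counts), all_codons())
  code <- codon_table()
  codons <- all_codons()

  nonstop <- code[codons] != "*"
  p_set <- nonstop & !codons %in% c("ATG", "ATA", "TGG")
  x3s_set <- nonstop & !codons %in% c("ATG", "ATT", "ATC", "ATA", "TGG")
  gc3s_set <- nonstop & !codons %in% c("ATG", "TGG")
  # fourfold-degenerate sites: codons whose four third-base variants all code
  # the same amino acid (classical PR2 axes, free of stop/Trp exclusions)
  block <- substr(codons, 1, 2)
  deg4 <- vapply(split(code[codons], block), function(a) length(unique(a)) == 1L,
                 logical(1))
  ff_set <- deg4[block]

  gc_at <- function(set, pos) positional_fraction(counts[set], codons[set], pos)
  base_at3 <- function(b) positional_fraction(counts[x3s_set], codons[x3s_set], 3, b)
  base_ff3 <- function(b) positional_fraction(counts[ff_set], codons[ff_set], 3, b)

  p1 <- gc_at(p_set, 1); p2 <- gc_at(p_set, 2); p3 <- gc_at(p_set, 3)
  tab <- structure(list(counts = unname(counts), codons = codons,
                        n_codons = sum(counts), n_skipped = 0L),
                   class = "codon_usage_table")
  out <- data.frame(
    gene_name = cds$gene_name, species_label = cds$species_label,
    n_codons = sum(counts),
    GC1 = 100 * gc_at(nonstop, 1), GC2 = 100 * gc_at(nonstop, 2),
    GC3 = 100 * gc_at(nonstop, 3),
    P1 = p1, P2 = p2, P3 = p3, P12 = (p1 + p2) / 2,
    A3s = base_at3("A"), T3s = base_at3("T"),
    C3s = base_at3("C"), G3s = base_at3("G"),
    A3f = base_ff3("A"), T3f = base_ff3("T"),
    C3f = base_ff3("C"), G3f = base_ff3("G"),
    GC3s = gc_at(gc3s_set, 3),
    ENC = enc(tab))
  class(out) <- c("gene_cub_metrics", class(out))
  out
}

#' Codon-usage metrics for a set of coding sequences
#'
#' @param cds_list list of [coding_sequence()] objects (typically the
#'   `retained` element of [filter_cds()])
#' @return data.frame with one row per gene
#' @export
cub_metrics_table <- function(cds_list) {
  out <- do.call(rbind, lapply(cds_list, gene_cub_metrics))
  class(out) <- "data.frame"
  out
}
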
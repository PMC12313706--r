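# Pairwise Ka/Ks by the Nei-Gojobori counting method (NG86) with Jukes-Cantor
# correction, over protein-guided codon alignments.
#
# Site counting: at each codon position the synonymous fraction is the number
# of synonymous single-base changes divided by the number of changes not
# creating a stop; S is the mean of the two sequences' site sums and N the
# remaining site mass. Differences are averaged over all minimum-length
# mutational pathways between the two codons, pathways through stop codons
# excluded. Rates are corrected as d = -(3/4) * log(1 - 4p/3).

#' Protein-guided codon alignment of two coding sequences
#'
#' Both sequences are translated under table 11 (terminal stop dropped), the
#' proteins are globally aligned (BLOSUM62, gap open 10, gap extend 0.5), the
#' gaps are transferred back to codons, and gapped codon columns are removed.
#'
#' @param cds_a,cds_b [coding_sequence()] objects (in frame, no internal stop)
#' @return object of class `codon_alignment`: gene_name, pair, codons_a,
#'   codons_b, n_codon_pairs
#' @export
align_codons <- function(cds_a, cds_b) {
  prep <- function(cds) {
    cods <- split_codons(cds$dna)
    if (length(cods) && cods[length(cods)] %in% VALID_STOPS) {
      cods <- cods[-length(cods)]
    }
    aa <- codon_table()[cods]
    bad <- which(is.na(aa) | aa == "*")
    if (length(bad)) {
      stop("gene ", cds$gene_name, ": untranslatable or stop codon at codon position ",
           bad[1], " (", cods[bad[1]], ")")
    }
    list(codons = cods, protein = paste(aa, collapse = ""))
  }
  a <- prep(cds_a); b <- prep(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$protein), Biostrings::AAString(b$protein),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  structure(
    list(gene_name = cds_a$gene_name,
         pair = c(cds_a$species_label, cds_b$species_label),
         codons_a = a$codons[ia[keep]],
         codons_b = b$codons[ib[keep]],
         n_codon_pairs = sum(keep)),
    class = "codon_alignment")
}

#' Nei-Gojobori (NG86) Ka/Ks estimate for a codon alignment
#'
#' @param alignment a [align_codons()] result, or a list with `codons_a` and
#'   `codons_b` character vectors of equal length (gap-free sense codons)
#' @return object of class `pairwise_kaks`: N, S, Nd, Sd, pN, pS, Ka, Ks,
#'   omega, omega_status ("ok", "undefined_Ks0", "saturated", "undefined_sites"),
#'   n_codon_pairs, n_blocked (codon pairs whose every pathway passes a stop)
#' @export
ng86 <- function(alignment) {
  ca <- alignment$codons_a; cb <- alignment$codons_b
  stopifnot(length(ca) == length(cb), length(ca) >= 1L)
  sites <- ng86_site_table()
  diffs <- ng86_diff_table()
  bad <- c(ca, cb)[!c(ca, cb) %in% names(sites$syn)]
  if (length(bad)) stop("non-sense codon in alignment: ", bad[1])

  S <- (sum(sites$syn[ca]) + sum(sites$syn[cb])) / 2
  total_mass <- (sum(sites$mass[ca]) + sum(sites$mass[cb])) / 2
  N <- total_mass - S

  idx <- cbind(match(ca, rownames(diffs$sd)), match(cb, colnames(diffs$sd)))
  blocked <- diffs$blocked[idx]
  Sd <- sum(diffs$sd[idx][!blocked])
  Nd <- sum(diffs$nd[idx][!blocked])

  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 0.75) return(NA_real_)  # saturated
    if (p == 0) return(0)
    -0.75 * log(1 - 4 * p / 3)
  }
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)

  status <- "ok"
  if (S == 0 || N == 0) status <- "undefined_sites"
  else if ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)) status <- "saturated"
  else if (Ks == 0) status <- "undefined_Ks0"
  omega <- if (status == "ok") Ka / Ks else NA_real_

  structure(
    list(gene_name = alignment$gene_name, pair = alignment$pair,
         N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
         Ka = Ka, Ks = Ks, omega = omega, omega_status = status,
         n_codon_pairs = length(ca), n_blocked = sum(blocked)),
    class = "pairwise_kaks")
}

#' @export
print.pairwise_kaks <- function(x, ...) {
  cat(sprintf(paste0("<pairwise_kaks> %s (%s vs %s), %d codon pairs\n",
                     "  S = %.2f  N = %.2f  Sd = %.2f  Nd = %.2f\n",
                     "  Ka = %s  Ks = %s  omega = %s [%s]\n"),
              if (is.null(x$gene_name)) "?" else x$gene_name,
              x$pair[1], x$pair[2], x$n_codon_pairs,
              x$S, x$N, x$Sd, x$Nd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$omega, digits = 4), x$omega_status))
  invisible(x)
}

#' Classify the selection regime from a Ka/Ks estimate
#'
#' @param result a [ng86()] result
#' @param neutral_band two values; omega inside it is called neutral (default
#'   c(0.95, 1.05)); above it positive, below it purifying
#' @return one of "positive", "purifying", "neutral", "undetermined"
#' @export
classify_selection <- function(result, neutral_band = c(0.95, 1.05)) {
  omega <- if (is.list(result)) result$omega else result
  if (is.na(omega)) return("undetermined")
  if (omega > neutral_band[2]) "positive"
  else if (omega < neutral_band[1]) "purifying"
  else "neutral"
}

#' Per-gene Ka/Ks scan between two annotated genomes
#'
#' Assembles and filters the CDS of both records, pairs genes by name, aligns
#' each pair, and estimates NG86 Ka/Ks with a selection class.
#'
#' @param record_a,record_b [plastome_record()] objects
#' @param genes optional character vector restricting the scan
#' @param min_len,start_policy passed to [filter_cds()]
#' @return data.frame: gene, pair, N, S, Nd, Sd, Ka, Ks, omega, class
#' @export
kaks_scan <- function(record_a, record_b, genes = NULL,
                      min_len = 300L, start_policy = "table11") {
  pick <- function(rec) {
    kept <- filter_cds(assemble_cds(rec), min_len = min_len,
                       start_policy = start_policy)$retained
    stats::setNames(kept, vapply(kept, `[[`, character(1), "gene_name"))
  }
  la <- pick(record_a); lb <- pick(record_b)
  shared <- intersect(names(la), names(lb))
  if (!is.null(genes)) shared <- intersect(shared, genes)
  rows <- lapply(sort(shared), function(g) {
    res <- ng86(align_codons(la[[g]], lb[[g]]))
    data.frame(gene = g,
               pair = paste(record_a$identifier, record_b$identifier, sep = "|"),
               N = res$N, S = res$S, Nd = res$Nd, Sd = res$Sd,
               Ka = res$Ka, Ks = res$Ks, omega = res$omega,
               class = classify_selection(res))
  })
  if (!length(rows)) {
    return(data.frame(gene = character(0), pair = character(0), N = numeric(0),
                      S = numeric(0), Nd = numeric(0), Sd = numeric(0),
                      Ka = numeric(0), Ks = numeric(0), omega = numeric(0),
                      class = character(0)))
  }
  do.call(rbind, rows)
}
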
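# Genetic-code machinery shared by the codon-usage and selection modules.
#
# Translation table 11 (bacterial/archaeal/plant-plastid code) assigns the same
# amino acid to every codon as the standard code (the tables differ only in
# which codons may initiate translation), so the synonymous-family structure
# used for RSCU and Wright's ENC is that of the standard code.

BASES <- c("A", "C", "G", "T")

#' All 64 codons in a fixed lexicographic order
#' @keywords internal
all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

# cached lookup tables live here
.plastocub_env <- new.env(parent = emptyenv())

#' Codon -> amino-acid map (translation table 11; one-letter codes, "*" = stop)
#' @keywords internal
codon_table <- function() {
  if (is.null(.plastocub_env$code)) {
    gc <- Biostrings::GENETIC_CODE  # identical residue assignments to table 11
    .plastocub_env$code <- gc[all_codons()]
    names(.plastocub_env$code) <- all_codons()
  }
  .plastocub_env$code
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate an in-frame DNA string under table 11
#'
#' @param dna in-frame DNA string over A/C/G/T (length a multiple of 3)
#' @return character vector of one-letter amino acids ("*" for stops)
#' @keywords internal
translate_codons <- function(dna) {
  cods <- split_codons(dna)
  unname(codon_table()[cods])
}

#' Split an in-frame DNA string into its codons
#' @keywords internal
split_codons <- function(dna) {
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(dna, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Synonymous-family sizes per amino acid (stops excluded)
#' @keywords internal
family_sizes <- function() {
  code <- codon_table()
  sense <- code[code != "*"]
  table(sense)
}

# --- NG86 lookup tables ------------------------------------------------------
#
# For each sense codon, the synonymous site count: at each of the three
# positions the synonymous fraction is (synonymous single-base changes) /
# (single-base changes not creating a stop); a position where every change
# creates a stop carries no site mass (does not occur under standard stops).
# For each ordered pair of sense codons, the pathway-averaged synonymous and
# nonsynonymous difference counts: average over all orderings of the differing
# positions, excluding pathways that pass through a stop codon.

ng86_site_table <- function() {
  if (!is.null(.plastocub_env$ng86_sites)) return(.plastocub_env$ng86_sites)
  code <- codon_table()
  sense <- names(code)[code != "*"]
  syn <- numeric(length(sense))
  mass <- numeric(length(sense))
  names(syn) <- names(mass) <- sense
  for (cod in sense) {
    aa <- code[[cod]]
    s_tot <- 0
    m_tot <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(BASES, substr(cod, pos, pos)), function(b) {
        x <- cod
        substr(x, pos, pos) <- b
        x
      }, character(1))
      aa_alts <- code[alts]
      nonstop <- aa_alts != "*"
      if (!any(nonstop)) next  # position carries no site mass
      frac <- sum(aa_alts[nonstop] == aa) / sum(nonstop)
      s_tot <- s_tot + frac
      m_tot <- m_tot + 1
    }
    syn[cod] <- s_tot
    mass[cod] <- m_tot
  }
  .plastocub_env$ng86_sites <- list(syn = syn, mass = mass)
  .plastocub_env$ng86_sites
}

ng86_diff_table <- function() {
  if (!is.null(.plastocub_env$ng86_diffs)) return(.plastocub_env$ng86_diffs)
  code <- codon_table()
  sense <- names(code)[code != "*"]
  k <- length(sense)
  sd_tab <- matrix(0, k, k, dimnames = list(sense, sense))
  nd_tab <- matrix(0, k, k, dimnames = list(sense, sense))
  blocked <- matrix(FALSE, k, k, dimnames = list(sense, sense))
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in seq_len(k)) {
    a <- sense[i]
    for (j in seq_len(k)) {
      if (i == j) next
      b <- sense[j]
      dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      nd <- length(dpos)
      if (nd == 1L) {
        if (code[[a]] == code[[b]]) sd_tab[i, j] <- 1 else nd_tab[i, j] <- 1
        next
      }
      perms <- if (nd == 2L) perms2 else perms3
      s_sum <- 0; n_sum <- 0; n_ok <- 0L
      for (p in perms) {
        cur <- a
        s <- 0; nn <- 0; ok <- TRUE
        for (step in dpos[p]) {
          nxt <- cur
          substr(nxt, step, step) <- substr(b, step, step)
          if (code[[nxt]] == "*") { ok <- FALSE; break }
          if (code[[cur]] == code[[nxt]]) s <- s + 1 else nn <- nn + 1
          cur <- nxt
        }
        if (ok) { s_sum <- s_sum + s; n_sum <- n_sum + nn; n_ok <- n_ok + 1L }
      }
      if (n_ok == 0L) {
        blocked[i, j] <- TRUE
      } else {
        sd_tab[i, j] <- s_sum / n_ok
        nd_tab[i, j] <- n_sum / n_ok
      }
    }
  }
  .plastocub_env$ng86_diffs <- list(sd = sd_tab, nd = nd_tab, blocked = blocked)
  .plastocub_env$ng86_diffs
}

#' Reverse complement of a DNA string
#'
#' Ambiguity code N complements to N; other characters pass through
#' [chartr()] unchanged and should be normalized upstream.
#' @param x DNA string
#' @return the reverse complement, 5'->3'
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}
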
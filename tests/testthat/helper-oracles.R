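# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they share no code path with the implementation.

# naive all-pairs, all-sites nucleotide diversity
naive_pi <- function(rows) {
  mats <- strsplit(rows, "")
  L <- length(mats[[1]])
  usable <- vapply(seq_len(L), function(k) {
    all(vapply(mats, function(m) m[k] %in% c("A", "C", "G", "T"), logical(1)))
  }, logical(1))
  u <- sum(usable)
  if (u == 0) return(list(pi = NA_real_, usable = 0L))
  n <- length(mats)
  total <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sum(mats[[i]][usable] != mats[[j]][usable])
    total <- total + d / u
    npairs <- npairs + 1
  }
  list(pi = total / npairs, usable = u)
}

# brute-force NG86 pathway-averaged difference counts for one codon pair,
# written recursively against Biostrings::GENETIC_CODE
brute_codon_diffs <- function(a, b) {
  code <- Biostrings::GENETIC_CODE
  walk <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(s = 0, n = 0)))
    out <- list()
    for (k in seq_along(remaining)) {
      pos <- remaining[k]
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (code[[nxt]] == "*") next
      step <- if (code[[cur]] == code[[nxt]]) c(s = 1, n = 0) else c(s = 0, n = 1)
      for (tail in walk(nxt, remaining[-k])) {
        out[[length(out) + 1]] <- step + tail
      }
    }
    out
  }
  dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(dpos)) return(c(s = 0, n = 0, blocked = 0))
  paths <- walk(a, dpos)
  if (!length(paths)) return(c(s = NA, n = NA, blocked = 1))
  avg <- Reduce(`+`, paths) / length(paths)
  c(avg, blocked = 0)
}

# random sense codons (no stops)
random_sense_codons <- function(n) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

# random in-frame CDS with valid start/stop and no internal stop
random_clean_cds <- function(n_codons, gene = "toy") {
  coding_sequence(gene, "test",
                  paste0("ATG", paste(random_sense_codons(n_codons - 2), collapse = ""),
                         "TAA"))
}

# star-tree alignment: 4 children of one ancestor, per-site substitution
# probability p per branch (uniform choice among the 3 alternative bases)
star_tree_alignment <- function(len, p, n_seq = 4) {
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  child <- function() {
    x <- anc
    hit <- which(runif(len) < p)
    for (k in hit) x[k] <- sample(setdiff(c("A", "C", "G", "T"), x[k]), 1)
    paste(x, collapse = "")
  }
  seqs <- vapply(seq_len(n_seq), function(i) child(), character(1))
  names(seqs) <- paste0("t", seq_len(n_seq))
  alignment_matrix(seqs)
}
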
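# Quadripartite structure: inverted-repeat detection, region statistics,
# junction/border-gene geometry, and the phylogeny-ready LSC+IRb+SSC sequence.
#
# The partition is reported on a canonical linearization that starts at LSC
# base 1 and runs LSC -> IRb -> SSC -> IRa, with LSC the longer single-copy
# arc. `offset` maps input coordinates to this frame:
# canonical = ((input - 1 - offset) mod n) + 1.

to_canonical_pos <- function(pos, offset, n) ((pos - 1L - offset) %% n) + 1L

rotate_sequence <- function(seq, offset) {
  n <- nchar(seq)
  offset <- offset %% n
  if (offset == 0L) return(seq)
  paste0(substr(seq, offset + 1L, n), substr(seq, 1L, offset))
}

# forward circular overlap test for arcs [a, a+la-1], [b, b+lb-1] (mod n)
circ_disjoint <- function(a, la, b, lb, n) {
  d1 <- (b - a) %% n
  d2 <- (a - b) %% n
  d1 >= la && d2 >= lb
}

#' Detect the inverted-repeat pair and delineate LSC/IRb/SSC/IRa
#'
#' Finds the maximal-length pair of disjoint, exactly reverse-complementary
#' substrings of length >= `min_len` on the circular sequence (seed-and-extend
#' on k-mers of the reverse complement; mismatch tolerance 0). The genome is
#' canonicalized as LSC -> IRb -> SSC -> IRa with LSC the longer single-copy
#' arc; junction positions are the last base of the upstream region.
#'
#' @param sequence DNA string (treated as circular when `is_circular`)
#' @param min_len minimum repeat length in bp (default 1000)
#' @param is_circular logical; circular topology (default TRUE)
#' @return an object of class `quadripartite_partition`; when no repeat of the
#'   required length exists, a partition with `found = FALSE`
#' @export
detect_inverted_repeats <- function(sequence, min_len = 1000L, is_circular = TRUE) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  no_structure <- structure(
    list(found = FALSE, genome_length = n, min_len = as.integer(min_len)),
    class = "quadripartite_partition")
  if (n < 2L * min_len) return(no_structure)

  ss <- if (is_circular) paste0(sequence, sequence) else sequence
  len2 <- nchar(ss)
  k <- as.integer(min(min_len, 24L))
  rr <- revcomp(ss)
  np <- len2 - k + 1L
  kms <- substring(ss, seq_len(np), seq_len(np) + k - 1L)
  kmr <- substring(rr, seq_len(np), seq_len(np) + k - 1L)

  uk <- unique(c(kms, kmr))
  is_id <- match(kms, uk)
  ir_id <- match(kmr, uk)
  by_id <- split(seq_len(np), ir_id)
  hits <- which(as.character(is_id) %in% names(by_id))
  if (length(hits) == 0L) return(no_structure)
  rpos <- by_id[as.character(is_id[hits])]
  i_vec <- rep(hits, lengths(rpos))
  p_vec <- unlist(rpos, use.names = FALSE)

  # maximal runs along each diagonal (i - p constant, i consecutive)
  d_vec <- i_vec - p_vec
  ord <- order(d_vec, i_vec)
  i_vec <- i_vec[ord]; p_vec <- p_vec[ord]; d_vec <- d_vec[ord]
  brk <- c(TRUE, diff(d_vec) != 0L | diff(i_vec) != 1L)
  run <- cumsum(brk)
  i0 <- tapply(i_vec, run, min)
  i1 <- tapply(i_vec, run, max)
  p0 <- tapply(p_vec, run, min)
  lens <- as.integer(i1 - i0 + k)

  cand <- data.frame(i = as.integer(i0), p = as.integer(p0), L = lens)
  cand <- cand[cand$L >= min_len & cand$L <= floor(n / 2), , drop = FALSE]
  if (nrow(cand) == 0L) return(no_structure)

  cand$a <- ((cand$i - 1L) %% n) + 1L
  j <- len2 - cand$p - cand$L + 2L
  cand$b <- ((j - 1L) %% n) + 1L
  ok <- mapply(function(a, b, L) circ_disjoint(a, L, b, L, n),
               cand$a, cand$b, cand$L)
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(no_structure)

  cand$key <- paste(pmin(cand$a, cand$b), pmax(cand$a, cand$b), cand$L)
  cand <- cand[!duplicated(cand$key), , drop = FALSE]
  best_len <- max(cand$L)
  best <- cand[cand$L == best_len, , drop = FALSE]
  if (nrow(best) > 1L) {
    warning("multiple maximal inverted-repeat candidates of length ", best_len,
            "; tie broken at the smallest start")
    best <- best[order(pmin(best$a, best$b)), , drop = FALSE]
  }
  a <- best$a[1]; b <- best$b[1]; L <- best$L[1]

  # single-copy arcs between the two repeat copies
  arc1_start <- ((a + L - 1L) %% n) + 1L     # after copy A, before copy B
  arc2_start <- ((b + L - 1L) %% n) + 1L     # after copy B, before copy A
  arc1_len <- (b - arc1_start) %% n
  arc2_len <- (a - arc2_start) %% n
  if (arc1_len >= arc2_len) {
    lsc_start <- arc1_start; lsc_len <- arc1_len; ssc_len <- arc2_len
  } else {
    lsc_start <- arc2_start; lsc_len <- arc2_len; ssc_len <- arc1_len
  }
  offset <- (lsc_start - 1L) %% n
  canon <- rotate_sequence(sequence, offset)

  irb <- c(lsc_len + 1L, lsc_len + L)
  ssc <- c(lsc_len + L + 1L, lsc_len + L + ssc_len)
  ira <- c(lsc_len + L + ssc_len + 1L, n)
  regions <- list(lsc = c(1L, lsc_len), irb = irb, ssc = ssc, ira = ira)
  region_length <- vapply(regions, function(r) r[2] - r[1] + 1L, integer(1))
  region_gc <- vapply(regions, function(r) gc_percent(substr(canon, r[1], r[2])),
                      numeric(1))
  structure(
    list(found = TRUE, genome_length = n, min_len = as.integer(min_len),
         offset = as.integer(offset),
         lsc = regions$lsc, irb = regions$irb, ssc = regions$ssc, ira = regions$ira,
         junctions = c(JLB = regions$lsc[2], JSB = irb[2], JSA = ssc[2], JLA = n),
         ir_length = as.integer(L),
         region_length = region_length, region_gc = region_gc),
    class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  if (!x$found) {
    cat("<quadripartite_partition> no quadripartite structure (min_len ",
        x$min_len, ")\n", sep = "")
    return(invisible(x))
  }
  cat("<quadripartite_partition> genome ", x$genome_length, " bp, IR ",
      x$ir_length, " bp\n", sep = "")
  for (r in c("lsc", "irb", "ssc", "ira")) {
    cat(sprintf("  %-4s %7d..%-7d %7d bp  GC %.1f%%\n", toupper(r),
                x[[r]][1], x[[r]][2], x$region_length[[r]], x$region_gc[[r]]))
  }
  invisible(x)
}

gc_percent <- function(seq) {
  tab <- table(strsplit(seq, "")[[1]])
  acgt <- sum(tab[intersect(names(tab), c("A", "C", "G", "T"))])
  if (acgt == 0) return(NA_real_)
  gcs <- sum(tab[intersect(names(tab), c("G", "C"))])
  100 * gcs / acgt
}

#' Region lengths and GC content for a partitioned genome
#'
#' GC is (G+C)/(A+C+G+T) per region, N excluded from numerator and
#' denominator, reported as a percent.
#'
#' @param record a [plastome_record()]
#' @param partition the matching [detect_inverted_repeats()] result
#' @return data.frame with columns region, start, end, length_bp, gc_pct
#' @export
region_statistics <- function(record, partition) {
  if (!partition$found) stop("partition has no quadripartite structure")
  if (nchar(record$sequence) != partition$genome_length) {
    stop("partition genome length (", partition$genome_length,
         ") does not match record length (", nchar(record$sequence), ")")
  }
  canon <- rotate_sequence(record$sequence, partition$offset)
  rows <- lapply(c("lsc", "irb", "ssc", "ira"), function(r) {
    iv <- partition[[r]]
    data.frame(region = toupper(r), start = iv[1], end = iv[2],
               length_bp = iv[2] - iv[1] + 1L,
               gc_pct = round(gc_percent(substr(canon, iv[1], iv[2])), 1))
  })
  do.call(rbind, rows)
}

# canonical-coordinate coverage intervals of one feature (may split on origin)
feature_canonical_intervals <- function(feature, offset, n) {
  out <- list()
  for (i in seq_len(nrow(feature$segments))) {
    s <- feature$segments$start[i]; e <- feature$segments$end[i]
    ivs <- if (s <= e) list(c(s, e)) else list(c(s, n), c(1L, e))
    for (iv in ivs) {
      cs <- to_canonical_pos(iv[1], offset, n)
      ce <- to_canonical_pos(iv[2], offset, n)
      if (cs <= ce) out[[length(out) + 1L]] <- c(cs, ce)
      else { out[[length(out) + 1L]] <- c(cs, n); out[[length(out) + 1L]] <- c(1L, ce) }
    }
  }
  out
}

covers <- function(intervals, pos) {
  any(vapply(intervals, function(iv) pos >= iv[1] && pos <= iv[2], logical(1)))
}

overlap_with <- function(intervals, lo, hi) {
  sum(vapply(intervals, function(iv) {
    max(0L, min(iv[2], hi) - max(iv[1], lo) + 1L)
  }, integer(1)))
}

#' Genes at the four region junctions
#'
#' For each junction (JLB, JSB, JSA, JLA) reports every gene spanning it, with
#' the number of bases lying inside the IR-side region, and the nearest
#' non-spanning gene on each flank with its distance to the junction. A
#' junction belongs to the last base of its upstream region; a gene spans it
#' when it covers both that base and the next one.
#'
#' @param record a [plastome_record()]
#' @param partition the matching partition
#' @return data.frame with columns junction, gene_name, relation, overlap_bp,
#'   distance_bp
#' @export
junction_report <- function(record, partition) {
  if (!partition$found) stop("partition has no quadripartite structure")
  n <- partition$genome_length
  feats <- record$features
  if (length(feats) == 0L) {
    return(data.frame(junction = character(0), gene_name = character(0),
                      relation = character(0), overlap_bp = integer(0),
                      distance_bp = integer(0)))
  }
  ivsets <- lapply(feats, feature_canonical_intervals,
                   offset = partition$offset, n = n)
  gene_names <- vapply(feats, `[[`, character(1), "gene_name")
  spans_start <- vapply(ivsets, function(iv) min(vapply(iv, `[`, integer(1), 1)), integer(1))
  spans_end <- vapply(ivsets, function(iv) max(vapply(iv, `[`, integer(1), 2)), integer(1))

  ir_side <- list(
    JLB = partition$irb,  # downstream region is IRb
    JSB = partition$irb,  # upstream region is IRb
    JSA = partition$ira,  # downstream region is IRa
    JLA = partition$ira   # upstream region is IRa
  )
  rows <- list()
  for (jn in c("JLB", "JSB", "JSA", "JLA")) {
    J <- partition$junctions[[jn]]
    J_next <- (J %% n) + 1L
    spanning <- vapply(seq_along(feats), function(i) {
      covers(ivsets[[i]], J) && covers(ivsets[[i]], J_next)
    }, logical(1))
    for (i in which(spanning)) {
      ov <- overlap_with(ivsets[[i]], ir_side[[jn]][1], ir_side[[jn]][2])
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene_name = gene_names[i], relation = "spans",
        overlap_bp = ov, distance_bp = 0L)
    }
    non <- which(!spanning)
    if (length(non)) {
      d_up <- (J - spans_end[non]) %% n
      iu <- non[which.min(d_up)]
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene_name = gene_names[iu], relation = "upstream",
        overlap_bp = 0L, distance_bp = as.integer(min(d_up)))
      d_dn <- (spans_start[non] - J - 1L) %% n
      idn <- non[which.min(d_dn)]
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jn, gene_name = gene_names[idn], relation = "downstream",
        overlap_bp = 0L, distance_bp = as.integer(min(d_dn)))
    }
  }
  do.call(rbind, rows)
}

#' Extract the LSC+IRb+SSC sequence (IRa excluded)
#'
#' The concatenation used for phylogeny-ready datasets: the canonical
#' linearization with the second inverted-repeat copy removed. Its length is
#' the genome length minus `ir_length`.
#'
#' @param record a [plastome_record()]
#' @param partition the matching partition
#' @return DNA string of length `genome_length - ir_length`
#' @export
extract_lsc_irb_ssc <- function(record, partition) {
  if (!partition$found) stop("partition has no quadripartite structure")
  if (nchar(record$sequence) != partition$genome_length) {
    stop("partition does not match record")
  }
  canon <- rotate_sequence(record$sequence, partition$offset)
  substr(canon, 1L, partition$genome_length - partition$ir_length)
}
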
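# Sliding-window nucleotide diversity over a multiple-genome alignment.
#
# pi is the mean pairwise per-site difference: over usable columns (no gap or
# N in any sequence), pi = 2/(n(n-1)) * sum_{i<j} d_ij with d_ij = differing
# usable sites / usable sites. Gap/N columns are excluded from numerator and
# denominator alike.

#' Construct an alignment matrix
#'
#' @param sequences named character vector of equal-length aligned sequences
#'   over A/C/G/T/N/- (at least two)
#' @return object of class `alignment_matrix`: a character matrix with one row
#'   per sequence
#' @export
alignment_matrix <- function(sequences) {
  if (length(sequences) < 2L) stop("an alignment needs at least two sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("aligned sequences must be equal length")
  mat <- do.call(rbind, strsplit(toupper(sequences), ""))
  rownames(mat) <- names(sequences)
  structure(mat, class = c("alignment_matrix", class(mat)))
}

# per-column usability and pairwise difference indicators (pairs x L)
alignment_indicators <- function(mat) {
  n <- nrow(mat)
  usable <- colSums(matrix(mat %in% c("A", "C", "G", "T"), nrow = n)) == n
  pairs <- utils::combn(n, 2)
  diffs <- matrix(FALSE, ncol(pairs), ncol(mat))
  for (p in seq_len(ncol(pairs))) {
    diffs[p, ] <- mat[pairs[1, p], ] != mat[pairs[2, p], ]
  }
  list(usable = usable, diffs = diffs)
}

#' Nucleotide diversity of an alignment slice
#'
#' @param mat an [alignment_matrix()] (or a character matrix slice of one)
#' @return list with `pi` (NA when no usable sites) and `usable_sites`
#' @export
nucleotide_diversity <- function(mat) {
  ind <- alignment_indicators(mat)
  usable <- sum(ind$usable)
  if (usable == 0L) return(list(pi = NA_real_, usable_sites = 0L))
  d <- rowSums(ind$diffs[, ind$usable, drop = FALSE]) / usable
  list(pi = mean(d), usable_sites = usable)
}

#' Sliding-window nucleotide diversity
#'
#' Windows start at 1, 1+step, ... while they fit inside the alignment; each
#' window's pi is computed over its usable columns. A window longer than the
#' alignment degenerates to a single truncated window covering everything.
#'
#' @param alignment an [alignment_matrix()]
#' @param window window length in alignment columns (default 600)
#' @param step step size in columns (default 200)
#' @return data.frame (start, end, midpoint, usable_sites, pi, truncated) with
#'   attributes `mean_pi` (mean over windows) and `max_window` (row index)
#' @export
sliding_windows <- function(alignment, window = 600L, step = 200L) {
  if (step < 1L || window < step) stop("need window >= step >= 1")
  L <- ncol(alignment)
  truncated <- window > L
  starts <- if (truncated) 1L else seq(1L, L - window + 1L, by = step)
  ends <- pmin(starts + window - 1L, L)

  ind <- alignment_indicators(alignment)
  cum_usable <- c(0L, cumsum(ind$usable))
  cum_diffs <- cbind(0L, t(apply(ind$diffs & rep(ind$usable, each = nrow(ind$diffs)),
                                 1, cumsum)))
  usable <- cum_usable[ends + 1L] - cum_usable[starts]
  pis <- vapply(seq_along(starts), function(i) {
    u <- usable[i]
    if (u == 0L) return(NA_real_)
    d <- (cum_diffs[, ends[i] + 1L] - cum_diffs[, starts[i]]) / u
    mean(d)
  }, numeric(1))

  out <- data.frame(start = starts, end = ends,
                    midpoint = floor((starts + ends) / 2),
                    usable_sites = usable, pi = pis, truncated = truncated)
  attr(out, "mean_pi") <- mean(pis, na.rm = TRUE)
  attr(out, "max_window") <- if (all(is.na(pis))) NA_integer_ else which.max(pis)
  out
}

#' Map alignment columns to positions of one reference row
#'
#' @param alignment an [alignment_matrix()]
#' @param ref_label row name of the reference sequence
#' @return integer vector, one entry per column: the reference position, or NA
#'   where the reference carries a gap
#' @export
alignment_to_genome_map <- function(alignment, ref_label) {
  if (!ref_label %in% rownames(alignment)) {
    stop("reference label '", ref_label, "' not in alignment")
  }
  row <- alignment[ref_label, ]
  notgap <- row != "-"
  map <- rep(NA_integer_, length(row))
  map[notgap] <- seq_len(sum(notgap))
  map
}

#' Label windows with overlapping or flanking genes
#'
#' Each window is labeled by the gene overlapping its mapped midpoint, by
#' "upstreamGene~downstreamGene" when the midpoint is intergenic, or by
#' "unaligned" when the reference carries a gap at the midpoint.
#'
#' @param windows data.frame from [sliding_windows()]
#' @param record the reference [plastome_record()]
#' @param map column-to-reference-position map from [alignment_to_genome_map()]
#' @return `windows` with an added `label` column
#' @export
label_windows <- function(windows, record, map) {
  feats <- record$features
  starts <- vapply(feats, function(f) min(f$segments$start), integer(1))
  ends <- vapply(feats, function(f) max(f$segments$end), integer(1))
  names_ <- vapply(feats, `[[`, character(1), "gene_name")
  lab <- character(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    pos <- map[windows$midpoint[i]]
    if (is.na(pos)) { lab[i] <- "unaligned"; next }
    inside <- which(starts <= pos & ends >= pos)
    if (length(inside)) { lab[i] <- names_[inside[1]]; next }
    up <- which(ends < pos)
    dn <- which(starts > pos)
    up_name <- if (length(up)) names_[up[which.max(ends[up])]] else ""
    dn_name <- if (length(dn)) names_[dn[which.min(starts[dn])]] else ""
    lab[i] <- paste0(up_name, "~", dn_name)
  }
  windows$label <- lab
  windows
}
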
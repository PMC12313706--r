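# Genome data model and GenBank/FASTA I/O.
#
# Coordinates are 1-based inclusive throughout (GenBank convention). A feature
# is an ordered list of segments in extraction order; a minus-strand segment is
# reverse-complemented on extraction, so a classic complement(join(a..b,c..d))
# location becomes the segment list [(c,d,-),(a,b,-)].

#' Construct a gene feature
#'
#' @param gene_name gene symbol (e.g. "ndhF")
#' @param feature_kind one of "CDS", "tRNA", "rRNA", "gene"
#' @param strand "+" or "-" (feature-level; per-segment strands live in
#'   `segments$strand`)
#' @param segments data.frame with columns `start`, `end` (1-based inclusive)
#'   and optionally `strand`; rows are in extraction order. A segment with
#'   `start > end` wraps the circular origin.
#' @param is_trans_spliced logical; TRUE for order()-joined or mixed-strand
#'   locations (rps12-style trans-splicing)
#' @param transl_table genetic code table number (11 for plastids)
#' @return an object of class `gene_feature`
#' @export
gene_feature <- function(gene_name, feature_kind = "CDS", strand = "+",
                         segments, is_trans_spliced = FALSE, transl_table = 11L) {
  if (!feature_kind %in% c("CDS", "tRNA", "rRNA", "gene")) {
    stop("unsupported feature kind: ", feature_kind)
  }
  segments <- as.data.frame(segments)
  if (nrow(segments) == 0L) stop("feature needs at least one segment")
  if (is.null(segments$strand)) segments$strand <- strand
  segments <- segments[, c("start", "end", "strand")]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  structure(
    list(gene_name = gene_name, feature_kind = feature_kind, strand = strand,
         segments = segments, is_trans_spliced = isTRUE(is_trans_spliced),
         transl_table = as.integer(transl_table)),
    class = "gene_feature"
  )
}

#' Construct an annotated plastome record
#'
#' Ambiguity codes other than N are normalized to N with a warning; the
#' sequence is stored uppercase.
#'
#' @param identifier accession or label
#' @param organism organism name
#' @param sequence DNA string
#' @param is_circular logical
#' @param features list of [gene_feature()] objects
#' @return an object of class `plastome_record`
#' @export
plastome_record <- function(identifier, organism = "", sequence,
                            is_circular = TRUE, features = list()) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence in record ", identifier)
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    warning("record ", identifier, ": ", nchar(bad),
            " ambiguity characters normalized to N")
    sequence <- gsub("[^ACGTN]", "N", sequence)
  }
  for (f in features) {
    segs <- f$segments
    wraps <- segs$start > segs$end
    if (any(wraps) && !is_circular) {
      stop("feature ", f$gene_name, " wraps the origin of a linear record")
    }
    if (any(segs$start < 1L) || any(segs$end > n) || any(segs$start > n)) {
      stop("feature ", f$gene_name, " has segments outside [1, ", n, "]")
    }
  }
  structure(
    list(identifier = identifier, organism = organism, sequence = sequence,
         is_circular = isTRUE(is_circular), features = features),
    class = "plastome_record"
  )
}

#' @export
print.plastome_record <- function(x, ...) {
  kinds <- vapply(x$features, function(f) f$feature_kind, character(1))
  cat("<plastome_record> ", x$identifier,
      if (nzchar(x$organism)) paste0(" (", x$organism, ")"), "\n",
      "  length: ", nchar(x$sequence), " bp",
      if (x$is_circular) " (circular)", "\n",
      "  features: ", length(x$features),
      if (length(kinds)) paste0(" [", paste(sprintf("%s: %d",
        names(table(kinds)), table(kinds)), collapse = ", "), "]"), "\n",
      sep = "")
  invisible(x)
}

# --- GenBank location strings -------------------------------------------------

# Parse a GenBank location into segments in extraction order.
# Returns list(segments = data.frame(start, end, strand), is_order = logical)
# or NULL if the location cannot be parsed.
parse_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  parse_node <- function(s) {
    if (grepl("^complement\\(", s)) {
      inner <- parse_node(sub("\\)$", "", sub("^complement\\(", "", s)))
      if (is.null(inner)) return(NULL)
      segs <- inner$segments[rev(seq_len(nrow(inner$segments))), , drop = FALSE]
      segs$strand <- ifelse(segs$strand == "+", "-", "+")
      return(list(segments = segs, is_order = inner$is_order))
    }
    if (grepl("^(join|order)\\(", s)) {
      is_order <- grepl("^order", s)
      body <- sub("\\)$", "", sub("^(join|order)\\(", "", s))
      # split on top-level commas
      depth <- 0L; parts <- character(0); cur <- ""
      for (ch in strsplit(body, "")[[1]]) {
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") depth <- depth - 1L
        if (ch == "," && depth == 0L) { parts <- c(parts, cur); cur <- "" }
        else cur <- paste0(cur, ch)
      }
      parts <- c(parts, cur)
      nodes <- lapply(parts, parse_node)
      if (any(vapply(nodes, is.null, logical(1)))) return(NULL)
      segs <- do.call(rbind, lapply(nodes, `[[`, "segments"))
      ord <- is_order || any(vapply(nodes, `[[`, logical(1), "is_order"))
      return(list(segments = segs, is_order = ord))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "\\.\\.")[[1]])
      return(list(segments = data.frame(start = ab[1], end = ab[2], strand = "+"),
                  is_order = FALSE))
    }
    if (grepl("^[0-9]+$", s)) {
      p <- as.integer(s)
      return(list(segments = data.frame(start = p, end = p, strand = "+"),
                  is_order = FALSE))
    }
    NULL
  }
  parse_node(loc)
}

format_location <- function(feature) {
  segs <- feature$segments
  one <- function(i) {
    s <- sprintf("%d..%d", segs$start[i], segs$end[i])
    if (segs$strand[i] == "-") s <- sprintf("complement(%s)", s) else s
  }
  if (nrow(segs) == 1L) return(one(1))
  if (all(segs$strand == "-")) {
    # invert the extraction-order transform back to complement(join(...))
    fwd <- rev(sprintf("%d..%d", segs$start, segs$end))
    return(sprintf("complement(join(%s))", paste(fwd, collapse = ",")))
  }
  op <- if (feature$is_trans_spliced) "order" else "join"
  sprintf("%s(%s)", op, paste(vapply(seq_len(nrow(segs)), one, character(1)),
                              collapse = ","))
}

# --- GenBank flat-file reader/writer -----------------------------------------

#' Read annotated genomes from a GenBank flat file
#'
#' Parses LOCUS/ACCESSION/ORGANISM headers, the feature table (CDS, tRNA,
#' rRNA and gene features; join/complement/order locations) and the ORIGIN
#' sequence. Unparseable locations are skipped with a warning; a record
#' without sequence is an error. Gene names come from the /gene qualifier,
#' falling back to /product.
#'
#' @param path path to a GenBank flat file (may contain multiple records)
#' @return list of [plastome_record()] objects
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_breaks <- grep("^//", lines)
  if (length(rec_breaks) == 0L) rec_breaks <- length(lines) + 1L
  starts <- c(1L, head(rec_breaks, -1L) + 1L)
  records <- list()
  for (r in seq_along(rec_breaks)) {
    chunk <- lines[starts[r]:(rec_breaks[r] - 1L)]
    if (!any(nzchar(trimws(chunk)))) next
    records[[length(records) + 1L]] <- parse_genbank_record(chunk)
  }
  records
}

parse_genbank_record <- function(chunk) {
  locus_line <- grep("^LOCUS", chunk, value = TRUE)[1]
  locus_fields <- strsplit(trimws(locus_line), "[[:space:]]+")[[1]]
  identifier <- locus_fields[2]
  is_circular <- any(grepl("circular", locus_fields, ignore.case = TRUE))
  acc <- grep("^ACCESSION", chunk, value = TRUE)
  if (length(acc) && length(strsplit(trimws(acc[1]), "[[:space:]]+")[[1]]) > 1) {
    identifier <- strsplit(trimws(acc[1]), "[[:space:]]+")[[1]][2]
  }
  org_line <- grep("^  ORGANISM", chunk, value = TRUE)
  organism <- if (length(org_line)) trimws(sub("^  ORGANISM", "", org_line[1])) else ""

  origin_at <- grep("^ORIGIN", chunk)
  if (length(origin_at) == 0L) stop("record ", identifier, " has no ORIGIN sequence")
  seq_lines <- if (origin_at[1] < length(chunk)) {
    chunk[(origin_at[1] + 1L):length(chunk)]
  } else character(0)
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("record ", identifier, " has an empty sequence")

  features <- list()
  feat_at <- grep("^FEATURES", chunk)
  if (length(feat_at)) {
    ftab <- chunk[(feat_at[1] + 1L):(origin_at[1] - 1L)]
    new_feat <- grepl("^     \\S", ftab)
    idx <- cumsum(new_feat)
    for (g in split(ftab[idx > 0], idx[idx > 0])) {
      head_fields <- strsplit(trimws(g[1]), "[[:space:]]+")[[1]]
      kind <- head_fields[1]
      if (!kind %in% c("CDS", "tRNA", "rRNA", "gene")) next
      body <- paste(trimws(g), collapse = "\n")
      # location = everything from after the key up to the first qualifier
      body1 <- sub(paste0("^", kind, "[[:space:]]+"), "", body)
      parts <- strsplit(body1, "\n/")[[1]]
      loc_str <- gsub("\n", "", parts[1])
      quals <- if (length(parts) > 1) parts[-1] else character(0)
      qual_get <- function(name) {
        hit <- grep(paste0("^", name, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        v <- sub(paste0("^", name, "="), "", hit[1])
        gsub("\n", " ", gsub("\"", "", v))
      }
      loc <- parse_location(loc_str)
      if (is.null(loc)) {
        warning("record ", identifier, ": skipping ", kind,
                " feature with unparseable location '", loc_str, "'")
        next
      }
      gene <- qual_get("gene")
      if (is.na(gene)) gene <- qual_get("product")
      if (is.na(gene)) gene <- kind
      tt <- suppressWarnings(as.integer(qual_get("transl_table")))
      strands <- unique(loc$segments$strand)
      mixed <- length(strands) > 1L
      features[[length(features) + 1L]] <- gene_feature(
        gene_name = gene, feature_kind = kind,
        strand = loc$segments$strand[1],
        segments = loc$segments,
        is_trans_spliced = loc$is_order || mixed,
        transl_table = if (is.na(tt)) 11L else tt
      )
    }
  }
  plastome_record(identifier, organism, sequence, is_circular, features)
}

#' Write plastome records as a GenBank flat file
#'
#' Emits the subset of GenBank that [read_genbank()] parses, so that a
#' write/read round trip preserves every field.
#'
#' @param records list of [plastome_record()] objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genbank <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    n <- nchar(rec$sequence)
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA",
                       rec$identifier, n,
                       if (rec$is_circular) "circular" else "linear"), con)
    writeLines(sprintf("ACCESSION   %s", rec$identifier), con)
    writeLines("SOURCE      synthetic", con)
    writeLines(sprintf("  ORGANISM  %s", rec$organism), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", n), con)
    for (f in rec$features) {
      writeLines(sprintf("     %-15s %s", f$feature_kind, format_location(f)), con)
      writeLines(sprintf("                     /gene=\"%s\"", f$gene_name), con)
      if (f$feature_kind == "CDS") {
        writeLines(sprintf("                     /transl_table=%d", f$transl_table), con)
      }
    }
    writeLines("ORIGIN", con)
    starts <- seq(1L, n, by = 60L)
    for (s in starts) {
      block <- substr(rec$sequence, s, min(s + 59L, n))
      tens <- substring(block, seq(1, nchar(block), 10),
                        pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
      writeLines(sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# --- feature sequence extraction ----------------------------------------------

#' Extract the coding-strand sequence of a feature
#'
#' Segments are concatenated in annotation (extraction) order; minus-strand
#' segments are reverse-complemented, so the result reads 5'->3' on the coding
#' strand. Origin-wrapping segments are supported on circular records.
#'
#' @param record a [plastome_record()]
#' @param feature a [gene_feature()] belonging to `record`
#' @return DNA string
#' @export
extract_feature_sequence <- function(record, feature) {
  n <- nchar(record$sequence)
  segs <- feature$segments
  pieces <- character(nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]
    if (s > e) {
      if (!record$is_circular) {
        stop("segment ", s, "..", e, " wraps the origin of a linear record")
      }
      piece <- paste0(substr(record$sequence, s, n), substr(record$sequence, 1L, e))
    } else {
      if (s < 1L || e > n) stop("segment ", s, "..", e, " out of bounds [1, ", n, "]")
      piece <- substr(record$sequence, s, e)
    }
    if (segs$strand[i] == "-") piece <- revcomp(piece)
    pieces[i] <- piece
  }
  paste(pieces, collapse = "")
}

# --- FASTA --------------------------------------------------------------------

#' Write sequences as FASTA (70-column wrapping)
#'
#' @param sequences named character vector of DNA strings (names are labels)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(sequences, path) {
  sequences <- unlist(sequences)
  if (is.null(sequences)) sequences <- stats::setNames(character(0), character(0))
  if (length(sequences) && anyDuplicated(names(sequences))) {
    stop("duplicate FASTA labels")
  }
  set <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read FASTA sequences (optionally aligned, with gaps)
#'
#' @param path FASTA path
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("[[:space:]].*$", "", names(set))
  out
}
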
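# Synthetic plastome generation with known ground truth: planted inverted
# repeats, annotated CDS with controllable per-position base composition,
# per-gene selection strength (omega) during divergence, and genesets with a
# tunable mutation-vs-selection structure for the neutrality diagnostic.
#
# Every operation is a pure function of (spec, seed): RNG state is scoped with
# withr::with_seed and never leaks.

#' Default per-position codon base weights
#'
#' Mimics plastid coding composition with first-position GC ~ 0.43, second
#' ~ 0.37 and third ~ 0.18, so synthetic codon-usage outputs resemble
#' AT-rich organellar genes.
#' @return list of three named numeric vectors (w1, w2, w3) summing to 1
#' @export
default_codon_model <- function() {
  list(
    w1 = c(A = 0.285, C = 0.215, G = 0.215, T = 0.285),
    w2 = c(A = 0.315, C = 0.185, G = 0.185, T = 0.315),
    w3 = c(A = 0.410, C = 0.090, G = 0.090, T = 0.410))
}

#' Default gene layout for the synthetic plastome
#' @return data.frame: name, region, strand, n_codons (including start and
#'   stop), junction (NA or JLB/JSB/JSA), junction_overlap_bp
#' @export
default_plastome_genes <- function() {
  data.frame(
    name = c("psbA", "rbcL", "atpA", "rpoB", "petA", "rps4",
             "ndhF", "chlL", "ccsA", "ndhB"),
    region = c(rep("lsc", 6), rep("ssc", 3), "ir"),
    strand = c("+", "+", "-", "+", "-", "+", "+", "-", "+", "+"),
    n_codons = c(300, 450, 400, 600, 300, 180, 350, 280, 300, 150),
    junction = NA_character_,
    junction_overlap_bp = NA_integer_)
}

#' Specification for a synthetic plastome
#'
#' @param seed integer RNG seed
#' @param lsc_len,ir_len,ssc_len region lengths in bp (LSC must be the longer
#'   single-copy region)
#' @param genes gene layout as in [default_plastome_genes()]
#' @param codon_model per-position base weights ([default_codon_model()])
#' @param intergenic_gc GC fraction of single-copy intergenic filler
#' @param ir_gc GC fraction of inverted-repeat filler
#' @return list of class `synthetic_plastome_spec`
#' @export
synthetic_plastome_spec <- function(seed = 1L, lsc_len = 12000L, ir_len = 1500L,
                                    ssc_len = 4000L,
                                    genes = default_plastome_genes(),
                                    codon_model = default_codon_model(),
                                    intergenic_gc = 0.30, ir_gc = 0.46) {
  stopifnot(lsc_len > 0, ir_len > 0, ssc_len > 0, lsc_len >= ssc_len)
  for (w in codon_model) {
    stopifnot(abs(sum(w) - 1) < 1e-8, all(names(w) %in% BASES))
  }
  structure(list(seed = as.integer(seed), lsc_len = as.integer(lsc_len),
                 ir_len = as.integer(ir_len), ssc_len = as.integer(ssc_len),
                 genes = genes, codon_model = codon_model,
                 intergenic_gc = intergenic_gc, ir_gc = ir_gc),
            class = "synthetic_plastome_spec")
}

sample_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

# sample one in-frame coding sequence: ATG + (n_codons-2) sense non-stop
# codons from the positional model + TAA
sample_gene_dna <- function(n_codons, model) {
  stopifnot(n_codons >= 3)
  k <- n_codons - 2L
  draw <- function(m) {
    b1 <- sample(BASES, m, TRUE, prob = model$w1[BASES])
    b2 <- sample(BASES, m, TRUE, prob = model$w2[BASES])
    b3 <- sample(BASES, m, TRUE, prob = model$w3[BASES])
    paste0(b1, b2, b3)
  }
  cods <- draw(k)
  bad <- which(cods %in% STOP_CODONS)
  while (length(bad)) {
    cods[bad] <- draw(length(bad))
    bad <- which(cods %in% STOP_CODONS)
  }
  paste0("ATG", paste(cods, collapse = ""), "TAA")
}

#' Simulate an annotated plastome with a planted inverted repeat
#'
#' Builds LSC + IRb + SSC + IRa with IRa the exact reverse complement of IRb,
#' writes each requested gene as a CDS feature with a valid start and stop
#' codon and no internal stops, duplicates genes placed in the IR, and
#' guarantees the planted repeat is maximal (its flanks do not extend it).
#' Junction-spanning genes are supported via the `junction` and
#' `junction_overlap_bp` columns (JLB: an LSC gene ending overlap bp inside
#' IRb; JSB: an SSC gene starting overlap bp inside IRb; JSA: an SSC gene
#' ending overlap bp inside IRa).
#'
#' @param spec a [synthetic_plastome_spec()]
#' @return list with `record` (a [plastome_record()]) and `truth` (the planted
#'   `quadripartite_partition`)
#' @export
simulate_plastome <- function(spec) {
  withr::with_seed(spec$seed, simulate_plastome_impl(spec))
}

simulate_plastome_impl <- function(spec) {
  lscL <- spec$lsc_len; irL <- spec$ir_len; sscL <- spec$ssc_len
  n <- lscL + 2L * irL + sscL
  lsc <- c(1L, lscL)
  irb <- c(lscL + 1L, lscL + irL)
  ssc <- c(irb[2] + 1L, irb[2] + sscL)
  ira <- c(ssc[2] + 1L, n)
  jpos <- c(JLB = lsc[2], JSB = irb[2], JSA = ssc[2], JLA = n)

  x <- rep(NA_character_, n)
  owner <- integer(n)   # gene index owning each base, 0 = filler
  genes <- spec$genes
  features <- list()
  region_iv <- list(lsc = lsc, ir = irb, ssc = ssc)

  # genomic extent of each gene
  extents <- vector("list", nrow(genes))
  margin <- 2L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- 3L * g$n_codons
    if (!is.na(g$junction)) {
      ov <- g$junction_overlap_bp
      stopifnot(!is.na(ov), ov >= 1, ov < len)
      ext <- switch(g$junction,
        JLB = c(jpos[["JLB"]] + ov - len + 1L, jpos[["JLB"]] + ov),
        JSB = c(jpos[["JSB"]] - ov + 1L, jpos[["JSB"]] - ov + len),
        JSA = c(jpos[["JSA"]] + ov - len + 1L, jpos[["JSA"]] + ov),
        stop("unsupported junction ", g$junction))
      extents[[i]] <- as.integer(ext)
    }
  }
  # sequential placement of plain genes inside their regions, skipping any
  # fixed junction-gene extents
  for (reg in names(region_iv)) {
    idx <- which(genes$region == reg & is.na(genes$junction))
    if (!length(idx)) next
    iv <- region_iv[[reg]]
    fixed <- Filter(Negate(is.null), extents)
    total <- sum(3L * genes$n_codons[idx])
    gapspace <- (iv[2] - iv[1] + 1L) - 2L * margin - total
    spacer <- max(2L, gapspace %/% (length(idx) + 1L))
    cursor <- iv[1] + margin + spacer
    for (i in idx) {
      len <- 3L * genes$n_codons[i]
      repeat {
        clash <- Filter(function(e) cursor <= e[2] + margin &&
                                     cursor + len - 1L >= e[1] - margin, fixed)
        if (!length(clash)) break
        cursor <- max(vapply(clash, `[`, integer(1), 2)) + margin + 1L
      }
      if (cursor + len - 1L > iv[2] - margin) {
        stop("gene ", genes$name[i], " does not fit in region ", reg)
      }
      extents[[i]] <- c(cursor, cursor + len - 1L)
      cursor <- cursor + len + spacer
    }
  }
  # overlap check across all extents
  ext_mat <- do.call(rbind, extents)
  ord <- order(ext_mat[, 1])
  if (any(ext_mat[ord, 1][-1] <= ext_mat[ord, 2][-nrow(ext_mat)])) {
    stop("gene layout produces overlapping genes; adjust the spec")
  }

  # write gene sequences
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    dna <- sample_gene_dna(g$n_codons, spec$codon_model)
    ext <- extents[[i]]
    locus <- if (g$strand == "+") dna else revcomp(dna)
    x[ext[1]:ext[2]] <- strsplit(locus, "")[[1]]
    owner[ext[1]:ext[2]] <- i
    features[[length(features) + 1L]] <- gene_feature(
      gene_name = g$name, feature_kind = "CDS", strand = g$strand,
      segments = data.frame(start = ext[1], end = ext[2], strand = g$strand))
  }

  # mirror-fill the inverted repeat (IRa = exact reverse complement of IRb)
  for (t in 0:(irL - 1L)) {
    pb <- irb[1] + t
    pa <- ira[2] - t
    if (!is.na(x[pb]) && !is.na(x[pa])) {
      if (x[pa] != comp_base(x[pb])) {
        stop("conflicting gene bases at IR mirror positions ", pb, "/", pa,
             ": junction genes on both IR flanks overlap through the mirror; ",
             "plant them in separate genomes")
      }
    } else if (!is.na(x[pb])) {
      x[pa] <- comp_base(x[pb])
    } else if (!is.na(x[pa])) {
      x[pb] <- comp_base(x[pa])
    } else {
      x[pb] <- sample_bases(1L, spec$ir_gc)
      x[pa] <- comp_base(x[pb])
    }
  }
  # duplicate features for IR genes (mirror copy in IRa, opposite strand)
  for (i in which(genes$region == "ir" & is.na(genes$junction))) {
    ext <- extents[[i]]
    ma <- ira[1] + (irb[2] - ext[2])
    mb <- ira[1] + (irb[2] - ext[1])
    strand2 <- if (genes$strand[i] == "+") "-" else "+"
    features[[length(features) + 1L]] <- gene_feature(
      gene_name = genes$name[i], feature_kind = "CDS", strand = strand2,
      segments = data.frame(start = ma, end = mb, strand = strand2))
  }

  # single-copy filler
  unfilled <- which(is.na(x))
  x[unfilled] <- sample_bases(length(unfilled), spec$intergenic_gc)

  # make the planted repeat maximal: break accidental 1-bp extensions
  break_extension <- function(p_keep, p_fix) {
    while (x[p_fix] == comp_base(x[p_keep])) {
      if (owner[p_fix] == 0L) x[p_fix] <<- sample_bases(1L, spec$intergenic_gc)
      else if (owner[p_keep] == 0L) {
        tmp <- p_fix; p_fix <- p_keep; p_keep <- tmp
      } else stop("cannot break IR extension: both flanking bases are gene-owned")
    }
  }
  break_extension(lsc[2], 1L)          # left flank of IRb vs right flank of IRa
  break_extension(ssc[1], ssc[2])      # right flank of IRb vs left flank of IRa

  record <- plastome_record(
    identifier = sprintf("SYN%06d", spec$seed),
    organism = sprintf("Synthetica plastomis seed%d", spec$seed),
    sequence = paste(x, collapse = ""), is_circular = TRUE,
    features = features)
  region_length <- c(lsc = lscL, irb = irL, ssc = sscL, ira = irL)
  region_gc <- vapply(list(lsc = lsc, irb = irb, ssc = ssc, ira = ira),
                      function(iv) gc_percent(substr(record$sequence, iv[1], iv[2])),
                      numeric(1))
  truth <- structure(
    list(found = TRUE, genome_length = n, min_len = NA_integer_, offset = 0L,
         lsc = lsc, irb = irb, ssc = ssc, ira = ira, junctions = jpos,
         ir_length = irL, region_length = region_length, region_gc = region_gc),
    class = "quadripartite_partition")
  list(record = record, truth = truth)
}

#' Specification for genome divergence
#'
#' @param seed integer RNG seed
#' @param omega named numeric vector of per-gene Ka/Ks acceptance
#'   probabilities; `default_omega` fills genes not named
#' @param default_omega fallback omega (default 0.2, clearly purifying)
#' @param coding_rate per-site substitution proposal probability in CDS
#' @param noncoding_rate per-site substitution probability outside CDS
#' @param beta probability a substituted base is G or C (split evenly)
#' @return list of class `divergence_spec`
#' @export
divergence_spec <- function(seed = 1L, omega = numeric(0), default_omega = 0.2,
                            coding_rate = 0.01, noncoding_rate = 0.03,
                            beta = 0.35) {
  stopifnot(coding_rate >= 0, coding_rate <= 1, noncoding_rate >= 0,
            noncoding_rate <= 1, beta >= 0, beta <= 1,
            all(omega >= 0), all(omega <= 1), default_omega >= 0,
            default_omega <= 1)
  structure(list(seed = as.integer(seed), omega = omega,
                 default_omega = default_omega, coding_rate = coding_rate,
                 noncoding_rate = noncoding_rate, beta = beta),
            class = "divergence_spec")
}

draw_new_base <- function(old, beta) {
  repeat {
    b <- if (stats::runif(1) < beta) sample(c("G", "C"), 1L)
         else sample(c("A", "T"), 1L)
    if (b != old) return(b)
  }
}

#' Derive a diverged genome under per-gene selection
#'
#' Noncoding sites substitute i.i.d. at the noncoding rate; coding sites are
#' proposed at the coding rate and accepted if synonymous, with probability
#' omega if nonsynonymous, never if they create (or destroy) a stop. Start and
#' terminal stop codons are frozen. The IRa copy is re-mirrored afterwards so
#' the two repeats stay exact reverse complements; genes lying wholly inside
#' the repeat therefore co-mutate, and bases of junction-spanning genes inside
#' IRa (plus their IRb mirrors) are frozen.
#'
#' @param record a [plastome_record()] from [simulate_plastome()]
#' @param dspec a [divergence_spec()]
#' @param partition optional ground-truth partition; detected when missing
#' @return a derived [plastome_record()] with the same annotation
#' @export
diverge_genome <- function(record, dspec, partition = NULL) {
  withr::with_seed(dspec$seed, diverge_genome_impl(record, dspec, partition))
}

diverge_genome_impl <- function(record, dspec, partition) {
  n <- nchar(record$sequence)
  x <- strsplit(record$sequence, "")[[1]]
  if (is.null(partition)) {
    partition <- detect_inverted_repeats(record$sequence, min_len = 200L)
  }
  has_ir <- isTRUE(partition$found)
  in_ira <- rep(FALSE, n)
  if (has_ir) {
    stopifnot(partition$offset == 0L)  # generator genomes are canonical
    in_ira[partition$ira[1]:partition$ira[2]] <- TRUE
  }
  frozen <- rep(FALSE, n)
  coding <- rep(FALSE, n)
  code <- codon_table()

  cds <- Filter(function(f) f$feature_kind == "CDS", record$features)
  gene_pos <- lapply(cds, function(f) {
    segs <- f$segments
    pos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
      p <- segs$start[i]:segs$end[i]
      if (segs$strand[i] == "-") rev(p) else p
    }))
    pos  # ordered 5'->3' on the coding strand
  })
  for (gp in gene_pos) coding[gp] <- TRUE

  omega_of <- function(g) {
    if (g %in% names(dspec$omega)) dspec$omega[[g]] else dspec$default_omega
  }

  for (k in seq_along(cds)) {
    f <- cds[[k]]
    gp <- gene_pos[[k]]
    minus <- f$segments$strand[1] == "-"
    wholly_in_ira <- has_ir && all(in_ira[gp])
    if (wholly_in_ira) next  # IR duplicate: co-mutates via the mirror
    ncod <- length(gp) %/% 3L
    frozen[gp[1:3]] <- TRUE
    frozen[gp[(length(gp) - 2L):length(gp)]] <- TRUE
    if (has_ir && any(in_ira[gp])) {
      # junction-spanning gene: freeze whole codons touching IRa (and mirrors)
      touch <- unique((which(in_ira[gp]) - 1L) %/% 3L + 1L)
      for (ci in touch) frozen[gp[(3L * ci - 2L):(3L * ci)]] <- TRUE
    }
    om <- omega_of(f$gene_name)
    for (ci in seq_len(ncod)) {
      p3 <- gp[(3L * ci - 2L):(3L * ci)]
      if (any(frozen[p3])) next
      for (j in 1:3) {
        if (stats::runif(1) >= dspec$coding_rate) next
        pos <- p3[j]
        old_codon <- paste(if (minus) comp_base(x[p3]) else x[p3], collapse = "")
        newb <- draw_new_base(x[pos], dspec$beta)
        y <- x[p3]; y[j] <- newb
        new_codon <- paste(if (minus) comp_base(y) else y, collapse = "")
        if (code[[new_codon]] == "*") next
        syn <- code[[new_codon]] == code[[old_codon]]
        if (syn || stats::runif(1) < om) x[pos] <- newb
      }
    }
  }

  # noncoding substitutions (IRa mirrored afterwards, so skip it)
  nc <- which(!coding & !in_ira & !frozen)
  hit <- nc[stats::runif(length(nc)) < dspec$noncoding_rate]
  # mirrors of frozen IRa gene bases must not mutate either
  if (has_ir) {
    mirror_frozen <- partition$irb[1] +
      (partition$ira[2] - which(frozen & in_ira))
    hit <- setdiff(hit, mirror_frozen)
  }
  for (pos in hit) x[pos] <- draw_new_base(x[pos], dspec$beta)

  if (has_ir) {
    irb <- partition$irb; ira <- partition$ira
    keep <- which(frozen & in_ira)   # junction-gene bases stay authoritative
    for (t in 0:(partition$ir_length - 1L)) {
      pa <- ira[2] - t
      if (pa %in% keep) next
      x[pa] <- comp_base(x[irb[1] + t])
    }
  }

  plastome_record(identifier = paste0(record$identifier, "_div"),
                  organism = paste0(record$organism, " derived"),
                  sequence = paste(x, collapse = ""),
                  is_circular = record$is_circular, features = record$features)
}

#' Simulate a diverged pair of coding sequences with known omega
#'
#' An ancestor is sampled from the codon model; one copy then accumulates
#' substitutions (synonymous always accepted, nonsynonymous accepted with
#' probability `omega`, stops never created) until the expected synonymous
#' divergence reaches `target_ks` under the Jukes-Cantor map.
#'
#' @param n_codons number of codons
#' @param omega nonsynonymous acceptance probability (true Ka/Ks)
#' @param target_ks target synonymous substitutions per synonymous site
#' @param seed integer RNG seed
#' @param codon_model positional base weights ([default_codon_model()])
#' @return list of two [coding_sequence()] objects
#' @export
simulate_codon_pair <- function(n_codons, omega, target_ks, seed,
                                codon_model = default_codon_model()) {
  stopifnot(n_codons > 0, omega >= 0, target_ks >= 0)
  withr::with_seed(seed, {
    draw <- function(m) {
      paste0(sample(BASES, m, TRUE, prob = codon_model$w1[BASES]),
             sample(BASES, m, TRUE, prob = codon_model$w2[BASES]),
             sample(BASES, m, TRUE, prob = codon_model$w3[BASES]))
    }
    anc <- draw(n_codons)
    bad <- which(anc %in% STOP_CODONS)
    while (length(bad)) {
      anc[bad] <- draw(length(bad))
      bad <- which(anc %in% STOP_CODONS)
    }
    code <- codon_table()
    der <- anc
    s_sites <- sum(ng86_site_table()$syn[anc])
    ps_target <- 0.75 * (1 - exp(-4 * target_ks / 3))
    target_syn <- round(s_sites * ps_target)
    accepted_syn <- 0L
    guard <- 0L
    while (accepted_syn < target_syn && guard < 1e6) {
      guard <- guard + 1L
      ci <- sample.int(n_codons, 1L)
      j <- sample.int(3L, 1L)
      old <- der[ci]
      newb <- sample(setdiff(BASES, substr(old, j, j)), 1L)
      cand <- old
      substr(cand, j, j) <- newb
      if (code[[cand]] == "*") next
      if (code[[cand]] == code[[old]]) {
        der[ci] <- cand
        accepted_syn <- accepted_syn + 1L
      } else if (stats::runif(1) < omega) {
        der[ci] <- cand
      }
    }
    list(coding_sequence("simulated", "lineage_a", paste(anc, collapse = "")),
         coding_sequence("simulated", "lineage_b", paste(der, collapse = "")))
  })
}

#' Simulate a geneset with controllable mutation-vs-selection structure
#'
#' Each gene draws its own mutational GC pressure uniformly in
#' `beta +- spread`. With `constraint = 0` that pressure drives all three
#' codon positions (codon usage tracks mutation alone, neutrality slope near
#' 1); with `constraint = 1` positions 1-2 are pinned to the fixed global
#' composition `beta` (selection on the protein, slope near 0); intermediate
#' values interpolate. Stop codons are never emitted.
#'
#' @param n_genes number of genes
#' @param beta central GC pressure
#' @param constraint fraction of positions 1-2 compositional variance removed,
#'   in [0, 1]
#' @param n_codons codons per gene
#' @param seed integer RNG seed
#' @param spread half-width of the per-gene GC pressure distribution
#' @return list of [coding_sequence()] objects
#' @export
simulate_neutrality_geneset <- function(n_genes = 200L, beta = 0.45,
                                        constraint = 0, n_codons = 400L,
                                        seed = 1L, spread = 0.2) {
  stopifnot(constraint >= 0, constraint <= 1, beta > 0, beta < 1)
  withr::with_seed(seed, {
    out <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      g <- stats::runif(1, beta - spread, beta + spread)
      g <- min(max(g, 0.05), 0.95)
      gc12 <- (1 - constraint) * g + constraint * beta
      draw <- function(m) {
        paste0(sample_bases(m, gc12), sample_bases(m, gc12), sample_bases(m, g))
      }
      cods <- draw(n_codons)
      bad <- which(cods %in% STOP_CODONS)
      while (length(bad)) {
        cods[bad] <- draw(length(bad))
        bad <- which(cods %in% STOP_CODONS)
      }
      out[[i]] <- coding_sequence(sprintf("g%03d", i), "synthetic",
                                  paste(cods, collapse = ""))
    }
    out
  })
}
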
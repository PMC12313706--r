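test_that("CDS assembly deduplicates IR-duplicated genes and keeps strand sense", {
  sim <- simulate_plastome(synthetic_plastome_spec(
    seed = 8, lsc_len = 5000, ir_len = 1000, ssc_len = 2000,
    genes = data.frame(name = c("gPlus", "gMinus", "gIR"),
                       region = c("lsc", "lsc", "ir"), strand = c("+", "-", "+"),
                       n_codons = c(120, 110, 70), junction = NA_character_,
                       junction_overlap_bp = NA_integer_)))
  expect_length(sim$record$features, 4)  # gIR annotated twice
  cds <- assemble_cds(sim$record)
  expect_length(cds, 3)                  # but assembled once
  for (cs in cds) {
    expect_equal(substr(cs$dna, 1, 3), "ATG")
    expect_true(substr(cs$dna, cs$length_bp - 2, cs$length_bp) %in%
                  c("TAA", "TAG", "TGA"))
  }
})

test_that("the CDS filter applies every rule with a reason", {
  mk <- function(name, dna) coding_sequence(name, "sp", dna)
  clean <- function(n_codons) {
    paste0("ATG", strrep("GCT", n_codons - 2), "TAA")
  }
  toy <- list(
    mk("short", clean(99)),                                     # 297 bp
    mk("okATG", clean(100)),                                    # 300 bp
    mk("internal", paste0("ATG", "TAA", strrep("GCT", 99), "TAA")),
    mk("okGTG", paste0("GTG", strrep("GCT", 98), "TAA")),
    mk("ragged", paste0(clean(100), "A")))                      # 301 bp
  res <- filter_cds(toy, min_len = 300)
  expect_length(res$retained, 2)
  expect_setequal(vapply(res$retained, `[[`, character(1), "gene_name"),
                  c("okATG", "okGTG"))
  expect_equal(nrow(res$rejected) + length(res$retained), length(toy))
  reasons <- setNames(res$rejected$reason, res$rejected$gene_name)
  expect_equal(reasons[["short"]], "too_short")
  expect_equal(reasons[["internal"]], "internal_stop")
  expect_equal(reasons[["ragged"]], "not_triplet")

  # stricter start policy drops the GTG start
  res_atg <- filter_cds(toy, min_len = 300, start_policy = "atg_only")
  expect_length(res_atg$retained, 1)
  expect_equal(res_atg$rejected$reason[res_atg$rejected$gene_name == "okGTG"],
               "bad_start")

  # trans-spliced genes are rejected with their own reason
  ts <- coding_sequence("rps12", "sp", clean(120), is_trans_spliced = TRUE)
  expect_equal(filter_cds(list(ts))$rejected$reason, "trans_spliced")

  # idempotence: filtering the retained set changes nothing
  res2 <- filter_cds(res$retained, min_len = 300)
  expect_length(res2$retained, 2)
  expect_equal(nrow(res2$rejected), 0)
})

test_that("codon counting is exact and additive", {
  cs <- coding_sequence("g", "sp", "ATGGCGTAA")
  tab <- codon_counts(cs)
  counts <- setNames(tab$counts, tab$codons)
  expect_equal(unname(counts[c("ATG", "GCG", "TAA")]), c(1L, 1L, 1L))
  expect_equal(tab$n_codons, 3L)
  expect_equal(sum(counts), tab$n_codons)

  # pooling two copies doubles every count; pooled equals the per-gene sum
  two <- codon_counts(list(cs, cs), pool = TRUE)
  expect_equal(two$counts, 2L * tab$counts)
  set.seed(71)
  genes <- lapply(1:5, function(i) random_clean_cds(sample(30:80, 1),
                                                    gene = paste0("g", i)))
  per_gene <- codon_counts(genes, pool = FALSE)
  pooled <- codon_counts(genes, pool = TRUE)
  expect_equal(Reduce(`+`, lapply(per_gene, `[[`, "counts")), pooled$counts)

  # codons containing N are skipped and tallied
  tabn <- codon_counts(coding_sequence("n", "sp", "ATGGNGTAA"))
  expect_equal(tabn$n_codons, 2L)
  expect_equal(tabn$n_skipped, 1L)
  expect_error(codon_counts(coding_sequence("bad", "sp", "ATGA")),
               "multiple of 3")
})

test_that("codon counts and RSCU agree with seqinr::uco", {
  skip_if_not_installed("seqinr")
  set.seed(19)
  for (i in 1:5) {
    cs <- random_clean_cds(sample(80:200, 1))
    # drop the terminal stop as gene metrics do, to match uco on sense codons
    body <- substr(cs$dna, 1, nchar(cs$dna) - 3)
    tab <- codon_counts(coding_sequence("x", "s", body))
    uco_eff <- seqinr::uco(strsplit(tolower(body), "")[[1]], index = "eff")
    counts <- setNames(tab$counts, tab$codons)
    expect_equal(unname(counts[toupper(names(uco_eff))]),
                 unname(as.integer(uco_eff)))
    uco_rscu <- seqinr::uco(strsplit(tolower(body), "")[[1]], index = "rscu")
    mine <- rscu(tab)
    cods <- intersect(toupper(names(uco_rscu)), names(mine))
    # uco reports stop-family RSCU too; compare sense codons with observations
    cmp <- cods[!is.na(mine[cods]) & !cods %in% c("ATG", "TGG")]
    expect_equal(unname(mine[cmp]), unname(uco_rscu[tolower(cmp)]),
                 tolerance = 1e-12)
  }
})

test_that("RSCU reproduces hand-computed families and sums to family size", {
  counts <- setNames(rep(0L, 64), plastocub:::all_codons())
  counts[c("GCT", "GCC", "GCA", "GCG")] <- c(3L, 1L, 0L, 0L)  # Ala family
  counts[c("GGT", "GGC", "GGA", "GGG")] <- 5L                 # uniform Gly
  tab <- structure(list(counts = unname(counts), codons = names(counts),
                        n_codons = sum(counts), n_skipped = 0L),
                   class = "codon_usage_table")
  r <- rscu(tab)
  expect_equal(unname(r[c("GCT", "GCC", "GCA", "GCG")]), c(3, 1, 0, 0))
  expect_equal(unname(r[c("GGT", "GGC", "GGA", "GGG")]), rep(1, 4))
  expect_equal(unname(r["ATG"]), 1)  # Met fixed by convention
  expect_true(all(is.na(r[c("TTT", "TTC")])))  # unobserved family

  # family sums equal family size on random data
  set.seed(3)
  code <- plastocub:::codon_table()
  for (i in 1:10) {
    cs <- random_clean_cds(150)
    tab <- codon_counts(cs)
    r <- rscu(tab)
    counts <- setNames(tab$counts, tab$codons)
    for (aa in setdiff(unique(code), "*")) {
      fam <- names(code)[code == aa]
      if (length(fam) > 1 && sum(counts[fam]) > 0) {
        expect_equal(sum(r[fam]), length(fam), tolerance = 1e-12)
      }
    }
  }
})

test_that("positional statistics follow their exclusion sets exactly", {
  m <- gene_cub_metrics(coding_sequence("toy", "sp", "ATGGCGTTTTAA"))
  expect_equal(m$GC1, 100 / 3, tolerance = 1e-9)
  expect_equal(m$GC2, 100 / 3, tolerance = 1e-9)
  expect_equal(m$GC3, 200 / 3, tolerance = 1e-9)
  expect_equal(c(m$P1, m$P2, m$P3, m$P12), rep(0.5, 4))
  expect_equal(c(m$A3s, m$T3s, m$C3s, m$G3s), c(0, 0.5, 0, 0.5))
  expect_equal(m$GC3s, 0.5)

  # all third positions G/C and no excluded codons
  allgc3 <- coding_sequence("gc3", "sp", paste0(strrep("GCGGCC", 20)))
  m2 <- gene_cub_metrics(allgc3)
  expect_equal(m2$GC3, 100)
  expect_equal(m2$P3, 1)

  # brute-force recount of every exclusion set on random CDS
  code <- plastocub:::codon_table()
  set.seed(11)
  for (i in 1:10) {
    cs <- random_clean_cds(sample(40:120, 1))
    cods <- plastocub:::split_codons(cs$dna)
    cods <- cods[-length(cods)]  # terminal stop
    m <- gene_cub_metrics(cs)
    gc_frac <- function(set, pos) {
      if (!length(set)) return(NA_real_)
      mean(substr(set, pos, pos) %in% c("G", "C"))
    }
    ns <- cods[code[cods] != "*"]
    expect_equal(m$GC1, 100 * gc_frac(ns, 1))
    expect_equal(m$GC2, 100 * gc_frac(ns, 2))
    expect_equal(m$GC3, 100 * gc_frac(ns, 3))
    pset <- ns[!ns %in% c("ATG", "ATA", "TGG")]
    expect_equal(m$P1, gc_frac(pset, 1))
    expect_equal(m$P12, (gc_frac(pset, 1) + gc_frac(pset, 2)) / 2)
    x3 <- ns[!ns %in% c("ATG", "ATT", "ATC", "ATA", "TGG")]
    expect_equal(m$A3s, mean(substr(x3, 3, 3) == "A"))
    expect_equal(m$GC3s, gc_frac(ns[!ns %in% c("ATG", "TGG")], 3))
    if (length(x3)) {
      expect_equal(m$A3s + m$T3s + m$C3s + m$G3s, 1, tolerance = 1e-12)
    }
  }
})

test_that("Wright's ENC hits its boundary constructions", {
  code <- plastocub:::codon_table()
  sense <- names(code)[code != "*"]
  mk_tab <- function(counts) {
    structure(list(counts = unname(counts), codons = names(counts),
                   n_codons = sum(counts), n_skipped = 0L),
              class = "codon_usage_table")
  }
  # one codon used per amino acid (n = 2 observations each) -> ENC = 20
  cnt <- setNames(rep(0L, 64), plastocub:::all_codons())
  for (aa in setdiff(unique(code), "*")) {
    cnt[names(code)[code == aa][1]] <- 2L
  }
  expect_equal(enc(mk_tab(cnt)), 20)

  # every degenerate family with counts (3,1,0,...) -> all F = 0.5 -> ENC = 38
  cnt <- setNames(rep(0L, 64), plastocub:::all_codons())
  for (aa in setdiff(unique(code), "*")) {
    fam <- names(code)[code == aa]
    if (length(fam) > 1) { cnt[fam[1]] <- 3L; cnt[fam[2]] <- 1L }
  }
  expect_equal(enc(mk_tab(cnt)), 38)

  # uniform usage at large n approaches (and is capped at) 61
  cnt <- setNames(rep(0L, 64), plastocub:::all_codons())
  cnt[sense] <- 1000L
  expect_equal(enc(mk_tab(cnt)), 61)

  # empty table is undefined
  cnt <- setNames(rep(0L, 64), plastocub:::all_codons())
  expect_true(is.na(enc(mk_tab(cnt))))

  # uniform random codon draw at n = 5000 lands within 0.5 of 61
  withr::with_seed(41, {
    cods <- sample(sense, 5000, replace = TRUE)
    cs <- coding_sequence("u", "sp", paste(cods, collapse = ""))
    expect_lt(abs(enc(codon_counts(cs)) - 61), 0.5)
  })

  # bounds hold on arbitrary clean genes
  set.seed(13)
  for (i in 1:10) {
    e <- enc(codon_counts(random_clean_cds(sample(100:300, 1))))
    if (!is.na(e)) expect_true(e >= 20 && e <= 61)
  }
})
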
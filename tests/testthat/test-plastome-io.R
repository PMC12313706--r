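test_that("a minimal handcrafted GenBank record parses", {
  gb <- c(
    "LOCUS       TOY01 60 bp    DNA     circular   UNA",
    "ACCESSION   TOY01",
    "SOURCE      toy",
    "  ORGANISM  Toyus minimus",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             1..60",
    "                     /gene=\"toyA\"",
    "                     /transl_table=11",
    "ORIGIN",
    paste0("        1 ", paste(rep("atgaaacccg", 6), collapse = " ")),
    "//")
  tf <- withr::local_tempfile(lines = gb)
  recs <- read_genbank(tf)
  expect_length(recs, 1)
  rec <- recs[[1]]
  expect_equal(rec$identifier, "TOY01")
  expect_equal(rec$organism, "Toyus minimus")
  expect_equal(nchar(rec$sequence), 60)
  expect_true(rec$is_circular)
  expect_length(rec$features, 1)
  f <- rec$features[[1]]
  expect_equal(f$feature_kind, "CDS")
  expect_equal(f$strand, "+")
  expect_equal(f$segments$start, 1L)
  expect_equal(f$segments$end, 60L)
  expect_false(f$is_trans_spliced)
})

test_that("GenBank location strings resolve to extraction-order segments", {
  cases <- list(
    list(loc = "complement(10..20)",
         segs = data.frame(start = 10L, end = 20L, strand = "-")),
    list(loc = "join(1..3,7..9)",
         segs = data.frame(start = c(1L, 7L), end = c(3L, 9L),
                           strand = c("+", "+"))),
    list(loc = "complement(join(1..3,7..9))",
         segs = data.frame(start = c(7L, 1L), end = c(9L, 3L),
                           strand = c("-", "-"))))
  for (cs in cases) {
    parsed <- plastocub:::parse_location(cs$loc)
    expect_equal(parsed$segments, cs$segs, ignore_attr = TRUE, label = cs$loc)
  }
  ord <- plastocub:::parse_location("order(1..3,7..9)")
  expect_true(ord$is_order)
  expect_null(plastocub:::parse_location("join(1..3,nonsense)"))
})

test_that("generator output survives a GenBank write/read round trip", {
  sim <- simulate_plastome(synthetic_plastome_spec(seed = 42, lsc_len = 4000,
                                                   ir_len = 600, ssc_len = 1500,
                                                   genes = data.frame(
    name = c("psbA", "ndhF", "irg"), region = c("lsc", "ssc", "ir"),
    strand = c("+", "-", "+"), n_codons = c(120, 100, 60),
    junction = NA_character_, junction_overlap_bp = NA_integer_)))
  tf <- withr::local_tempfile(fileext = ".gb")
  write_genbank(list(sim$record), tf)
  back <- read_genbank(tf)[[1]]
  expect_identical(back$sequence, sim$record$sequence)
  expect_identical(back$identifier, sim$record$identifier)
  expect_identical(back$organism, sim$record$organism)
  expect_identical(back$is_circular, sim$record$is_circular)
  expect_equal(back$features, sim$record$features, ignore_attr = TRUE)
})

test_that("a record without sequence is a hard error; bad locations warn", {
  gb <- c("LOCUS       X 10 bp DNA linear", "FEATURES", "ORIGIN", "//")
  tf <- withr::local_tempfile(lines = gb)
  expect_error(read_genbank(tf), "empty sequence")
  gb2 <- c("LOCUS       X 10 bp DNA linear",
           "FEATURES             Location/Qualifiers",
           "     CDS             join(1..3,weird)",
           "                     /gene=\"g\"",
           "ORIGIN",
           "        1 acgtacgtac", "//")
  tf2 <- withr::local_tempfile(lines = gb2)
  expect_warning(recs <- read_genbank(tf2), "unparseable")
  expect_length(recs[[1]]$features, 0)
})

test_that("feature sequences extract on the coding strand", {
  rec <- plastome_record("r", "org", "AAATTTGGGCCC", is_circular = FALSE,
                         features = list())
  fwd <- gene_feature("g", "CDS", "+", data.frame(start = 4, end = 9))
  expect_equal(extract_feature_sequence(rec, fwd), "TTTGGG")

  rec2 <- plastome_record("r2", "org", "ATGCATGCAT", is_circular = FALSE)
  minus2 <- gene_feature("g2", "CDS", "-",
                         data.frame(start = c(7, 1), end = c(9, 3),
                                    strand = c("-", "-")))
  expect_equal(extract_feature_sequence(rec2, minus2), "TGCCAT")

  # origin wrap on a circular record
  rec3 <- plastome_record("r3", "org", "AAATTTGGGCCC", is_circular = TRUE)
  wrap <- gene_feature("g3", "CDS", "+", data.frame(start = 10, end = 3))
  expect_equal(extract_feature_sequence(rec3, wrap), "CCCAAA")
  rec3lin <- plastome_record("r3l", "org", "AAATTTGGGCCC", is_circular = FALSE)
  expect_error(plastome_record("bad", "org", "AAATTTGGGCCC",
                               is_circular = FALSE, features = list(wrap)),
               "wraps")
})

test_that("reverse complement composed with itself is the identity", {
  set.seed(5)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("ambiguity codes other than N normalize to N with a warning", {
  expect_warning(rec <- plastome_record("amb", "o", "ACGTRYSW"), "normalized")
  expect_equal(rec$sequence, "ACGTNNNN")
})

test_that("FASTA output wraps at 70 columns and round-trips", {
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(s1 = "ACGTACGTAC"), tf)
  expect_length(readLines(tf), 2)

  seq150 <- paste(rep("ACGTA", 30), collapse = "")
  write_fasta(c(long = seq150), tf)
  lines <- readLines(tf)
  expect_length(lines, 4)  # header + 70 + 70 + 10
  expect_equal(nchar(lines[2]), 70)
  expect_equal(read_fasta(tf)[["long"]], seq150)

  write_fasta(list(), tf)
  expect_equal(file.size(tf), 0)
  expect_error(write_fasta(c(a = "ACGT", a = "AAAA"), tf), "duplicate")
})
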
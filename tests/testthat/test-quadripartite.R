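sim_small <- function(seed, ...) {
  simulate_plastome(synthetic_plastome_spec(
    seed = seed, lsc_len = 6000, ir_len = 1200, ssc_len = 2500,
    genes = data.frame(name = c("gA", "gB", "gC"),
                       region = c("lsc", "ssc", "ir"), strand = c("+", "-", "+"),
                       n_codons = c(150, 120, 80), junction = NA_character_,
                       junction_overlap_bp = NA_integer_), ...))
}

test_that("planted inverted repeats are recovered exactly", {
  for (seed in c(1, 2, 3)) {
    sim <- sim_small(seed)
    part <- detect_inverted_repeats(sim$record$sequence, min_len = 1000)
    expect_true(part$found)
    expect_identical(part$irb, sim$truth$irb)
    expect_identical(part$ira, sim$truth$ira)
    expect_identical(part$lsc, sim$truth$lsc)
    expect_identical(part$ssc, sim$truth$ssc)
    expect_equal(part$ir_length, sim$truth$ir_length)
    expect_equal(part$offset, 0L)
  }
})

test_that("a random sequence without long repeats reports no structure", {
  withr::with_seed(9, {
    s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  })
  part <- detect_inverted_repeats(s, min_len = 1000)
  expect_false(part$found)
  expect_error(region_statistics(plastome_record("x", "", s), part),
               "no quadripartite")
})

test_that("partitioning is invariant under rotation of the circular genome", {
  sim <- sim_small(17)
  seq0 <- sim$record$sequence
  n <- nchar(seq0)
  base <- detect_inverted_repeats(seq0, min_len = 1000)
  canon0 <- plastocub:::rotate_sequence(seq0, base$offset)
  for (shift in c(137, 5000, n - 300)) {
    rot <- paste0(substr(seq0, shift + 1, n), substr(seq0, 1, shift))
    part <- detect_inverted_repeats(rot, min_len = 1000)
    expect_true(part$found)
    expect_equal(part$region_length, base$region_length)
    expect_equal(part$junctions, base$junctions)
    # the canonical linearization itself is rotation-invariant
    expect_identical(plastocub:::rotate_sequence(rot, part$offset), canon0)
  }
})

test_that("region statistics tile the genome and report GC per region", {
  sim <- sim_small(23)
  part <- detect_inverted_repeats(sim$record$sequence, min_len = 1000)
  stats <- region_statistics(sim$record, part)
  expect_equal(sum(stats$length_bp), nchar(sim$record$sequence))
  expect_equal(stats$region, c("LSC", "IRB", "SSC", "IRA"))
  expect_equal(stats$gc_pct[stats$region == "IRB"],
               stats$gc_pct[stats$region == "IRA"])
  # junction convention: last base of the upstream region
  expect_equal(unname(part$junctions),
               cumsum(stats$length_bp))

  # an all-AT genome has GC 0 in every region (partition supplied directly)
  at_rec <- plastome_record("at", "", strrep("ATTA", 250))
  part_at <- structure(list(
    found = TRUE, genome_length = 1000L, offset = 0L,
    lsc = c(1L, 500L), irb = c(501L, 650L), ssc = c(651L, 850L),
    ira = c(851L, 1000L),
    junctions = c(JLB = 500L, JSB = 650L, JSA = 850L, JLA = 1000L),
    ir_length = 150L), class = "quadripartite_partition")
  expect_true(all(region_statistics(at_rec, part_at)$gc_pct == 0))
  expect_error(region_statistics(plastome_record("short", "", "ACGT"), part),
               "does not match")
})

test_that("junction-spanning genes are reported with their IR-side overlap", {
  # a JSB-spanning gene's IRb bases mirror onto IRa's first bases, exactly
  # where a JSA-spanning gene would sit, so the two live in separate genomes
  genes1 <- data.frame(
    name = c("lscA", "ndhFlike", "sscB"),
    region = c("lsc", "ssc", "ssc"),
    strand = c("+", "+", "+"),
    n_codons = c(100, 130, 60),
    junction = c("JLB", "JSB", NA),
    junction_overlap_bp = c(10L, 64L, NA))
  sim <- simulate_plastome(synthetic_plastome_spec(
    seed = 4, lsc_len = 6000, ir_len = 1200, ssc_len = 2500, genes = genes1))
  part <- detect_inverted_repeats(sim$record$sequence, min_len = 1000)
  expect_identical(part$irb, sim$truth$irb)
  rep <- junction_report(sim$record, part)
  spans <- rep[rep$relation == "spans", ]
  expect_equal(spans$overlap_bp[spans$junction == "JLB" & spans$gene_name == "lscA"], 10L)
  expect_equal(spans$overlap_bp[spans$junction == "JSB" & spans$gene_name == "ndhFlike"], 64L)
  # flanking genes carry distances, not overlaps
  flank <- rep[rep$relation != "spans", ]
  expect_true(all(flank$overlap_bp == 0))
  expect_true(all(flank$distance_bp >= 0))
  # empty feature list -> empty report
  bare <- plastome_record("bare", "", sim$record$sequence)
  expect_equal(nrow(junction_report(bare, part)), 0)

  genes2 <- data.frame(
    name = c("lscA", "chlLlike"), region = c("lsc", "ssc"),
    strand = c("+", "-"), n_codons = c(100, 90),
    junction = c(NA, "JSA"), junction_overlap_bp = c(NA, 5L))
  sim2 <- simulate_plastome(synthetic_plastome_spec(
    seed = 4, lsc_len = 6000, ir_len = 1200, ssc_len = 2500, genes = genes2))
  part2 <- detect_inverted_repeats(sim2$record$sequence, min_len = 1000)
  rep2 <- junction_report(sim2$record, part2)
  spans2 <- rep2[rep2$relation == "spans", ]
  expect_equal(spans2$overlap_bp[spans2$junction == "JSA" &
                                   spans2$gene_name == "chlLlike"], 5L)

  # conflicting junction-gene layouts are rejected, not silently corrupted
  genes3 <- rbind(genes1[genes1$name == "ndhFlike", ],
                  genes2[genes2$name == "chlLlike", ])
  expect_error(simulate_plastome(synthetic_plastome_spec(
    seed = 4, lsc_len = 6000, ir_len = 1200, ssc_len = 2500, genes = genes3)),
    "mirror")
})

test_that("the LSC+IRb+SSC extraction drops exactly one repeat copy", {
  sim <- sim_small(31)
  part <- detect_inverted_repeats(sim$record$sequence, min_len = 1000)
  core <- extract_lsc_irb_ssc(sim$record, part)
  expect_equal(nchar(core), part$genome_length - part$ir_length)
  # reconstruction: appending the reverse complement of IRb restores the genome
  irb_seq <- substr(core, part$irb[1], part$irb[2])
  canon <- plastocub:::rotate_sequence(sim$record$sequence, part$offset)
  expect_identical(paste0(core, revcomp(irb_seq)), canon)
  expect_error(extract_lsc_irb_ssc(sim$record,
                                   structure(list(found = FALSE),
                                             class = "quadripartite_partition")),
               "no quadripartite")
})
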
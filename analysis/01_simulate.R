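#!/usr/bin/env Rscript
# Build the study dataset: one ancestral synthetic plastome with a planted
# 1.5 kb inverted repeat and ten annotated CDS, plus three diverged genomes
# with known per-gene selection strength. Writes GenBank, FASTA and the
# planted ground truth under results/data/.

suppressMessages(library(plastocub))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

SEED <- 20260101L

genes <- default_plastome_genes()
genes$junction[genes$name == "rps4"] <- "JLB"
genes$junction_overlap_bp[genes$name == "rps4"] <- 10L

sim <- simulate_plastome(synthetic_plastome_spec(seed = SEED, genes = genes))
message("ancestor: ", sim$record$identifier, ", ",
        nchar(sim$record$sequence), " bp, ",
        length(sim$record$features), " CDS features (IR gene duplicated)")

# three descendants: increasing divergence, rbcL frozen (omega 0), psbA and
# petA under strong purifying selection, the rest at omega 0.2
derived <- lapply(1:3, function(i) {
  d <- diverge_genome(sim$record, divergence_spec(
    seed = SEED + i,
    omega = c(rbcL = 0, psbA = 0.05, petA = 0.05),
    default_omega = 0.2,
    coding_rate = 0.004 * i, noncoding_rate = 0.012 * i),
    partition = sim$truth)
  d$identifier <- sprintf("SYNDIV%02d", i)
  d$organism <- sprintf("Synthetica plastomis lineage %d", i)
  d
})

records <- c(list(sim$record), derived)
write_genbank(records, "results/data/genomes.gb")
seqs <- setNames(vapply(records, `[[`, character(1), "sequence"),
                 vapply(records, `[[`, character(1), "identifier"))
# divergence is substitution-only, so the genomes align column-for-column
write_fasta(seqs, "results/data/alignment.fasta")

truth <- list(
  seed = SEED,
  partition = sim$truth[c("lsc", "irb", "ssc", "ira", "ir_length")],
  omega = list(rbcL = 0, psbA = 0.05, petA = 0.05, default = 0.2),
  jlb_overlap_gene = "rps4", jlb_overlap_bp = 10)
jsonlite::write_json(truth, "results/data/ground_truth.json",
                     auto_unbox = TRUE, pretty = TRUE)
message("wrote results/data/{genomes.gb, alignment.fasta, ground_truth.json}")
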
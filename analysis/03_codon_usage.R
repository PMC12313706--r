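#!/usr/bin/env Rscript
# Codon usage bias per genome: filtered CDS sets, per-gene positional GC /
# RSCU / ENC, and the three diagnostics (ENC-GC3s, PR2, neutrality plot).

suppressMessages(library(plastocub))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)

records <- read_genbank("results/data/genomes.gb")

metrics <- list(); rscu_rows <- list(); neut_rows <- list()
for (rec in records) {
  filt <- filter_cds(assemble_cds(rec), min_len = 300, start_policy = "table11")
  met <- cub_metrics_table(filt$retained)
  metrics[[rec$identifier]] <- cbind(genome = rec$identifier, met)
  message(rec$identifier, ": ", length(filt$retained), " CDS retained, ",
          nrow(filt$rejected), " rejected; mean ENC ",
          round(mean(met$ENC, na.rm = TRUE), 2),
          ", mean GC3 ", round(mean(met$GC3, na.rm = TRUE), 2), "%")

  rv <- rscu(codon_counts(filt$retained, pool = TRUE))
  rscu_rows[[rec$identifier]] <- data.frame(
    genome = rec$identifier, codon = names(rv), rscu = round(unname(rv), 4))

  ea <- enc_gc3s_analysis(met)
  pr <- pr2_analysis(met)
  nr <- neutrality_regression(met)
  neut_rows[[rec$identifier]] <- data.frame(
    genome = rec$identifier, slope = nr$slope, intercept = nr$intercept,
    pearson_r = nr$pearson_r, p_value = nr$p_value,
    mutation_share_pct = nr$mutation_share,
    mean_enc_deviation = ea$mean_deviation,
    pr2_lower_left = unname(pr$quadrant_counts["lower-left"]),
    pr2_total = nrow(pr$points))
}

met_all <- do.call(rbind, metrics)
write.table(met_all, "results/tables/cub_metrics.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, rscu_rows), "results/tables/rscu.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, neut_rows), "results/tables/cub_diagnostics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

rv_anc <- subset(do.call(rbind, rscu_rows), genome == records[[1]]$identifier)
over1 <- rv_anc$codon[!is.na(rv_anc$rscu) & rv_anc$rscu > 1]
message(length(over1), " codons with RSCU > 1 in the ancestor; ",
        sum(substr(over1, 3, 3) %in% c("T", "A")), " end in U or A")
message("wrote results/tables/{cub_metrics.tsv, rscu.tsv, cub_diagnostics.tsv}")
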
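# End-to-end comparative report over two or more annotated genomes:
# partition -> CDS -> codon usage -> diagnostics -> (pi) -> pairwise Ka/Ks.

#' Run the full comparative analysis
#'
#' Executes, per genome: quadripartite partitioning and region statistics,
#' junction geometry, CDS assembly/filtering, per-gene codon-usage metrics,
#' RSCU, and the three codon-usage diagnostics; then sliding-window
#' nucleotide diversity when an alignment is supplied, and pairwise NG86
#' Ka/Ks for every genome pair. Any stage failure aborts naming the stage and
#' the offending genome.
#'
#' @param records list of [plastome_record()] objects (or a single record)
#' @param alignment optional [alignment_matrix()] of the same genomes
#' @param min_ir_len minimum inverted-repeat length (default 1000)
#' @param min_cds_len,start_policy CDS filter settings ([filter_cds()])
#' @param window,step sliding-window settings ([sliding_windows()])
#' @return list of class `comparative_report`: genome_summary, junctions,
#'   cub_metrics, rscu, diagnostics, pi_windows, kaks, provenance
#' @export
run_comparative <- function(records, alignment = NULL, min_ir_len = 1000L,
                            min_cds_len = 300L, start_policy = "table11",
                            window = 600L, step = 200L) {
  if (inherits(records, "plastome_record")) records <- list(records)
  if (length(records) < 1L) stop("need at least one genome")
  ids <- vapply(records, `[[`, character(1), "identifier")
  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", what, "' failed for genome ", id, ": ",
           conditionMessage(e), call. = FALSE)
    })
  }

  summaries <- list(); junctions <- list(); metrics <- list()
  rscu_tabs <- list(); diags <- list(); retained_by_id <- list()
  for (rec in records) {
    id <- rec$identifier
    part <- stage("partition", id,
                  detect_inverted_repeats(rec$sequence, min_len = min_ir_len))
    reg <- if (part$found) stage("region_statistics", id,
                                 region_statistics(rec, part)) else NULL
    if (part$found) {
      junctions[[id]] <- cbind(genome = id,
                               stage("junctions", id, junction_report(rec, part)))
    }
    filt <- stage("cds_filter", id,
                  filter_cds(assemble_cds(rec), min_len = min_cds_len,
                             start_policy = start_policy))
    retained_by_id[[id]] <- filt$retained
    met <- stage("cub_metrics", id, cub_metrics_table(filt$retained))
    metrics[[id]] <- cbind(genome = id, met)
    pooled <- stage("codon_counts", id, codon_counts(filt$retained, pool = TRUE))
    rv <- stage("rscu", id, rscu(pooled))
    rscu_tabs[[id]] <- data.frame(genome = id, codon = names(rv),
                                  amino_acid = unname(codon_table()[names(rv)]),
                                  rscu = round(unname(rv), 4))
    diags[[id]] <- list(
      enc_gc3s = stage("enc_gc3s", id, enc_gc3s_analysis(met)),
      pr2 = stage("pr2", id, pr2_analysis(met)),
      neutrality = if (nrow(met) >= 3L && stats::var(met$P3, na.rm = TRUE) > 0)
        stage("neutrality", id, neutrality_regression(met)) else NULL)
    summaries[[id]] <- data.frame(
      genome = id, organism = rec$organism, length_bp = nchar(rec$sequence),
      lsc_bp = if (part$found) part$region_length[["lsc"]] else NA_integer_,
      ir_bp = if (part$found) part$ir_length else NA_integer_,
      ssc_bp = if (part$found) part$region_length[["ssc"]] else NA_integer_,
      gc_pct = round(gc_percent(rec$sequence), 1),
      lsc_gc_pct = if (part$found) round(part$region_gc[["lsc"]], 1) else NA_real_,
      ir_gc_pct = if (part$found) round(part$region_gc[["irb"]], 1) else NA_real_,
      ssc_gc_pct = if (part$found) round(part$region_gc[["ssc"]], 1) else NA_real_,
      n_cds = length(filt$retained) + nrow(filt$rejected),
      n_cds_retained = length(filt$retained))
  }

  pi_windows <- NULL
  if (!is.null(alignment)) {
    if (!all(rownames(alignment) %in% ids) && !all(ids %in% rownames(alignment))) {
      stop("alignment labels do not match genome identifiers")
    }
    pi_windows <- sliding_windows(alignment, window = window, step = step)
    ref <- ids[ids %in% rownames(alignment)][1]
    pi_windows <- label_windows(
      pi_windows, records[[which(ids == ref)]],
      alignment_to_genome_map(alignment, ref))
  }

  kaks <- list()
  if (length(records) >= 2L) {
    for (i in seq_len(length(records) - 1L)) {
      for (j in (i + 1L):length(records)) {
        kaks[[length(kaks) + 1L]] <- kaks_scan(records[[i]], records[[j]],
                                               min_len = min_cds_len,
                                               start_policy = start_policy)
      }
    }
  }
  kaks <- if (length(kaks)) do.call(rbind, kaks)
          else data.frame(gene = character(0), pair = character(0))

  structure(
    list(genome_summary = do.call(rbind, summaries[order(names(summaries))]),
         junctions = if (length(junctions))
           do.call(rbind, junctions[order(names(junctions))]) else NULL,
         cub_metrics = do.call(rbind, metrics[order(names(metrics))]),
         rscu = do.call(rbind, rscu_tabs[order(names(rscu_tabs))]),
         diagnostics = diags[order(names(diags))],
         pi_windows = pi_windows,
         kaks = kaks[order(kaks$pair, kaks$gene), , drop = FALSE],
         provenance = list(
           genomes = sort(ids), min_ir_len = min_ir_len,
           min_cds_len = min_cds_len, start_policy = start_policy,
           window = window, step = step,
           package_version = as.character(utils::packageVersion("plastocub")))),
    class = "comparative_report")
}

fmt_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "f"))
}

#' Write a comparative report as a TSV bundle
#'
#' Emits genome_summary.tsv, junctions.tsv, cub_metrics.tsv, rscu.tsv,
#' neutrality.tsv, pi_windows.tsv and kaks.tsv (those with content) with
#' deterministic row order and fixed float formatting, so identical inputs
#' give byte-identical output.
#'
#' @param report a [run_comparative()] result
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name, num_digits = list()) {
    if (is.null(df) || nrow(df) == 0L) return(invisible(NULL))
    for (col in names(num_digits)) {
      if (col %in% names(df)) df[[col]] <- fmt_num(df[[col]], num_digits[[col]])
    }
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  emit(report$genome_summary, "genome_summary.tsv")
  emit(report$junctions, "junctions.tsv")
  emit(report$cub_metrics, "cub_metrics.tsv",
       list(GC1 = 2, GC2 = 2, GC3 = 2, P1 = 4, P2 = 4, P3 = 4, P12 = 4,
            A3s = 4, T3s = 4, C3s = 4, G3s = 4, GC3s = 4, ENC = 2))
  emit(report$rscu, "rscu.tsv")
  neut <- do.call(rbind, lapply(names(report$diagnostics), function(id) {
    nr <- report$diagnostics[[id]]$neutrality
    if (is.null(nr)) return(NULL)
    data.frame(genome = id, slope = nr$slope, intercept = nr$intercept,
               pearson_r = nr$pearson_r, p_value = nr$p_value,
               n_genes = nr$n_genes, mutation_share_pct = nr$mutation_share)
  }))
  emit(neut, "neutrality.tsv",
       list(slope = 4, intercept = 4, pearson_r = 4, p_value = 6,
            mutation_share_pct = 2))
  emit(report$pi_windows, "pi_windows.tsv", list(pi = 4))
  emit(report$kaks, "kaks.tsv",
       list(N = 2, S = 2, Nd = 2, Sd = 2, Ka = 4, Ks = 4, omega = 4))
  invisible(dir)
}
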
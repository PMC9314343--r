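#' End-to-end analysis on synthetic data
#'
#' Runs the full chain on one seed: simulate truth and replicate contact
#' maps for two conditions, pool donors per condition, call TADs and loops
#' on the pooled maps, merge the per-condition loop calls, score all
#' replicate samples over the merged loops (raw and total-normalised),
#' derive custom size factors, test loops for differential contact,
#' annotate loop anchors with simulated peak classes, simulate expression
#' and rank genes by the differential statistic, and run ranked set
#' enrichment of the genes residing in depleted loop domains. Everything
#' is deterministic in `seed`.
#'
#' @param seed integer master seed.
#' @param truth optional pre-built [sim_truth()]; default built from
#'   `seed` with package defaults.
#' @param replicates donors per condition (default 3).
#' @param noise a [noise_model()].
#' @param normalize_total scoring normalisation target (default 5e6).
#' @param fc_threshold domain differential fold-change threshold
#'   (default 1: test any change, as in domain-score comparisons).
#' @param nperm permutations for set enrichment (default 500).
#' @param out_dir optional directory; when given, tables and tracks are
#'   written there (BED/BEDPE/bedGraph/TSV).
#' @return list with `truth`, `metadata`, `tads`, `loops_control`,
#'   `loops_kd`, `merged_loops`, `score_table`, `size_factors`,
#'   `differential`, `anchors`, `expression_test`, `enrichment`.
#' @export
run_pipeline <- function(seed = 1, truth = NULL, replicates = 3,
                         noise = noise_model(), normalize_total = 5e6,
                         fc_threshold = 1, nperm = 500, out_dir = NULL) {
  if (is.null(truth)) truth <- sim_truth(seed = seed)
  sim <- simulate_condition_set(truth, replicates = replicates,
                                noise = noise, seed = seed)
  conds <- truth$conditions[1:2]
  pooled <- lapply(conds, function(cn)
    pool_maps(sim$samples[sim$metadata$sample[sim$metadata$condition == cn]]))
  names(pooled) <- conds
  ## TADs on the pooled control maps
  tads <- lapply(pooled[[1]], call_tads)
  ## loops per condition, then merged across conditions
  loop_calls <- lapply(conds, function(cn)
    do.call(rbind, lapply(pooled[[cn]], call_loops)))
  names(loop_calls) <- conds
  merged <- merge_2d(loop_calls, tolerance_bp = 2 * truth$resolution)
  ## per-sample scoring per chromosome, summed into one table
  score_tab <- .score_merged(sim, merged, truth, normalize_total)
  sf <- size_factors(score_tab)
  design <- sim$metadata$condition[match(colnames(score_tab$raw),
                                         sim$metadata$sample)]
  diff <- differential_domains(score_tab, design, fc_threshold = fc_threshold,
                               sf = sf)
  ## anchor annotation against the simulated peak classes
  pk <- simulate_peaks_and_tracks(truth, seed = seed)
  ann <- annotate_anchors(merged, pk$peaks, window_bp = 15000)
  ## expression + ranked set enrichment of depleted-domain genes
  expr <- simulate_expression(truth, replicates = replicates, noise = noise,
                              seed = seed)
  et <- differential_test(expr, fc_threshold = 1)
  et_ok <- et[!is.na(et$p), ]
  ranking <- ranked_stat(et_ok$name,
                         sign(et_ok$logFC) * -log10(pmax(et_ok$p, 1e-300)))
  dep_genes <- truth$genes$gene[truth$genes$domain != "unlinked"]
  sets <- list(depleted_domain_genes = dep_genes,
               housekeeping = truth$genes$gene[truth$genes$housekeeping])
  enr <- ranked_set_enrichment(ranking, sets, nperm = nperm, seed = seed)
  out <- list(truth = truth, metadata = sim$metadata, tads = tads,
              loops_control = loop_calls[[1]], loops_kd = loop_calls[[2]],
              merged_loops = merged, score_table = score_tab,
              size_factors = sf, differential = diff, anchors = ann,
              expression_test = et, enrichment = enr)
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  out
}

.score_merged <- function(sim, merged, truth, normalize_total) {
  chroms <- unique(merged$chrom)
  per_chrom <- lapply(chroms, function(ch) {
    feats <- merged[merged$chrom == ch, , drop = FALSE]
    mats <- lapply(sim$samples, function(m) m[[ch]])
    score_features(mats, feats, anchor_window = 1.5 * truth$resolution,
                   normalize_total = normalize_total)
  })
  tab <- list(features = do.call(rbind, lapply(per_chrom, `[[`, "features")),
              raw = do.call(rbind, lapply(per_chrom, `[[`, "raw")),
              norm = do.call(rbind, lapply(per_chrom, `[[`, "norm")),
              dropped = unlist(lapply(per_chrom, `[[`, "dropped")))
  tab$raw_totals <- colSums(tab$raw)
  tab$norm_totals <- colSums(tab$norm)
  class(tab) <- "domain_score_table"
  tab
}

.write_pipeline <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_truth(out$truth, p("truth.json"))
  for (ch in names(out$tads)) {
    td <- out$tads[[ch]]
    if (nrow(td$tads))
      write_regions(intervals(td$tads$chrom, td$tads$start1, td$tads$end2,
                              name = td$tads$name, score = td$tads$score),
                    p(paste0("tads_", ch, ".bed")))
    write_bedgraph(bintrack_to_bedgraph(td$insulation),
                   p(paste0("insulation_", ch, ".bedgraph")))
    write_bedgraph(bintrack_to_bedgraph(td$directionality),
                   p(paste0("directionality_", ch, ".bedgraph")))
  }
  write_regions(out$merged_loops, p("loops_merged.bedpe"))
  utils::write.table(data.frame(out$score_table$features,
                                out$score_table$raw, check.names = FALSE),
                     p("loop_scores_raw.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(out$differential, p("differential_loops.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(out$size_factors),
                                sf = out$size_factors),
                     p("size_factors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(out$expression_test, p("differential_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$enrichment, p("set_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
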
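#' Run the full panel-characterization pipeline on synthetic inputs
#'
#' Orchestrates both analysis arms end to end, entirely driven by a
#' [sim_config()] (all randomness derives from its seed, so reruns are
#' deterministic):
#'
#' 1. panel assembly from the supplied gene lists (default: the packaged
#'    pain-panel fixture);
#' 2. variant arm: gene models, located variants with genotypes,
#'    Hardy-Weinberg filtering, location table, percentage-bend correlation
#'    of per-gene variant count versus gene length;
#' 3. functional arm: ontology with planted enrichment, over-representation
#'    analysis, remarkableness scores, details, headlines, ABC set A,
#'    subsumption into functional areas, node classification.
#'
#' When no term is significant the functional reduction is skipped and the
#' report carries empty detail/headline/area sets.
#'
#' @param config a [sim_config()].
#' @param subset1,subset2 panel gene lists; default the packaged fixture.
#' @param ora a [ora_config()].
#' @param hwe_alpha,hwe_method Hardy-Weinberg filter settings.
#' @param target_min,target_max subsumption target range.
#' @param out_dir optional directory; when given, TSV/DOT/JSON artifacts are
#'   written there.
#' @return Object of class `pipeline_report`: nested list with `panel`,
#'   `variants` and `functional` summaries plus the full intermediate
#'   objects under `objects`.
#' @export
run_full <- function(config = sim_config(),
                     subset1 = NULL, subset2 = NULL,
                     ora = ora_config(),
                     hwe_alpha = 0.05, hwe_method = "fisher_expected",
                     target_min = 5L, target_max = 9L,
                     out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(subset1) || is.null(subset2)) {
    fixture <- pain_panel_genes()
    if (is.null(subset1)) subset1 <- fixture$subset1
    if (is.null(subset2)) subset2 <- fixture$subset2
  }
  panel <- assemble_panel(subset1, subset2)

  # ---- variant arm -------------------------------------------------------
  models <- gen_gene_models(config)
  variants <- gen_variants(config, models)
  loc <- classify_location(variants$chrom, variants$pos, models)
  variants$gene <- loc$gene
  variants$location <- loc$location
  hwe <- hwe_filter(variants[, c("n_ref_hom", "n_het", "n_alt_hom")],
                    alpha = hwe_alpha, method = hwe_method)
  retained <- variants[hwe$retained, , drop = FALSE]
  loc_table <- variant_location_table(
    retained, panel_genes = unique(models$gene))
  spans <- models[models$feature == "span", ]
  glen <- stats::setNames(spans$end - spans$start, spans$gene)
  bg <- loc_table$by_gene
  pb <- percentage_bend_correlation(glen[bg$gene], bg$n_variants)

  # ---- functional arm ----------------------------------------------------
  dag <- gen_ontology(config)
  gen <- gen_annotations_with_planting(dag, config)
  ora_res <- run_ora(dag, gen$ann, gen$study_set, ora,
                     namespace = "synthetic")
  n_sig <- sum(ora_res$significant)
  if (n_sig > 0) {
    scores <- term_scores(ora_res)
    details <- find_details(dag, scores$term_id)
    headlines <- find_headlines(dag, details, scores)
    important <- if (length(headlines) >= 3)
      select_important_headlines(headlines, scores) else headlines
    subs <- subsume(dag, important, target_min, target_max)
    areas <- subs$areas
  } else {
    scores <- NULL; details <- character(); headlines <- character()
    important <- character(); subs <- NULL; areas <- character()
  }
  classes <- classify_nodes(dag, ora_res, details, headlines, areas)

  report <- structure(list(
    seed = config$seed,
    config = config,
    panel = panel$summary,
    variants = list(
      n_total = nrow(variants),
      n_hwe_dropped = sum(!hwe$retained),
      by_location = loc_table$by_location,
      zero_variant_genes = loc_table$zero_variant_genes,
      length_correlation = pb[c("r", "p_value", "n")]),
    functional = list(
      n_tested = nrow(ora_res), n_significant = n_sig,
      n_details = length(details), n_headlines = length(headlines),
      n_important = length(important), areas = areas,
      theme_recovered = !is.null(gen$truth$theme) &&
        gen$truth$theme %in% areas),
    objects = list(panel = panel, models = models, variants = variants,
                   hwe = hwe, dag = dag, annotations = gen,
                   ora = ora_res, scores = scores, details = details,
                   headlines = headlines, important = important,
                   subsumption = subs, classes = classes)),
    class = "pipeline_report")

  if (!is.null(out_dir)) .write_report_artifacts(report, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (seed", x$seed, ")\n")
  s <- x$panel
  cat(sprintf("  panel: %d genes (subset1 %d, subset2 %d, shared %d)\n",
              s["n_union"], s["n_subset1"], s["n_subset2"], s["n_shared"]))
  v <- x$variants
  cat(sprintf("  variants: %d called, %d dropped by HWE; r(length) = %.3f\n",
              v$n_total, v$n_hwe_dropped, v$length_correlation$r))
  f <- x$functional
  cat(sprintf("  functional: %d/%d significant; %d detail(s), %d headline(s), %d area(s)\n",
              f$n_significant, f$n_tested, f$n_details, f$n_headlines,
              length(f$areas)))
  invisible(x)
}

.write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- report$objects
  utils::write.table(o$ora, file.path(out_dir, "ora_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(o$scores)) {
    sc <- o$scores
    sc$node_class <- o$classes$class[match(sc$term_id, o$classes$term_id)]
    utils::write.table(sc, file.path(out_dir, "term_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(o$variants, file.path(out_dir, "variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_dot(o$dag, o$classes, file.path(out_dir, "classified_dag.dot"))
  summary <- report[c("seed", "panel", "variants", "functional")]
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
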
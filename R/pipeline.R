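#' Pipeline configuration
#'
#' Bundles every stage threshold (defaulting to the published cutoffs),
#' the simulation configuration and the output directory into one object.
#'
#' @param sim A [sim_config()] (used when no `bundle_dir` is given).
#' @param bundle_dir Optional directory with a pre-written bundle
#'   ([write_bundle()] layout); when set, the simulate stage is skipped.
#' @param out Output directory (NULL = no files written, results returned
#'   only).
#' @param p_cut Adjusted-p cutoff shared by all DE/DM layers (0.05).
#' @param lfc_cut |log2FC| cutoff for genes and miRNAs (1).
#' @param min_reads,min_samples circRNA junction-support rule (2 reads, 2
#'   samples).
#' @param dm_cut |delta M| cutoff (0.5).
#' @param cor_p_cut Spearman significance cutoff (0.05).
#' @param score_min,energy_max Duplex thresholds (140, -20).
#' @param flank_convention "stranded" or "genomic-left".
#' @param prediction_require "both" or "either" seed/duplex routes.
#' @param classify_k CV folds for the classifier harness (10).
#' @param seed Master seed (overrides `sim$seed`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), bundle_dir = NULL, out = NULL,
                            p_cut = 0.05, lfc_cut = 1, min_reads = 2,
                            min_samples = 2, dm_cut = 0.5, cor_p_cut = 0.05,
                            score_min = 140, energy_max = -20,
                            flank_convention = c("stranded", "genomic-left"),
                            prediction_require = c("both", "either"),
                            classify_k = 10, seed = NULL) {
  stopifnot(p_cut > 0, p_cut <= 1, lfc_cut >= 0, dm_cut >= 0,
            cor_p_cut > 0, cor_p_cut <= 1, min_reads >= 0, min_samples >= 0)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, bundle_dir = bundle_dir, out = out,
                 p_cut = p_cut, lfc_cut = lfc_cut, min_reads = min_reads,
                 min_samples = min_samples, dm_cut = dm_cut,
                 cor_p_cut = cor_p_cut, score_min = score_min,
                 energy_max = energy_max,
                 flank_convention = match.arg(flank_convention),
                 prediction_require = match.arg(prediction_require),
                 classify_k = classify_k),
            class = "pipeline_config")
}

#' Run the full integrative pipeline
#'
#' Stages: simulate (or load) the bundle; junction-support filtering of the
#' circRNA catalog; NB differential expression per layer; moderated-t
#' differential methylation; circRNA-region construction and probe mapping;
#' decoupling filter; methylation-expression correlation; region/direction
#' DM summaries; opposite-pattern circRNAs; chromosome density; ceRNA
#' prediction and network assembly; cross-validated classification from
#' DE-circRNA expression. All stage outputs are returned (and written as
#' TSV/GraphML when `config$out` is set) together with a run report whose
#' headline counts satisfy the subset chain
#' correlated \eqn{\subseteq} decoupled \eqn{\subseteq} DE-circ-with-DM
#' \eqn{\subseteq} DE circ.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with elements bundle, de (gene /
#'   circ / mirna), dm, assignments, decoupled, correlations, summary,
#'   opposite, density, predicted, network, cv and report.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- if (!is.null(config$bundle_dir)) read_bundle(config$bundle_dir)
            else simulate_bundle(config$sim)
  design <- bundle$design

  ## --- differential expression ---
  keep <- filter_catalog(bundle$counts$circ, config$min_samples, config$min_reads)
  circ_counts <- bundle$counts$circ[keep, , drop = FALSE]
  de <- list(
    gene = de_analysis(bundle$counts$gene, design, layer = "gene",
                       p_cut = config$p_cut, lfc_cut = config$lfc_cut),
    circ = de_analysis(circ_counts, design, layer = "circ",
                       p_cut = config$p_cut, min_reads = config$min_reads,
                       min_samples = config$min_samples),
    mirna = de_analysis(bundle$counts$mirna, design, layer = "mirna",
                        p_cut = config$p_cut, lfc_cut = config$lfc_cut)
  )

  ## --- differential methylation ---
  dm <- dm_analysis(bundle$probes, design, dm_cut = config$dm_cut,
                    p_cut = config$p_cut)

  ## --- regions & integration ---
  regions <- circ_regions(bundle$circs, chrom_sizes = bundle$chrom_sizes,
                          convention = config$flank_convention)
  assignments <- map_probes(bundle$probes[, c("probe_id", "chrom", "pos")], regions)
  decoupled <- decoupled_circrnas(de$circ, de$gene, assignments, dm, bundle$circs)

  circ_expr <- normalize_circ_expression(circ_counts,
                                         sf = attr(de$circ, "size_factors"))
  mmat <- beta_to_m(as.matrix(bundle$probes[, design$sample_id, drop = FALSE]))
  rownames(mmat) <- bundle$probes$probe_id
  correlations <- correlate_methylation_expression(decoupled, circ_expr, mmat,
                                                   p_cut = config$cor_p_cut)
  summary_dm <- region_dm_summary(assignments, dm, de$circ)
  opposite <- opposite_pattern(de$circ, de$gene, bundle$circs)
  de_circ_ids <- de$circ$feature_id[de$circ$call != "ns"]
  density <- chromosome_density(de_circ_ids, bundle$circs, bundle$genes)

  ## --- ceRNA network ---
  circ_dir <- stats::setNames(decoupled$direction, decoupled$circ_id)
  predicted <- predict_circ_mirna(bundle$mirna_seqs,
                                  bundle$circ_seqs[names(circ_dir)],
                                  score_min = config$score_min,
                                  energy_max = config$energy_max,
                                  require = config$prediction_require)
  network <- build_cerna(circ_dir, de$mirna, de$gene, predicted,
                         bundle$mirna_targets)

  ## --- classification from DE circRNA expression ---
  cv <- NULL
  if (length(de_circ_ids) >= 2) {
    feats <- t(circ_expr[de_circ_ids, , drop = FALSE])
    labels <- group_indicator(design)[match(rownames(feats), design$sample_id)]
    cv <- cv_auc(feats, labels, classifier_nearest_centroid(),
                 k = min(config$classify_k, min(table(labels))),
                 seed = config$sim$seed)
  }

  ## --- report ---
  de_circ_with_dm <- unique(assignments$feature_id[
    assignments$feature_id %in% de_circ_ids &
      assignments$probe_id %in% dm$probe_id[dm$call != "ns"]])
  report <- list(
    seed = config$sim$seed,
    thresholds = config[c("p_cut", "lfc_cut", "min_reads", "min_samples",
                          "dm_cut", "cor_p_cut", "score_min", "energy_max")],
    n_circ_detected = length(keep),
    n_de = vapply(de, function(d) sum(d$call != "ns"), integer(1)),
    n_dm = sum(dm$call != "ns"),
    n_de_circ_with_dm = length(de_circ_with_dm),
    n_decoupled = nrow(decoupled),
    n_correlated = length(unique(correlations$circ_id[correlations$significant])),
    mean_auc = if (is.null(cv)) NA_real_ else cv$mean_auc,
    subset_chain_ok =
      all(unique(correlations$circ_id[correlations$significant]) %in%
            decoupled$circ_id) &&
      all(decoupled$circ_id %in% de_circ_with_dm) &&
      all(de_circ_with_dm %in% de_circ_ids)
  )

  result <- structure(list(bundle = bundle, de = de, dm = dm,
                           assignments = assignments, decoupled = decoupled,
                           correlations = correlations, summary = summary_dm,
                           opposite = opposite, density = density,
                           predicted = predicted, network = network, cv = cv,
                           report = report),
                      class = "pipeline_result")
  if (!is.null(config$out)) write_pipeline_outputs(result, config$out)
  result
}

write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  p <- function(...) file.path(dir, ...)
  for (layer in names(result$de)) {
    write_tsv(result$de[[layer]], p(sprintf("de_%s.tsv", layer)))
  }
  write_tsv(result$dm, p("dm.tsv"))
  write_tsv(result$assignments, p("assignments.tsv"))
  write_tsv(result$decoupled, p("decoupled.tsv"))
  write_tsv(result$correlations, p("correlations.tsv"))
  write_tsv(result$opposite, p("opposite.tsv"))
  write_tsv(result$density, p("chromosome_density.tsv"))
  write_tsv(result$predicted, p("predicted_circ_mirna.tsv"))
  write_tsv(as.data.frame.table(result$summary$site_counts,
                                responseName = "n_sites"),
            p("region_dm_site_counts.tsv"))
  write_tsv(as.data.frame.table(result$summary$circ_counts,
                                responseName = "n_circ"),
            p("region_dm_circ_counts.tsv"))
  if (nrow(result$network$nodes)) {
    write_cerna_graphml(result$network, p("cerna.graphml"))
  }
  write_tsv(result$network$edges, p("cerna_edges.tsv"))
  rep <- result$report
  lines <- c(
    sprintf("seed\t%d", rep$seed),
    sprintf("n_circ_detected\t%d", rep$n_circ_detected),
    sprintf("n_de_gene\t%d", rep$n_de[["gene"]]),
    sprintf("n_de_circ\t%d", rep$n_de[["circ"]]),
    sprintf("n_de_mirna\t%d", rep$n_de[["mirna"]]),
    sprintf("n_dm\t%d", rep$n_dm),
    sprintf("n_de_circ_with_dm\t%d", rep$n_de_circ_with_dm),
    sprintf("n_decoupled\t%d", rep$n_decoupled),
    sprintf("n_correlated\t%d", rep$n_correlated),
    sprintf("mean_auc\t%s", format(rep$mean_auc)),
    sprintf("subset_chain_ok\t%s", rep$subset_chain_ok)
  )
  writeLines(lines, p("report.tsv"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("Integrative circRNA-methylation pipeline (seed ", r$seed, ")\n", sep = "")
  cat(sprintf("  circRNAs passing support filter : %d\n", r$n_circ_detected))
  cat(sprintf("  DE genes / circRNAs / miRNAs    : %d / %d / %d\n",
              r$n_de[["gene"]], r$n_de[["circ"]], r$n_de[["mirna"]]))
  cat(sprintf("  DM sites                        : %d\n", r$n_dm))
  cat(sprintf("  DE circRNAs with DM sites       : %d\n", r$n_de_circ_with_dm))
  cat(sprintf("  decoupled circRNAs              : %d\n", r$n_decoupled))
  cat(sprintf("  methylation-correlated circRNAs : %d\n", r$n_correlated))
  cat(sprintf("  mean CV AUC (nearest centroid)  : %.3f\n", r$mean_auc))
  cat(sprintf("  subset chain holds              : %s\n", r$subset_chain_ok))
  invisible(x)
}

#' Validate the files of a written bundle directory
#'
#' Schema and consistency checks: required files present, coordinate sanity
#' (start <= end in BED, positive probe positions), beta-values within
#' [0, 1], count matrices nonnegative with sample columns matching the
#' design, and circRNA parental genes resolvable in the gene table.
#'
#' @param dir Bundle directory.
#' @return data.frame of issues (file, problem); zero rows means the bundle
#'   validates.
#' @export
validate_inputs <- function(dir) {
  issues <- list()
  note <- function(file, problem) {
    issues[[length(issues) + 1]] <<- data.frame(file = file, problem = problem,
                                                stringsAsFactors = FALSE)
  }
  required <- c("design.tsv", "genes.tsv", "circs.bed", "probes.tsv",
                "counts_gene.tsv", "counts_circ.tsv", "counts_mirna.tsv",
                "mirna_targets.tsv", "mirna.fasta")
  for (f in required) {
    if (!file.exists(file.path(dir, f))) note(f, "missing file")
  }
  done <- function() {
    out <- if (length(issues)) do.call(rbind, issues)
           else data.frame(file = character(0), problem = character(0))
    rownames(out) <- NULL
    out
  }
  if (nrow(done())) return(done())

  design <- read_tsv(file.path(dir, "design.tsv"))
  if (!all(c("sample_id", "group") %in% names(design))) {
    note("design.tsv", "missing sample_id/group columns")
    return(done())
  }
  bed <- read_tsv(file.path(dir, "circs.bed"), header = FALSE)
  if (any(bed[[2]] > bed[[3]])) note("circs.bed", "start > end")
  if (any(bed[[2]] < 0)) note("circs.bed", "negative coordinates")
  genes <- read_tsv(file.path(dir, "genes.tsv"))
  parents <- setdiff(bed[[8]], c(".", genes$gene_id))
  if (length(parents)) {
    note("circs.bed", paste("parental genes missing from genes.tsv:",
                            paste(parents, collapse = ",")))
  }
  probes <- read_tsv(file.path(dir, "probes.tsv"))
  missing_cols <- setdiff(design$sample_id, names(probes))
  if (length(missing_cols)) {
    note("probes.tsv", paste("missing sample columns:",
                             paste(missing_cols, collapse = ",")))
  } else {
    b <- as.matrix(probes[, design$sample_id, drop = FALSE])
    if (any(b < 0 | b > 1, na.rm = TRUE)) note("probes.tsv", "beta outside [0, 1]")
  }
  if ("pos" %in% names(probes) && any(probes$pos < 1)) {
    note("probes.tsv", "probe position < 1")
  }
  for (layer in c("gene", "circ", "mirna")) {
    f <- sprintf("counts_%s.tsv", layer)
    d <- read_tsv(file.path(dir, f))
    miss <- setdiff(design$sample_id, names(d))
    if (length(miss)) {
      note(f, paste("missing sample columns:", paste(miss, collapse = ",")))
    } else if (any(as.matrix(d[, design$sample_id]) < 0)) {
      note(f, "negative counts")
    }
  }
  done()
}
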
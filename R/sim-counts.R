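#' Simulate gene, circRNA (BSJ) and miRNA count matrices with planted effects
#'
#' Counts are drawn from a negative binomial generative model,
#' `y_ij ~ NB(mu_i * s_j * 2^(x_j * lfc_i), alpha)`, where `x_j` is the tumor
#' indicator, `s_j` a per-sample size factor drawn log-uniform on [0.5, 2]
#' (to exercise normalization) and `alpha = config$nb_dispersion`. A
#' `de_fraction` of the features in each layer receives `|log2FC| =
#' config$lfc_effect` with random sign.
#'
#' DE circRNAs possessing a parental gene are additionally assigned a class
#' from `config$class_props`, which constrains the planted effect of that
#' gene: "coupled" (same sign), "opposite" (opposite sign) or "decoupled"
#' (gene locked to zero effect — these are the circRNAs the downstream
#' decoupling filter must recover). A gene parenting several DE circRNAs is
#' constrained once; its later circRNAs inherit the compatible class.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param design A [sample_design()] table.
#' @param config A [sim_config()] object.
#' @return List of class `sim_counts`:
#'   \describe{
#'     \item{counts}{list of gene/circ/mirna integer matrices (features x samples)}
#'     \item{size_factors}{list of per-layer named size-factor vectors}
#'     \item{log2fc}{list of per-layer named vectors of planted log2FC
#'       (nonzero entries only)}
#'     \item{classes}{data.frame circ_id, class, gene_id for classed DE circRNAs}
#'     \item{decoupled_circ, opposite_circ}{character vectors of circ ids}
#'     \item{circ_mu}{matrix of per-sample NB means for the circ layer
#'       (needed by [couple_circ_methylation()] to preserve margins)}
#'   }
#' @export
simulate_counts <- function(annotation, design, config) {
  stopifnot(inherits(annotation, "sim_annotation"), inherits(config, "sim_config"))
  x <- group_indicator(design)
  n_samples <- nrow(design)
  genes <- annotation$genes
  circs <- annotation$circs

  ## --- plant effects (dedicated stream) ---
  plant <- with_seed(derive_seed(config$seed, "plant"), {
    pick_de <- function(ids, frac) {
      n <- round(frac * length(ids))
      if (n == 0) character(0) else sample(ids, n)
    }
    de_circ <- pick_de(circs$circ_id, config$de_fraction)
    circ_lfc <- stats::setNames(
      config$lfc_effect * sample(c(-1, 1), length(de_circ), replace = TRUE), de_circ)

    gene_sign <- list()   # gene_id -> +1 / -1 / 0 (0 = locked null)
    cls <- character(0); cls_gene <- character(0); cls_circ <- character(0)
    parented <- de_circ[de_circ %in% circs$circ_id[!is.na(circs$gene_id)]]
    for (cid in parented) {
      gid <- circs$gene_id[match(cid, circs$circ_id)]
      s_circ <- sign(circ_lfc[[cid]])
      if (is.null(gene_sign[[gid]])) {
        k <- sample(names(config$class_props), 1, prob = config$class_props)
        gene_sign[[gid]] <- switch(k, coupled = s_circ, opposite = -s_circ, decoupled = 0)
      } else {
        gs <- gene_sign[[gid]]
        k <- if (gs == 0) "decoupled" else if (gs == s_circ) "coupled" else "opposite"
      }
      cls <- c(cls, k); cls_gene <- c(cls_gene, gid); cls_circ <- c(cls_circ, cid)
    }
    classes <- data.frame(circ_id = cls_circ, class = cls, gene_id = cls_gene,
                          stringsAsFactors = FALSE)

    forced <- vapply(gene_sign, identity, numeric(1))
    forced_de <- names(forced)[forced != 0]
    locked_null <- names(forced)[forced == 0]
    gene_lfc <- stats::setNames(config$lfc_effect * forced[forced_de], forced_de)
    n_de_gene <- round(config$de_fraction * config$n_genes)
    pool <- setdiff(genes$gene_id, c(forced_de, locked_null))
    extra <- max(0, n_de_gene - length(forced_de))
    if (extra > 0 && length(pool) > 0) {
      add <- sample(pool, min(extra, length(pool)))
      gene_lfc <- c(gene_lfc, stats::setNames(
        config$lfc_effect * sample(c(-1, 1), length(add), replace = TRUE), add))
    }

    mirna_ids <- sprintf("hsa-miR-sim-%03d", seq_len(config$n_mirna))
    de_mir <- pick_de(mirna_ids, config$de_fraction)
    mirna_lfc <- stats::setNames(
      config$lfc_effect * sample(c(-1, 1), length(de_mir), replace = TRUE), de_mir)

    list(circ_lfc = circ_lfc, gene_lfc = gene_lfc, mirna_lfc = mirna_lfc,
         classes = classes, mirna_ids = mirna_ids)
  })

  draw_layer <- function(ids, lfc_map, meanlog, sdlog, stream) {
    with_seed(derive_seed(config$seed, stream), {
      sf <- exp(stats::runif(n_samples, log(0.5), log(2)))
      names(sf) <- design$sample_id
      mu0 <- stats::rlnorm(length(ids), meanlog, sdlog)
      lfc <- stats::setNames(rep(0, length(ids)), ids)
      lfc[names(lfc_map)] <- lfc_map
      mu <- outer(mu0, sf) * 2^(lfc %o% x)
      y <- if (config$nb_dispersion > 0) {
        matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
               nrow = length(ids))
      } else {
        matrix(stats::rpois(length(mu), lambda = mu), nrow = length(ids))
      }
      storage.mode(y) <- "integer"
      dimnames(y) <- list(ids, design$sample_id)
      dimnames(mu) <- dimnames(y)
      list(counts = y, sf = sf, mu = mu)
    })
  }

  gene_l <- draw_layer(genes$gene_id, plant$gene_lfc, log(100), 1, "gene")
  circ_l <- draw_layer(circs$circ_id, plant$circ_lfc, log(15), 1, "circ")
  mir_l <- draw_layer(plant$mirna_ids, plant$mirna_lfc, log(200), 1.2, "mirna")

  cl <- plant$classes
  structure(list(
    counts = list(gene = gene_l$counts, circ = circ_l$counts, mirna = mir_l$counts),
    size_factors = list(gene = gene_l$sf, circ = circ_l$sf, mirna = mir_l$sf),
    log2fc = list(gene = plant$gene_lfc, circ = plant$circ_lfc, mirna = plant$mirna_lfc),
    classes = cl,
    decoupled_circ = cl$circ_id[cl$class == "decoupled"],
    opposite_circ = cl$circ_id[cl$class == "opposite"],
    circ_mu = circ_l$mu
  ), class = "sim_counts")
}
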
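#' Simulation configuration for paired tumor/normal multi-omics bundles
#'
#' Collects every knob of the synthetic-data generator into a validated
#' configuration object. Defaults describe the emulated study design: 20
#' tumor/normal pairs profiled for gene, circRNA back-splice-junction (BSJ)
#' and miRNA counts plus 450K-style methylation beta-values, with planted
#' log2 fold changes, planted M-value shifts inside circRNA-relative regions,
#' Gaussian-copula coupling between selected circRNA/probe pairs, and circRNA
#' origin classes dominated by exonic back-splicing.
#'
#' @param n_pairs Number of tumor/normal pairs (total samples = 2 * n_pairs).
#' @param n_genes,n_circ,n_mirna,n_probes Feature counts per layer.
#' @param nb_dispersion Negative-binomial dispersion alpha shared by all count
#'   features (variance = mu + alpha * mu^2).
#' @param beta_precision Beta-distribution concentration used for null
#'   methylation probes: beta_ij ~ Beta(b0 * phi, (1 - b0) * phi).
#' @param de_fraction Fraction of features per count layer with a planted
#'   log2 fold change.
#' @param dm_fraction Fraction of circRNA-region probes with a planted
#'   M-value shift.
#' @param lfc_effect Magnitude of planted |log2 fold change|.
#' @param dm_effect Magnitude of planted |delta M| (tumor minus normal).
#' @param coupling_rho Latent Gaussian-copula correlation for coupled
#'   circRNA/probe pairs, in [-1, 1].
#' @param origin_props Named proportions over c(exonic, intronic, intergenic)
#'   circRNA origin classes; must sum to 1.
#' @param class_props Named proportions over c(coupled, decoupled, opposite)
#'   classes assigned to DE circRNAs that have a parental gene: "coupled"
#'   plants the same-sign effect in the gene, "decoupled" forces the gene to
#'   stay null (the circRNAs the integration stage must recover), "opposite"
#'   plants the opposite-sign gene effect.
#' @param m_sd Per-sample M-value standard deviation for probes generated on
#'   the Gaussian M scale (planted DM and coupled probes).
#' @param probe_region_fraction Fraction of the non-guaranteed probes placed
#'   inside circRNA-relative regions (the rest scatter over the chromosomes).
#' @param n_chrom Number of synthetic chromosomes.
#' @param seed Master seed; all layer streams are derived from it.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_pairs = 4, n_genes = 50, n_circ = 20,
#'                   n_mirna = 10, n_probes = 100, seed = 7)
#' cfg$n_pairs
#' @export
sim_config <- function(n_pairs = 20,
                       n_genes = 1000,
                       n_circ = 300,
                       n_mirna = 150,
                       n_probes = 4000,
                       nb_dispersion = 0.1,
                       beta_precision = 30,
                       de_fraction = 0.1,
                       dm_fraction = 0.1,
                       lfc_effect = 2,
                       dm_effect = 1,
                       coupling_rho = 0.8,
                       origin_props = c(exonic = 0.90, intronic = 0.04, intergenic = 0.06),
                       class_props = c(coupled = 0.4, decoupled = 0.4, opposite = 0.2),
                       m_sd = 0.5,
                       probe_region_fraction = 0.5,
                       n_chrom = 4,
                       seed = 1L) {
  cfg <- list(
    n_pairs = as.integer(n_pairs), n_genes = as.integer(n_genes),
    n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
    n_probes = as.integer(n_probes), nb_dispersion = nb_dispersion,
    beta_precision = beta_precision, de_fraction = de_fraction,
    dm_fraction = dm_fraction, lfc_effect = lfc_effect,
    dm_effect = dm_effect, coupling_rho = coupling_rho,
    origin_props = origin_props, class_props = class_props,
    m_sd = m_sd, probe_region_fraction = probe_region_fraction,
    n_chrom = as.integer(n_chrom), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_pairs < 2) stop("n_pairs must be >= 2")
    counts <- c(n_genes = n_genes, n_circ = n_circ, n_mirna = n_mirna,
                n_probes = n_probes, n_chrom = n_chrom)
    if (any(counts <= 0)) stop("all feature counts must be positive")
    if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
    if (beta_precision <= 0) stop("beta_precision must be positive")
    for (f in c(de_fraction, dm_fraction)) {
      if (f < 0 || f > 1) stop("de_fraction/dm_fraction must lie in [0, 1]")
    }
    if (abs(coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]")
    if (dm_fraction > 0 && dm_effect <= 0) {
      stop("configuration error: dm_effect must be > 0 when dm_fraction > 0")
    }
    if (!identical(sort(names(origin_props)), c("exonic", "intergenic", "intronic"))) {
      stop("origin_props must be named exonic/intronic/intergenic")
    }
    if (abs(sum(origin_props) - 1) > 1e-8) stop("origin_props must sum to 1")
    if (any(origin_props < 0)) stop("origin_props must be nonnegative")
    if (abs(sum(class_props) - 1) > 1e-8) stop("class_props must sum to 1")
    if (m_sd <= 0) stop("m_sd must be positive")
    if (probe_region_fraction < 0 || probe_region_fraction > 1) {
      stop("probe_region_fraction must lie in [0, 1]")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_pairs, "tumor/normal pairs;",
      x$n_genes, "genes,", x$n_circ, "circRNAs,",
      x$n_mirna, "miRNAs,", x$n_probes, "probes\n")
  cat("  planted |log2FC| =", x$lfc_effect, "in", x$de_fraction,
      "of count features; |dM| =", x$dm_effect, "; copula rho =",
      x$coupling_rho, "; seed =", x$seed, "\n")
  invisible(x)
}

#' Paired tumor/normal sample design
#'
#' @param n_pairs Number of subject pairs.
#' @return data.frame with columns sample_id, subject, group ("tumor"/"normal").
#'   Normal samples come first (N1..Nn), then tumors (T1..Tn); sample i of each
#'   block belongs to subject i.
#' @examples
#' sample_design(3)
#' @export
sample_design <- function(n_pairs) {
  n_pairs <- as.integer(n_pairs)
  stopifnot(n_pairs >= 1)
  data.frame(
    sample_id = c(paste0("N", seq_len(n_pairs)), paste0("T", seq_len(n_pairs))),
    subject = rep(paste0("P", seq_len(n_pairs)), 2),
    group = rep(c("normal", "tumor"), each = n_pairs),
    stringsAsFactors = FALSE
  )
}
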
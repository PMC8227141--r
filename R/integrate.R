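#' Filter a circRNA catalog by junction-read support
#'
#' Keeps circRNAs whose BSJ count is at least `min_reads` in at least
#' `min_samples` samples (defaults 2 and 2), the confidence filter applied
#' before differential analysis.
#'
#' @param circ_counts BSJ count matrix (circRNAs x samples).
#' @param min_samples,min_reads Support thresholds.
#' @return Character vector of retained circ ids.
#' @export
filter_catalog <- function(circ_counts, min_samples = 2, min_reads = 2) {
  m <- as.matrix(circ_counts)
  rownames(m)[rowSums(m >= min_reads) >= min_samples]
}

#' Decoupled circRNAs: DE circRNAs with DM sites but non-DE parental genes
#'
#' Returns exactly the circRNAs that (i) are differentially expressed, (ii)
#' harbor at least one DM probe in any of their Pre2000/Interior/After2000
#' regions, and (iii) have a parental gene that is NOT differentially
#' expressed. Intergenic circRNAs have no parental gene and are excluded.
#'
#' @param circ_de DE table for the circ layer (feature_id, log2FC, p_adj, call).
#' @param gene_de DE table for the gene layer.
#' @param assignments Probe-to-region assignments from [map_probes()] run on
#'   circRNA regions (probe_id, feature_id, region).
#' @param dm DM table (probe_id, delta_m, p_adj, call).
#' @param circs circRNA catalog (circ_id, origin, gene_id).
#' @return data.frame: circ_id, direction, gene_id, gene_padj, n_dm_probes,
#'   dm_probes (comma-collapsed probe ids), dm_regions (comma-collapsed).
#' @export
decoupled_circrnas <- function(circ_de, gene_de, assignments, dm, circs) {
  de_circ <- circ_de[circ_de$call != "ns", , drop = FALSE]
  parent <- circs$gene_id[match(de_circ$feature_id, circs$circ_id)]
  de_circ <- de_circ[!is.na(parent), , drop = FALSE]
  parent <- parent[!is.na(parent)]
  missing <- setdiff(parent, gene_de$feature_id)
  if (length(missing)) {
    stop("parental genes absent from the gene DE table: ",
         paste(unique(missing), collapse = ", "))
  }
  dm_sig <- dm$probe_id[dm$call != "ns"]
  hits <- assignments[assignments$probe_id %in% dm_sig, , drop = FALSE]
  gene_call <- gene_de$call[match(parent, gene_de$feature_id)]
  gene_padj <- gene_de$p_adj[match(parent, gene_de$feature_id)]

  keep <- which(gene_call == "ns" & de_circ$feature_id %in% hits$feature_id)
  if (!length(keep)) {
    return(data.frame(circ_id = character(0), direction = character(0),
                      gene_id = character(0), gene_padj = numeric(0),
                      n_dm_probes = integer(0), dm_probes = character(0),
                      dm_regions = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(keep, function(i) {
    cid <- de_circ$feature_id[i]
    h <- hits[hits$feature_id == cid, , drop = FALSE]
    h <- h[!duplicated(h$probe_id), , drop = FALSE]
    data.frame(circ_id = cid, direction = de_circ$call[i],
               gene_id = parent[i], gene_padj = gene_padj[i],
               n_dm_probes = nrow(h),
               dm_probes = paste(h$probe_id, collapse = ","),
               dm_regions = paste(h$region, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$circ_id), , drop = FALSE]
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' rho is the Pearson correlation of mid-ranks (tie-aware). For `n >= 10`
#' the p-value uses the t approximation `t = rho * sqrt((n - 2)/(1 - rho^2))`
#' on `n - 2` degrees of freedom; for `n < 10` the two-sided p is computed by
#' full enumeration of the `n!` permutations of one vector.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @return list(rho, p, method). Constant input yields `rho = NA`, `p = NA`
#'   with a warning.
#' @examples
#' spearman_test(1:4, c(2, 4, 6, 8))$rho  # 1
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    list(rho = rho, p = min(p, 1), method = "t-approximation")
  } else {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact-permutation")
  }
}

# All n! permutations of 1..n as a matrix (rows). Only used for small n.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Methylation-expression correlation for decoupled circRNAs
#'
#' One Spearman test per (circRNA, DM probe in its regions) pair, computed
#' across all samples jointly (tumor + normal). circRNA expression is the
#' size-factor-normalized BSJ count on the log2(x + 1) scale; methylation is
#' the probe M-value. A pair is significant at raw `p < p_cut` (no multiple
#' testing adjustment unless `adjust = TRUE`).
#'
#' @param decoupled Output of [decoupled_circrnas()].
#' @param circ_expr Normalized log2 circ expression matrix (circ x samples).
#' @param m Probe M-value matrix (probes x samples), same sample columns.
#' @param p_cut Significance cutoff (default 0.05).
#' @param adjust Apply BH across the tested pairs (default FALSE).
#' @return data.frame: circ_id, probe_id, rho, p, significant; attribute
#'   "multi_probe_circ" lists circRNAs with more than one significant probe.
#' @export
correlate_methylation_expression <- function(decoupled, circ_expr, m,
                                             p_cut = 0.05, adjust = FALSE) {
  if (!setequal(colnames(circ_expr), colnames(m))) {
    stop("sample columns of expression and methylation matrices differ")
  }
  m <- m[, colnames(circ_expr), drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(decoupled))) {
    cid <- decoupled$circ_id[i]
    pids <- strsplit(decoupled$dm_probes[i], ",")[[1]]
    for (pid in pids) {
      st <- spearman_test(circ_expr[cid, ], m[pid, ])
      rows[[length(rows) + 1]] <- data.frame(
        circ_id = cid, probe_id = pid, rho = st$rho, p = st$p,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(circ_id = character(0), probe_id = character(0),
                      rho = numeric(0), p = numeric(0), significant = logical(0))
    attr(out, "multi_probe_circ") <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  pp <- if (adjust) bh_adjust(out$p) else out$p
  out$significant <- !is.na(pp) & pp < p_cut
  tab <- table(out$circ_id[out$significant])
  attr(out, "multi_probe_circ") <- names(tab)[tab > 1]
  out
}

#' Summarize DM sites over circRNA directions and regions
#'
#' Counts DM sites by (circRNA direction x region x hyper/hypo) — a probe
#' assigned to several circRNAs contributes one site per (circRNA, probe)
#' assignment — plus, per circRNA, the number of distinct regions harboring
#' at least one DM site, the fraction of DE circRNAs with exactly one such
#' region, and circRNA-level counts (circRNAs with >= 1 DM site per region).
#'
#' @param assignments Probe-to-circ-region assignments (probe_id, feature_id,
#'   region).
#' @param dm DM table (probe_id, call).
#' @param circ_de circ DE table (feature_id, call).
#' @return list(site_counts, circ_counts, regions_per_circ,
#'   one_region_fraction).
#' @export
region_dm_summary <- function(assignments, dm, circ_de) {
  dirs <- c("up", "down"); regs <- c("Pre2000", "Interior", "After2000")
  states <- c("hyper", "hypo")
  a <- assignments
  a$dm_call <- dm$call[match(a$probe_id, dm$probe_id)]
  a$dir <- circ_de$call[match(a$feature_id, circ_de$feature_id)]
  a <- a[!is.na(a$dm_call) & a$dm_call != "ns" &
           !is.na(a$dir) & a$dir != "ns", , drop = FALSE]
  a <- a[!duplicated(a[, c("probe_id", "feature_id", "region")]), , drop = FALSE]

  site_counts <- array(0L, dim = c(2, 3, 2), dimnames = list(dirs, regs, states))
  circ_counts <- array(0L, dim = c(2, 3), dimnames = list(dirs, regs))
  if (nrow(a)) {
    t1 <- table(factor(a$dir, dirs), factor(a$region, regs), factor(a$dm_call, states))
    site_counts[] <- t1
    u <- unique(a[, c("feature_id", "region", "dir")])
    t2 <- table(factor(u$dir, dirs), factor(u$region, regs))
    circ_counts[] <- t2
  }
  regions_per_circ <- if (nrow(a)) {
    vapply(split(a$region, a$feature_id), function(r) length(unique(r)),
           integer(1))
  } else {
    integer(0)
  }
  one_frac <- if (length(regions_per_circ)) {
    mean(regions_per_circ == 1)
  } else {
    NA_real_
  }
  list(site_counts = site_counts, circ_counts = circ_counts,
       regions_per_circ = regions_per_circ, one_region_fraction = one_frac)
}

#' circRNAs with expression opposite to their parental gene
#'
#' Flags circRNAs where both the circRNA and its parental gene are called
#' differentially expressed but with opposite signs of log2FC.
#'
#' @param circ_de,gene_de DE tables (feature_id, log2FC, call).
#' @param circs circRNA catalog with parental gene mapping.
#' @return data.frame: circ_id, circ_call, gene_id, gene_call.
#' @export
opposite_pattern <- function(circ_de, gene_de, circs) {
  de <- circ_de[circ_de$call != "ns", , drop = FALSE]
  gid <- circs$gene_id[match(de$feature_id, circs$circ_id)]
  g <- match(gid, gene_de$feature_id)
  gcall <- gene_de$call[g]
  glfc <- gene_de$log2FC[g]
  keep <- !is.na(gid) & !is.na(gcall) & gcall != "ns" &
    sign(de$log2FC) != sign(glfc)
  data.frame(circ_id = de$feature_id[keep], circ_call = de$call[keep],
             gene_id = gid[keep], gene_call = gcall[keep],
             stringsAsFactors = FALSE)
}

#' Per-chromosome DE-circRNA density normalized by gene count
#'
#' @param de_circ_ids circ ids called DE.
#' @param circs circRNA catalog.
#' @param genes Gene annotation table.
#' @return data.frame sorted by decreasing density: chrom, n_circ, n_genes,
#'   density (= n_circ / n_genes), rank. Chromosomes without genes are
#'   excluded with a warning.
#' @export
chromosome_density <- function(de_circ_ids, circs, genes) {
  cc <- circs[circs$circ_id %in% de_circ_ids, , drop = FALSE]
  gtab <- table(genes$chrom)
  ctab <- table(factor(cc$chrom, levels = names(gtab)))
  zero <- setdiff(unique(cc$chrom), names(gtab))
  if (length(zero)) warning("chromosomes without genes excluded: ",
                            paste(zero, collapse = ", "))
  out <- data.frame(chrom = names(gtab), n_circ = as.integer(ctab),
                    n_genes = as.integer(gtab),
                    density = as.numeric(ctab) / as.numeric(gtab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$density, out$chrom), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for set overlap
#'
#' Builds the 2x2 membership table of `detected` vs `catalog` within a
#' universe of `universe_size` elements and sums the hypergeometric
#' probabilities of all tables at least as extreme (probability at or below
#' that of the observed table), the standard two-sided Fisher p.
#'
#' @param detected,catalog Character vectors (or sets) of element ids.
#' @param universe_size Total number of elements; must be at least
#'   `length(union(detected, catalog))`.
#' @return list(odds_ratio, p, table).
#' @export
overlap_fisher <- function(detected, catalog, universe_size) {
  detected <- unique(detected); catalog <- unique(catalog)
  a <- length(intersect(detected, catalog))
  b <- length(detected) - a
  cc <- length(catalog) - a
  d <- universe_size - a - b - cc
  if (d < 0) stop("universe smaller than the union of the two sets")
  tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
  list(odds_ratio = (a * d) / max(b * cc, .Machine$double.xmin),
       p = fisher_p_2x2(a, b, cc, d), table = tab)
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
fisher_p_2x2 <- function(a, b, cc, d) {
  m <- a + b          # row 1 total
  n <- cc + d         # row 2 total
  k <- a + cc         # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p per gene set (equivalently, one-sided Fisher
#' exact on the 2x2 table), BH-adjusted across sets; significant iff
#' FDR < `fdr_cut`.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `universe` and nonempty.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all genes.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return data.frame: set, n_set, n_overlap, expected, p, p_adj, significant.
#' @export
enrichment_ora <- function(query, gene_sets, universe, fdr_cut = 0.05) {
  query <- unique(query)
  if (!length(query)) stop("empty query set")
  if (length(setdiff(query, universe))) stop("query is not a subset of the universe")
  N <- length(unique(universe))
  n <- length(query)
  rows <- lapply(names(gene_sets), function(s) {
    set <- intersect(unique(gene_sets[[s]]), universe)
    k <- length(intersect(query, set))
    K <- length(set)
    data.frame(set = s, n_set = K, n_overlap = k, expected = n * K / N,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr_cut
  out
}

#' Normalized log2 circRNA expression for correlation analyses
#'
#' BSJ counts divided by the layer's size factors, then log2(x + 1).
#'
#' @param circ_counts BSJ count matrix.
#' @param sf Size factors (default: computed with a pseudo-reference
#'   fallback, since BSJ matrices are sparse).
#' @return Matrix of normalized log2 expression.
#' @export
normalize_circ_expression <- function(circ_counts, sf = NULL) {
  m <- as.matrix(circ_counts)
  if (is.null(sf)) {
    sf <- size_factors(m, pseudo_reference = !any(rowSums(m > 0) == ncol(m)))
  }
  log2(sweep(m, 2, sf, "/") + 1)
}
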
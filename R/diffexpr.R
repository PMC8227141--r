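#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio of its count to the feature's geometric mean over samples, computed
#' on the features with all-positive counts; the factors are then rescaled
#' to have geometric mean 1.
#'
#' @param counts Nonnegative integer matrix (features x samples).
#' @param pseudo_reference If no feature has all-positive counts, setting
#'   this to TRUE computes the geometric means over the positive entries of
#'   features expressed in at least half the samples instead of failing.
#' @return Named numeric vector of positive size factors.
#' @examples
#' size_factors(matrix(c(10, 30, 20, 60), 2))  # ~ (0.707, 1.414)
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    if (!pseudo_reference) {
      stop("no feature has all-positive counts; re-run with pseudo_reference = TRUE")
    }
    use <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(use)) stop("no feature is expressed in at least half the samples")
    logref <- apply(counts[use, , drop = FALSE], 1,
                    function(r) mean(log(r[r > 0])))
    ratios <- log(counts[use, , drop = FALSE]) - logref
    ratios[!is.finite(ratios)] <- NA
    sf <- exp(apply(ratios, 2, stats::median, na.rm = TRUE))
  } else {
    logref <- rowMeans(log(counts[allpos, , drop = FALSE]))
    sf <- exp(apply(log(counts[allpos, , drop = FALSE]) - logref, 2, stats::median))
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments dispersion estimation with trend shrinkage
#'
#' Per feature, a raw dispersion is estimated on normalized counts as
#' `alpha = max(0, (v - m) / m^2)` using the within-group pooled variance
#' `v` and the mean of group means `m`; the raw estimates are then shrunk
#' toward a fitted mean-dispersion trend `alpha_tr(mu) = a0 + a1 / mu`
#' (nonnegative least squares on the positive raw estimates) by a
#' precision-weighted average `(d * alpha_raw + w0 * alpha_tr) / (d + w0)`
#' with `d` the residual degrees of freedom and prior weight `w0 = 8`.
#'
#' @param counts Count matrix (features x samples).
#' @param sf Size factors from [size_factors()].
#' @param design Design table (two groups, tumor/normal).
#' @return data.frame: feature_id, mean (normalized), alpha_raw, alpha_trend,
#'   alpha, excluded (all-zero features, which have no defined dispersion).
#' @export
estimate_dispersion <- function(counts, sf, design) {
  x <- align_design(counts, design)
  if (sum(x == 1) < 2 || sum(x == 0) < 2) stop("each group needs at least 2 samples")
  norm <- sweep(as.matrix(counts), 2, sf, "/")
  nt <- norm[, x == 1, drop = FALSE]; nn <- norm[, x == 0, drop = FALSE]
  n1 <- ncol(nt); n0 <- ncol(nn)
  m1 <- rowMeans(nt); m0 <- rowMeans(nn)
  v <- (rowSums((nt - m1)^2) + rowSums((nn - m0)^2)) / (n1 + n0 - 2)
  mu <- (m1 + m0) / 2
  excluded <- mu == 0
  alpha_raw <- ifelse(excluded, NA_real_, pmax(0, (v - mu) / mu^2))

  ok <- !excluded & alpha_raw > 0 & mu > 0
  if (sum(ok) >= 10) {
    fit <- stats::lm(alpha_raw[ok] ~ I(1 / mu[ok]))
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- max(stats::median(alpha_raw[!excluded], na.rm = TRUE), 1e-8)
    a1 <- 0
  }
  alpha_trend <- ifelse(excluded, NA_real_, a0 + a1 / pmax(mu, 1e-8))
  d <- n1 + n0 - 2
  w0 <- 8
  alpha <- ifelse(excluded, NA_real_, (d * alpha_raw + w0 * alpha_trend) / (d + w0))
  data.frame(feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             mean = mu, alpha_raw = alpha_raw, alpha_trend = alpha_trend,
             alpha = alpha, excluded = excluded, stringsAsFactors = FALSE)
}

#' Negative-binomial Wald test for two-group designs
#'
#' Fits, per feature, the NB generalized linear model
#' `log mu_ij = log s_j + b0 + b1 x_j` (x = tumor indicator, dispersion
#' known) by iteratively reweighted least squares, vectorized across
#' features, and tests `b1 = 0` with a two-sided normal Wald test.
#' `log2FC = b1 / log(2)`.
#'
#' @param counts Count matrix (features x samples).
#' @param sf Size factors.
#' @param alpha Per-feature dispersion vector (recycled if scalar).
#' @param design Design table.
#' @return data.frame: feature_id, baseMean, log2FC, SE (on the log2 scale),
#'   stat, p, flagged (all-zero features: p = 1, log2FC = 0).
#' @export
nb_wald_test <- function(counts, sf, alpha, design) {
  counts <- as.matrix(counts)
  x <- align_design(counts, design)
  if (sum(x == 1) < 2 || sum(x == 0) < 2) stop("each group needs at least 2 samples")
  nf <- nrow(counts); ns <- ncol(counts)
  alpha <- rep_len(alpha, nf)
  alpha[is.na(alpha)] <- 0
  o <- matrix(log(sf), nf, ns, byrow = TRUE)
  xm <- matrix(x, nf, ns, byrow = TRUE)
  norm <- sweep(counts, 2, sf, "/")
  m1 <- rowMeans(norm[, x == 1, drop = FALSE])
  m0 <- rowMeans(norm[, x == 0, drop = FALSE])
  flagged <- m1 == 0 & m0 == 0

  eps <- 0.01
  b0 <- log(m0 + eps)
  b1 <- log(m1 + eps) - b0
  for (iter in 1:50) {
    eta <- pmin(b0 + b1 * xm + o, 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- eta - o + (counts - mu) / mu
    wz <- w * z
    sw <- rowSums(w)
    swx <- rowSums(w * xm)
    swz <- rowSums(wz)
    swxz <- rowSums(wz * xm)
    b0_new <- (swz - swxz) / (sw - swx)
    b1_new <- swxz / swx - b0_new
    # cap the effect to keep exp() finite for separated (one group all-zero)
    # features; SEs blow up correspondingly, so inference is unaffected
    b1_new <- pmin(pmax(b1_new, -15), 15)
    delta <- max(abs(c(b0_new - b0, b1_new - b1)), na.rm = TRUE)
    b0 <- b0_new; b1 <- b1_new
    if (delta < 1e-10) break
  }
  eta <- pmin(b0 + b1 * xm + o, 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  se_b1 <- sqrt(1 / rowSums(w * xm) + 1 / rowSums(w * (1 - xm)))
  stat <- b1 / se_b1
  p <- 2 * stats::pnorm(-abs(stat))
  log2fc <- b1 / log(2)
  log2fc[flagged] <- 0
  p[flagged] <- 1
  stat[flagged] <- 0
  data.frame(feature_id = rownames(counts) %||% as.character(seq_len(nf)),
             baseMean = rowMeans(norm), log2FC = log2fc, SE = se_b1 / log(2),
             stat = stat, p = p, flagged = flagged, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Native implementation of the BH step-up procedure with monotonicity
#' enforcement; order-preserving and idempotent on the adjusted scale.
#'
#' @param p Numeric vector of p-values in [0, 1] (NA allowed, propagated).
#' @return Adjusted p-values (>= the input p-values).
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  n <- length(ok)
  if (!n) return(out)
  o <- order(p[ok], decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * p[ok][o]))
  out[ok][o] <- adj
  out
}

#' Call differential expression with per-layer rules
#'
#' Genes and miRNAs: up/down iff `p_adj < p_cut` and `|log2FC| > lfc_cut`.
#' circRNAs: up/down iff `p_adj < p_cut` and the junction-read support rule
#' holds — BSJ count `>= min_reads` in at least `min_samples` samples — with
#' no fold-change cutoff (defaults: p < 0.05, |log2FC| > 1, 2 reads in 2
#' samples).
#'
#' @param res data.frame with columns log2FC and p_adj (features in rows).
#' @param layer One of "gene", "circ", "mirna".
#' @param counts Raw count matrix, required for the circ layer's junction
#'   support rule (rows matching `res$feature_id`).
#' @param p_cut,lfc_cut,min_reads,min_samples Thresholds.
#' @return Character vector in {"up", "down", "ns"}.
#' @export
call_de <- function(res, layer, counts = NULL, p_cut = 0.05, lfc_cut = 1,
                    min_reads = 2, min_samples = 2) {
  if (!layer %in% c("gene", "circ", "mirna")) stop("unknown layer tag: ", layer)
  sig <- res$p_adj < p_cut
  if (layer == "circ") {
    if (is.null(counts)) stop("circ layer calling requires the count matrix")
    support <- rowSums(as.matrix(counts) >= min_reads) >= min_samples
    sig <- sig & support[match(res$feature_id, rownames(counts))]
  } else {
    sig <- sig & abs(res$log2FC) > lfc_cut
  }
  sig[is.na(sig)] <- FALSE
  unname(ifelse(sig & res$log2FC > 0, "up",
                ifelse(sig & res$log2FC < 0, "down", "ns")))
}

#' Differential expression analysis of one count layer
#'
#' Convenience wrapper: size factors, dispersion estimation, NB Wald test,
#' BH adjustment and per-layer calling.
#'
#' @inheritParams call_de
#' @param counts Count matrix (features x samples).
#' @param design Design table.
#' @param sf Optional pre-computed size factors.
#' @param ... Passed to [call_de()].
#' @return data.frame with feature_id, baseMean, log2FC, SE, stat, p, p_adj,
#'   call; size factors attached as attribute "size_factors".
#' @export
de_analysis <- function(counts, design, layer = "gene", sf = NULL, ...) {
  counts <- as.matrix(counts)
  if (is.null(sf)) {
    sf <- size_factors(counts, pseudo_reference = !any(rowSums(counts > 0) == ncol(counts)))
  }
  disp <- estimate_dispersion(counts, sf, design)
  res <- nb_wald_test(counts, sf, disp$alpha, design)
  res$p[disp$excluded] <- NA
  res$p_adj <- bh_adjust(res$p)
  res$p_adj[disp$excluded] <- NA
  res$call <- call_de(res, layer = layer, counts = counts, ...)
  attr(res, "size_factors") <- sf
  res
}
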
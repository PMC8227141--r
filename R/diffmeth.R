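#' Convert methylation beta-values to M-values (and back)
#'
#' `M = log2(beta / (1 - beta))` after clamping beta into `[eps, 1 - eps]`
#' so that boundary values stay finite. The transform is strictly increasing
#' on the clamped interval and `m_to_beta()` inverts it.
#'
#' @param beta Numeric vector/matrix of beta-values in [0, 1].
#' @param eps Clamp width for beta in {0, 1} (default 1e-6).
#' @return M-values with the same shape as the input.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta-values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(m) <- dim(beta)
  dimnames(m) <- dimnames(beta)
  m
}

#' @rdname beta_to_m
#' @param m Numeric vector/matrix of M-values.
#' @export
m_to_beta <- function(m) {
  b <- 2^m / (1 + 2^m)
  b[is.infinite(m) & m > 0] <- 1
  dimnames(b) <- dimnames(m)
  b
}

#' Per-probe difference of group-mean M-values
#'
#' `delta M = mean(M | tumor) - mean(M | normal)`, the unpaired estimator.
#'
#' @param m Matrix of M-values (probes x samples).
#' @param design Design table with sample_id/group columns matching the
#'   matrix columns.
#' @return Named numeric vector of delta-M values.
#' @export
delta_m <- function(m, design) {
  x <- align_design(m, design)
  rowMeans(m[, x == 1, drop = FALSE]) - rowMeans(m[, x == 0, drop = FALSE])
}

align_design <- function(mat, design) {
  if (!setequal(colnames(mat), design$sample_id)) {
    stop("matrix columns do not match the design's sample ids")
  }
  x <- group_indicator(design)
  x[match(colnames(mat), design$sample_id)]
}

# Inverse of the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); used when moment-matching the inverse-chi-square variance prior.
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 0) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    if (yy < 1e-6) return(1 / yy)
    x <- 0.5 + 1 / yy
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderated two-group t-test
#'
#' Fits, per probe, the two-group linear model and shrinks the residual
#' variances toward a common prior: the per-probe variances `s^2` (d degrees
#' of freedom) are modeled as scaled-F draws around a prior `s0^2` with `d0`
#' prior degrees of freedom; `(d0, s0^2)` are estimated by moment-matching on
#' `log s^2` (digamma/trigamma equations) and the posterior variance
#' `s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d)` yields a t-statistic on
#' `d0 + d` degrees of freedom. With `d0 = 0` this is the ordinary t-test;
#' with `d0 = Inf` all probes share the prior variance.
#'
#' @param m Matrix of M-values (probes x samples).
#' @param design Design table (sample_id, group in tumor/normal).
#' @param prior Optional list(d0, s02) overriding the fitted prior (mainly
#'   for testing the limiting cases).
#' @return data.frame: probe_id, delta_m, t, df, p, s2, s2_post plus
#'   attributes `d0` and `s02`.
#' @export
moderated_t <- function(m, design, prior = NULL) {
  x <- align_design(m, design)
  n1 <- sum(x == 1); n0 <- sum(x == 0)
  if (n1 < 2 || n0 < 2) stop("each group needs at least 2 samples")
  mt <- m[, x == 1, drop = FALSE]; mn <- m[, x == 0, drop = FALSE]
  dm <- rowMeans(mt) - rowMeans(mn)
  s2 <- (rowSums((mt - rowMeans(mt))^2) + rowSums((mn - rowMeans(mn))^2)) / (n1 + n0 - 2)
  d <- n1 + n0 - 2

  if (is.null(prior)) {
    ok <- s2 > 0
    if (!any(ok)) stop("all probes have zero residual variance; cannot fit prior")
    e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.na(evar) || evar <= 0) {
      # less spread in log s^2 than the chi-square alone implies: variances
      # are essentially common, take the d0 -> Inf limit with s0^2 equal to
      # the geometric mean of the observed s^2
      d0 <- Inf
      s02 <- exp(mean(e) + digamma(d / 2) - log(d / 2))
    } else {
      half_d0 <- trigamma_inverse(evar)
      d0 <- 2 * half_d0
      s02 <- exp(mean(e) + digamma(half_d0) - log(half_d0))
      if (!is.finite(d0) || !is.finite(s02)) {
        warning("variance-prior fit did not converge; falling back to d0 = Inf")
        d0 <- Inf
        s02 <- exp(mean(e) + digamma(d / 2) - log(d / 2))
      }
    }
  } else {
    d0 <- prior$d0
    s02 <- prior$s02
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n0))
  t <- dm / se
  df_total <- min(d0 + d, 1e6)
  flagged <- se == 0
  t[flagged] <- 0
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[flagged] <- 1
  out <- data.frame(probe_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    delta_m = dm, t = t, df = df_total, p = p,
                    s2 = s2, s2_post = s2_post, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  rownames(out) <- NULL
  out
}

#' Classify differentially methylated probes
#'
#' A probe is called hypermethylated iff `delta_m > dm_cut` and
#' `p_adj < p_cut`, hypomethylated iff `delta_m < -dm_cut` and
#' `p_adj < p_cut`, otherwise "ns". Defaults are adjusted p < 0.05 and
#' |delta M| > 0.5.
#'
#' @param res data.frame with columns delta_m and p_adj.
#' @param dm_cut,p_cut Cutoffs.
#' @return Character vector in {"hyper", "hypo", "ns"}.
#' @export
call_dm <- function(res, dm_cut = 0.5, p_cut = 0.05) {
  ifelse(res$p_adj < p_cut & res$delta_m > dm_cut, "hyper",
         ifelse(res$p_adj < p_cut & res$delta_m < -dm_cut, "hypo", "ns"))
}

#' Differential methylation analysis of a probe table
#'
#' Runs beta-to-M conversion, the moderated t-test, BH adjustment and
#' hyper/hypo calling in one step.
#'
#' @param probes Probe data.frame (probe_id, chrom, pos, beta columns per
#'   sample) or a beta matrix with probe rownames.
#' @param design Design table.
#' @param dm_cut,p_cut Calling cutoffs (defaults 0.5 and 0.05).
#' @param eps Beta clamp for the logit transform.
#' @return data.frame: probe_id (plus chrom/pos when available), delta_m, t,
#'   p, p_adj, call.
#' @export
dm_analysis <- function(probes, design, dm_cut = 0.5, p_cut = 0.05, eps = 1e-6) {
  if (is.data.frame(probes)) {
    beta <- as.matrix(probes[, design$sample_id, drop = FALSE])
    rownames(beta) <- probes$probe_id
    meta <- probes[, intersect(c("probe_id", "chrom", "pos"), names(probes)), drop = FALSE]
  } else {
    beta <- probes
    meta <- data.frame(probe_id = rownames(beta), stringsAsFactors = FALSE)
  }
  m <- beta_to_m(beta, eps = eps)
  res <- moderated_t(m, design)
  res$p_adj <- bh_adjust(res$p)
  res$call <- call_dm(res, dm_cut = dm_cut, p_cut = p_cut)
  out <- cbind(meta, res[, c("delta_m", "t", "df", "p", "p_adj", "call")])
  rownames(out) <- NULL
  out
}
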
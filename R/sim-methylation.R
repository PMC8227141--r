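#' Simulate a 450K-style methylation probe table with planted DM sites
#'
#' Probes are placed partly inside circRNA-relative regions (Pre2000 /
#' Interior / After2000) and partly uniformly over the chromosomes. Null
#' probes draw beta-values from a Beta distribution around a per-probe
#' baseline (`Beta(b0 * phi, (1 - b0) * phi)`, `phi = config$beta_precision`).
#' A `dm_fraction` of the probes landing inside circRNA regions instead draw
#' M-values from a Gaussian whose tumor-group mean is shifted by
#' `+/- config$dm_effect` (sign is hypermethylated with probability 0.8,
#' mirroring the predominance of hypermethylation around DE circRNAs);
#' beta-values are recovered by the inverse-logit, which keeps them strictly
#' inside (0, 1).
#'
#' `guarantee_circ` lists circRNA ids that must each receive at least one
#' planted DM probe in one of their regions (the simulator uses this for the
#' planted "decoupled" circRNAs so that ground truth is recoverable); these
#' guaranteed probes are also the candidates for copula coupling.
#'
#' @param annotation A [simulate_annotation()] result.
#' @param design A [sample_design()] table.
#' @param config A [sim_config()] object.
#' @param guarantee_circ Character vector of circ ids (possibly empty).
#' @return List of class `sim_methylation`:
#'   \describe{
#'     \item{probes}{data.frame: probe_id, chrom, pos, then one beta column
#'       per sample}
#'     \item{dm_probes}{data.frame: probe_id, delta_m, region, circ_id
#'       (circ_id NA for non-guaranteed planted probes)}
#'     \item{m_mean}{matrix of per-sample Gaussian M means for the planted
#'       probes (margins, used by [couple_circ_methylation()])}
#'     \item{m_sd}{scalar M-value SD used for planted probes}
#'   }
#' @export
simulate_methylation <- function(annotation, design, config, guarantee_circ = character(0)) {
  stopifnot(inherits(annotation, "sim_annotation"), inherits(config, "sim_config"))
  if (config$dm_fraction > 0 && config$dm_effect <= 0) {
    stop("configuration error: dm_effect must be > 0 when dm_fraction > 0")
  }
  x <- group_indicator(design)
  n_samples <- nrow(design)
  sizes <- annotation$chrom_sizes
  regions <- circ_regions(annotation$circs, chrom_sizes = sizes)

  with_seed(derive_seed(config$seed, "meth"), {
    n_guar <- length(guarantee_circ)
    if (n_guar > config$n_probes) stop("n_probes too small for guaranteed DM probes")

    pos_in_region <- function(r) r$start + sample.int(r$end - r$start + 1, 1) - 1

    ## guaranteed probes: one per listed circRNA, region weighted toward the
    ## Interior as in real circRNA-associated DM sites
    guar <- NULL
    if (n_guar) {
      rows <- lapply(guarantee_circ, function(cid) {
        rr <- regions[regions$feature_id == cid, , drop = FALSE]
        w <- c(Pre2000 = 0.1, Interior = 0.8, After2000 = 0.1)[rr$region]
        r <- rr[sample(nrow(rr), 1, prob = w), ]
        data.frame(chrom = r$chrom, pos = pos_in_region(r), region = r$region,
                   circ_id = cid, stringsAsFactors = FALSE)
      })
      guar <- do.call(rbind, rows)
    }

    ## remaining probes: a fraction inside circ regions, the rest genome-wide
    n_rest <- config$n_probes - n_guar
    n_in <- round(config$probe_region_fraction * n_rest)
    in_rows <- if (n_in > 0) {
      idx <- sample(nrow(regions), n_in, replace = TRUE,
                    prob = regions$end - regions$start + 1)
      data.frame(chrom = regions$chrom[idx],
                 pos = vapply(idx, function(i) pos_in_region(regions[i, ]), numeric(1)),
                 stringsAsFactors = FALSE)
    } else NULL
    n_out <- n_rest - n_in
    out_rows <- if (n_out > 0) {
      ci <- sample(length(sizes), n_out, replace = TRUE, prob = sizes)
      data.frame(chrom = names(sizes)[ci],
                 pos = vapply(sizes[ci], function(s) sample.int(s, 1), numeric(1)),
                 stringsAsFactors = FALSE)
    } else NULL

    loc <- rbind(
      if (n_guar) guar[, c("chrom", "pos")] else NULL,
      in_rows, out_rows
    )
    o <- order(loc$chrom, loc$pos)
    probe_id <- character(nrow(loc))
    probe_id[o] <- sprintf("cg%08d", seq_len(nrow(loc)))
    guar_ids <- if (n_guar) probe_id[seq_len(n_guar)] else character(0)

    ## choose planted-DM probes among the non-guaranteed in-region probes;
    ## "in-region" is decided by actual containment, not placement intent
    assign_all <- map_probes(
      data.frame(probe_id = probe_id, chrom = loc$chrom, pos = loc$pos,
                 stringsAsFactors = FALSE),
      regions
    )
    in_region_ids <- setdiff(unique(assign_all$probe_id), guar_ids)
    n_dm_extra <- round(config$dm_fraction * length(in_region_ids))
    extra_dm <- if (n_dm_extra > 0) sample(in_region_ids, n_dm_extra) else character(0)

    dm_ids <- c(guar_ids, extra_dm)
    sign_dm <- sample(c(1, -1), length(dm_ids), replace = TRUE, prob = c(0.8, 0.2))
    delta_m <- config$dm_effect * sign_dm

    region_of <- function(pid) {
      a <- assign_all[assign_all$probe_id == pid, , drop = FALSE]
      if (!nrow(a)) NA_character_ else a$region[1]
    }
    dm_region <- c(if (n_guar) guar$region else character(0),
                   vapply(extra_dm, region_of, character(1), USE.NAMES = FALSE))
    dm_circ <- c(if (n_guar) guar$circ_id else character(0),
                 rep(NA_character_, length(extra_dm)))

    ## beta generation
    beta <- matrix(NA_real_, nrow = nrow(loc), ncol = n_samples,
                   dimnames = list(probe_id, design$sample_id))
    is_dm <- probe_id %in% dm_ids
    n_null <- sum(!is_dm)
    if (n_null) {
      comp <- sample(1:3, n_null, replace = TRUE, prob = c(0.4, 0.4, 0.2))
      b0 <- ifelse(comp == 1, stats::rbeta(n_null, 2, 8),
            ifelse(comp == 2, stats::rbeta(n_null, 8, 2), stats::rbeta(n_null, 2, 2)))
      phi <- config$beta_precision
      beta[!is_dm, ] <- stats::rbeta(n_null * n_samples,
                                     shape1 = rep(b0 * phi, n_samples),
                                     shape2 = rep((1 - b0) * phi, n_samples))
    }
    m_mean <- NULL
    if (length(dm_ids)) {
      m0 <- stats::rnorm(length(dm_ids), 0, 1.5)
      m_mean <- outer(rep(1, length(dm_ids)), x) * delta_m + m0
      dimnames(m_mean) <- list(dm_ids, design$sample_id)
      mm <- m_mean + matrix(stats::rnorm(length(m_mean), 0, config$m_sd),
                            nrow = nrow(m_mean))
      beta[dm_ids, ] <- m_to_beta(mm)
    }
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)

    probes <- data.frame(probe_id = probe_id, chrom = loc$chrom, pos = loc$pos,
                         stringsAsFactors = FALSE)
    probes <- cbind(probes, as.data.frame(beta))
    probes <- probes[order(probes$chrom, probes$pos), ]
    rownames(probes) <- NULL

    dm_probes <- data.frame(probe_id = dm_ids, delta_m = delta_m,
                            region = dm_region, circ_id = dm_circ,
                            stringsAsFactors = FALSE)
    structure(list(probes = probes, dm_probes = dm_probes,
                   m_mean = m_mean, m_sd = config$m_sd),
              class = "sim_methylation")
  })
}

#' Couple circRNA counts and probe methylation through a Gaussian copula
#'
#' For each (circ, probe) pair a per-sample latent bivariate normal draw with
#' correlation `rho` is pushed through the negative-binomial quantile function
#' (circ margin) and the Gaussian M margin followed by the inverse logit
#' (probe margin). Both marginal distributions are therefore exactly
#' preserved while the pair acquires the target latent correlation; for a
#' bivariate normal copula the population Spearman correlation is
#' `(6 / pi) * asin(rho / 2)`.
#'
#' @param circ_counts circRNA count matrix (features x samples).
#' @param probe_beta probe beta matrix (probes x samples), or the probe
#'   data.frame from [simulate_methylation()] (beta columns are replaced).
#' @param pairs data.frame with columns circ_id, probe_id, rho.
#' @param circ_mu matrix of per-sample NB means for the circ layer.
#' @param circ_size NB size parameter (1 / dispersion).
#' @param probe_m_mean matrix of per-sample M means for the probes involved.
#' @param m_sd M-value standard deviation of the probe margin.
#' @param seed Integer seed for the coupling stream.
#' @return list(circ_counts, probe_beta) with the paired rows regenerated.
#' @export
couple_circ_methylation <- function(circ_counts, probe_beta, pairs,
                                    circ_mu, circ_size, probe_m_mean, m_sd, seed) {
  if (!nrow(pairs)) return(list(circ_counts = circ_counts, probe_beta = probe_beta))
  if (any(abs(pairs$rho) > 1)) stop("|rho| > 1 in coupled pairs")
  missing_c <- setdiff(pairs$circ_id, rownames(circ_counts))
  missing_p <- setdiff(pairs$probe_id, rownames(probe_beta))
  if (length(missing_c) || length(missing_p)) {
    stop("coupled pair references unknown ids: ",
         paste(c(missing_c, missing_p), collapse = ", "))
  }
  n <- ncol(circ_counts)
  with_seed(seed, {
    for (k in seq_len(nrow(pairs))) {
      cid <- pairs$circ_id[k]; pid <- pairs$probe_id[k]; rho <- pairs$rho[k]
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      u1 <- stats::pnorm(z1)
      circ_counts[cid, ] <- stats::qnbinom(u1, mu = circ_mu[cid, ], size = circ_size)
      m <- probe_m_mean[pid, ] + m_sd * z2
      probe_beta[pid, ] <- pmin(pmax(m_to_beta(m), 1e-6), 1 - 1e-6)
    }
    list(circ_counts = circ_counts, probe_beta = probe_beta)
  })
}
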
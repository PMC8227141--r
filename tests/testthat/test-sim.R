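test_that("annotation respects origin proportions and determinism", {
  # degenerate proportions: everything exonic, with a parental gene
  cfg <- tiny_config(origin_props = c(exonic = 1, intronic = 0, intergenic = 0))
  ann <- simulate_annotation(cfg)
  expect_true(all(ann$circs$origin == "exonic"))
  expect_true(all(!is.na(ann$circs$gene_id)))
  expect_true(all(ann$circs$gene_id %in% ann$genes$gene_id))

  # binomial 99% bounds on class counts at n_circ = 1000
  cfg2 <- sim_config(n_pairs = 2, n_genes = 200, n_circ = 1000, n_mirna = 5,
                     n_probes = 50, seed = 42,
                     origin_props = c(exonic = 0.90, intronic = 0.04, intergenic = 0.06))
  ann2 <- simulate_annotation(cfg2)
  tab <- table(ann2$circs$origin)
  props <- c(exonic = 0.90, intronic = 0.04, intergenic = 0.06)
  # joint 99% band: Bonferroni split of alpha = 0.01 over the three classes
  for (cl in names(props)) {
    lo <- qbinom(0.005 / 3, 1000, props[[cl]])
    hi <- qbinom(1 - 0.005 / 3, 1000, props[[cl]])
    expect_gte(tab[[cl]], lo)
    expect_lte(tab[[cl]], hi)
  }

  # same seed twice: identical catalogs
  expect_identical(simulate_annotation(cfg2), ann2)
  # exonic/intronic circRNAs nested inside their parental gene span
  cc <- ann2$circs[!is.na(ann2$circs$gene_id), ]
  g <- ann2$genes[match(cc$gene_id, ann2$genes$gene_id), ]
  expect_true(all(cc$start >= g$start & cc$end <= g$end))
  expect_true(all(cc$strand == g$strand))
})

test_that("annotation errors when n_circ is below the class count", {
  expect_error(simulate_annotation(tiny_config(n_circ = 2)), "origin classes")
})

test_that("count simulation plants effects as configured", {
  cfg <- tiny_config(de_fraction = 0)
  ann <- simulate_annotation(cfg)
  design <- sample_design(cfg$n_pairs)
  cnt <- simulate_counts(ann, design, cfg)
  expect_length(cnt$log2fc$gene, 0)
  expect_length(cnt$log2fc$circ, 0)
  expect_identical(colnames(cnt$counts$gene), design$sample_id)
  expect_true(all(cnt$counts$gene >= 0))

  # determinism
  cnt2 <- simulate_counts(ann, design, cfg)
  expect_identical(cnt, cnt2)

  # law-of-large-numbers: near-zero dispersion, many pairs, sf-normalized
  # group mean ratio recovers 2^lfc
  cfg3 <- sim_config(n_pairs = 200, n_genes = 500, n_circ = 10, n_mirna = 5,
                     n_probes = 50, nb_dispersion = 1e-3, de_fraction = 0.5,
                     lfc_effect = 2, seed = 9)
  ann3 <- simulate_annotation(cfg3)
  design3 <- sample_design(200)
  cnt3 <- simulate_counts(ann3, design3, cfg3)
  norm <- sweep(cnt3$counts$gene, 2, cnt3$size_factors$gene, "/")
  tumor <- design3$group == "tumor"
  ratio <- log2(rowMeans(norm[, tumor]) / rowMeans(norm[, !tumor]))
  planted <- cnt3$log2fc$gene
  err <- ratio[names(planted)] - planted
  expect_lt(mean(abs(err)), 0.1)
  # naive estimator bias averaged over planted features is small at n=20
  cfg4 <- sim_config(n_pairs = 20, n_genes = 1000, n_circ = 10, n_mirna = 5,
                     n_probes = 50, nb_dispersion = 0.1, de_fraction = 0.6,
                     lfc_effect = 2, seed = 10)
  cnt4 <- simulate_counts(simulate_annotation(cfg4), sample_design(20), cfg4)
  norm4 <- sweep(cnt4$counts$gene, 2, cnt4$size_factors$gene, "/")
  t4 <- sample_design(20)$group == "tumor"
  lr <- log2(rowMeans(norm4[, t4]) / rowMeans(norm4[, !t4]))
  pl <- cnt4$log2fc$gene
  expect_gt(length(pl), 500)
  expect_lt(abs(mean(lr[names(pl)] - pl)), 0.2)
})

test_that("decoupled/opposite classes are disjoint and consistent", {
  cfg <- tiny_config(seed = 5, de_fraction = 0.4)
  ann <- simulate_annotation(cfg)
  cnt <- simulate_counts(ann, sample_design(cfg$n_pairs), cfg)
  expect_length(intersect(cnt$decoupled_circ, cnt$opposite_circ), 0)
  for (i in seq_len(nrow(cnt$classes))) {
    cid <- cnt$classes$circ_id[i]
    gid <- cnt$classes$gene_id[i]
    cl <- cnt$classes$class[i]
    clfc <- cnt$log2fc$circ[[cid]]
    glfc <- cnt$log2fc$gene[gid]
    if (cl == "decoupled") expect_false(gid %in% names(cnt$log2fc$gene))
    if (cl == "coupled") expect_equal(sign(unname(glfc)), sign(clfc))
    if (cl == "opposite") expect_equal(sign(unname(glfc)), -sign(clfc))
  }
})

test_that("methylation simulation plants DM sites and keeps beta in (0,1)", {
  design <- sample_design(4)
  cfg0 <- tiny_config(dm_fraction = 0)
  ann0 <- simulate_annotation(cfg0)
  meth0 <- simulate_methylation(ann0, design, cfg0)
  expect_equal(nrow(meth0$dm_probes), 0)
  b <- as.matrix(meth0$probes[, design$sample_id])
  expect_true(all(b > 0 & b < 1))

  # dm_effect <= 0 with dm_fraction > 0 is a configuration error
  expect_error(tiny_config(dm_fraction = 0.1, dm_effect = 0), "dm_effect")

  # planted delta-M recovered at large n
  cfg <- sim_config(n_pairs = 200, n_genes = 100, n_circ = 40, n_mirna = 5,
                    n_probes = 400, dm_fraction = 0.5, dm_effect = 1, seed = 3)
  ann <- simulate_annotation(cfg)
  d200 <- sample_design(200)
  meth <- simulate_methylation(ann, d200, cfg)
  m <- beta_to_m(as.matrix(meth$probes[, d200$sample_id]))
  rownames(m) <- meth$probes$probe_id
  dmhat <- delta_m(m, d200)
  pl <- meth$dm_probes
  expect_gt(nrow(pl), 20)
  se <- cfg$m_sd * sqrt(2 / 200)
  expect_true(all(abs(dmhat[pl$probe_id] - pl$delta_m) < 4 * se))
  # Monte-Carlo mean over probes well within 3 SE of the planted magnitude
  expect_lt(abs(mean(abs(dmhat[pl$probe_id])) - cfg$dm_effect), 3 * se)
})

test_that("guaranteed circRNAs each receive an in-region DM probe", {
  cfg <- tiny_config(seed = 8)
  ann <- simulate_annotation(cfg)
  design <- sample_design(cfg$n_pairs)
  guar <- ann$circs$circ_id[1:5]
  meth <- simulate_methylation(ann, design, cfg, guarantee_circ = guar)
  got <- meth$dm_probes[!is.na(meth$dm_probes$circ_id), ]
  expect_setequal(got$circ_id, guar)
  # planted probes really fall inside the claimed region
  regions <- circ_regions(ann$circs, chrom_sizes = ann$chrom_sizes)
  asg <- map_probes(meth$probes[, c("probe_id", "chrom", "pos")], regions)
  for (i in seq_len(nrow(got))) {
    hit <- asg[asg$probe_id == got$probe_id[i] & asg$feature_id == got$circ_id[i], ]
    expect_true(got$region[i] %in% hit$region)
  }
})

test_that("copula coupling hits the closed-form Spearman value and keeps margins", {
  n <- 500
  design <- sample_design(n / 2)
  mu <- matrix(200, 2, n, dimnames = list(c("c1", "c2"), design$sample_id))
  counts <- matrix(rnbinom(2 * n, mu = 200, size = 10), 2, n,
                   dimnames = dimnames(mu))
  m_mean <- matrix(0, 2, n, dimnames = list(c("p1", "p2"), design$sample_id))
  beta <- matrix(0.5, 2, n, dimnames = dimnames(m_mean))

  run <- function(rho, seed = 77) {
    pairs <- data.frame(circ_id = "c1", probe_id = "p1", rho = rho)
    out <- couple_circ_methylation(counts, beta, pairs, mu, 10, m_mean, 0.5, seed)
    cor(out$circ_counts["c1", ], beta_to_m(out$probe_beta["p1", ]),
        method = "spearman")
  }
  expect_lt(abs(run(0)), 0.15)                       # independence
  expect_gt(run(1), 0.99)                            # comonotone up to ties
  target <- (6 / pi) * asin(0.25)                    # rho = 0.5 closed form
  expect_lt(abs(run(0.5) - target), 3 * 1.06 / sqrt(n - 3))

  # margins preserved: coupled mean within 3 SE of the NB mean
  pairs <- data.frame(circ_id = "c1", probe_id = "p1", rho = 0.8)
  out <- couple_circ_methylation(counts, beta, pairs, mu, 10, m_mean, 0.5, 99)
  se_nb <- sqrt(200 + 0.1 * 200^2) / sqrt(n)
  expect_lt(abs(mean(out$circ_counts["c1", ]) - 200), 3 * se_nb)
  expect_lt(abs(mean(beta_to_m(out$probe_beta["p1", ]))), 3 * 0.5 / sqrt(n))
  # invalid correlation rejected
  expect_error(couple_circ_methylation(counts, beta,
    data.frame(circ_id = "c1", probe_id = "p1", rho = 1.5), mu, 10, m_mean, 0.5, 1),
    "rho")
})

test_that("bundles are deterministic and round-trip through disk", {
  cfg <- tiny_config(seed = 21)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1, b2)

  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  # byte-identical writes for identical configs
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  rt <- read_bundle(d1)
  expect_identical(rt$design, b1$design)
  expect_identical(rt$circs, b1$circs)
  expect_identical(rt$counts, b1$counts)
  expect_identical(rt$mirna_seqs, b1$mirna_seqs)
  expect_equal(rt$probes, b1$probes, tolerance = 1e-12)
  expect_equal(rt$chrom_sizes, b1$chrom_sizes)

  # manifest referential integrity against the written files
  man <- rt$manifest
  expect_true(all(names(man$de_features$gene) %in% rt$genes$gene_id))
  expect_true(all(names(man$de_features$circ) %in% rt$circs$circ_id))
  expect_true(all(man$dm_probes$probe_id %in% rt$probes$probe_id))
  expect_true(all(man$coupled_pairs$circ_id %in% rt$circs$circ_id))
  expect_true(all(man$coupled_pairs$probe_id %in% rt$probes$probe_id))
  expect_true(all(man$decoupled_circ %in% rt$circs$circ_id))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("an empty miRNA set still writes a valid FASTA", {
  cfg <- tiny_config(seed = 13)
  b <- simulate_bundle(cfg)
  b$mirna_seqs <- stats::setNames(character(0), character(0))
  d <- file.path(tempdir(), "bundle_empty_mirna")
  write_bundle(b, d)
  got <- Biostrings::readRNAStringSet(file.path(d, "mirna.fasta"))
  expect_length(got, 0)
  unlink(d, recursive = TRUE)
})
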
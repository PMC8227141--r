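test_that("catalog filtering applies the junction-support rule", {
  counts <- rbind(a = c(2, 2, 0, 0), b = c(5, 0, 0, 0), c = c(0, 0, 0, 0),
                  d = c(1, 1, 1, 1), e = c(3, 2, 2, 0))
  expect_setequal(filter_catalog(counts), c("a", "e"))
  expect_setequal(filter_catalog(counts, min_reads = 1), c("a", "d", "e"))
})

test_that("decoupling filter equals the brute-force intersection oracle", {
  set.seed(31)
  for (i in 1:200) {
    cs <- random_decoupling_case()
    got <- decoupled_circrnas(cs$circ_de, cs$gene_de, cs$assignments, cs$dm,
                              cs$circs)
    expect_identical(got$circ_id,
                     decoupled_oracle(cs$circ_de, cs$gene_de, cs$assignments,
                                      cs$dm, cs$circs))
    # every reported circRNA: non-ns circ call, ns gene, >=1 DM probe
    if (nrow(got)) {
      expect_true(all(got$n_dm_probes >= 1))
      gcall <- cs$gene_de$call[match(got$gene_id, cs$gene_de$feature_id)]
      expect_true(all(gcall == "ns"))
    }
  }
})

test_that("decoupling errors when a parental gene is missing", {
  cs <- random_decoupling_case()
  cs$circ_de$call <- "up"
  cs$circs$gene_id[!is.na(cs$circs$gene_id)][1] <- "missing_gene"
  expect_error(
    decoupled_circrnas(cs$circ_de, cs$gene_de, cs$assignments, cs$dm, cs$circs),
    "missing_gene")
})

test_that("spearman_test is exact for ties and small n", {
  expect_equal(spearman_test(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_test(1:4, c(8, 6, 4, 2))$rho, -1)

  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    x <- sample(1:4, n, replace = TRUE)  # ties likely
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_test(x, y)
    orc <- spearman_exact_oracle(x, y)
    expect_equal(got$rho, orc$rho, tolerance = 1e-12)
    expect_equal(got$p, orc$p, tolerance = 1e-12)
  }
  # t-approximation branch agrees with cor.test for larger n
  x <- rnorm(40); y <- rnorm(40)
  got <- spearman_test(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_warning(spearman_test(rep(1, 10), rnorm(10)), "constant")
})

test_that("correlation stage flags coupled pairs and respects the null", {
  set.seed(23)
  n <- 40
  # power: latent rho = 0.9 pairs across 40 samples
  hits <- replicate(100, {
    z1 <- rnorm(n); z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(n)
    spearman_test(qnbinom(pnorm(z1), mu = 20, size = 10), z2)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
  # null rate ~ 5%
  nulls <- replicate(500, spearman_test(rnorm(n), rnorm(n))$p < 0.05)
  expect_lt(abs(mean(nulls) - 0.05), 0.03)

  # wiring: multi-probe circRNAs are reported
  dec <- data.frame(circ_id = "c1", direction = "up", gene_id = "g1",
                    gene_padj = 0.5, n_dm_probes = 2,
                    dm_probes = "p1,p2", dm_regions = "Interior,Interior")
  expr <- matrix(rnorm(n), 1, n, dimnames = list("c1", paste0("s", 1:n)))
  mmat <- rbind(p1 = expr[1, ] + rnorm(n, sd = 0.1),
                p2 = -expr[1, ] + rnorm(n, sd = 0.1))
  colnames(mmat) <- paste0("s", 1:n)
  out <- correlate_methylation_expression(dec, expr, mmat)
  expect_true(all(out$significant))
  expect_equal(attr(out, "multi_probe_circ"), "c1")
  expect_error(correlate_methylation_expression(dec, expr,
                                                mmat[, 1:10, drop = FALSE]),
               "sample columns")
})

test_that("region DM summary counts sites and regions conservatively", {
  circ_de <- data.frame(feature_id = c("c1", "c2", "c3"),
                        call = c("up", "down", "ns"))
  dm <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                   call = c("hyper", "hypo", "hyper", "ns"))
  asg <- data.frame(probe_id = c("p1", "p2", "p3", "p3", "p4"),
                    feature_id = c("c1", "c1", "c2", "c3", "c1"),
                    region = c("Interior", "Pre2000", "Interior", "Interior",
                               "After2000"))
  s <- region_dm_summary(asg, dm, circ_de)
  expect_equal(s$site_counts["up", "Interior", "hyper"], 1)
  expect_equal(s$site_counts["up", "Pre2000", "hypo"], 1)
  expect_equal(s$site_counts["down", "Interior", "hyper"], 1)
  expect_equal(sum(s$site_counts), 3)  # ns probe and ns circ dropped
  expect_equal(unname(s$regions_per_circ[c("c1", "c2")]), c(2, 1))
  expect_equal(s$one_region_fraction, 0.5)

  # a circ with DM sites in all three regions
  asg3 <- data.frame(probe_id = c("p1", "p2", "p3"), feature_id = "c1",
                     region = c("Pre2000", "Interior", "After2000"))
  s3 <- region_dm_summary(asg3, dm, circ_de)
  expect_equal(unname(s3$regions_per_circ["c1"]), 3)

  # empty DM set: all-zero summary
  dm0 <- dm; dm0$call <- "ns"
  s0 <- region_dm_summary(asg, dm0, circ_de)
  expect_equal(sum(s0$site_counts), 0)
  expect_true(is.na(s0$one_region_fraction))

  # conservation: totals equal the DM-assignment count
  set.seed(2)
  for (i in 1:20) {
    cs <- random_decoupling_case()
    s <- region_dm_summary(cs$assignments, cs$dm, cs$circ_de)
    a <- unique(cs$assignments)
    a$dmc <- cs$dm$call[match(a$probe_id, cs$dm$probe_id)]
    a$dir <- cs$circ_de$call[match(a$feature_id, cs$circ_de$feature_id)]
    expect_equal(sum(s$site_counts),
                 sum(a$dmc != "ns" & a$dir != "ns"))
  }
})

test_that("opposite_pattern requires both layers called with opposite signs", {
  circs <- data.frame(circ_id = c("c1", "c2", "c3"), gene_id = c("g1", "g2", "g3"))
  circ_de <- data.frame(feature_id = c("c1", "c2", "c3"),
                        log2FC = c(2, 2, 2), call = c("up", "up", "up"))
  gene_de <- data.frame(feature_id = c("g1", "g2", "g3"),
                        log2FC = c(-2, 2, -2), call = c("down", "up", "ns"))
  got <- opposite_pattern(circ_de, gene_de, circs)
  expect_equal(got$circ_id, "c1")
})

test_that("chromosome density normalizes by gene count and ranks enrichment", {
  genes <- data.frame(gene_id = paste0("g", 1:130),
                      chrom = rep(c("chr1", "chr2"), c(100, 30)))
  circs <- data.frame(circ_id = paste0("c", 1:25),
                      chrom = rep(c("chr1", "chr2"), c(10, 15)))
  d <- chromosome_density(circs$circ_id, circs, genes)
  expect_equal(d$density[d$chrom == "chr1"], 0.1)
  expect_equal(d$density[d$chrom == "chr2"], 0.5)
  expect_equal(d$chrom[1], "chr2")  # planted enrichment ranks first
  # doubling genes halves the ratio
  genes2 <- rbind(genes, data.frame(gene_id = paste0("h", 1:100), chrom = "chr1"))
  d2 <- chromosome_density(circs$circ_id, circs, genes2)
  expect_equal(d2$density[d2$chrom == "chr1"], 0.05)
})

test_that("overlap_fisher matches hand enumeration and fisher.test", {
  # [[2,0],[0,2]] -> two-sided p = 1/3
  r <- overlap_fisher(c("a", "b"), c("a", "b"), 4)
  expect_equal(r$table, matrix(c(2, 0, 0, 2), 2, byrow = TRUE))
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  # [[1,1],[1,1]] -> p = 1
  r2 <- overlap_fisher(c("a", "b"), c("a", "c"), 4)
  expect_equal(r2$p, 1, tolerance = 1e-12)
  expect_error(overlap_fisher(letters[1:5], letters[3:8], 6), "universe")

  set.seed(41)
  for (i in 1:100) {
    a <- sample(0:40, 1); b <- sample(0:40, 1)
    cc <- sample(0:40, 1); d <- sample(0:40, 1)
    if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) next
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    expect_equal(circmeth:::fisher_p_2x2(a, b, cc, d),
                 fisher.test(tab)$p.value, tolerance = 1e-10)
  }
})

test_that("hypergeometric ORA behaves at the extremes", {
  universe <- paste0("g", 1:50)
  sets <- list(hit = paste0("g", 1:10), background = paste0("g", 11:40))
  # query identical to a set: minimal possible p
  r <- enrichment_ora(paste0("g", 1:10), sets, universe)
  expect_equal(r$p[r$set == "hit"],
               1 / choose(50, 10), tolerance = 1e-10)
  expect_true(r$significant[r$set == "hit"])
  # overlap at expectation (6 = 10 * 30/50): upper-tail p >= 0.5
  r2 <- enrichment_ora(paste0("g", c(1:4, 11:16)), sets, universe)
  expect_gte(r2$p[r2$set == "background"], 0.5)
  # identity with one-sided Fisher
  r3 <- enrichment_ora(paste0("g", c(1:4, 45:50)), sets, universe)
  ft <- fisher.test(matrix(c(4, 6, 6, 34), 2), alternative = "greater")
  expect_equal(r3$p[r3$set == "hit"], ft$p.value, tolerance = 1e-10)
  expect_error(enrichment_ora(character(0), sets, universe), "empty")
  expect_error(enrichment_ora("not_in_universe", sets, universe), "subset")
})
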
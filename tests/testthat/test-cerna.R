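test_that("seed sites are classified by the canonical hierarchy", {
  mir <- "UGAGGUAGUAGGUUGUAUAGUU"  # seed 2-8 = GAGGUAG
  # reverse complement of positions 2-8 is CUACCUC; A1 follows it
  t8 <- paste0("GGG", "CUACCUC", "A", "GGG")
  s8 <- seed_match(mir, t8)
  expect_equal(s8$type, "8mer")
  expect_equal(c(s8$start, s8$end), c(4, 11))
  # drop the A -> 7mer-m8
  t7 <- paste0("GGG", "CUACCUC", "G", "GGG")
  expect_equal(seed_match(mir, t7)$type, "7mer-m8")
  # 2-7 complement only (no m8 C), plus A -> 7mer-A1
  tA <- paste0("GGG", "UACCUC", "A", "GGG")
  expect_equal(seed_match(mir, tA)$type, "7mer-A1")
  # bare 6mer
  t6 <- paste0("GGG", "UACCUC", "G", "GGG")
  expect_equal(seed_match(mir, t6)$type, "6mer")
  # no complement anywhere -> empty
  expect_equal(nrow(seed_match(mir, "AAAAAAAAAAAAAAA")), 0)
  # DNA alphabet tolerated, junk rejected
  expect_equal(seed_match(mir, chartr("U", "T", t7))$type, "7mer-m8")
  expect_error(seed_match(mir, "ACGXACG"), "alphabet")
  expect_error(seed_match("ACGU", "ACGUACGU"), "at least 8")
})

test_that("seed_match equals the sliding-window oracle on random pairs", {
  set.seed(51)
  for (i in 1:500) {
    mir <- random_rna(sample(19:23, 1))
    target <- random_rna(sample(30:60, 1))
    expect_identical(seed_match(mir, target), seed_match_oracle(mir, target))
  }
})

test_that("duplex score follows the weighted scheme and thresholds", {
  set.seed(52)
  mir <- random_rna(22)
  perfect <- chartr("ACGU", "UGCA", paste(rev(strsplit(mir, "")[[1]]),
                                          collapse = ""))
  d <- duplex_score(mir, perfect)
  # 7 seed positions x 5 x 4 + 15 others x 5 = 215
  expect_equal(d$score, 215)
  expect_lt(d$energy, -20)
  expect_true(d$retained)

  # seed-only match: score and stacks too small -> rejected. The miRNA is
  # built over {A, C} so that the all-C flanks cannot pair or wobble, making
  # the seed the only paired stretch by construction.
  mir_ac <- paste(sample(c("A", "C"), 22, replace = TRUE), collapse = "")
  mv <- strsplit(mir_ac, "")[[1]]
  seed_site <- paste0(chartr("ACGU", "UGCA", mv[8]),
                      paste(rev(chartr("ACGU", "UGCA", mv[2:7])), collapse = ""))
  window <- paste0(strrep("C", 12), seed_site, strrep("C", 3))
  ds <- duplex_score(mir_ac, window)
  expect_false(ds$retained)
  expect_gte(ds$energy, -20)
  expect_lte(ds$score, 140)
  expect_error(duplex_score(mir, "ACGU"), "shorter")
})

test_that("extending complementarity never decreases the duplex score", {
  set.seed(53)
  for (i in 1:20) {
    mir <- random_rna(22)
    mv <- strsplit(mir, "")[[1]]
    comp <- rev(chartr("ACGU", "UGCA", mv))  # target-side bases, 5'->3'
    scores <- vapply(seq(8, 22, by = 2), function(k) {
      # complement the 3'-most k miRNA positions... build window matching
      # miRNA positions 1..k, pad the rest with A/G noise kept constant
      site <- c(rep("A", 22 - k), comp[(22 - k + 1):22])
      duplex_score(mir, paste(site, collapse = ""))$score
    }, numeric(1))
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("predicted interactions honor the both/either evidence routes", {
  set.seed(54)
  mir <- stats::setNames(random_rna(22), "miR-x")
  perfect_site <- chartr("ACGU", "UGCA",
                         paste(rev(strsplit(mir[[1]], "")[[1]]), collapse = ""))
  circs <- c(full = paste0(random_rna(30), perfect_site, random_rna(30)),
             none = random_rna(80))
  pred <- predict_circ_mirna(mir, circs)
  expect_equal(pred$circ_id, "full")
  expect_true(pred$seed_pass && pred$duplex_pass)
  # a seed-only target passes "either" but not "both" (A/C-only miRNA so the
  # C flanks cannot contribute extra pairs)
  mir_ac <- stats::setNames(paste(sample(c("A", "C"), 22, TRUE), collapse = ""),
                            "miR-ac")
  mv <- strsplit(mir_ac[[1]], "")[[1]]
  seed_site <- paste0(chartr("ACGU", "UGCA", mv[8]),
                      paste(rev(chartr("ACGU", "UGCA", mv[2:7])), collapse = ""))
  circs2 <- c(seedonly = paste0(strrep("C", 24), seed_site, strrep("C", 4)))
  expect_equal(nrow(predict_circ_mirna(mir_ac, circs2, require = "both")), 0)
  p2 <- predict_circ_mirna(mir_ac, circs2, require = "either")
  expect_equal(nrow(p2), 1)
  expect_false(p2$duplex_pass)
})

test_that("ceRNA networks satisfy the tripartite direction constraints", {
  circ_dir <- c(c1 = "up", c2 = "down")
  mirna_de <- data.frame(feature_id = c("m1", "m2", "m3"),
                         call = c("down", "up", "ns"))
  gene_de <- data.frame(feature_id = c("g1", "g2", "g3"),
                        call = c("up", "down", "ns"))
  predicted <- data.frame(circ_id = c("c1", "c1", "c2", "c2"),
                          mirna_id = c("m1", "m2", "m2", "m3"))
  validated <- data.frame(mirna_id = c("m1", "m1", "m2", "m2"),
                          gene_id = c("g1", "g2", "g1", "g2"))
  net <- build_cerna(circ_dir, mirna_de, gene_de, predicted, validated)
  e <- net$edges
  # up circ pairs only with down miRNA; miRNA-mRNA opposite too
  expect_true(all(c("c1|m1", "c2|m2") %in% paste(e$from, e$to, sep = "|")))
  expect_false("c1|m2" %in% paste(e$from, e$to, sep = "|"))  # same direction
  expect_false("c2|m3" %in% paste(e$from, e$to, sep = "|"))  # ns miRNA
  expect_true(all(c("m1|g1", "m2|g2") %in% paste(e$from, e$to, sep = "|")))
  expect_false("m1|g2" %in% paste(e$from, e$to, sep = "|"))
  dirmap <- stats::setNames(net$nodes$direction, net$nodes$id)
  expect_true(all(dirmap[e$from] != dirmap[e$to]))
  # isolated nodes dropped
  expect_false("m3" %in% net$nodes$id)
  expect_error(build_cerna(c(c1 = NA), mirna_de, gene_de, predicted, validated),
               "up")

  # fuzzed networks always satisfy the invariant
  set.seed(55)
  for (i in 1:50) {
    nc <- sample(2:6, 1); nm <- sample(2:6, 1); ng <- sample(2:8, 1)
    cd <- stats::setNames(sample(c("up", "down"), nc, TRUE), paste0("c", 1:nc))
    md <- data.frame(feature_id = paste0("m", 1:nm),
                     call = sample(c("up", "down", "ns"), nm, TRUE))
    gd <- data.frame(feature_id = paste0("g", 1:ng),
                     call = sample(c("up", "down", "ns"), ng, TRUE))
    pr <- unique(data.frame(circ_id = sample(names(cd), 8, TRUE),
                            mirna_id = sample(md$feature_id, 8, TRUE)))
    va <- unique(data.frame(mirna_id = sample(md$feature_id, 10, TRUE),
                            gene_id = sample(gd$feature_id, 10, TRUE)))
    net <- build_cerna(cd, md, gd, pr, va)
    if (!nrow(net$edges)) next
    dm <- stats::setNames(net$nodes$direction, net$nodes$id)
    tm <- stats::setNames(net$nodes$type, net$nodes$id)
    expect_true(all(dm[net$edges$from] != dm[net$edges$to]))
    expect_true(all(tm[net$edges$from][net$edges$layer == "circ-mirna"] == "circ"))
    expect_true(all(tm[net$edges$to][net$edges$layer == "circ-mirna"] == "mirna"))
    expect_true(all(tm[net$edges$from][net$edges$layer == "mirna-mrna"] == "mirna"))
    expect_true(all(tm[net$edges$to][net$edges$layer == "mirna-mrna"] == "mrna"))
    deg <- table(factor(c(net$edges$from, net$edges$to), levels = net$nodes$id))
    expect_true(all(deg > 0))
  }
})

test_that("network stats report degrees, hubs and the handshake identity", {
  circ_dir <- c(hub = "up")
  mirna_de <- data.frame(feature_id = paste0("m", 1:10), call = "down")
  gene_de <- data.frame(feature_id = "g1", call = "up")
  predicted <- data.frame(circ_id = "hub", mirna_id = paste0("m", 1:10))
  validated <- data.frame(mirna_id = "m1", gene_id = "g1")
  net <- build_cerna(circ_dir, mirna_de, gene_de, predicted, validated)
  st <- network_stats(net)
  expect_equal(st$hubs, "hub")
  expect_equal(st$degrees$degree[st$degrees$id == "hub"], 10)
  expect_equal(sum(st$degrees$degree), 2 * nrow(net$edges))

  empty <- build_cerna(c(c1 = "up"),
                       data.frame(feature_id = "m1", call = "up"),
                       gene_de, data.frame(circ_id = "c1", mirna_id = "m1"),
                       validated)
  st0 <- network_stats(empty)
  expect_equal(nrow(st0$degrees), 0)
  expect_length(st0$hubs, 0)

  # GraphML export round-trips through igraph
  f <- tempfile(fileext = ".graphml")
  write_cerna_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
  unlink(f)
})
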
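# Brute-force oracles used by the unit and acceptance tests. Each is written
# as a direct, unoptimized transcription of the defining computation and is
# kept independent of the package code paths it checks.

# BH step-up straight from the sorted-definition: adj_(i) = min_{k>=i} n p_(k)/k.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(k) n * p[o[k]] / k, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# Per-base containment scan for probe-to-region mapping.
map_probes_oracle <- function(probes, regions) {
  rows <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(regions))) {
      if (probes$chrom[i] == regions$chrom[j] &&
          probes$pos[i] >= regions$start[j] && probes$pos[i] <= regions$end[j]) {
        rows[[length(rows) + 1]] <- data.frame(
          probe_id = probes$probe_id[i], feature_id = regions$feature_id[j],
          region = regions$region[j], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(probe_id = character(0), feature_id = character(0),
                      region = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$probe_id, out$feature_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Three-way set-intersection oracle for the decoupling filter.
decoupled_oracle <- function(circ_de, gene_de, assignments, dm, circs) {
  out <- character(0)
  dm_sig <- dm$probe_id[dm$call != "ns"]
  for (i in seq_len(nrow(circ_de))) {
    cid <- circ_de$feature_id[i]
    if (circ_de$call[i] == "ns") next
    gid <- circs$gene_id[circs$circ_id == cid]
    if (length(gid) != 1 || is.na(gid)) next
    gcall <- gene_de$call[gene_de$feature_id == gid]
    if (length(gcall) != 1 || gcall != "ns") next
    probes_here <- assignments$probe_id[assignments$feature_id == cid]
    if (any(probes_here %in% dm_sig)) out <- c(out, cid)
  }
  sort(out)
}

# Mann-Whitney pair-enumeration AUC.
auc_oracle <- function(scores, labels) {
  labels <- as.integer(labels == max(labels))
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Exact permutation distribution of the tie-aware Spearman rho (independent
# enumeration via recursive permutation generation on the raw vectors).
perms_oracle <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms_oracle(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}

spearman_exact_oracle <- function(x, y) {
  rho <- cor(x, y, method = "spearman")
  rhos <- vapply(perms_oracle(length(y)),
                 function(idx) cor(x, y[idx], method = "spearman"), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Sliding-window complementarity oracle for seed matching.
seed_match_oracle <- function(mirna, target) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  mirna <- chartr("T", "U", toupper(mirna))
  target <- chartr("T", "U", toupper(target))
  mv <- strsplit(mirna, "")[[1]]
  tv <- strsplit(target, "")[[1]]
  tl <- length(tv)
  rows <- list()
  for (i in seq_len(max(0, tl - 5))) {
    # target positions i..i+5 must pair miRNA positions 7..2 (antiparallel)
    ok6 <- all(tv[i:(i + 5)] == comp[mv[7:2]])
    if (!ok6) next
    has_m8 <- i > 1 && tv[i - 1] == comp[mv[8]]
    has_a1 <- (i + 6) <= tl && tv[i + 6] == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    rows[[length(rows) + 1]] <- data.frame(
      start = if (has_m8) i - 1L else as.integer(i),
      end = if (has_a1) i + 6L else i + 5L,
      type = type, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0), type = character(0)))
  }
  do.call(rbind, rows)
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# Random inputs for fuzzing the decoupling filter.
random_decoupling_case <- function() {
  n_circ <- sample(5:15, 1)
  n_gene <- sample(3:8, 1)
  n_probe <- sample(5:20, 1)
  gene_ids <- paste0("g", seq_len(n_gene))
  circs <- data.frame(
    circ_id = paste0("c", seq_len(n_circ)),
    origin = sample(c("exonic", "intronic", "intergenic"), n_circ, TRUE),
    stringsAsFactors = FALSE)
  circs$gene_id <- ifelse(circs$origin == "intergenic", NA_character_,
                          sample(gene_ids, n_circ, TRUE))
  circ_de <- data.frame(feature_id = circs$circ_id,
                        log2FC = rnorm(n_circ),
                        p_adj = runif(n_circ),
                        call = sample(c("up", "down", "ns"), n_circ, TRUE),
                        stringsAsFactors = FALSE)
  gene_de <- data.frame(feature_id = gene_ids, log2FC = rnorm(n_gene),
                        p_adj = runif(n_gene),
                        call = sample(c("up", "down", "ns"), n_gene, TRUE),
                        stringsAsFactors = FALSE)
  probe_ids <- paste0("p", seq_len(n_probe))
  dm <- data.frame(probe_id = probe_ids, delta_m = rnorm(n_probe),
                   p_adj = runif(n_probe),
                   call = sample(c("hyper", "hypo", "ns"), n_probe, TRUE),
                   stringsAsFactors = FALSE)
  n_asg <- sample(0:30, 1)
  assignments <- data.frame(
    probe_id = sample(probe_ids, n_asg, TRUE),
    feature_id = sample(circs$circ_id, n_asg, TRUE),
    region = sample(c("Pre2000", "Interior", "After2000"), n_asg, TRUE),
    stringsAsFactors = FALSE)
  list(circ_de = circ_de, gene_de = gene_de, assignments = assignments,
       dm = dm, circs = circs)
}

# Small default simulation config used across tests (kept light for runtime).
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_pairs = 4, n_genes = 80, n_circ = 30, n_mirna = 20,
         n_probes = 200, seed = seed),
    list(...))
  do.call(sim_config, args)
}
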
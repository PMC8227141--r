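.rna_comp <- c(A = "U", C = "G", G = "C", U = "A")

# Normalize a nucleotide string to uppercase RNA (T -> U); error on anything
# outside {A, C, G, U/T}.
norm_rna <- function(s, what = "sequence") {
  s <- chartr("Tt", "Uu", toupper(s))
  if (grepl("[^ACGU]", s)) stop("invalid ", what, " alphabet (A/C/G/U/T only)")
  s
}

#' Find miRNA seed-match sites in a target sequence
#'
#' Scans the target (5'->3') for Watson-Crick complements of the miRNA seed
#' and classifies each site following the canonical site-type hierarchy:
#' \itemize{
#'   \item 8mer: positions 2-8 paired plus an A in the target opposite
#'     miRNA position 1;
#'   \item 7mer-m8: positions 2-8 paired;
#'   \item 7mer-A1: positions 2-7 paired plus the A;
#'   \item 6mer: positions 2-7 paired.
#' }
#' Because the duplex is antiparallel, the match of miRNA positions 2-7 spans
#' target positions `i..i+5` with position `i+5` opposite miRNA position 2,
#' the m8 match sits at `i-1` and the t1 A at `i+6`.
#'
#' @param mirna miRNA sequence (5'->3', length >= 8).
#' @param target Target sequence; T and U are equivalent.
#' @return data.frame: start (1-based position of the leftmost matched
#'   target base, including the m8 base for 8mer/7mer-m8), end (rightmost,
#'   including the t1 A where applicable), type. Empty if no seed complement
#'   occurs.
#' @examples
#' seed_match("UGAGGUAGUAGGUUGUAUAGUU", "AAAACUACCUCAAAA")  # 7mer-m8 + A1 = 8mer
#' @export
seed_match <- function(mirna, target) {
  mirna <- norm_rna(mirna, "miRNA")
  target <- norm_rna(target, "target")
  if (nchar(mirna) < 8) stop("miRNA must be at least 8 nt")
  mv <- strsplit(mirna, "")[[1]]
  core <- paste(rev(.rna_comp[mv[2:7]]), collapse = "")  # target-side 6mer
  m8c <- .rna_comp[[mv[8]]]
  tl <- nchar(target)
  hits <- gregexpr(core, target, fixed = TRUE)[[1]]
  if (hits[1] == -1) {
    return(data.frame(start = integer(0), end = integer(0), type = character(0)))
  }
  ## gregexpr misses overlapping occurrences; rescan manually
  starts <- which(vapply(seq_len(tl - 5), function(i)
    substr(target, i, i + 5) == core, logical(1)))
  rows <- lapply(starts, function(i) {
    has_m8 <- i > 1 && substr(target, i - 1, i - 1) == m8c
    has_a1 <- i + 6 <= tl && substr(target, i + 6, i + 6) == "A"
    type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
            else if (has_a1) "7mer-A1" else "6mer"
    data.frame(start = if (has_m8) i - 1L else as.integer(i),
               end = if (has_a1) i + 6L else i + 5L,
               type = type, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simplified miRNA:target duplex score and free-energy proxy
#'
#' Aligns the miRNA (5'->3') against the reversed target window with a
#' Gotoh affine-gap dynamic program over complementarity scores: +5 for a
#' Watson-Crick pair, +2 for a G:U wobble, -3 for a mismatch, gap open -9 and
#' gap extension -4; pair scores at miRNA seed positions 2-8 are weighted
#' x4. The energy proxy sums nearest-neighbor-style stack terms over
#' consecutive paired positions (per pair: G:C 1.6, A:U 0.9, G:U 0.4
#' kcal/mol-like units, two pairs per stack) minus a +4.1 initiation
#' penalty. A candidate interaction is retained iff `score > 140` and
#' `energy < -20`, so seed-only matches (too few stacks to reach -20) are
#' rejected and extended complementarity is required.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param window Target window containing the candidate site; must be at
#'   least as long as the miRNA.
#' @return list(score, energy, retained).
#' @export
duplex_score <- function(mirna, window) {
  mirna <- norm_rna(mirna, "miRNA")
  window <- norm_rna(window, "window")
  n <- nchar(mirna); m <- nchar(window)
  if (m < n) stop("window shorter than the miRNA")
  a <- strsplit(mirna, "")[[1]]
  b <- rev(strsplit(window, "")[[1]])  # antiparallel pairing

  pair_score <- function(x, y) {
    if (.rna_comp[[x]] == y) 5
    else if ((x == "G" && y == "U") || (x == "U" && y == "G")) 2
    else -3
  }
  wgt <- ifelse(seq_len(n) >= 2 & seq_len(n) <= 8, 4, 1)
  S <- outer(seq_len(n), seq_len(m),
             Vectorize(function(i, j) wgt[i] * pair_score(a[i], b[j])))

  gap_open <- -9; gap_ext <- -4
  NEG <- -1e9
  ## semi-global: free gaps in the window, miRNA aligned end to end
  M <- matrix(NEG, n + 1, m + 1)   # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in window (consumes miRNA)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in miRNA (consumes window)
  M[1, ] <- 0; Y[1, ] <- 0
  X[2:(n + 1), 1] <- gap_open + gap_ext * (seq_len(n) - 1)
  ptr <- array(0L, dim = c(n + 1, m + 1, 3))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- cand[k] + S[i - 1, j - 1]
      ptr[i, j, 1] <- k
      cand <- c(M[i - 1, j] + gap_open, X[i - 1, j] + gap_ext, Y[i - 1, j] + gap_open)
      k <- which.max(cand)
      X[i, j] <- cand[k]
      ptr[i, j, 2] <- k
      cand <- c(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open, Y[i, j - 1] + gap_ext)
      k <- which.max(cand)
      Y[i, j] <- cand[k]
      ptr[i, j, 3] <- k
    }
  }
  ends <- pmax(M[n + 1, ], Y[n + 1, ])
  j <- which.max(ends)
  score <- ends[j]

  ## traceback to collect paired miRNA positions and their pair strengths
  ## (G:C 1.6, A:U 0.9, G:U wobble 0.4) for the energy proxy
  state <- if (M[n + 1, j] >= Y[n + 1, j]) 1L else 3L
  i <- n + 1
  paired <- logical(n)
  per_pair <- numeric(n)
  while (i > 1 && j > 1) {
    if (state == 1L) {
      ii <- i - 1
      x <- a[ii]; y <- b[j - 1]
      ps <- pair_score(x, y)
      if (ps > 0) {
        paired[ii] <- TRUE
        per_pair[ii] <- if (ps == 2) 0.4
                        else if ((x == "G" && y == "C") || (x == "C" && y == "G")) 1.6
                        else 0.9
      }
      state <- ptr[i, j, 1]; i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      state <- ptr[i, j, 2]; i <- i - 1
    } else {
      state <- ptr[i, j, 3]; j <- j - 1
    }
  }
  ## each stack of adjacent paired positions contributes both pair terms
  stacks <- 0
  for (ii in seq_len(n - 1)) {
    if (paired[ii] && paired[ii + 1]) {
      stacks <- stacks + (per_pair[ii] + per_pair[ii + 1])
    }
  }
  energy <- 4.1 - stacks
  list(score = score, energy = energy, retained = score > 140 && energy < -20)
}

#' Predict circRNA-miRNA interactions
#'
#' Combines a seed-match requirement (site type at least 7mer by default,
#' the TargetScan-style route) with the duplex score/energy thresholds
#' (score > 140 and energy < -20, the miRanda-style route). `require =
#' "both"` keeps the intersection of the two routes (default); "either"
#' keeps the union.
#'
#' @param mirna_seqs Named character vector of miRNA sequences.
#' @param circ_seqs Named character vector of circRNA sequences.
#' @param score_min,energy_max Duplex thresholds.
#' @param min_type Minimum seed site class: "7mer" (default) or "6mer".
#' @param require "both" or "either".
#' @return data.frame: circ_id, mirna_id, best_type, score, energy,
#'   seed_pass, duplex_pass.
#' @export
predict_circ_mirna <- function(mirna_seqs, circ_seqs, score_min = 140,
                               energy_max = -20, min_type = c("7mer", "6mer"),
                               require = c("both", "either")) {
  min_type <- match.arg(min_type)
  require <- match.arg(require)
  type_rank <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)
  min_rank <- if (min_type == "7mer") 2 else 1
  rows <- list()
  for (cid in names(circ_seqs)) {
    target <- circ_seqs[[cid]]
    tl <- nchar(target)
    for (mid in names(mirna_seqs)) {
      mir <- mirna_seqs[[mid]]
      sites <- seed_match(mir, target)
      if (!nrow(sites)) next
      best <- sites$type[which.max(type_rank[sites$type])]
      seed_pass <- max(type_rank[sites$type]) >= min_rank
      ## duplex-score the window around the best-scoring candidate sites
      n <- nchar(mir)
      sc <- -Inf; en <- Inf
      for (k in seq_len(nrow(sites))) {
        lo <- max(1, sites$end[k] - (n + 6))
        hi <- min(tl, sites$end[k] + 1)
        if (hi - lo + 1 < n) lo <- max(1, hi - n + 1)
        if (hi - lo + 1 < n) next
        ds <- duplex_score(mir, substr(target, lo, hi))
        if (ds$score > sc) { sc <- ds$score; en <- ds$energy }
      }
      duplex_pass <- is.finite(sc) && sc > score_min && en < energy_max
      keep <- if (require == "both") seed_pass && duplex_pass
              else seed_pass || duplex_pass
      if (keep) {
        rows[[length(rows) + 1]] <- data.frame(
          circ_id = cid, mirna_id = mid, best_type = best,
          score = sc, energy = en, seed_pass = seed_pass,
          duplex_pass = duplex_pass, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(circ_id = character(0), mirna_id = character(0),
                      best_type = character(0), score = numeric(0),
                      energy = numeric(0), seed_pass = logical(0),
                      duplex_pass = logical(0)))
  }
  do.call(rbind, rows)
}

#' Assemble the direction-constrained ceRNA network
#'
#' Two tripartite sub-networks are built: (up circRNA, down miRNA, up mRNA)
#' and (down circRNA, up miRNA, down mRNA). A circRNA-miRNA edge requires a
#' predicted interaction and opposite directions; a miRNA-mRNA edge requires
#' the pair to appear in the validated-interaction table, opposite
#' directions, and the miRNA to be anchored to at least one circRNA.
#' Isolated nodes are dropped.
#'
#' @param circ_dir Named character vector circ_id -> "up"/"down" (typically
#'   the decoupled circRNAs' directions).
#' @param mirna_de,gene_de DE tables (feature_id, call).
#' @param predicted Predicted circRNA-miRNA pairs ([predict_circ_mirna()]).
#' @param validated Validated miRNA-target table (mirna_id, gene_id).
#' @return Object of class `cerna_network`: list(nodes, edges) with
#'   nodes(id, type, direction) and edges(from, to, layer, evidence).
#' @export
build_cerna <- function(circ_dir, mirna_de, gene_de, predicted, validated) {
  if (any(is.na(circ_dir)) || !all(circ_dir %in% c("up", "down"))) {
    stop("circ_dir must map every circRNA to 'up' or 'down'")
  }
  mir_dir <- stats::setNames(mirna_de$call, mirna_de$feature_id)
  gene_dir <- stats::setNames(gene_de$call, gene_de$feature_id)

  cm <- predicted[predicted$circ_id %in% names(circ_dir), , drop = FALSE]
  cm$cdir <- circ_dir[cm$circ_id]
  cm$mdir <- mir_dir[cm$mirna_id]
  cm <- cm[!is.na(cm$mdir) & cm$mdir %in% c("up", "down") &
             cm$cdir != cm$mdir, , drop = FALSE]

  mg <- validated[validated$mirna_id %in% cm$mirna_id, , drop = FALSE]
  mg$mdir <- mir_dir[mg$mirna_id]
  mg$gdir <- gene_dir[mg$gene_id]
  mg <- mg[!is.na(mg$gdir) & mg$gdir %in% c("up", "down") &
             mg$mdir != mg$gdir, , drop = FALSE]

  edges <- rbind(
    if (nrow(cm)) data.frame(from = cm$circ_id, to = cm$mirna_id,
                             layer = "circ-mirna", evidence = "predicted",
                             stringsAsFactors = FALSE),
    if (nrow(mg)) data.frame(from = mg$mirna_id, to = mg$gene_id,
                             layer = "mirna-mrna", evidence = "validated",
                             stringsAsFactors = FALSE)
  ) %||% data.frame(from = character(0), to = character(0),
                    layer = character(0), evidence = character(0))

  used <- unique(c(edges$from, edges$to))
  node_df <- function(ids, type) {
    data.frame(id = ids, type = rep_len(type, length(ids)),
               stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_df(intersect(names(circ_dir), used), "circ"),
    node_df(intersect(unique(cm$mirna_id), used), "mirna"),
    node_df(intersect(unique(mg$gene_id), used), "mrna")
  )
  dir_all <- c(circ_dir, mir_dir, gene_dir)
  nodes$direction <- unname(dir_all[nodes$id])
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat("ceRNA network:", sum(tt), "nodes (",
      paste(names(tt), tt, collapse = ", "), ");",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Degree table and hub circRNAs of a ceRNA network
#'
#' @param network A `cerna_network`.
#' @return list(degrees = data.frame(id, type, direction, degree),
#'   hubs = circ ids of maximal degree). Empty networks yield empty stats.
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  nodes <- network$nodes
  if (!nrow(nodes)) {
    return(list(degrees = data.frame(id = character(0), type = character(0),
                                     direction = character(0), degree = integer(0)),
                hubs = character(0)))
  }
  deg <- table(factor(c(network$edges$from, network$edges$to), levels = nodes$id))
  nodes$degree <- as.integer(deg[nodes$id])
  circ <- nodes[nodes$type == "circ", , drop = FALSE]
  hubs <- if (nrow(circ)) circ$id[circ$degree == max(circ$degree)] else character(0)
  list(degrees = nodes, hubs = hubs)
}

#' Export a ceRNA network to GraphML
#'
#' @param network A `cerna_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cerna_graphml <- function(network, path) {
  stopifnot(inherits(network, "cerna_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = network$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
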
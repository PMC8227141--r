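#' Simulate a complete paired tumor/normal multi-omics bundle
#'
#' Orchestrates [simulate_annotation()], [simulate_counts()],
#' [simulate_methylation()] and [couple_circ_methylation()] and additionally
#' generates miRNA sequences, synthetic circRNA sequences with planted miRNA
#' binding sites, and a validated miRNA-target interaction table. Every
#' planted effect is recorded in a ground-truth manifest.
#'
#' Each planted "decoupled" circRNA is guaranteed one planted DM probe in one
#' of its regions, and that (circRNA, probe) pair is copula-coupled at
#' `config$coupling_rho` so the downstream Spearman stage has signal to find.
#' Each DE circRNA with available opposite-direction DE miRNAs gets 1-3
#' full-complement miRNA sites embedded in its synthetic sequence.
#'
#' @param config A [sim_config()] object.
#' @return List of class `multiomics_bundle`: design, genes, circs,
#'   chrom_sizes, counts (gene/circ/mirna matrices), probes, mirna_seqs,
#'   circ_seqs (named character vectors), mirna_targets (data.frame
#'   mirna_id/gene_id), and `manifest` — a list with de_features, dm_probes,
#'   coupled_pairs, decoupled_circ, opposite_circ, classes, size_factors and
#'   planted_sites.
#' @examples
#' b <- simulate_bundle(sim_config(n_pairs = 3, n_genes = 60, n_circ = 20,
#'                                 n_mirna = 15, n_probes = 150, seed = 2))
#' dim(b$counts$circ)
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- sample_design(config$n_pairs)
  ann <- simulate_annotation(config)
  cnt <- simulate_counts(ann, design, config)
  meth <- simulate_methylation(ann, design, config,
                               guarantee_circ = cnt$decoupled_circ)

  ## copula-couple each decoupled circRNA with its guaranteed DM probe
  guar <- meth$dm_probes[!is.na(meth$dm_probes$circ_id), , drop = FALSE]
  pairs <- data.frame(circ_id = guar$circ_id, probe_id = guar$probe_id,
                      rho = rep(config$coupling_rho, nrow(guar)),
                      stringsAsFactors = FALSE)
  beta <- as.matrix(meth$probes[, design$sample_id, drop = FALSE])
  rownames(beta) <- meth$probes$probe_id
  if (nrow(pairs) && config$nb_dispersion > 0) {
    coupled <- couple_circ_methylation(
      cnt$counts$circ, beta, pairs,
      circ_mu = cnt$circ_mu, circ_size = 1 / config$nb_dispersion,
      probe_m_mean = meth$m_mean, m_sd = meth$m_sd,
      seed = derive_seed(config$seed, "coupling")
    )
    storage.mode(coupled$circ_counts) <- "integer"
    cnt$counts$circ <- coupled$circ_counts
    beta <- coupled$probe_beta
  }
  probes <- meth$probes
  probes[, design$sample_id] <- beta[probes$probe_id, , drop = FALSE]

  ## sequences: random miRNAs, random circ sequences with planted sites
  sq <- with_seed(derive_seed(config$seed, "seqs"), {
    rand_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                  collapse = "")
    mirna_ids <- rownames(cnt$counts$mirna)
    mirna_seqs <- stats::setNames(vapply(rep(22, length(mirna_ids)), rand_seq,
                                         character(1)), mirna_ids)
    circ_ids <- ann$circs$circ_id
    lens <- pmin(ann$circs$end - ann$circs$start + 1, 400)
    circ_seqs <- stats::setNames(vapply(pmax(lens, 60), rand_seq, character(1)),
                                 circ_ids)
    mir_dir <- ifelse(cnt$log2fc$mirna > 0, "up", "down")
    circ_de <- names(cnt$log2fc$circ)
    circ_dir <- ifelse(cnt$log2fc$circ > 0, "up", "down")
    sites <- NULL
    for (cid in circ_de) {
      opp <- names(mir_dir)[mir_dir != circ_dir[[cid]]]
      if (!length(opp)) next
      chosen <- sample(opp, min(length(opp), sample(1:3, 1)))
      seq <- circ_seqs[[cid]]
      for (mid in chosen) {
        site <- revcomp_rna(mirna_seqs[[mid]])
        pos <- sample(nchar(seq) - nchar(site) + 1, 1)
        substr(seq, pos, pos + nchar(site) - 1) <- site
        sites <- rbind(sites, data.frame(circ_id = cid, mirna_id = mid, pos = pos,
                                         stringsAsFactors = FALSE))
      }
      circ_seqs[[cid]] <- seq
    }
    list(mirna_seqs = mirna_seqs, circ_seqs = circ_seqs,
         planted_sites = sites %||% data.frame(circ_id = character(0),
                                               mirna_id = character(0),
                                               pos = integer(0)))
  })

  ## validated miRNA-target table, biased toward DE genes so that the ceRNA
  ## stage has admissible miRNA-mRNA edges
  targets <- with_seed(derive_seed(config$seed, "targets"), {
    de_genes <- names(cnt$log2fc$gene)
    rows <- lapply(names(sq$mirna_seqs), function(mid) {
      k <- sample(5:30, 1)
      n_de <- min(length(de_genes), round(0.3 * k))
      gs <- unique(c(if (n_de) sample(de_genes, n_de) else character(0),
                     sample(ann$genes$gene_id, k - n_de)))
      data.frame(mirna_id = mid, gene_id = gs, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  manifest <- list(
    de_features = cnt$log2fc,
    dm_probes = meth$dm_probes,
    coupled_pairs = pairs,
    decoupled_circ = cnt$decoupled_circ,
    opposite_circ = cnt$opposite_circ,
    classes = cnt$classes,
    size_factors = cnt$size_factors,
    planted_sites = sq$planted_sites
  )
  structure(list(design = design, genes = ann$genes, circs = ann$circs,
                 chrom_sizes = ann$chrom_sizes, counts = cnt$counts,
                 probes = probes, mirna_seqs = sq$mirna_seqs,
                 circ_seqs = sq$circ_seqs, mirna_targets = targets,
                 manifest = manifest),
            class = "multiomics_bundle")
}

revcomp_rna <- function(s) {
  chartr("ACGU", "UGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Write a multi-omics bundle to a directory of plain-text files
#'
#' Formats: BED6 for the circRNA catalog (0-based half-open; the name column
#' keeps the 1-based "chr:start-end" id), TSV for the gene table, count
#' matrices, probe table, design, chromosome sizes and validated
#' interactions, FASTA for miRNA and circRNA sequences, and a `manifest/`
#' subdirectory of TSVs for the ground truth. [read_bundle()] reverses the
#' conversion.
#'
#' @param bundle A `multiomics_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "multiomics_bundle"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir)
  }
  p <- function(...) file.path(dir, ...)
  write_tsv(bundle$design, p("design.tsv"))
  write_tsv(bundle$genes, p("genes.tsv"))
  bed <- data.frame(chrom = bundle$circs$chrom, start = bundle$circs$start - 1L,
                    end = bundle$circs$end, name = bundle$circs$circ_id,
                    score = 0L, strand = bundle$circs$strand,
                    origin = bundle$circs$origin,
                    gene_id = ifelse(is.na(bundle$circs$gene_id), ".",
                                     bundle$circs$gene_id))
  data.table::fwrite(bed, p("circs.bed"), sep = "\t", quote = FALSE, col.names = FALSE)
  write_tsv(data.frame(chrom = names(bundle$chrom_sizes),
                       size = as.integer(bundle$chrom_sizes)), p("chrom_sizes.tsv"))
  for (layer in names(bundle$counts)) {
    m <- bundle$counts[[layer]]
    write_tsv(data.frame(feature_id = rownames(m), m, check.names = FALSE),
              p(sprintf("counts_%s.tsv", layer)))
  }
  write_tsv(bundle$probes, p("probes.tsv"))
  write_tsv(bundle$mirna_targets, p("mirna_targets.tsv"))
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(bundle$mirna_seqs),
                              p("mirna.fasta"))
  Biostrings::writeXStringSet(Biostrings::RNAStringSet(bundle$circ_seqs),
                              p("circ_seqs.fasta"))
  if (!is.null(bundle$manifest)) write_manifest(bundle$manifest, p("manifest"))
  invisible(dir)
}

write_manifest <- function(manifest, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  de <- do.call(rbind, lapply(names(manifest$de_features), function(layer) {
    v <- manifest$de_features[[layer]]
    if (!length(v)) return(NULL)
    data.frame(layer = layer, feature_id = names(v), log2fc = unname(v),
               stringsAsFactors = FALSE)
  }))
  write_tsv(de %||% data.frame(layer = character(0), feature_id = character(0),
                               log2fc = numeric(0)), p("de_features.tsv"))
  write_tsv(manifest$dm_probes, p("dm_probes.tsv"))
  write_tsv(manifest$coupled_pairs, p("coupled_pairs.tsv"))
  write_tsv(data.frame(circ_id = manifest$decoupled_circ), p("decoupled_circ.tsv"))
  write_tsv(data.frame(circ_id = manifest$opposite_circ), p("opposite_circ.tsv"))
  write_tsv(manifest$classes, p("classes.tsv"))
  sf <- do.call(rbind, lapply(names(manifest$size_factors), function(layer) {
    v <- manifest$size_factors[[layer]]
    data.frame(layer = layer, sample_id = names(v), size_factor = unname(v),
               stringsAsFactors = FALSE)
  }))
  write_tsv(sf, p("size_factors.tsv"))
  write_tsv(manifest$planted_sites, p("planted_sites.tsv"))
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Directory produced by [write_bundle()].
#' @return A `multiomics_bundle` (manifest included when present).
#' @export
read_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  design <- read_tsv(p("design.tsv"))
  genes <- read_tsv(p("genes.tsv"))
  bed <- read_tsv(p("circs.bed"), header = FALSE)
  names(bed) <- c("chrom", "start", "end", "name", "score", "strand", "origin", "gene_id")
  circs <- data.frame(circ_id = bed$name, chrom = bed$chrom,
                      start = bed$start + 1L, end = bed$end, strand = bed$strand,
                      origin = bed$origin,
                      gene_id = ifelse(bed$gene_id == ".", NA_character_, bed$gene_id),
                      stringsAsFactors = FALSE)
  cs <- read_tsv(p("chrom_sizes.tsv"))
  chrom_sizes <- stats::setNames(as.numeric(cs$size), cs$chrom)
  counts <- lapply(c(gene = "gene", circ = "circ", mirna = "mirna"), function(layer) {
    d <- read_tsv(p(sprintf("counts_%s.tsv", layer)))
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$feature_id
    storage.mode(m) <- "integer"
    m
  })
  probes <- read_tsv(p("probes.tsv"))
  targets <- read_tsv(p("mirna_targets.tsv"))
  mirna <- Biostrings::readRNAStringSet(p("mirna.fasta"))
  circ_seqs <- Biostrings::readRNAStringSet(p("circ_seqs.fasta"))
  manifest <- if (dir.exists(p("manifest"))) read_manifest(p("manifest")) else NULL
  structure(list(design = design, genes = genes, circs = circs,
                 chrom_sizes = chrom_sizes, counts = counts, probes = probes,
                 mirna_seqs = stats::setNames(as.character(mirna), names(mirna)),
                 circ_seqs = stats::setNames(as.character(circ_seqs), names(circ_seqs)),
                 mirna_targets = targets, manifest = manifest),
            class = "multiomics_bundle")
}

read_manifest <- function(dir) {
  p <- function(...) file.path(dir, ...)
  de <- read_tsv(p("de_features.tsv"))
  de_features <- lapply(c(gene = "gene", circ = "circ", mirna = "mirna"), function(l) {
    d <- de[de$layer == l, , drop = FALSE]
    stats::setNames(d$log2fc, d$feature_id)
  })
  sf <- read_tsv(p("size_factors.tsv"))
  size_factors <- lapply(split(sf, sf$layer), function(d) {
    stats::setNames(d$size_factor, d$sample_id)
  })
  list(de_features = de_features,
       dm_probes = read_tsv(p("dm_probes.tsv"),
                            colClasses = list(character = c("probe_id", "region", "circ_id"))),
       coupled_pairs = read_tsv(p("coupled_pairs.tsv")),
       decoupled_circ = read_tsv(p("decoupled_circ.tsv"))$circ_id %||% character(0),
       opposite_circ = read_tsv(p("opposite_circ.tsv"))$circ_id %||% character(0),
       classes = read_tsv(p("classes.tsv")),
       size_factors = size_factors[c("gene", "circ", "mirna")],
       planted_sites = read_tsv(p("planted_sites.tsv")))
}
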
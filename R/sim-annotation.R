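#' Simulate a gene annotation table and a circRNA catalog
#'
#' Genes are laid out sequentially (with intergenic gaps) on `n_chrom`
#' synthetic chromosomes; each circRNA is assigned an origin class drawn from
#' `config$origin_props`. Exonic and intronic circRNAs are nested inside a
#' randomly chosen parental gene's span and inherit its strand; intergenic
#' circRNAs are placed outside every gene span with a random strand. circRNA
#' identifiers follow the "chr:start-end" convention (1-based inclusive).
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_annotation` with elements
#'   \describe{
#'     \item{genes}{data.frame: gene_id, chrom, strand, start, end, tss}
#'     \item{circs}{data.frame: circ_id, chrom, start, end, strand, origin,
#'       gene_id (NA for intergenic)}
#'     \item{chrom_sizes}{named numeric vector of chromosome lengths}
#'   }
#' @examples
#' ann <- simulate_annotation(sim_config(n_genes = 40, n_circ = 12, seed = 1))
#' table(ann$circs$origin)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_classes <- sum(config$origin_props > 0)
  if (config$n_circ < n_classes) {
    stop("configuration error: n_circ (", config$n_circ,
         ") is smaller than the number of origin classes (", n_classes, ")")
  }
  with_seed(derive_seed(config$seed, "annotation"), {
    ## genes: sequential placement with gaps, split across chromosomes
    n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chrom + 1)))
    genes <- vector("list", config$n_chrom)
    sizes <- numeric(config$n_chrom)
    for (ci in seq_len(config$n_chrom)) {
      ng <- n_per[ci]
      gaps <- round(stats::runif(ng, 5000, 20000))
      lens <- round(stats::runif(ng, 3000, 30000))
      start <- 10000 + cumsum(gaps) + c(0, cumsum(lens[-ng]))
      end <- start + lens - 1
      strand <- sample(c("+", "-"), ng, replace = TRUE)
      genes[[ci]] <- data.frame(
        chrom = paste0("chr", ci), strand = strand,
        start = as.integer(start), end = as.integer(end),
        tss = as.integer(ifelse(strand == "+", start, end)),
        stringsAsFactors = FALSE
      )
      sizes[ci] <- max(end) + 50000
    }
    genes <- do.call(rbind, genes)
    genes <- data.frame(gene_id = sprintf("G%04d", seq_len(nrow(genes))), genes,
                        stringsAsFactors = FALSE)
    names(sizes) <- paste0("chr", seq_len(config$n_chrom))

    ## circRNAs
    origin <- sample(names(config$origin_props), config$n_circ,
                     replace = TRUE, prob = config$origin_props)
    ## guarantee representation of classes with positive probability so a
    ## tiny n_circ still exercises every branch
    for (cl in names(config$origin_props)[config$origin_props > 0]) {
      if (!cl %in% origin) origin[sample(length(origin), 1)] <- cl
    }
    circs <- vector("list", config$n_circ)
    seen <- character(0)
    for (k in seq_len(config$n_circ)) {
      for (attempt in 1:100) {
        if (origin[k] %in% c("exonic", "intronic")) {
          gi <- sample(nrow(genes), 1)
          g <- genes[gi, ]
          w <- g$end - g$start + 1
          clen <- sample(200:max(201, min(w, 8000)), 1)
          clen <- min(clen, w)
          cstart <- g$start + sample(0:(w - clen), 1)
          rec <- data.frame(chrom = g$chrom, start = cstart,
                            end = cstart + clen - 1, strand = g$strand,
                            origin = origin[k], gene_id = g$gene_id,
                            stringsAsFactors = FALSE)
        } else {
          ci <- sample(config$n_chrom, 1)
          chrom <- paste0("chr", ci)
          clen <- sample(200:2000, 1)
          cstart <- sample(seq_len(max(1, sizes[ci] - clen - 1000)), 1)
          gc <- genes[genes$chrom == chrom, ]
          if (any(cstart <= gc$end + 2000 & cstart + clen - 1 >= gc$start - 2000)) next
          rec <- data.frame(chrom = chrom, start = cstart,
                            end = cstart + clen - 1, strand = sample(c("+", "-"), 1),
                            origin = "intergenic", gene_id = NA_character_,
                            stringsAsFactors = FALSE)
        }
        rec$start <- as.integer(rec$start)
        rec$end <- as.integer(rec$end)
        id <- sprintf("%s:%d-%d", rec$chrom, rec$start, rec$end)
        if (!id %in% seen) {
          seen <- c(seen, id)
          circs[[k]] <- data.frame(circ_id = id, rec, stringsAsFactors = FALSE)
          break
        }
      }
      if (is.null(circs[[k]])) stop("failed to place circRNA ", k)
    }
    circs <- do.call(rbind, circs)
    structure(list(genes = genes, circs = circs, chrom_sizes = sizes),
              class = "sim_annotation")
  })
}
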
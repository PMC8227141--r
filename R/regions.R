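#' circRNA-relative genomic regions (Pre2000 / Interior / After2000)
#'
#' For each circRNA the methylation analysis considers three intervals: the
#' circRNA span itself (Interior), the 2 kb immediately upstream of the
#' back-splice acceptor (Pre2000) and the 2 kb immediately downstream of the
#' back-splice donor (After2000). "Upstream"/"downstream" are strand-aware by
#' default (`convention = "stranded"`): on the minus strand Pre2000 lies at
#' higher coordinates. `convention = "genomic-left"` reproduces a
#' strand-naive reading in which Pre2000 is always the left flank.
#'
#' Coordinates are 1-based inclusive. Flanks are clamped at position 1 and,
#' when `chrom_sizes` is supplied, at the chromosome end; an interval that is
#' empty after clamping is dropped. If `chrom_sizes` is supplied but lacks a
#' required chromosome, clamping cannot be decided and an error is raised.
#'
#' @param circs data.frame with columns circ_id, chrom, start, end, strand
#'   (one or more rows). Strand "unknown"/NA defaults to "+" with a warning.
#' @param chrom_sizes Optional named vector of chromosome lengths.
#' @param flank Flank width in bases (default 2000).
#' @param convention "stranded" (default) or "genomic-left".
#' @return data.frame: feature_id, region (Pre2000/Interior/After2000),
#'   chrom, start, end.
#' @examples
#' circ_regions(data.frame(circ_id = "chr1:10001-12000", chrom = "chr1",
#'                         start = 10001, end = 12000, strand = "+"))
#' @export
circ_regions <- function(circs, chrom_sizes = NULL, flank = 2000,
                         convention = c("stranded", "genomic-left")) {
  convention <- match.arg(convention)
  stopifnot(all(c("circ_id", "chrom", "start", "end", "strand") %in% names(circs)))
  if (any(circs$start > circs$end)) stop("circRNA with start > end")
  strand <- circs$strand
  if (any(is.na(strand) | !strand %in% c("+", "-"))) {
    warning("unknown strand defaulted to '+'")
    strand[is.na(strand) | !strand %in% c("+", "-")] <- "+"
  }
  left <- data.frame(start = circs$start - flank, end = circs$start - 1)
  right <- data.frame(start = circs$end + 1, end = circs$end + flank)
  pre_is_left <- if (convention == "stranded") strand == "+" else rep(TRUE, nrow(circs))
  mk <- function(region, iv) {
    data.frame(feature_id = circs$circ_id, region = region, chrom = circs$chrom,
               start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  }
  pre <- mk("Pre2000", data.frame(start = ifelse(pre_is_left, left$start, right$start),
                                  end = ifelse(pre_is_left, left$end, right$end)))
  aft <- mk("After2000", data.frame(start = ifelse(pre_is_left, right$start, left$start),
                                    end = ifelse(pre_is_left, right$end, left$end)))
  interior <- mk("Interior", data.frame(start = circs$start, end = circs$end))
  out <- rbind(pre, interior, aft)
  clamp_regions(out, chrom_sizes)
}

#' Gene promoter and gene-body regions
#'
#' The promoter is the 2 kb immediately upstream of the TSS (strand-aware);
#' the gene body is the annotated span.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand, tss.
#' @inheritParams circ_regions
#' @return data.frame: feature_id, region (promoter/gene_body), chrom, start, end.
#' @export
gene_regions <- function(genes, chrom_sizes = NULL, flank = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "tss") %in% names(genes)))
  if (any(genes$tss < genes$start | genes$tss > genes$end)) {
    stop("TSS outside the annotated gene span")
  }
  plus <- genes$strand == "+"
  prom <- data.frame(
    feature_id = genes$gene_id, region = "promoter", chrom = genes$chrom,
    start = ifelse(plus, genes$tss - flank, genes$tss + 1),
    end = ifelse(plus, genes$tss - 1, genes$tss + flank),
    stringsAsFactors = FALSE
  )
  body <- data.frame(feature_id = genes$gene_id, region = "gene_body",
                     chrom = genes$chrom, start = genes$start, end = genes$end,
                     stringsAsFactors = FALSE)
  clamp_regions(rbind(prom, body), chrom_sizes)
}

# Clamp intervals to [1, chrom length]; drop intervals emptied by clamping.
clamp_regions <- function(regions, chrom_sizes = NULL) {
  regions$start <- pmax(regions$start, 1)
  if (!is.null(chrom_sizes)) {
    missing <- setdiff(unique(regions$chrom), names(chrom_sizes))
    if (length(missing)) {
      stop("chromosome length unknown for: ", paste(missing, collapse = ", "))
    }
    regions$end <- pmin(regions$end, chrom_sizes[regions$chrom])
  }
  out <- regions[regions$start <= regions$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map methylation probes to labeled regions
#'
#' Reports every (probe, feature, region) containment; a probe may fall in
#' several features and several region types. Output order is canonical
#' (probe_id, feature_id, region), so the result is invariant to input order.
#'
#' @param probes data.frame with columns probe_id, chrom, pos (1-based).
#' @param regions data.frame as returned by [circ_regions()] /
#'   [gene_regions()] (feature_id, region, chrom, start, end).
#' @return data.frame: probe_id, feature_id, region. Probes on chromosomes
#'   absent from `regions` are simply unassigned.
#' @export
map_probes <- function(probes, regions) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(probes)),
            all(c("feature_id", "region", "chrom", "start", "end") %in% names(regions)))
  empty <- data.frame(probe_id = character(0), feature_id = character(0),
                      region = character(0), stringsAsFactors = FALSE)
  chroms <- intersect(unique(probes$chrom), unique(regions$chrom))
  pieces <- lapply(chroms, function(ch) {
    p <- probes[probes$chrom == ch, , drop = FALSE]
    r <- regions[regions$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(IRanges::IRanges(p$pos, p$pos),
                                  IRanges::IRanges(r$start, r$end))
    if (!length(hits)) return(NULL)
    data.frame(probe_id = p$probe_id[S4Vectors::queryHits(hits)],
               feature_id = r$feature_id[S4Vectors::subjectHits(hits)],
               region = r$region[S4Vectors::subjectHits(hits)],
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  out <- out[order(out$probe_id, out$feature_id, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}
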
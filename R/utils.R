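# Internal helpers shared across modules.

# Offsets used to split one master seed into per-layer RNG streams, so that
# e.g. adding probes never perturbs the count matrices.
.layer_offsets <- c(
  annotation = 1L, plant = 2L, gene = 3L, circ = 4L, mirna = 5L,
  meth = 6L, coupling = 7L, seqs = 8L, targets = 9L
)

# Derive a deterministic 32-bit sub-seed for a named layer from the master seed.
derive_seed <- function(seed, layer) {
  if (!layer %in% names(.layer_offsets)) {
    stop("unknown RNG layer: ", layer)
  }
  off <- .layer_offsets[[layer]]
  as.integer((abs(as.numeric(seed)) * 48271 + off * 1000003) %% 2147483647L)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  data.table::fread(path, sep = "\t", data.table = FALSE, na.strings = "NA", ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tumor indicator (0/1) from a design table; errors on anything but the
# two-group tumor/normal labelling used throughout.
group_indicator <- function(design) {
  stopifnot(is.data.frame(design), all(c("sample_id", "group") %in% names(design)))
  g <- design$group
  bad <- setdiff(unique(g), c("tumor", "normal"))
  if (length(bad)) stop("unknown group labels: ", paste(bad, collapse = ", "))
  as.integer(g == "tumor")
}
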
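# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a private RNG stream, restoring the caller's seed
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# derive a child seed from a base seed, kept within 32-bit integer range
child_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483587L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_binary_volume <- function(x) {
  is.array(x) && length(dim(x)) == 3 && (is.logical(x) || all(x %in% c(0, 1)))
}

as_logical_volume <- function(x) {
  if (!is.logical(x)) {
    d <- dim(x)
    x <- x > 0
    dim(x) <- d
  }
  x
}

# FNV-1a hash of a serialized R object, as hex (used for config provenance)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

# connected-component labelling (26-connectivity in 3D, 8 in 2D by default)
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  if (is.null(d)) stopf("mask must be a matrix or 3D array")
  .cpp_label_components(as.logical(mask), as.integer(d), as.integer(connectivity))
}

component_sizes <- function(labels) {
  n <- attr(labels, "n_components")
  if (n == 0) integer(0) else tabulate(labels[labels > 0], nbins = n)
}

# fill interior holes of a 2D binary mask: background components not touching
# the image border are holes
fill_holes_2d <- function(mask) {
  bg <- !mask
  lab <- label_components(bg, 26L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  filled <- mask | !(lab %in% c(0L, border))
  dim(filled) <- dim(mask)
  filled
}
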
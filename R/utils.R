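#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Round half away from zero
#'
#' Deterministic rounding used wherever a fraction of a count must become a
#' count (e.g. the number of accumulation-positive myotubes in a field), so
#' that 0.5 rounds up rather than to even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, 2.4, -0.5))
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate code under a temporary RNG state so generators are deterministic
# without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sample() without the scalar-x surprise
sample_safe <- function(x, n) x[sample.int(length(x), n)]

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single number in [0, 1]", name)
  x
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || (strict && x <= 0) ||
      (!strict && x < 0))
    stopf("'%s' must be a single %s number", name,
          if (strict) "positive" else "non-negative")
  x
}

check_bit_depth <- function(x) {
  if (!x %in% c(8L, 16L)) stopf("'bit_depth' must be 8 or 16")
  as.integer(x)
}

bit_scale <- function(bit_depth) 2^bit_depth - 1

# Guess the bit depth of an integer-valued intensity matrix.
infer_bit_depth <- function(x) if (max(x) > 255) 16L else 8L

standard_error <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold computed on an arbitrary vector of
#' intensities, so it can be applied within a mask (e.g. within one myotube)
#' and not only to whole images. Pixels strictly above the returned value are
#' "positive".
#'
#' @param v numeric vector of intensities (>= 0).
#' @param max_value top of the intensity scale used for binning; defaults to
#'   `max(v)`.
#' @param levels number of histogram bins.
#' @return scalar threshold; `Inf` when `v` is (near-)constant, so that no
#'   pixel is called positive.
#' @export
otsu_threshold <- function(v, max_value = NULL, levels = 256L) {
  v <- as.numeric(v)
  if (length(v) == 0) return(Inf)
  if (is.null(max_value)) max_value <- max(v)
  if (max_value <= 0 || diff(range(v)) < 1e-10) return(Inf)
  bins <- pmax(1L, pmin(levels, floor(v / max_value * levels) + 1L))
  h <- tabulate(bins, nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(levels))
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  k <- which.max(sb2)
  k / levels * max_value
}

# Relabel a label matrix to consecutive 1..n, dropping labels not in `keep`.
relabel_keep <- function(lab, keep) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    map <- integer(max(lab))
    map[keep] <- seq_along(keep)
    nz <- lab > 0
    out[nz] <- map[lab[nz]]
  }
  out
}

label_areas <- function(lab) {
  if (max(lab) == 0) return(integer(0))
  tabulate(lab[lab > 0], nbins = max(lab))
}

# Per-label centroids (row, col) of a label matrix.
label_centroids <- function(lab) {
  n <- max(lab)
  if (n == 0)
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  r <- (idx - 1) %% nrow(lab) + 1
  c <- (idx - 1) %/% nrow(lab) + 1
  data.frame(label = seq_len(n),
             row = as.numeric(tapply(r, factor(l, levels = seq_len(n)), mean)),
             col = as.numeric(tapply(c, factor(l, levels = seq_len(n)), mean)))
}

as_ebi <- function(m) EBImage::Image(m)
from_ebi <- function(img) {
  m <- EBImage::imageData(img)
  dim(m) <- dim(m)[1:2]
  m
}
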
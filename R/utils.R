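#' @import stats
#' @importFrom utils head tail combn modifyList
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-stage sub-seed from a global seed; stays below 2^31.
substream_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, phenotype = 23L, field = 37L, aggregate = 41L,
            permute = 53L, pipeline = 67L)
  k <- if (stage %in% names(offs)) offs[[stage]] else 97L
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

# Reflect (symmetric, edge included) padding of a matrix by r rows/cols.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  if (r >= nr || r >= nc)
    stop("padding radius exceeds image dimensions")
  ri <- c(r:1, seq_len(nr), nr:(nr - r + 1))
  ci <- c(r:1, seq_len(nc), nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# Summed-area table with a leading zero row/col so box sums are 4 lookups.
integral_image <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

# Local box mean and population sd over a (window x window) neighbourhood,
# reflected padding at the boundary.
local_stats <- function(m, window) {
  r <- (window - 1L) %/% 2L
  p <- pad_reflect(m, r)
  S1 <- integral_image(p)
  S2 <- integral_image(p * p)
  nr <- nrow(m); nc <- ncol(m)
  i1 <- seq_len(nr); i2 <- i1 + 2L * r
  j1 <- seq_len(nc); j2 <- j1 + 2L * r
  box <- function(S) S[i2 + 1L, j2 + 1L] + S[i1, j1] - S[i1, j2 + 1L] - S[i2 + 1L, j1]
  n <- as.double(window)^2
  mu <- box(S1) / n
  v <- box(S2) / n - mu * mu
  list(mean = mu, sd = sqrt(pmax(v, 0)))
}

# Gaussian smoothing with reflected boundary handling. sigma in pixels.
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  if (all(m == m[1L])) return(m)  # constant image is a fixed point (exactly)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  # reflect padding cannot exceed image size; fall back to replicate-extend
  rr <- min(r, nrow(m) - 1L, ncol(m) - 1L)
  if (rr < 1L) return(m)
  p <- pad_reflect(m, rr)
  size <- 2L * rr + 1L
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  k <- k / sum(k)
  sm <- EBImage::filter2(p, k, boundary = "circular")
  sm[rr + seq_len(nrow(m)), rr + seq_len(ncol(m)), drop = FALSE]
}

odd_window <- function(px) {
  w <- as.integer(round(px))
  if (w %% 2L == 0L) w <- w + 1L
  max(w, 3L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
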
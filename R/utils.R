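## Internal numerical helpers shared across modules.

## Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
## RNG stream is untouched. All randomness in the package flows through this.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive `n` child seeds from one parent seed (kept < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

## Block-mean pooling of a matrix to a fixed (rows, cols) grid. Output pixel
## (i, j) is the mean of the input pixels whose scaled index falls in its bin;
## exact, deterministic, and averages sensor noise like an area downsample.
meanPool <- function(mat, outDim) {
  h <- nrow(mat); w <- ncol(mat)
  oh <- outDim[1]; ow <- outDim[2]
  stopifnot(oh >= 1, ow >= 1, oh <= h, ow <= w)
  rg <- pmin(floor((seq_len(h) - 1L) * oh / h) + 1L, oh)
  cg <- pmin(floor((seq_len(w) - 1L) * ow / w) + 1L, ow)
  s <- rowsum(mat, rg, reorder = TRUE)            # oh x w
  s <- t(rowsum(t(s), cg, reorder = TRUE))        # oh x ow (sums)
  cnt <- tabulate(rg, oh) %o% tabulate(cg, ow)
  s / cnt
}

## 1-d Gaussian kernel, radius 3 sigma, normalized.
gaussKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian blur of a matrix with replicate edge padding.
gaussBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- gaussKernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  padConv <- function(m) {
    # pad rows by replication, filter each column (C-level), crop
    idx <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
    f <- stats::filter(m[idx, , drop = FALSE], k, sides = 2)
    matrix(f[(r + 1L):(r + nrow(m)), ], nrow = nrow(m))
  }
  t(padConv(t(padConv(mat))))
}

## Centered running quantile with window w (odd); edges use truncated
## windows. The filter output is slow by construction, so it is evaluated on
## a stride and linearly interpolated in between.
runningQuantile <- function(x, w, prob, stride = NULL) {
  n <- length(x)
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  r <- (w - 1L) %/% 2L
  if (is.null(stride)) stride <- max(1L, r %/% 6L)
  at <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(at, function(i) {
    lo <- max(1L, i - r); hi <- min(n, i + r)
    stats::quantile(x[lo:hi], prob, names = FALSE, type = 7)
  }, numeric(1))
  if (length(at) == n) q else stats::approx(at, q, xout = seq_len(n))$y
}

## Centered running median with truncated edge windows.
runningMedian <- function(x, w) {
  n <- length(x)
  w <- min(w, if (n %% 2L == 1L) n else n - 1L)
  if (w < 3L) return(x)
  out <- stats::runmed(x, w, endrule = "keep")
  # fix the edge samples with truncated centered windows
  r <- (w - 1L) %/% 2L
  for (i in seq_len(min(r, n))) {
    out[i] <- stats::median(x[1:min(n, i + r)])
    j <- n - i + 1L
    out[j] <- stats::median(x[max(1L, j - r):n])
  }
  out
}

## Stable short hash of an R object (for config provenance).
configHash <- function(x) digest::digest(x, algo = "xxhash64")

## odd window length in samples for a window given in seconds
oddWindow <- function(windowS, dt, nMax) {
  w <- max(3L, round(windowS / dt))
  if (w %% 2L == 0L) w <- w + 1L
  min(w, if (nMax %% 2L == 1L) nMax else nMax - 1L)
}
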
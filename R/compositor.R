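## compositor: 3x3 composites of nine same-group waveform images.

#' Tile nine waveform rasters into a 3 x 3 grid
#'
#' Places the nine tiles row-major after a seeded random permutation: a
#' waveform's grid position carries no information, and a fixed placement
#' rule would hand the classifier positional artifacts to exploit.
#'
#' @param tiles list of nine pixel matrices of identical dimensions.
#' @param orderSeed integer seed for the tile permutation; `NULL` keeps the
#'   input order.
#' @return A pixel matrix with 3 x the tile height and 3 x the tile width.
#' @export
tile3x3 <- function(tiles, orderSeed = NULL) {
  if (length(tiles) != 9L) stop("exactly 9 tiles are required")
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims != dims[, 1]))
    stop("dimension error: tiles have heterogeneous sizes")
  if (!is.null(orderSeed))
    tiles <- tiles[withSeed(orderSeed, sample.int(9L))]
  th <- dims[1, 1]; tw <- dims[2, 1]
  out <- matrix(0, 3L * th, 3L * tw)
  for (k in 0:8) {
    r <- k %/% 3L; c <- k %% 3L
    out[r * th + seq_len(th), c * tw + seq_len(tw)] <- tiles[[k + 1L]]
  }
  out
}

## Deterministic sampling plan for a set of composites: which nine pool
## members each composite uses, and the per-composite tile-order seed.
compositePlan <- function(poolSize, nOut, seed, reuseAcross = TRUE) {
  seeds <- deriveSeeds(seed, nOut + 1L)
  draws <- withSeed(seeds[nOut + 1L], {
    if (reuseAcross) {
      lapply(seq_len(nOut), function(i) sample(poolSize, 9L))
    } else {
      perm <- sample(poolSize)
      lapply(seq_len(nOut), function(i) perm[(i - 1L) * 9L + 1:9])
    }
  })
  list(draws = draws, orderSeeds = seeds[seq_len(nOut)])
}

#' Build composite training images from a single-group pool
#'
#' Each composite draws nine *distinct* members uniformly without replacement
#' from the pool and tiles them 3 x 3 in seeded random order. With
#' `reuseAcross = TRUE` (default) a waveform may appear in any number of
#' different composites, matching how more composites than `pool / 9` can be
#' built; with `reuseAcross = FALSE` draws are globally disjoint, which
#' requires `9 * nOut <= length(pool)`.
#'
#' @param pool list of [`WaveformImage`][WaveformImage-class], all of one
#'   group; at least 9.
#' @param group expected group label of the pool.
#' @param nOut number of composites to build.
#' @param seed integer seed; the member lists and rasters are deterministic
#'   given `(pool, nOut, seed)`.
#' @param reuseAcross allow members to recur across composites.
#' @return List of [`CompositeImage`][CompositeImage-class].
#' @examples
#' tr <- makeBenchmark(BenchmarkSpec(nTracesPerGroup = 9, seed = 1))
#' imgs <- renderWaveforms(lapply(tr[1:9], dffTrace),
#'                         RenderConfig(canvasPx = c(32, 32)))
#' cmp <- buildComposites(imgs, "negative", nOut = 1, seed = 1)
#' memberIds(cmp[[1]])
#' @export
buildComposites <- function(pool, group, nOut, seed, reuseAcross = TRUE) {
  if (length(pool) < 9L)
    stop("insufficient-pool error: need at least 9 waveform images, got ",
         length(pool))
  groups <- vapply(pool, imageGroup, character(1))
  if (any(groups != group))
    stop("label error: pool contains groups other than '", group, "'")
  ids <- vapply(pool, function(x) x@roiId, character(1))
  if (anyDuplicated(ids))
    stop("label error: pool contains duplicate image ids")
  if (!reuseAcross && 9L * nOut > length(pool))
    stop("insufficient-pool error: ", nOut, " disjoint composites need ",
         9L * nOut, " images, pool has ", length(pool))

  plan <- compositePlan(length(pool), nOut, seed, reuseAcross)
  draws <- plan$draws; seeds <- plan$orderSeeds
  lapply(seq_len(nOut), function(i) {
    members <- pool[draws[[i]]]
    new("CompositeImage",
        pixels = tile3x3(lapply(members, imagePixels), orderSeed = seeds[i]),
        memberIds = ids[draws[[i]]],
        group = group,
        seed = seeds[i])
  })
}
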
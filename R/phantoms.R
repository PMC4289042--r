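# Deterministic phantoms with known analytic dimension, plus the folded
# ribbon used as a cortical-sheet surrogate. All phantoms use 1 mm isotropic
# spacing; geometry is in voxel units.

#' Solid cube phantom (analytic D = 3)
#'
#' @param size grid edge in voxels (>= 8).
#' @return A [binary_mask()]: a fully-foreground `size^3` grid.
#' @export
make_solid_block <- function(size) {
  size <- as.integer(size)
  stopifnot(size >= 8L)
  binary_mask(array(TRUE, c(size, size, size)))
}

#' Flat slab phantom (analytic D = 2)
#'
#' A `size x size x thickness` sheet centered in a `size^3` grid. The
#' occupied z layers are voxel centers falling in the half-open band
#' `[size/2 - thickness/2, size/2 + thickness/2)`, which makes
#' [make_folded_ribbon()] with zero fold frequency and zero jitter reduce to
#' exactly this slab.
#'
#' @param size grid edge in voxels (>= 8).
#' @param thickness slab thickness in voxels (1 <= thickness < size).
#' @return A [binary_mask()].
#' @export
make_slab <- function(size, thickness = 1) {
  size <- as.integer(size)
  stopifnot(size >= 8L, thickness >= 1, thickness < size)
  z <- seq_len(size) - 0.5
  keep <- z >= size / 2 - thickness / 2 & z < size / 2 + thickness / 2
  g <- array(FALSE, c(size, size, size))
  g[, , keep] <- TRUE
  binary_mask(g)
}

#' Straight line phantom (analytic D = 1)
#'
#' A 1-voxel-thick line of length `size` along the x axis, centered in a
#' `size^3` grid.
#'
#' @param size grid edge in voxels (>= 8).
#' @return A [binary_mask()].
#' @export
make_line <- function(size) {
  size <- as.integer(size)
  stopifnot(size >= 8L)
  g <- array(FALSE, c(size, size, size))
  mid <- size %/% 2L
  g[, mid, mid] <- TRUE
  binary_mask(g)
}

#' Menger sponge phantom (analytic D = log 20 / log 3)
#'
#' Recursive construction on a `3^level` cube: each 3x3x3 subdivision keeps
#' the 20 subcubes that are not the body center or a face center, at every
#' level. The voxel count is exactly `20^level` and the analytic fractal
#' dimension is log(20)/log(3) ~ 2.7268.
#'
#' @param level recursion depth, 1..4 (level 4 is an 81^3 grid; deeper
#'   levels are refused as a memory guard).
#' @return A [binary_mask()].
#' @export
make_menger_sponge <- function(level) {
  level <- as.integer(level)
  if (level < 1L || level > 4L) {
    abort("Menger sponge level must be between 1 and 4.")
  }
  n <- 3L^level
  coords <- 0:(n - 1)
  keep <- array(TRUE, c(n, n, n))
  for (k in 0:(level - 1)) {
    digit1 <- ((coords %/% 3L^k) %% 3L) == 1L
    d1 <- as.integer(digit1)
    # a cell is removed when >= 2 of its base-3 digits at place k equal 1
    removed <- outer(outer(d1, d1, "+"), d1, "+") >= 2L
    keep <- keep & !removed
  }
  binary_mask(keep)
}

#' Folded-ribbon phantom (cortical-sheet surrogate)
#'
#' Voxelizes the doubly-sinusoidal sheet
#' `z = size/2 + amplitude * sin(2*pi*f*x/size + phi_x) * sin(2*pi*f*y/size + phi_y)`
#' thickened by `thickness` voxels along the local surface normal (a voxel
#' center belongs to the ribbon when its vertical distance to the sheet is
#' below `thickness/2` times the local normal obliquity factor
#' `sqrt(1 + |grad z|^2)`). The phases `phi` carry a small seeded jitter so
#' simulated subjects are not identical; with `fold_frequency = 0` and
#' `jitter = 0` the ribbon is exactly [make_slab()] of the same thickness.
#' Fold frequency is the monotone complexity knob: more folds per grid width
#' raise the fractal dimension of the ribbon.
#'
#' @param size grid edge in voxels (>= 8).
#' @param fold_frequency number of folding cycles across the grid (>= 0,
#'   need not be an integer).
#' @param amplitude fold amplitude in voxels; `amplitude + thickness` must
#'   stay below `size/2` so the ribbon fits the grid.
#' @param thickness ribbon thickness in voxels (>= 1, may be fractional).
#' @param seed integer seed for the phase jitter (deterministic given seed).
#' @param jitter phase jitter half-range in radians (default 0.15).
#' @return A [binary_mask()].
#' @examples
#' m <- make_folded_ribbon(48, fold_frequency = 4, amplitude = 4,
#'                         thickness = 3, seed = 1)
#' compute_fd(m, "BC", "lobe")$D
#' @export
make_folded_ribbon <- function(size, fold_frequency, amplitude, thickness,
                               seed = 1L, jitter = 0.15) {
  size <- as.integer(size)
  stopifnot(size >= 8L, fold_frequency >= 0, thickness >= 1, amplitude >= 0,
            jitter >= 0)
  if (amplitude + thickness >= size / 2) {
    abort("`amplitude + thickness` must be smaller than size/2 to fit the grid.")
  }
  phi <- if (jitter > 0) {
    with_preserved_seed(seed, runif(2, -jitter, jitter))
  } else {
    c(0, 0)
  }
  xy <- seq_len(size) - 0.5
  wave_x <- sin(2 * pi * fold_frequency * xy / size + phi[1])
  wave_y <- sin(2 * pi * fold_frequency * xy / size + phi[2])
  dwave_x <- (2 * pi * fold_frequency / size) *
    cos(2 * pi * fold_frequency * xy / size + phi[1])
  dwave_y <- (2 * pi * fold_frequency / size) *
    cos(2 * pi * fold_frequency * xy / size + phi[2])
  zc <- size / 2 + amplitude * outer(wave_x, wave_y)          # sheet height
  gx <- amplitude * outer(dwave_x, wave_y)                    # dz/dx
  gy <- amplitude * outer(wave_x, dwave_y)                    # dz/dy
  halfw <- (thickness / 2) * sqrt(1 + gx^2 + gy^2)
  if (any(zc + halfw > size) || any(zc - halfw < 0)) {
    abort("Ribbon leaves the grid; reduce amplitude or thickness.")
  }
  g <- array(FALSE, c(size, size, size))
  z <- seq_len(size) - 0.5
  lo <- zc - halfw
  hi <- zc + halfw
  for (k in seq_len(size)) {
    g[, , k] <- z[k] >= lo & z[k] < hi
  }
  binary_mask(g)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
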
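#' Box counting over a regular lattice
#'
#' Counts the number of lattice cells of edge `r` (in voxels) containing at
#' least one foreground voxel. The lattice is anchored at the minimum corner
#' of the foreground bounding box, which makes the count deterministic and
#' invariant under any integer translation of the mask; no offset averaging
#' is performed. `r = 1` returns the foreground voxel count.
#'
#' The box count of a fractal set scales as N(r) ~ r^-D, and D is recovered
#' by [fit_fd()] from the log-log slope.
#'
#' @param mask a non-empty [binary_mask()].
#' @param r box edge length in voxels (positive integer).
#' @return Number of occupied boxes (positive integer).
#' @seealso [box_count_series()], [fit_fd()]
#' @export
box_count <- function(mask, r) {
  idx0 <- fg_index0(mask)
  box_count_idx(idx0, r)
}

# 0-based foreground voxel coordinates, relative to bounding-box min corner
fg_index0 <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$voxel_count == 0L) {
    abort("Mask is empty; fractal-dimension operations require foreground voxels.")
  }
  idx <- which(mask$grid, arr.ind = TRUE)
  mins <- c(min(idx[, 1]), min(idx[, 2]), min(idx[, 3]))
  idx[, 1] <- idx[, 1] - mins[1]
  idx[, 2] <- idx[, 2] - mins[2]
  idx[, 3] <- idx[, 3] - mins[3]
  idx
}

box_count_idx <- function(idx0, r) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 1L) {
    abort("Box edge `r` must be a positive integer.")
  }
  cx <- idx0[, 1] %/% r
  cy <- idx0[, 2] %/% r
  cz <- idx0[, 3] %/% r
  kx <- max(cx) + 1
  ky <- max(cy) + 1
  id <- cx + kx * (cy + ky * cz)
  length(unique(id))
}

#' Box-count scale series
#'
#' Evaluates [box_count()] at every integer box edge from `r_min` to `r_max`
#' (edge length increased by one voxel per step). If `r_max` exceeds the
#' longest edge of the foreground bounding box the series is truncated there
#' with a warning, since all larger boxes would trivially count 1.
#'
#' @inheritParams box_count
#' @param r_min,r_max inclusive integer scale range, `1 <= r_min < r_max`.
#' @return A tibble with columns `method` (`"BC"`), `r`, `measure` (box
#'   count N(r)).
#' @export
box_count_series <- function(mask, r_min, r_max) {
  r_min <- as.integer(r_min)
  r_max <- as.integer(r_max)
  stopifnot(r_min >= 1L, r_min < r_max)
  idx0 <- fg_index0(mask)
  longest <- max(apply(idx0, 2, max)) + 1L
  if (r_max > longest) {
    warn(paste0("Box-count r_max = ", r_max,
                " exceeds the foreground bounding-box longest edge (", longest,
                "); series truncated at r = ", longest, "."))
    r_max <- longest
  }
  if (r_max <= r_min) {
    abort("Scale range collapsed after truncation; mask is too small for this range.")
  }
  rs <- seq.int(r_min, r_max)
  tibble(
    method = "BC",
    r = rs,
    measure = vapply(rs, function(r) as.numeric(box_count_idx(idx0, r)), numeric(1))
  )
}

#' Minkowski dilation voxel count
#'
#' Counts voxels whose center lies within Euclidean distance `r` (voxel
#' units) of some foreground voxel center -- the voxel count of the
#' Minkowski dilation by a discrete closed ball of radius `r`. Computed from
#' an exact Euclidean distance transform on a grid padded by `r` voxels per
#' side so no dilated voxel is clipped. `r = 0` returns the voxel count.
#'
#' @param mask a non-empty [binary_mask()].
#' @param r dilation radius in voxels (non-negative integer).
#' @return Dilated voxel count (positive integer).
#' @seealso [dilation_series()], [fit_fd()]
#' @export
dilate_count <- function(mask, r) {
  r <- as.integer(r)
  stopifnot(length(r) == 1L, !is.na(r), r >= 0L)
  if (r == 0L) {
    if (mask$voxel_count == 0L) abort("Mask is empty.")
    return(mask$voxel_count)
  }
  dilation_counts(mask, r)[r]
}

# counts for every integer radius 1..r_max, from a single padded EDT
dilation_counts <- function(mask, r_max) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$voxel_count == 0L) {
    abort("Mask is empty; fractal-dimension operations require foreground voxels.")
  }
  d <- dim(mask$grid)
  pad <- as.integer(r_max)
  pd <- d + 2L * pad
  g <- array(FALSE, pd)
  g[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <-
    mask$grid
  dsq <- .edt_sq_cpp(as.vector(g), as.integer(pd))
  vapply(seq_len(r_max), function(r) sum(dsq <= r * r + 0.5), numeric(1))
}

#' Minkowski-Bouligand dilation series
#'
#' Evaluates [dilate_count()] at every integer radius from `r_min` to
#' `r_max` (radius increased by one voxel per step; the standard range for
#' ribbon masks is r = 1..7). The dilated volume V(r) of a D-dimensional set
#' embedded in 3-space scales as r^(3-D); [fit_fd()] recovers D from the
#' log-log slope.
#'
#' @inheritParams dilate_count
#' @param r_min,r_max inclusive integer radius range, `1 <= r_min < r_max`.
#' @return A tibble with columns `method` (`"MB"`), `r`, `measure` (dilated
#'   voxel count V(r)).
#' @export
dilation_series <- function(mask, r_min = 1, r_max = 7) {
  r_min <- as.integer(r_min)
  r_max <- as.integer(r_max)
  stopifnot(r_min >= 1L, r_min < r_max)
  counts <- dilation_counts(mask, r_max)
  rs <- seq.int(r_min, r_max)
  tibble(method = "MB", r = rs, measure = counts[rs])
}

#' Standard scale ranges per method and region kind
#'
#' Box counting uses r = 2..30 voxels for whole brain and hemispheres and
#' r = 2..14 for lobes; Minkowski-Bouligand dilation uses r = 1..7 for every
#' region kind.
#'
#' @param method `"BC"` or `"MB"`.
#' @param region_kind `"whole_brain"`, `"hemisphere"` or `"lobe"`.
#' @return Integer vector `c(r_min, r_max)`.
#' @export
fd_scale_range <- function(method = c("BC", "MB"),
                           region_kind = c("whole_brain", "hemisphere", "lobe")) {
  method <- match.arg(method)
  region_kind <- match.arg(region_kind)
  if (method == "MB") return(c(1L, 7L))
  if (region_kind == "lobe") c(2L, 14L) else c(2L, 30L)
}

#' Fit a fractal dimension to a scale series
#'
#' Ordinary least-squares fit of log(measure) against log(scale) over all
#' entries of the series (no automatic linear-regime selection; the r2 of
#' the fit is reported so linearity can be judged). For box counting
#' D = -slope; for Minkowski-Bouligand dilation D = 3 - slope, the standard
#' dilation ("sausage") estimator for a set embedded in 3-space.
#'
#' @param series a tibble from [box_count_series()] or [dilation_series()]
#'   (columns `method`, `r`, `measure`), with at least 3 entries.
#' @return An object of class `fd_estimate`: a list with elements `D`,
#'   `method`, `r_min`, `r_max`, `n_points`, `fit_r2`, `slope`, `intercept`
#'   and the input `series`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_fd <- function(series) {
  series <- as_tibble(series)
  stopifnot(all(c("method", "r", "measure") %in% names(series)))
  method <- unique(series$method)
  if (length(method) != 1L || !method %in% c("BC", "MB")) {
    abort("Series must carry a single method, 'BC' or 'MB'.")
  }
  if (nrow(series) < 3L) {
    abort("At least 3 scales are required to fit a fractal dimension.")
  }
  r <- series$r
  m <- series$measure
  if (any(diff(r) <= 0) || any(r < 1)) {
    abort("Scales must be strictly increasing positive integers.")
  }
  if (any(m <= 0)) abort("All measures must be strictly positive.")
  # Anchored-lattice box counts can rise locally at scales incommensurate
  # with the structure (lattice-phase effect, visible e.g. on the Menger
  # sponge); only an overall increase marks an invalid series.
  if (method == "BC" && m[length(m)] > m[1]) {
    abort("Box counts must not increase from r_min to r_max.")
  }
  if (method == "MB" && any(diff(m) < 0)) {
    abort("Dilation volumes must be non-decreasing in r.")
  }
  if (length(unique(r)) < 2L) abort("Zero variance in log(r).")
  fit <- lm(log(m) ~ log(r))
  slope <- unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- NA_real_
  structure(
    list(
      D = if (method == "BC") -slope else 3 - slope,
      method = method,
      r_min = min(r), r_max = max(r), n_points = length(r),
      fit_r2 = r2,
      slope = slope, intercept = unname(coef(fit)[1]),
      series = series
    ),
    class = "fd_estimate"
  )
}

#' Fractal dimension of a ribbon mask
#'
#' Composes the scale series for the requested method over the standard
#' scale range for the region kind (see [fd_scale_range()]) with the log-log
#' fit of [fit_fd()]. Deterministic: identical input yields identical
#' output. Requires a non-empty mask with isotropic voxels, since scales are
#' expressed in voxel units.
#'
#' @inheritParams box_count
#' @param method `"BC"` (box counting) or `"MB"` (Minkowski-Bouligand
#'   dilation).
#' @param region_kind `"whole_brain"`, `"hemisphere"` or `"lobe"`; selects
#'   the scale range.
#' @return An `fd_estimate` (see [fit_fd()]).
#' @examples
#' m <- make_solid_block(16)
#' compute_fd(m, "BC", "lobe")$D
#' @export
compute_fd <- function(mask, method = c("BC", "MB"),
                       region_kind = c("whole_brain", "hemisphere", "lobe")) {
  method <- match.arg(method)
  region_kind <- match.arg(region_kind)
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$voxel_count == 0L) {
    abort("Mask is empty; cannot estimate a fractal dimension.")
  }
  assert_isotropic(mask$spacing)
  rng <- fd_scale_range(method, region_kind)
  series <- if (method == "BC") {
    box_count_series(mask, rng[1], rng[2])
  } else {
    dilation_series(mask, rng[1], rng[2])
  }
  fit_fd(series)
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat("<fd_estimate> ", x$method, " D = ", sprintf("%.4f", x$D),
      "  (r = ", x$r_min, "..", x$r_max, ", ", x$n_points,
      " scales, fit R² = ", sprintf("%.4f", x$fit_r2), ")\n", sep = "")
  invisible(x)
}

#' Broom-style accessors and diagnostics for FD fits
#'
#' `tidy()` returns the per-scale series with log coordinates and fitted
#' values; `glance()` returns a one-row fit summary; `autoplot()` draws the
#' log-log scatter with the fitted line.
#'
#' @param x an `fd_estimate` from [fit_fd()] or [compute_fd()].
#' @param object an `fd_estimate`.
#' @param ... unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot object (`autoplot`).
#' @name fd_estimate_methods
NULL

#' @rdname fd_estimate_methods
#' @method tidy fd_estimate
#' @export
tidy.fd_estimate <- function(x, ...) {
  dplyr::mutate(
    x$series,
    log_r = log(.data$r),
    log_measure = log(.data$measure),
    fitted = x$intercept + x$slope * log(.data$r)
  )
}

#' @rdname fd_estimate_methods
#' @method glance fd_estimate
#' @export
glance.fd_estimate <- function(x, ...) {
  tibble(
    method = x$method, D = x$D, r_min = x$r_min, r_max = x$r_max,
    n_points = x$n_points, fit_r2 = x$fit_r2
  )
}

#' @rdname fd_estimate_methods
#' @method autoplot fd_estimate
#' @export
autoplot.fd_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log_r, y = .data$log_measure)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(
      x = "log r (voxels)",
      y = if (object$method == "BC") "log N(r)" else "log V(r)",
      title = sprintf("%s fit: D = %.3f (R² = %.4f)",
                      object$method, object$D, object$fit_r2)
    ) +
    ggplot2::theme_minimal()
}

#' Write a scale series as CSV
#'
#' Columns: `region`, `method`, `r`, `measure`, `log_r`, `log_measure`.
#'
#' @param series a scale-series tibble.
#' @param path output CSV path.
#' @param region region name recorded in the `region` column.
#' @return `path`, invisibly.
#' @export
write_scale_series <- function(series, path, region = "WB") {
  out <- dplyr::mutate(as_tibble(series),
                       region = region,
                       log_r = log(.data$r),
                       log_measure = log(.data$measure))
  readr::write_csv(out[, c("region", "method", "r", "measure", "log_r", "log_measure")],
                   path)
  invisible(path)
}
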
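#' Phantom validation suite
#'
#' Estimates the fractal dimension of the reference phantoms with both
#' methods and checks the package's validation properties: recovery of the
#' analytic dimension within the documented discretization-bias bands (see
#' the methods vignette), the dimension ordering line < slab < sponge <
#' solid, BC-MB method agreement on the sheet-like phantoms, and
#' determinism of repeated estimation.
#'
#' @param size grid edge for the block/slab/line phantoms (default 64).
#' @param ribbon_size,ribbon_f,ribbon_amplitude,ribbon_thickness folded
#'   ribbon settings (defaults 96, 6, 8, 3).
#' @param sponge_level Menger sponge recursion depth (default 4).
#' @return A tibble with one row per (phantom, method): `phantom`,
#'   `method`, `D`, `analytic` (NA for the ribbon), `abs_error`, `band`,
#'   `pass`.
#' @export
validate_phantoms <- function(size = 64, ribbon_size = 96, ribbon_f = 6,
                              ribbon_amplitude = 8, ribbon_thickness = 3,
                              sponge_level = 4) {
  phantoms <- list(
    line = make_line(size),
    slab = make_slab(size, 1),
    sponge = make_menger_sponge(sponge_level),
    ribbon = make_folded_ribbon(ribbon_size, ribbon_f, ribbon_amplitude,
                                ribbon_thickness, seed = 1),
    block = make_solid_block(size)
  )
  analytic <- c(line = 1, slab = 2, sponge = log(20) / log(3),
                ribbon = NA_real_, block = 3)
  # accuracy bands reflect the finite-scale discretization bias of each
  # estimator on desk-scale grids (methods vignette, "Estimator accuracy")
  band <- list(
    line = c(BC = 0.10, MB = 0.25),
    slab = c(BC = 0.10, MB = 0.15),
    sponge = c(BC = 0.25, MB = 0.25),   # level-4 lattice misalignment ~0.18
    ribbon = c(BC = NA, MB = NA),
    block = c(BC = 0.15, MB = 0.30)
  )
  rows <- list()
  for (ph in names(phantoms)) {
    for (meth in c("BC", "MB")) {
      D <- compute_fd(phantoms[[ph]], meth, "lobe")$D
      b <- band[[ph]][[meth]]
      err <- abs(D - analytic[[ph]])
      rows[[paste(ph, meth)]] <- tibble(
        phantom = ph, method = meth, D = D, analytic = analytic[[ph]],
        abs_error = err, band = as.numeric(b),
        pass = if (is.na(b)) NA else err <= b
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  # ribbon plausibility: BC FD in the band bracketing reported cortical FDs
  rib_bc <- out$D[out$phantom == "ribbon" & out$method == "BC"]
  out$pass[out$phantom == "ribbon"] <-
    rep(rib_bc >= 2.2 && rib_bc <= 2.8, 2)
  out$band[out$phantom == "ribbon"] <- NA_real_
  attr(out, "ordering_ok") <- all(
    vapply(c("BC", "MB"), function(m) {
      d <- out$D[out$method == m]
      names(d) <- out$phantom[out$method == m]
      d[["line"]] < d[["slab"]] && d[["slab"]] < d[["sponge"]] &&
        d[["sponge"]] < d[["block"]]
    }, logical(1))
  )
  agree <- dplyr::summarise(
    dplyr::group_by(out[out$phantom %in% c("slab", "sponge", "ribbon"), ],
                    .data$phantom),
    diff = abs(diff(.data$D))
  )
  attr(out, "method_agreement_max") <- max(agree$diff)
  out
}
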
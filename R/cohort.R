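#' Specification of a simulated two-group cohort
#'
#' Describes a cohort of folded-ribbon phantom "subjects" in the design of
#' the study being emulated: two age groups (adolescent, adult) stratified
#' by sex, with default cell sizes 11/6 adolescents (female/male) versus 7/7
#' adults. Group differences are induced through the folded-ribbon
#' parameters: fold frequency is the complexity knob driving the fractal
#' dimension (and, secondarily, volume, so the adolescent group also carries
#' more grey matter, as reported cohorts do); thickness is an FD-neutral
#' volume knob left identical across groups by default. The default fold
#' frequency gap (6 vs 5.5, sd 0.5) was calibrated once against the ribbon
#' generator's measured frequency-to-FD response so the group FD gap lands
#' near 0.03 with within-group FD sd around 0.01-0.04, the scale of
#' reported cortical FD group differences; see the methods vignette.
#'
#' @param n named integer vector of cell counts with names
#'   `adolescent_female`, `adolescent_male`, `adult_female`, `adult_male`
#'   (each >= 2).
#' @param size phantom grid edge in voxels.
#' @param fold_frequency list with elements `adolescent` and `adult`, each
#'   `c(mean = , sd = )`, for the per-subject fold-frequency draw.
#' @param thickness same structure, for the per-subject ribbon thickness.
#' @param amplitude fold amplitude in voxels (common to all subjects).
#' @param jitter phase jitter half-range in radians passed to
#'   [make_folded_ribbon()].
#' @param scale_kind scale range used for FD of the phantoms; phantoms at
#'   desk-scale grid sizes have lobe-like extents, so the lobe range is the
#'   default.
#' @param seed integer; the single source of all randomness in the cohort.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(adolescent_female = 11, adolescent_male = 6,
                              adult_female = 7, adult_male = 7),
                        size = 64,
                        fold_frequency = list(adolescent = c(mean = 6, sd = 0.5),
                                              adult = c(mean = 5.5, sd = 0.5)),
                        thickness = list(adolescent = c(mean = 3, sd = 0.2),
                                         adult = c(mean = 3, sd = 0.2)),
                        amplitude = 6,
                        jitter = 0.15,
                        scale_kind = "lobe",
                        seed = 1L) {
  cells <- c("adolescent_female", "adolescent_male", "adult_female", "adult_male")
  stopifnot(all(names(n) %in% cells))
  n <- n[intersect(cells, names(n))]
  n <- n[n > 0]
  if (length(n) == 0) abort("Cohort has no subjects.")
  if (any(n < 2)) abort("Each simulated cell needs at least 2 subjects.")
  for (par in list(fold_frequency, thickness)) {
    stopifnot(all(c("adolescent", "adult") %in% names(par)))
    for (g in c("adolescent", "adult")) {
      if (is.na(par[[g]]["sd"]) || par[[g]]["sd"] < 0) {
        abort("Parameter distributions need a non-negative sd.")
      }
    }
  }
  structure(
    list(n = n, size = as.integer(size), fold_frequency = fold_frequency,
         thickness = thickness, amplitude = amplitude, jitter = jitter,
         scale_kind = scale_kind, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a two-group phantom cohort and measure it
#'
#' Draws per-subject folded-ribbon parameters from the group distributions
#' of a [cohort_spec()] (all randomness flows from the single spec seed;
#' identical seed gives an identical table), builds one phantom per subject
#' as a whole-brain surrogate (region label `"WB"`), and computes the
#' requested measures.
#'
#' @param spec a [cohort_spec()].
#' @param measures subset of
#'   `c("fd_bc", "fd_mb", "volume_mm3", "surface_mm2")`.
#' @param keep_masks if `TRUE`, also return the per-subject masks (memory:
#'   `size^3` logicals each).
#' @return A list with elements `cohort` (long tibble: `subject_id`,
#'   `group`, `sex`, `region`, `measure`, `value`), `params` (per-subject
#'   drawn parameters) and, if requested, `masks` (named list of
#'   [binary_mask()]).
#' @export
simulate_cohort <- function(spec,
                            measures = c("fd_bc", "fd_mb", "volume_mm3",
                                         "surface_mm2"),
                            keep_masks = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  measures <- match.arg(measures, several.ok = TRUE)

  cells <- tibble(
    cell = names(spec$n),
    n = as.integer(spec$n),
    group = sub("_.*$", "", names(spec$n)),
    sex = sub("^.*_", "", names(spec$n))
  )
  subjects <- tidyr::uncount(cells, .data$n, .remove = FALSE)
  subjects <- dplyr::group_by(subjects, .data$cell)
  subjects <- dplyr::mutate(subjects, idx = dplyr::row_number())
  subjects <- dplyr::ungroup(subjects)
  subjects$subject_id <- sprintf("%s_%02d", subjects$cell, subjects$idx)

  ns <- nrow(subjects)
  draws <- with_preserved_seed(spec$seed, {
    f <- numeric(ns)
    th <- numeric(ns)
    # draws are truncated at +/- 2.5 sd so extreme subjects cannot push the
    # ribbon outside its grid
    rtrunc <- function(mean, sd) mean + sd * max(min(rnorm(1), 2.5), -2.5)
    for (i in seq_len(ns)) {
      g <- subjects$group[i]
      f[i] <- rtrunc(spec$fold_frequency[[g]]["mean"],
                     spec$fold_frequency[[g]]["sd"])
      th[i] <- rtrunc(spec$thickness[[g]]["mean"], spec$thickness[[g]]["sd"])
    }
    list(f = pmax(f, 0), th = pmax(th, 1),
         sub_seed = sample.int(.Machine$integer.max - 1L, ns))
  })
  subjects$fold_frequency <- draws$f
  subjects$thickness <- draws$th
  subjects$mask_seed <- draws$sub_seed

  masks <- if (keep_masks) vector("list", ns) else NULL
  rows <- vector("list", ns)
  for (i in seq_len(ns)) {
    mask <- make_folded_ribbon(spec$size, subjects$fold_frequency[i],
                               spec$amplitude, subjects$thickness[i],
                               seed = subjects$mask_seed[i],
                               jitter = spec$jitter)
    vals <- c(
      if ("fd_bc" %in% measures)
        c(fd_bc = compute_fd(mask, "BC", spec$scale_kind)$D),
      if ("fd_mb" %in% measures)
        c(fd_mb = compute_fd(mask, "MB", spec$scale_kind)$D),
      if ("volume_mm3" %in% measures) c(volume_mm3 = gm_volume(mask)),
      if ("surface_mm2" %in% measures) c(surface_mm2 = gm_surface_area(mask))
    )
    rows[[i]] <- tibble(
      subject_id = subjects$subject_id[i],
      group = subjects$group[i],
      sex = subjects$sex[i],
      region = "WB",
      measure = names(vals),
      value = unname(vals)
    )
    if (keep_masks) masks[[i]] <- mask
  }
  if (keep_masks) names(masks) <- subjects$subject_id
  out <- list(
    cohort = dplyr::bind_rows(rows),
    params = subjects[, c("subject_id", "group", "sex", "fold_frequency",
                          "thickness", "mask_seed")]
  )
  if (keep_masks) out$masks <- masks
  out
}
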
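#' Mann-Whitney U test (SPSS-style reporting convention)
#'
#' Computes U1 from the midrank sum of the first sample,
#' U1 = R1 - n1(n1+1)/2, and reports U = min(U1, U2) -- the convention of
#' standard statistical packages. The two-tailed p-value is exact (from the
#' Wilcoxon rank-sum distribution, equivalent to enumerating all
#' choose(n1+n2, n1) group assignments) when n1+n2 <= 16 and there are no
#' ties; otherwise it uses the tie-corrected normal approximation without
#' continuity correction, the asymptotic convention of the major
#' statistical packages (e.g. `p = 0.892` at `U = 37` for groups of 11 and
#' 7).
#'
#' @param a,b numeric samples (non-empty, finite).
#' @return A list with elements `U`, `p`, `U1`, `U2`, `exact` (logical).
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("Both samples must be non-empty.")
  if (anyNA(a) || anyNA(b) || any(!is.finite(c(a, b)))) {
    abort("Samples must be finite with no missing values.")
  }
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  ties <- any(duplicated(pooled))
  exact <- !ties && (n1 + n2) <= 16

  if (exact) {
    # two-tailed: double the smaller tail of the exact U distribution
    p <- if (U1 > n1 * n2 / 2) {
      2 * pwilcox(U1 - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * pwilcox(U1, n1, n2)
    }
    p <- min(p, 1)
  } else {
    # tie-corrected normal approximation, no continuity correction (the
    # asymptotic two-tailed significance of the major statistical packages)
    N <- n1 + n2
    tt <- table(pooled)
    tie_term <- sum(tt^3 - tt) / (N * (N - 1))
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- abs(U1 - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(2 * pnorm(z, lower.tail = FALSE), 1)
    }
  }
  list(U = U, p = p, U1 = U1, U2 = U2, exact = exact)
}

#' Pearson correlation with two-tailed p-value
#'
#' Standard product-moment correlation; the p-value comes from the t
#' transform with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, each with nonzero
#'   variance.
#' @param x_name,y_name labels recorded in the output.
#' @return A one-row tibble with columns `x_name`, `y_name`, `n`, `R`, `p`.
#' @export
pearson_r <- function(x, y, x_name = "x", y_name = "y") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Pearson correlation requires n >= 3.")
  if (sd(x) == 0) abort(paste0("Zero variance in '", x_name, "'."))
  if (sd(y) == 0) abort(paste0("Zero variance in '", y_name, "'."))
  R <- cor(x, y)
  p <- if (abs(R) >= 1) {
    0
  } else {
    tstat <- R * sqrt((n - 2) / (1 - R^2))
    2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  tibble(x_name = x_name, y_name = y_name, n = n, R = R, p = p)
}

#' Two-group comparison for one region and measure
#'
#' Filters a long-format cohort table to one sex, splits it into the
#' adolescent and adult groups, and reports group means and sample standard
#' deviations (n - 1 denominator) with the Mann-Whitney U test -- one row of
#' an age-comparison table.
#'
#' @param cohort a long cohort tibble with columns `subject_id`, `group`
#'   (`"adolescent"`/`"adult"`), `sex` (`"female"`/`"male"`), `region`,
#'   `measure`, `value`.
#' @param sex which sex stratum to compare.
#' @param region region name (e.g. `"Frontal LH"`, `"WB"`).
#' @param measure_name one of `"fd_bc"`, `"fd_mb"`, `"volume_mm3"`,
#'   `"surface_mm2"`.
#' @return A one-row tibble: `region`, `measure`, `n1`, `mean1`, `sd1`,
#'   `n2`, `mean2`, `sd2` (1 = adolescent, 2 = adult), `U`, `p`,
#'   `direction` (group with the larger mean).
#' @export
compare_groups <- function(cohort, sex, region, measure_name) {
  cohort <- as_tibble(cohort)
  sub <- dplyr::filter(cohort, .data$sex == !!sex, .data$region == !!region,
                       .data$measure == !!measure_name)
  g1 <- sub$value[sub$group == "adolescent"]
  g2 <- sub$value[sub$group == "adult"]
  if (length(g1) == 0 || length(g2) == 0) {
    empty <- if (length(g1) == 0) "adolescent" else "adult"
    abort(paste0("No ", empty, " ", sex, " subjects with measure '",
                 measure_name, "' in region '", region, "'."))
  }
  mw <- mann_whitney_u(g1, g2)
  tibble(
    region = region, measure = measure_name,
    n1 = length(g1), mean1 = mean(g1), sd1 = sd(g1),
    n2 = length(g2), mean2 = mean(g2), sd2 = sd(g2),
    U = mw$U, p = mw$p,
    direction = if (mean(g1) >= mean(g2)) "adolescent" else "adult"
  )
}

#' FD-volume Pearson correlations per hemisphere and whole brain
#'
#' Pools adolescent and adult subjects of one sex and correlates grey-matter
#' volume with fractal dimension region-by-region for the matched pairings
#' (GM-LH with FD-LH, GM-RH with FD-RH, GM-WB with FD-WB). Regions absent
#' from the table (e.g. single-region simulated cohorts) are skipped with a
#' warning.
#'
#' @inheritParams compare_groups
#' @param fd_measure which FD measure to correlate (`"fd_bc"` or `"fd_mb"`).
#' @param regions regions to pair (defaults to LH, RH, WB).
#' @return A tibble with one row per available pairing: `x_name` (e.g.
#'   `"GM-LH"`), `y_name` (e.g. `"FD-LH"`), `n`, `R`, `p`.
#' @export
fd_volume_correlations <- function(cohort, sex, fd_measure = "fd_bc",
                                   regions = c("LH", "RH", "WB")) {
  cohort <- as_tibble(cohort)
  sub <- dplyr::filter(cohort, .data$sex == !!sex,
                       .data$region %in% !!regions,
                       .data$measure %in% c("volume_mm3", !!fd_measure))
  wide <- tidyr::pivot_wider(sub, id_cols = c("subject_id", "region"),
                             names_from = "measure", values_from = "value")
  out <- list()
  for (rg in regions) {
    w <- wide[wide$region == rg, , drop = FALSE]
    if (nrow(w) == 0 || !all(c("volume_mm3", fd_measure) %in% names(w))) {
      warn(paste0("Region '", rg, "' not available for FD-volume correlation; skipped."))
      next
    }
    res <- tryCatch(
      pearson_r(w$volume_mm3, w[[fd_measure]],
                x_name = paste0("GM-", rg),
                y_name = paste0("FD-", rg)),
      error = function(e) {
        warn(paste0("FD-volume correlation unavailable for region '", rg,
                    "': ", conditionMessage(e)))
        NULL
      }
    )
    out[[rg]] <- res
  }
  if (length(out) == 0) {
    return(tibble(x_name = character(), y_name = character(),
                  n = integer(), R = numeric(), p = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Full comparison table across regions and measures
#'
#' Runs [compare_groups()] for every available (region, measure) cell of one
#' sex stratum and adds a Holm-adjusted p-value (`p_holm`, adjusted within
#' each measure family; an extension over raw per-region reporting) and a
#' `significant` flag at alpha = 0.05 on the raw p.
#'
#' @inheritParams compare_groups
#' @param regions,measures subsets to compare; defaults to everything
#'   present in the table.
#' @return A tibble with one row per (region, measure), columns as in
#'   [compare_groups()] plus `sex`, `p_holm`, `significant`.
#' @export
compare_all_groups <- function(cohort, sex, regions = NULL, measures = NULL) {
  cohort <- as_tibble(cohort)
  sub <- dplyr::filter(cohort, .data$sex == !!sex)
  if (nrow(sub) == 0) abort(paste0("No subjects with sex '", sex, "'."))
  if (is.null(regions)) regions <- unique(sub$region)
  if (is.null(measures)) measures <- unique(sub$measure)
  rows <- list()
  for (ms in measures) {
    for (rg in regions) {
      if (!any(sub$region == rg & sub$measure == ms)) next
      rows[[paste(ms, rg)]] <- compare_groups(sub, sex, rg, ms)
    }
  }
  out <- dplyr::bind_rows(rows)
  out$sex <- sex
  out <- dplyr::group_by(out, .data$measure)
  out <- dplyr::mutate(out, p_holm = p.adjust(.data$p, method = "holm"))
  out <- dplyr::ungroup(out)
  out$significant <- out$p < 0.05
  dplyr::relocate(out, "sex")
}
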
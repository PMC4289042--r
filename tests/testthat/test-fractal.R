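test_that("box counts match closed forms on solids and points", {
  blk8 <- make_solid_block(8)
  expect_equal(box_count(blk8, 2), 64)      # (8/2)^3
  expect_equal(box_count(blk8, 8), 1)
  expect_equal(box_count(blk8, 1), 512)

  g <- array(FALSE, c(9, 9, 9))
  g[1:9, 1:9, 1:9] <- TRUE
  expect_equal(box_count(binary_mask(g), 2), 125)  # ceil(9/2)^3, partial cells count

  single <- array(FALSE, c(7, 7, 7))
  single[4, 4, 4] <- TRUE
  sm <- binary_mask(single)
  for (r in c(1, 2, 5, 9)) expect_equal(box_count(sm, r), 1)

  expect_error(box_count(binary_mask(array(FALSE, c(4, 4, 4))), 2), "empty")
  expect_error(box_count(blk8, 0), "positive")
})

test_that("box-count series agrees with the brute-force lattice oracle", {
  blk8 <- make_solid_block(8)
  s <- box_count_series(blk8, 2, 8)
  expect_equal(s$r, 2:8)
  expect_equal(s$measure,
               vapply(2:8, function(r) as.numeric(oracle_box_count(blk8$grid, r)),
                      numeric(1)))

  set.seed(7)
  for (i in 1:8) {
    m <- random_mask(20, p = 0.15)
    rs <- 1:10
    fast <- vapply(rs, function(r) box_count(m, r), numeric(1))
    slow <- vapply(rs, function(r) as.numeric(oracle_box_count(m$grid, r)), numeric(1))
    expect_equal(fast, slow)
  }
})

test_that("series edge cases: r = 1 equals voxel count, truncation warns", {
  set.seed(11)
  m <- random_mask(15, p = 0.3)
  s <- box_count_series(m, 1, 5)
  expect_equal(s$measure[1], m$voxel_count)

  small <- make_solid_block(8)
  expect_warning(s2 <- box_count_series(small, 2, 30), "truncated")
  expect_equal(max(s2$r), 8)
})

test_that("box_count is invariant under arbitrary integer translations", {
  set.seed(3)
  pat <- array(runif(5 * 4 * 6) < 0.4, c(5, 4, 6))
  if (!any(pat)) pat[1, 1, 1] <- TRUE
  count_at <- function(off) {
    g <- array(FALSE, c(24, 24, 24))
    g[off[1] + 1:5, off[2] + 1:4, off[3] + 1:6] <- pat
    vapply(1:7, function(r) box_count(binary_mask(g), r), numeric(1))
  }
  base <- count_at(c(0, 0, 0))
  for (off in list(c(1, 2, 3), c(7, 0, 5), c(11, 13, 2))) {
    expect_equal(count_at(off), base)
  }
})

test_that("dilation counts match lattice-ball enumeration", {
  g <- array(FALSE, c(5, 5, 5))
  g[3, 3, 3] <- TRUE
  sv <- binary_mask(g)
  expect_equal(dilate_count(sv, 0), 1)
  expect_equal(dilate_count(sv, 1), 7)    # |{x^2+y^2+z^2 <= 1}|
  expect_equal(dilate_count(sv, 2), 33)   # |{x^2+y^2+z^2 <= 4}|
  s <- dilation_series(sv, 1, 3)
  expect_equal(s$measure, c(7, 33, 123))
  expect_equal(s$measure, vapply(1:3, function(r) {
    as.numeric(oracle_dilate_count_mindist(g, r))
  }, numeric(1)))
})

test_that("dilation agrees with the brute-force distance oracle on random masks", {
  set.seed(19)
  for (i in 1:8) {
    m <- random_mask(12, p = 0.1)
    for (r in 1:4) {
      expect_equal(dilate_count(m, r), oracle_dilate_count(m$grid, r))
    }
  }
})

test_that("dilation of a large block grows like surface area times radius", {
  blk <- make_solid_block(40)
  v0 <- blk$voxel_count
  s <- dilation_series(blk, 1, 3)
  for (i in 1:3) {
    ratio <- (s$measure[i] - v0) / (6 * 40^2 * s$r[i])
    expect_gt(ratio, 0.8)
    expect_lt(ratio, 1.2)
  }
  expect_true(all(diff(s$measure) > 0))   # dilation is strictly inclusive
})

test_that("log-log fits recover exact power laws and enforce preconditions", {
  r <- 2:10
  bc <- tibble::tibble(method = "BC", r = r, measure = 1000 * r^-3)
  expect_equal(fit_fd(bc)$D, 3, tolerance = 1e-12)
  mb <- tibble::tibble(method = "MB", r = 1:7, measure = 50 * (1:7))
  fit <- fit_fd(mb)
  expect_equal(fit$D, 2, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)

  expect_error(fit_fd(bc[1:2, ]), "3 scales")
  bad_mb <- tibble::tibble(method = "MB", r = 1:4, measure = c(5, 4, 6, 7))
  expect_error(fit_fd(bad_mb), "non-decreasing")
  bad_bc <- tibble::tibble(method = "BC", r = 1:4, measure = c(5, 6, 7, 8))
  expect_error(fit_fd(bad_bc), "must not increase")
})

test_that("scale ranges follow the method and region kind", {
  expect_equal(fd_scale_range("BC", "whole_brain"), c(2L, 30L))
  expect_equal(fd_scale_range("BC", "hemisphere"), c(2L, 30L))
  expect_equal(fd_scale_range("BC", "lobe"), c(2L, 14L))
  for (kind in c("whole_brain", "hemisphere", "lobe")) {
    expect_equal(fd_scale_range("MB", kind), c(1L, 7L))
  }
})

test_that("compute_fd is deterministic and matches frozen phantom values", {
  blk <- make_solid_block(64)
  a <- compute_fd(blk, "BC", "lobe")
  b <- compute_fd(blk, "BC", "lobe")
  expect_identical(a$D, b$D)
  expect_identical(a$series, b$series)

  # frozen values from the brute-force-validated implementation
  expect_equal(a$D, 2.8747, tolerance = 1e-4)
  expect_equal(compute_fd(blk, "MB", "lobe")$D, 2.7603, tolerance = 1e-4)
  slab <- make_slab(64, 1)
  expect_equal(compute_fd(slab, "BC", "lobe")$D, 1.9165, tolerance = 1e-4)
  expect_equal(compute_fd(slab, "MB", "lobe")$D, 2.0436, tolerance = 1e-4)
})

test_that("estimated dimension orders line < slab < sponge < block", {
  ests <- list(
    line = make_line(64), slab = make_slab(64, 1),
    sponge = make_menger_sponge(3), block = make_solid_block(64)
  )
  for (meth in c("BC", "MB")) {
    d <- vapply(ests, function(m) compute_fd(m, meth, "lobe")$D, numeric(1))
    expect_true(all(diff(d) > 0),
                label = paste(meth, "ordering:", paste(round(d, 3), collapse = " < ")))
  }
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- compute_fd(make_solid_block(16), "BC", "lobe")
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n_points)
  expect_true(all(c("log_r", "log_measure", "fitted") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$D, fit$D)
  expect_equal(gl$n_points, fit$n_points)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("scale series export has the documented schema", {
  s <- box_count_series(make_solid_block(16), 2, 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scale_series(s, path, region = "WB")
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(out),
               c("region", "method", "r", "measure", "log_r", "log_measure"))
  expect_equal(out$log_measure, log(out$measure))
})
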
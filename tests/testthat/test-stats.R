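test_that("Mann-Whitney U follows the min(U1, U2) reporting convention", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)          # 2 of 20 assignments as extreme
  expect_true(res$exact)

  tied <- mann_whitney_u(c(5, 5), c(5, 5))
  expect_equal(tied$U, 2)           # n1*n2/2
  expect_equal(tied$p, 1)

  a <- 101:111; b <- 1:7            # n = 11 vs 7, complete separation
  res2 <- mann_whitney_u(a, b)
  expect_equal(res2$U, 0)
  expect_equal(res2$U1 + res2$U2, 77)
  expect_false(res2$exact)          # n1+n2 = 18 > 16: normal approximation
  expect_lt(res2$p, 0.001)
})

test_that("exact p equals brute-force enumeration on tie-free samples", {
  set.seed(23)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- sample(1:60, n1 + n2)
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    res <- mann_whitney_u(a, b)
    expect_true(res$exact)
    expect_equal(res$p, oracle_mw_exact_p(a, b))
  }
})

test_that("U and p are symmetric and rank-invariant", {
  set.seed(31)
  for (i in 1:10) {
    a <- sample(1:100, 5); b <- sample(101:200, 4) - 100.5
    r1 <- mann_whitney_u(a, b); r2 <- mann_whitney_u(b, a)
    expect_equal(r1$U, r2$U)
    expect_equal(r1$p, r2$p)
    # strictly monotone transform of the pooled values
    r3 <- mann_whitney_u(exp(a / 50), exp(b / 50))
    expect_equal(r1$U, r3$U)
    expect_equal(r1$p, r3$p)
  }
})

test_that("Pearson correlation matches hand-computed values and affine invariance", {
  x <- c(0.3, 1.7, 2, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$R, 1)
  expect_equal(pearson_r(x, -x)$R, -1)
  res <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$R, 0.8)
  expect_equal(res$n, 4)
  expect_equal(res$p, unname(stats::cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))$p.value))

  set.seed(2)
  u <- rnorm(10); v <- rnorm(10)
  expect_equal(pearson_r(u, v)$R, pearson_r(3 * u + 2, 0.5 * v - 7)$R)
  expect_error(pearson_r(rep(1, 5), rnorm(5), x_name = "vol"), "vol")
})

test_that("group comparisons report means, sds and the U test per stratum", {
  mk <- function(values, group, sex) {
    tibble::tibble(
      subject_id = paste0(group, sex, seq_along(values)),
      group = group, sex = sex, region = "WB", measure = "fd_bc",
      value = values
    )
  }
  coh <- dplyr::bind_rows(
    mk(2.5 + (1:6) / 100, "adolescent", "male"),
    mk(2.3 + (1:7) / 100, "adult", "male")
  )
  cmp <- compare_groups(coh, "male", "WB", "fd_bc")
  expect_equal(cmp$n1, 6); expect_equal(cmp$n2, 7)
  expect_equal(cmp$U, 0)
  expect_lt(cmp$p, 0.01)
  expect_equal(cmp$direction, "adolescent")
  expect_equal(cmp$mean1, mean(2.5 + (1:6) / 100))
  expect_equal(cmp$sd1, sd(2.5 + (1:6) / 100))

  same <- dplyr::bind_rows(
    mk(c(1, 2, 3, 4), "adolescent", "female"),
    mk(c(1, 2, 3, 4), "adult", "female")
  )
  cmp2 <- compare_groups(same, "female", "WB", "fd_bc")
  expect_equal(cmp2$p, 1)
  expect_equal(cmp2$U, 8)           # n1*n2/2

  expect_error(compare_groups(coh, "female", "WB", "fd_bc"), "female")
})

test_that("the comparison table carries Holm adjustment and significance flags", {
  set.seed(4)
  rows <- list()
  for (rg in c("LH", "RH", "WB")) {
    for (grp in c("adolescent", "adult")) {
      shift <- if (grp == "adolescent" && rg == "WB") 3 else 0
      n <- if (grp == "adolescent") 8 else 7
      rows[[paste(rg, grp)]] <- tibble::tibble(
        subject_id = paste0(grp, rg, 1:n), group = grp, sex = "female",
        region = rg, measure = "fd_bc", value = rnorm(n) + shift
      )
    }
  }
  tab <- compare_all_groups(dplyr::bind_rows(rows), "female")
  expect_setequal(
    names(tab),
    c("sex", "region", "measure", "n1", "mean1", "sd1", "n2", "mean2", "sd2",
      "U", "p", "p_holm", "direction", "significant")
  )
  expect_true(all(tab$p_holm >= tab$p))
  expect_equal(tab$significant, tab$p < 0.05)
})

test_that("FD-volume correlations pair matched regions and detect exact dependence", {
  subj <- paste0("s", 1:8)
  rows <- list()
  set.seed(6)
  for (rg in c("LH", "RH", "WB")) {
    vol <- rnorm(8, 3e5, 2e4)
    rows[[rg]] <- dplyr::bind_rows(
      tibble::tibble(subject_id = subj, group = "adolescent", sex = "female",
                     region = rg, measure = "volume_mm3", value = vol),
      tibble::tibble(subject_id = subj, group = "adolescent", sex = "female",
                     region = rg, measure = "fd_bc", value = 2 + vol * 1e-6)
    )
  }
  out <- fd_volume_correlations(dplyr::bind_rows(rows), "female")
  expect_equal(out$x_name, c("GM-LH", "GM-RH", "GM-WB"))
  expect_equal(out$y_name, c("FD-LH", "FD-RH", "FD-WB"))
  expect_equal(out$R, rep(1, 3))

  # single-region table: missing pairings are skipped with a warning
  single <- dplyr::bind_rows(rows)[dplyr::bind_rows(rows)$region == "WB", ]
  expect_warning(out2 <- fd_volume_correlations(single, "female"), "LH")
  expect_equal(out2$x_name, "GM-WB")
})

test_that("independent FD and volume yield nominal false-positive rates", {
  set.seed(77)
  hits <- 0
  for (i in 1:500) {
    if (pearson_r(rnorm(18), rnorm(18))$p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 500, 0.03)
  expect_lt(hits / 500, 0.07)
})

test_that("the asymptotic p reproduces the standard package convention", {
  # tie-free samples constructed to hit a prescribed U1, n = 11 vs 7 (N = 18
  # so the asymptotic branch applies); p-values frozen from the
  # z = (U - n1 n2 / 2) / sqrt(n1 n2 (N + 1) / 12) mapping that the major
  # packages print
  mk <- function(U1, n1, n2) {
    b <- as.numeric(seq_len(n2))
    beats <- integer(n1)
    left <- U1
    for (i in seq_len(n1)) {
      beats[i] <- min(n2, left)
      left <- left - beats[i]
    }
    a <- ifelse(beats == 0, -seq_len(n1), beats + 0.5 + seq_len(n1) * 1e-4)
    list(a = a, b = b)
  }
  cases <- list(c(37, 0.892), c(27, 0.298), c(11, 0.013), c(12, 0.016),
                c(4, 0.002))
  for (cs in cases) {
    s <- mk(cs[1], 11, 7)
    res <- mann_whitney_u(s$a, s$b)
    expect_equal(res$U, cs[1])
    expect_equal(round(res$p, 3), cs[2])
  }
})

test_that("the U test detects a 1.5-sd location shift with substantial power", {
  # at n = 11 vs 7, alpha = 0.05 the discrete rejection region is U <= 16
  # and the true power at a 1.5-sd normal shift is ~0.78; assert a level the
  # test provably exceeds
  set.seed(55)
  rej <- 0
  for (i in 1:300) {
    if (mann_whitney_u(rnorm(11, 1.5), rnorm(7))$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 300, 0.70)
})
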
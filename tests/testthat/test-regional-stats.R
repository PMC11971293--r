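test_that("Mann-Whitney matches hand cases and the enumeration oracle", {
  # identical multisets: symmetric, p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # fully separated small samples: U = 0, exact two-sided p = 2/20
  res <- mann_whitney(1:3, 4:6)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  # exhaustive oracle on random untied fixtures with n_a + n_b <= 10
  set.seed(20)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1:50, n1 + n2)  # distinct -> no ties
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    expect_equal(mann_whitney(a, b)$p_value,
                 enumeration_pvalue(a, b, mw_stat), tolerance = 1e-12)
  }
})

test_that("Ansari-Bradley matches the enumeration oracle and detects scale", {
  expect_equal(ansari_bradley(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 1)
  expect_error(ansari_bradley(1, 1:4), "at least two")
  set.seed(21)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1:50, n1 + n2)
    a <- v[seq_len(n1)]; b <- v[-seq_len(n1)]
    expect_equal(ansari_bradley(a, b)$p_value,
                 enumeration_pvalue(a, b, ab_stat), tolerance = 1e-12)
  }
  # power against a pure scale alternative at n = 30 (reduced-replicate form
  # of the full power simulation; the acceptance suite runs it larger)
  hits <- replicate(50, {
    a <- rnorm(30)
    b <- 10 * (rnorm(30))
    ansari_bradley(a, b)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("ansari_bradley large-sample path agrees with the exact path", {
  # same untied data evaluated by both routes should give similar p
  set.seed(22)
  a <- rnorm(14); b <- rnorm(14) * 1.2
  exact <- ansari_bradley(a, b)$p_value       # n = 28 <= 30 -> exact
  big <- ansari_bradley(c(a, 100), c(b, -100))$p_value
  expect_true(is.finite(exact) && is.finite(big))
  # approximation against enumeration on a moderate fixture
  v <- sample(1:100, 12)
  a <- v[1:6]; b <- v[7:12]
  p_exact <- enumeration_pvalue(a, b, ab_stat)
  r <- rank(c(a, b)); sc <- pmin(r, 13 - r)
  AB <- sum(sc[1:6])
  e <- 6 * mean(sc); vv <- 36 / (144 * 11) * (12 * sum(sc^2) - sum(sc)^2)
  p_norm <- 2 * pnorm(-abs(AB - e) / sqrt(vv))
  expect_lt(abs(p_exact - p_norm), 0.15)  # sanity: routes are consistent
})

test_that("coefficient of variation follows the signed-mean definition", {
  expect_equal(coef_variation(rep(5, 10)), 0)
  expect_equal(coef_variation(c(10, 20)), 100 * sd(c(10, 20)) / 15)
  x <- rgamma(20, 3)
  expect_equal(coef_variation(3 * x), coef_variation(x))
  expect_lt(coef_variation(-x), 0)  # signed mean
  expect_error(coef_variation(c(-1, 1)), "zero mean")
})

test_that("compare_regions dispatches on the requested test", {
  vals <- list(EAST = rnorm(10), NORTHWEST = rnorm(12))
  mw <- compare_regions(vals, "MANN_WHITNEY")
  ab <- compare_regions(vals, "ANSARI_BRADLEY")
  expect_equal(mw$test, "MANN_WHITNEY")
  expect_equal(ab$test, "ANSARI_BRADLEY")
  expect_equal(mw$n_a, 10); expect_equal(mw$n_b, 12)
  expect_error(compare_regions(list(EAST = 1:3)), "NORTHWEST")
})

make_two_region_occs <- function(n_e = 12, n_nw = 10, span = 20) {
  rows <- list()
  for (i in seq_len(n_e))
    rows[[length(rows) + 1]] <- occ_row(30 + 5 * i, 30 + 5 * i + span,
                                        lon = 35 + (i %% 4), lat = 2 + (i %% 3),
                                        site = sprintf("E%02d", i), region = "EAST")
  for (i in seq_len(n_nw))
    rows[[length(rows) + 1]] <- occ_row(40 + 6 * i, 40 + 6 * i + span,
                                        lon = -5 + (i %% 4), lat = 25 + (i %% 3),
                                        site = sprintf("N%02d", i), region = "NORTHWEST")
  do.call(rbind, rows)
}

test_that("sensitivity permutation is deterministic and handles constant cubes", {
  cube <- iid_cube(nt = 200, seed = 31)
  occs <- make_two_region_occs()
  s1 <- sensitivity_permutation(occs, cube, "x", "MANN_WHITNEY",
                                n_iter = 60, seed = 5)
  s2 <- sensitivity_permutation(occs, cube, "x", "MANN_WHITNEY",
                                n_iter = 60, seed = 5)
  expect_identical(s1$statistics, s2$statistics)
  expect_identical(s1$p_values, s2$p_values)
  # occupation order invariance
  s3 <- sensitivity_permutation(occs[sample(nrow(occs)), ], cube, "x",
                                "MANN_WHITNEY", n_iter = 60, seed = 5)
  expect_identical(s1$statistics, s3$statistics)
  expect_equal(length(s1$statistics), 60)
  # a cube constant in time reproduces the mid-age result in every iteration
  ccube <- iid_cube(nt = 1, seed = 32)
  ccube2 <- climate_cube(ccube$lon_axis, ccube$lat_axis, 0:199,
                         list(x = array(rep(ccube$variables$x[1, , ], each = 200),
                                        c(200, dim(ccube$land_mask)))),
                         ccube$land_mask, ccube$resolution)
  s4 <- sensitivity_permutation(occs, ccube2, "x", "MANN_WHITNEY",
                                n_iter = 40, seed = 5)
  expect_true(all(s4$statistics == s4$mid_age_statistic))
  expect_equal(s4$percentile_of_mid_statistic, 50)  # mean-rank tie rule
})

test_that("region boxes carry the study bounding boxes", {
  bx <- region_boxes()
  expect_equal(unname(bx$EAST), c(30, 55, -9, 20))
  expect_equal(unname(bx$NORTHWEST), c(-15, 35, 18, 39))
})

test_that("background resampling is deterministic and directional", {
  cube <- iid_cube(nt = 120, seed = 33)
  set.seed(40)
  obs <- rnorm(25)
  b1 <- background_resample(cube, "x", region_boxes()$EAST, obs, 0, 119,
                            n_iter = 50, seed = 9)
  b2 <- background_resample(cube, "x", region_boxes()$EAST, obs, 0, 119,
                            n_iter = 50, seed = 9)
  expect_identical(b1$p_values, b2$p_values)
  # observations far above the background: all significant, direction +1
  b3 <- background_resample(cube, "x", region_boxes()$EAST, obs + 5, 0, 119,
                            n_iter = 50, seed = 9)
  expect_gte(b3$n_significant / b3$n_iter, 0.95)
  expect_equal(b3$direction_summary, 1)
  expect_true(all(b3$directions == 1))
  # no land in box
  sea <- constant_cube(mask = matrix(FALSE, 3, 4))
  expect_error(background_resample(sea, "x", c(0, 2, 0, 2), obs, 0, 10,
                                   n_iter = 5, seed = 1), "no land cells")
})
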
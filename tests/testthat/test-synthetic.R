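# a small, fast generator configuration used throughout
small_config <- function(...) {
  generator_config(resolution = 4, t_max = 150, sea_fraction = 0.15,
                   n_sites = c(EAST = 6, NORTHWEST = 5),
                   occ_lambda = c(EAST = 0.5, NORTHWEST = 1.5),
                   seed = 42, ...)
}

test_that("generator config validates its inputs", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(noise_fraction = c(EAST = 1.2, NORTHWEST = 0.5)))
  expect_error(generator_config(sea_fraction = 1))
  expect_error(generator_config(n_sites = c(EAST = 0, NORTHWEST = 3)))
})

test_that("cube generation is reproducible and respects the mask", {
  cfg <- small_config()
  a <- make_climate_cube(cfg)
  b <- make_climate_cube(cfg)
  expect_identical(a$cube$variables$bio01, b$cube$variables$bio01)
  sea <- which(!a$cube$land_mask, arr.ind = TRUE)
  if (nrow(sea))
    expect_true(all(is.na(a$cube$variables$bio12[, sea[1, 1], sea[1, 2]])))
  land <- which(a$cube$land_mask, arr.ind = TRUE)
  expect_true(all(is.finite(a$cube$variables$npp[, land[1, 1], land[1, 2]])))
  # truth covers every land cell
  expect_true(all(is.finite(a$truth$f_noise[a$cube$land_mask])))
})

test_that("emitted bio variables derive exactly from emitted monthly stacks", {
  cfg <- small_config(emit_monthly = TRUE)
  sim <- make_climate_cube(cfg)
  cube <- sim$cube
  land <- which(cube$land_mask, arr.ind = TRUE)
  set.seed(1)
  for (p in sample(nrow(land), 5)) {
    i <- land[p, 1]; j <- land[p, 2]
    for (t in c(1, 50)) {
      temp <- sapply(1:12, function(m)
        cube$variables[[sprintf("temp_%02d", m)]][t, i, j])
      prec <- sapply(1:12, function(m)
        cube$variables[[sprintf("prec_%02d", m)]][t, i, j])
      expect_equal(cube$variables$bio01[t, i, j], bio01(temp), tolerance = 1e-12)
      expect_equal(cube$variables$bio04[t, i, j], bio04(temp), tolerance = 1e-12)
      expect_equal(cube$variables$bio12[t, i, j], bio12(prec), tolerance = 1e-12)
      expect_equal(cube$variables$bio15[t, i, j], bio15(prec), tolerance = 1e-12)
    }
  }
})

test_that("precession phase inverts across the equator", {
  t <- 0:300
  for (lon in c(35, 40.5)) {
    north <- synthetic_precession(t, 5.3, lon)
    south <- synthetic_precession(t, -5.3, lon)
    expect_lte(cor(north, south), -0.95)
  }
})

test_that("noise fraction governs CVD variability recovery on cube cells", {
  # small ensemble; the full-scale recovery runs in the acceptance suite
  cfg <- generator_config(lon_range = c(30, 54), lat_range = c(0, 16),
                          resolution = 4, t_max = 300, sea_fraction = 0,
                          noise_fraction = 0, seed = 3)
  sim0 <- make_climate_cube(cfg)
  cfg1 <- generator_config(lon_range = c(30, 54), lat_range = c(0, 16),
                           resolution = 4, t_max = 300, sea_fraction = 0,
                           noise_fraction = 1, seed = 3)
  sim1 <- make_climate_cube(cfg1)
  pv <- function(sim, i, j)
    suppressWarnings(cvd_decompose(sim$cube$variables$bio01[, i, j]))$pct_variability
  cells <- cbind(c(1, 2, 3), c(1, 3, 5))
  pv0 <- mean(apply(cells, 1, function(rc) pv(sim0, rc[1], rc[2])))
  pv1 <- mean(apply(cells, 1, function(rc) pv(sim1, rc[1], rc[2])))
  expect_lt(pv0, 5)
  expect_gte(pv1, 90)
})

test_that("AR(1) noise option produces autocorrelated residual noise", {
  cfg <- small_config(noise_model = "AR1", ar1_rho = 0.8, noise_fraction = 1)
  sim <- make_climate_cube(cfg)
  land <- which(sim$cube$land_mask, arr.ind = TRUE)
  x <- sim$cube$variables$bio01[, land[1, 1], land[1, 2]]
  expect_gt(cor(x[-1], x[-length(x)]), 0.5)
})

test_that("occupation tables have the documented shape and reproducibility", {
  cfg <- small_config()
  cube <- make_climate_cube(cfg)$cube
  occ1 <- make_occupations(cfg, cube)
  occ2 <- make_occupations(cfg, cube)
  expect_identical(occ1, occ2)  # byte-identical under a fixed seed
  expect_named(occ1, c("site_id", "layer_id", "region", "lon", "lat",
                       "age", "age_sd"))
  expect_setequal(unique(occ1$region), c("EAST", "NORTHWEST"))
  norm <- normalize_occupations(occ1)
  dd <- dedupe_occupations(norm)
  expect_lt(nrow(dd), nrow(norm))  # engineered duplicates were collapsed
  # sites on land inside the region boxes
  bx <- region_boxes()
  half <- cfg$resolution / 2  # coordinates jitter within the chosen cell
  for (r in c("EAST", "NORTHWEST")) {
    g <- occ1[occ1$region == r, ]
    expect_true(all(g$lon >= bx[[r]][1] - half & g$lon <= bx[[r]][2] + half))
    expect_true(all(g$lat >= bx[[r]][3] - half & g$lat <= bx[[r]][4] + half))
  }
  # long-span engineering: at least the configured fraction of sites
  sites <- site_spans(dd)
  expect_gte(sum(sites$covers_precession),
             floor(0.5 * sum(cfg$n_sites)) - 1)
})

test_that("zero duplicate fraction makes dedupe the identity", {
  cfg <- small_config(duplicate_fraction = 0)
  cube <- make_climate_cube(cfg)$cube
  norm <- normalize_occupations(make_occupations(cfg, cube))
  dd <- dedupe_occupations(norm)
  expect_equal(nrow(dd), nrow(norm))
})

test_that("default site counts mirror the study inventories", {
  cfg <- generator_config()
  expect_equal(unname(cfg$n_sites["EAST"]), 37)
  expect_equal(unname(cfg$n_sites["NORTHWEST"]), 21)
})

test_that("insufficient land in a region box raises an error", {
  cfg <- small_config()
  tiny <- constant_cube(nlon = 2, nlat = 2)  # extent far from the boxes
  expect_error(make_occupations(cfg, tiny), "insufficient land")
})
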
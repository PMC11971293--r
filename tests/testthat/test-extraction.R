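test_that("locate_cell maps points to cells with the half-open edge rule", {
  cube <- constant_cube(nlon = 4, nlat = 3, res = 0.5)
  # cell centres at 0.25, 0.75, ...: a centre maps to its own cell
  expect_equal(unname(locate_cell(cube, 0.75, 0.25)), c(1, 2))
  # a shared edge belongs to the larger-index cell
  expect_equal(unname(locate_cell(cube, 0.5, 0.5)), c(2, 2))
  expect_error(locate_cell(cube, 5, 0.2), "outside")
  expect_error(locate_cell(cube, 0.2, -0.1), "outside")
  # outer far edge still belongs to the last cell
  expect_equal(unname(locate_cell(cube, 2.0, 1.5)), c(3, 4))
})

test_that("locate_cell honours descending latitude axes", {
  cube <- constant_cube(nlon = 4, nlat = 3, res = 0.5, lat_desc = TRUE)
  expect_equal(unname(locate_cell(cube, 0.25, 1.25)), c(1, 1))
  expect_equal(unname(locate_cell(cube, 0.25, 0.25)), c(3, 1))
})

test_that("nearest_land is identity on land, else closest with deterministic ties", {
  mask <- matrix(FALSE, 3, 3)
  mask[2, 1] <- TRUE; mask[2, 3] <- TRUE
  cube <- field_cube(matrix(1:9, 3, 3), mask = mask)
  expect_equal(unname(nearest_land(cube, 2, 1)), c(2, 1))
  # (2,2) is equidistant from (2,1) and (2,3): same latitude, one cell of
  # longitude either way; tie-break picks the smaller column
  expect_equal(unname(nearest_land(cube, 2, 2)), c(2, 1))
  # single nearest neighbour wins over the farther cell
  expect_equal(unname(nearest_land(cube, 1, 3)), c(2, 3))
  no_land <- field_cube(matrix(0, 2, 2), mask = matrix(FALSE, 2, 2))
  expect_error(nearest_land(no_land, 1, 1), "no land")
})

test_that("buffered_value averages the focal cell and in-grid land neighbours", {
  f <- matrix(as.numeric(1:12), 3, 4)  # column-major: f[i,j]
  cube <- field_cube(f)
  # interior cell: mean over full 3x3 block
  expect_equal(buffered_value(cube, "x", 2, 2, 0), mean(f[1:3, 1:3]))
  # corner cell: only 4 in-grid cells
  expect_equal(buffered_value(cube, "x", 1, 1, 0), mean(f[1:2, 1:2]))
  # constant field: buffered value equals the constant everywhere
  cc <- constant_cube(7)
  for (rc in list(c(1, 1), c(2, 2), c(3, 4)))
    expect_equal(buffered_value(cc, "x", rc[1], rc[2], 5), 7)
  # sea neighbours are excluded
  mask <- matrix(TRUE, 3, 4); mask[1, 2] <- FALSE; mask[2, 1] <- FALSE
  cube2 <- field_cube(f, mask = mask)
  nb <- f[1:2, 1:2]; nb <- nb[c(1, 4)]  # only (1,1) and (2,2) remain land
  expect_equal(buffered_value(cube2, "x", 1, 1, 0), mean(nb))
  expect_error(buffered_value(cube2, "x", 2, 1, 0), "sea")
})

test_that("occupation series snap to the 1 ka grid with inclusive bounds", {
  cube <- constant_cube(7, nt = 60)
  s <- extract_occupation_series(cube, "x", occ_row(50, 52))
  expect_equal(length(s$values), 3)
  expect_equal(s$slices, c(52, 51, 50))  # oldest first
  expect_equal(s$values, rep(7, 3))
  s2 <- extract_occupation_series(cube, "x", occ_row(50.4, 52.6))
  expect_equal(s2$slices, 53:50)  # nearest-integer snapping at both ends
  expect_error(extract_occupation_series(cube, "x", occ_row(100, 120)),
               "no time overlap")
})

test_that("mid-value picks the slice nearest the mid-age, ties toward older", {
  nt <- 120
  v <- array(rep(0:(nt - 1), 3 * 4), c(nt, 3, 4))  # value = slice index
  cube <- climate_cube(seq(0.5, 3.5), seq(0.5, 2.5), 0:(nt - 1),
                       list(x = v), matrix(TRUE, 3, 4), 1)
  expect_equal(extract_mid_value(cube, "x", occ_row(50, 52)), 51)
  expect_equal(extract_mid_value(cube, "x", occ_row(50, 53)), 52)  # tie -> older
  expect_equal(extract_mid_value(cube, "x", occ_row(50, 100)), 75)
  s <- extract_occupation_series(cube, "x", occ_row(50, 53))
  expect_equal(extract_mid_value(cube, "x", occ_row(50, 53)),
               s$values[s$slices == 52])
})

test_that("extraction is invariant to latitude orientation", {
  set.seed(21)
  f <- matrix(rnorm(12), 3, 4)
  up <- field_cube(f, nt = 30)
  down <- climate_cube(up$lon_axis, rev(up$lat_axis), up$time_axis,
                       list(x = up$variables$x[, 3:1, , drop = FALSE]),
                       up$land_mask[3:1, ], 1)
  occ <- occ_row(5, 20, lon = 2.3, lat = 1.1)
  expect_equal(extract_occupation_series(down, "x", occ)$values,
               extract_occupation_series(up, "x", occ)$values)
})

test_that("site series cover the combined span", {
  cube <- constant_cube(3, nt = 100)
  site <- data.frame(site_id = "S", lon = 1.2, lat = 1.3,
                     span_min = 10, span_max = 60)
  s <- extract_site_series(cube, "x", site)
  expect_equal(length(s$values), 51)
  expect_equal(s$t_start, 10); expect_equal(s$t_end, 60)
})

test_that("extract_table emits the long CSV layout losslessly", {
  cube <- constant_cube(2.5, nt = 40)
  occs <- rbind(occ_row(5, 8, site = "A"), occ_row(20, 22, site = "B"))
  tab <- extract_table(cube, "x", occs)
  expect_named(tab, c("occ_id", "variable", "t_ka", "value"))
  expect_equal(nrow(tab), 4 + 3)
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_equal(read.csv(f, stringsAsFactors = FALSE), tab)
})

test_that("cube text serialization and the data.frame adapter round-trip", {
  set.seed(3)
  f <- matrix(rnorm(12), 3, 4)
  mask <- matrix(TRUE, 3, 4); mask[1, 1] <- FALSE
  cube <- field_cube(f, nt = 5, mask = mask)
  d <- tempfile()
  write_climate_cube(cube, d)
  back <- read_climate_cube(d)
  expect_equal(back$variables$x, cube$variables$x)
  expect_equal(back$land_mask, cube$land_mask)
  expect_equal(back$time_axis, cube$time_axis)
  # long-format adapter
  grid <- expand.grid(t_ka = 0:4, lat = cube$lat_axis, lon = cube$lon_axis)
  grid$variable <- "x"
  grid$value <- as.vector(cube$variables$x)
  grid$land <- rep(as.vector(mask), each = 5)
  cube2 <- as_climate_cube(grid, resolution = 1)
  expect_equal(cube2$variables$x, cube$variables$x)
  unlink(d, recursive = TRUE)
})
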
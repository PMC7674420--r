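test_that("fluc1 matches the hand-evaluated formula", {
  expect_equal(fluc1(rep(0.5, 5)), 0)
  expect_equal(fluc1(c(0, 1, 0, 1, 0)), 0.8)   # (1+1+1+1)/5
  expect_equal(fluc1(c(0, 1)), 0.5)            # 1/2
  expect_error(fluc1(1), "length >= 2")
  expect_error(fluc1(c(1, NA, 2)), "complete")
  # non-negative, zero iff constant
  set.seed(1)
  for (i in 1:20) {
    x <- runif(5)
    expect_gte(fluc1(x), 0)
    expect_equal(fluc1(x) == 0, length(unique(x)) == 1)
  }
})

test_that("fill_or_flag implements the one-missing repair rule", {
  tms <- c(0, 30, 60, 120, 180)
  vals <- c(5, 8, 7, 6, 5.5)

  none <- fill_or_flag(tms, vals)
  expect_identical(none$values, vals)
  expect_false(none$degenerate)

  one <- fill_or_flag(tms, replace(vals, 3, NA))
  expect_false(one$degenerate)
  expect_false(anyNA(one$values))
  # interpolation of the 4 remaining points, evaluated at the missing time
  expect_equal(one$values[3],
               spline(tms[-3], vals[-3], xout = tms[3], method = "fmm")$y)

  two <- fill_or_flag(tms, replace(vals, c(2, 4), NA))
  expect_true(two$degenerate)
  expect_true(fill_or_flag(tms, rep(NA_real_, 5))$degenerate)
})

test_that("interpolate_dense passes through support points and preserves lines", {
  tms <- c(0, 30, 60, 120, 180)
  vals <- c(5, 8, 7, 6, 5.5)
  dense <- interpolate_dense(tms, vals, n_points = 100)
  expect_length(dense$values, 100)
  at_support <- dense$values[match(tms, dense$times, nomatch = 0)]
  # grid includes the end points exactly
  expect_equal(dense$values[1], vals[1])
  expect_equal(dense$values[100], vals[5])
  # spline interpolant reproduces observed points at their own times
  redo <- spline(tms, vals, xout = tms, method = "fmm")$y
  expect_equal(redo, vals, tolerance = 1e-12)
  # collinear input stays linear
  lin <- interpolate_dense(tms, 2 + 0.5 * tms, n_points = 100)
  expect_equal(lin$values, 2 + 0.5 * lin$times, tolerance = 1e-9)
  expect_message(interpolate_dense(c(0, 60, 180), c(1, 2, 3)), "linear")
})

test_that("rasterize produces the declared layout", {
  # constant series on a 10x10 grid: one occupied cell per column, same row
  dense <- list(times = seq(0, 180, length.out = 100),
                values = rep(5, 100))
  img <- rasterize(dense$times, dense$values, 10, c(0, 10))
  expect_length(img$vec, 100)
  expect_equal(fluc2(img), 10)
  m <- matrix(img$vec, nrow = 10)
  expect_true(all(colSums(m) == 1))
  expect_equal(unique(apply(m, 2, which.max)), 6)  # value 5 -> 6th bin of [0,10)

  # full-range diagonal: every column occupied
  diag <- rasterize(seq(0, 180, length.out = 100),
                    seq(0, 10, length.out = 100), 10, c(0, 10))
  expect_true(all(colSums(matrix(diag$vec, 10)) >= 1))

  # out-of-bounds values are clamped into the boundary cells
  clamp <- rasterize(c(0, 90, 180), c(-5, 5, 25), 10, c(0, 10))
  mm <- matrix(clamp$vec, 10)
  expect_equal(mm[1, 1], 1L)    # below range -> bottom cell
  expect_equal(mm[10, 10], 1L)  # above range -> top cell

  expect_error(rasterize(c(0, 1), c(1, 2), 10, c(3, 3)), "y_bounds")
})

test_that("fluc2/fluc3 match definitions on constructed images", {
  g <- 10
  img <- structure(list(vec = integer(g^2), g = g, y_bounds = c(0, 1)),
                   class = "raster_image")
  expect_equal(fluc2(img), 0)
  expect_equal(fluc3(img), 0)

  # isolated 1s: fluc3 filters all of them
  iso <- img
  iso$vec[seq(1, g^2, by = 2 * g)] <- 1L
  expect_gt(fluc2(iso), 0)
  expect_equal(fluc3(iso), 0)

  # one column fully occupied: a single run of length g
  colfull <- img
  colfull$vec[(3 * g + 1):(4 * g)] <- 1L
  expect_equal(fluc2(colfull), g)
  expect_equal(fluc3(colfull), g)

  # run spanning a column boundary counts only under cross_columns = TRUE
  span <- img
  span$vec[c(g, g + 1)] <- 1L  # top of col 1, bottom of col 2
  expect_equal(fluc3(span, cross_columns = FALSE), 0)
  expect_equal(fluc3(span, cross_columns = TRUE), 2)
})

test_that("fluc2/fluc3 equal the brute-force oracle on random series", {
  set.seed(7)
  for (i in 1:60) {
    g <- sample(c(10, 50), 1)
    tms <- seq(0, 180, length.out = 100)
    vals <- cumsum(rnorm(100))
    yb <- range(vals) + c(-0.5, 0.5)
    img <- rasterize(tms, vals, g, yb)
    expect_identical(img$vec, oracle_rasterize(tms, vals, g, yb))
    expect_equal(fluc3(img), oracle_fluc3(img$vec, g))
    expect_equal(fluc3(img, cross_columns = TRUE),
                 oracle_fluc3(img$vec, g, cross_columns = TRUE))
    # occupancy bounds and filtering inequality
    expect_lte(fluc3(img), fluc2(img))
    expect_lte(fluc2(img), min(100, g^2))
  }
})

test_that("translation within bounds leaves fluc2 unchanged", {
  set.seed(11)
  tms <- seq(0, 180, length.out = 100)
  vals <- 5 + cumsum(rnorm(100, sd = 0.1))
  yb <- c(0, 10)
  g <- 10
  base <- fluc2(rasterize(tms, vals, g, yb))
  shifted <- fluc2(rasterize(tms, vals + 1, g, c(1, 11)))
  expect_equal(shifted, base)
})

test_that("auc_trapezoid matches geometry", {
  expect_equal(auc_trapezoid(c(0, 60, 120, 180), rep(2, 4)), 360)  # rectangle
  expect_equal(auc_trapezoid(c(0, 60), c(0, 1)), 30)               # triangle
  sym <- c(1, 3, 5, 3, 1)
  tms <- c(0, 45, 90, 135, 180)
  expect_equal(auc_trapezoid(tms, sym), auc_trapezoid(tms, rev(sym)))
  expect_error(auc_trapezoid(0, 1), "at least 2")
})

test_that("fluc_features handles degenerate series and the feature block builds", {
  tms <- c(0, 30, 60, 120, 180)
  deg <- fluc_features(tms, c(1, NA, NA, 2, 3), 10, c(0, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$fluc2, 0L)
  expect_equal(deg$fluc3, 0L)

  cfg <- small_synth_config(seed = 3)
  sim <- simulate_cohort(cfg)
  pp <- simulate_postprandial(cfg, sim$cohort, sim$truth)
  blk <- postprandial_feature_block(pp)
  expect_s3_class(blk, "feature_block")
  expect_equal(nrow(blk$values), nrow(sim$cohort))
  # 5 markers x (fluc1, AUC, fluc2/fluc3 at 10 and 50)
  expect_equal(ncol(blk$values), 5 * 6)
  expect_false(anyNA(blk$values))
  # duplicate fasting measurements are averaged, not duplicated
  dup <- pp[pp$marker == "breath_h2" & pp$sample_id == pp$sample_id[1], ]
  dup2 <- rbind(dup, data.frame(sample_id = dup$sample_id[1], marker = "breath_h2",
                                time_min = 0, value = dup$value[1] + 2))
  blk2 <- postprandial_feature_block(dup2)
  expect_equal(nrow(blk2$values), 1)
})
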
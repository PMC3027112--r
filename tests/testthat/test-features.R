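test_that("interpolation is exact on measured points, linear between, no extrapolation", {
  p <- st_profile(c(0, 2), c(0, 4))
  expect_equal(suppressWarnings(interpolate_profile(p, c(0, 1, 2)))$values,
               c(0, 2, 4))
  expect_error(interpolate_profile(p, 3), "range")
  # idempotence on a grid
  p2 <- st_profile(c(0, 1, 3), c(1, -1, 1))
  g <- c(0, 0.5, 1, 2, 3)
  once <- suppressWarnings(interpolate_profile(p2, g))
  twice <- interpolate_profile(once, g)
  expect_equal(twice, once)
})

test_that("interpolating more than 10% of the grid warns", {
  p <- st_profile(c(0, 10), c(0, 1))
  expect_warning(interpolate_profile(p, seq(0, 10, by = 1)), "interpolated")
  expect_silent(interpolate_profile(p, c(0, 10)))
})

test_that("signed AUC matches hand values and a dense Riemann oracle", {
  expect_equal(signed_auc(st_profile(c(0, 1), c(1, 1))), 1)
  expect_equal(signed_auc(st_profile(c(0, 1, 3), c(1, -1, 1))), 0)
  expect_equal(signed_auc(st_profile(c(0, 2), c(0, 2))), 2)
  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(3:8, 1)
      times <- sort(runif(n, 0, 10))
      while (min(diff(times)) < 1e-3) times <- sort(runif(n, 0, 10))
      values <- rnorm(n)
      lim <- sort(runif(2, min(times), max(times)))
      while (diff(lim) < 1e-2) lim <- sort(runif(2, min(times), max(times)))
      p <- st_profile(times, values)
      expect_lt(abs(signed_auc(p, lim[1], lim[2]) -
                      riemann_auc(times, values, lim[1], lim[2])), 1e-9)
    }
  })
})

test_that("signed AUC is additive over adjacent intervals and odd under negation", {
  withr::with_seed(7, {
    for (i in 1:20) {
      times <- sort(runif(5, 0, 8))
      values <- rnorm(5)
      p <- st_profile(times, values)
      a <- min(times); c <- max(times); b <- runif(1, a, c)
      expect_equal(signed_auc(p, a, c),
                   signed_auc(p, a, b) + signed_auc(p, b, c),
                   tolerance = 1e-12)
      pneg <- st_profile(times, -values)
      expect_equal(signed_auc(pneg, a, c), -signed_auc(p, a, c),
                   tolerance = 1e-12)
    }
  })
  expect_error(signed_auc(st_profile(c(0, 1), c(0, 1)), 1, 1), "t_start")
})

test_that("slope and value_at behave as stated", {
  p <- st_profile(c(0, 2), c(0, 4))
  expect_equal(slope_between(p, 0, 2), 2)
  expect_equal(slope_between(p, 0, 1), 2)
  expect_error(slope_between(p, 1, 1), "differ")
  expect_equal(value_at(p, 1), 2)                   # midpoint mean
  expect_equal(value_at(p, 2), 4)                   # measured
  expect_error(value_at(p, 5), "range")
  # the rise-over-run formula is invariant to argument order
  withr::with_seed(2, for (i in 1:10) {
    t12 <- sort(runif(2, 0, 2))
    expect_equal(slope_between(p, t12[1], t12[2]),
                 slope_between(p, t12[2], t12[1]))
  })
})

test_that("extrema use the grid and break ties by earliest time", {
  p <- st_profile(c(0, 1, 2), c(1, 3, 2))
  ex <- profile_extrema(p, c(0, 1, 2))
  expect_equal(ex, list(max_expr = 3, min_expr = 1, t_of_max = 1,
                        t_of_min = 0))
  pc <- st_profile(c(0, 1, 2), c(5, 5, 5))
  exc <- profile_extrema(pc, c(0, 1, 2))
  expect_equal(exc$t_of_max, 0)
  expect_equal(exc$t_of_min, 0)
  ex1 <- profile_extrema(p, 1)
  expect_equal(ex1$max_expr, ex1$min_expr)
  expect_error(profile_extrema(p, numeric()), "empty")
})

test_that("steepest slopes are the extreme consecutive-segment slopes", {
  p <- st_profile(c(0, 1, 2), c(0, 2, 1))
  expect_equal(steepest_slopes(p, c(0, 1, 2)),
               list(steepest_pos_slope = 2, steepest_neg_slope = -1))
  mono <- st_profile(c(0, 1, 2), c(0, 1, 3))
  expect_equal(steepest_slopes(mono, c(0, 1, 2)),
               list(steepest_pos_slope = 2, steepest_neg_slope = 1))
  flat <- st_profile(c(0, 1), c(2, 2))
  expect_equal(steepest_slopes(flat, c(0, 1)),
               list(steepest_pos_slope = 0, steepest_neg_slope = 0))
  expect_error(steepest_slopes(p, 1), "at least 2")
  # steepest_pos >= overall slope >= steepest_neg
  withr::with_seed(4, for (i in 1:10) {
    tt <- sort(runif(5, 0, 5)); vv <- rnorm(5)
    pr <- st_profile(tt, vv)
    st <- steepest_slopes(pr, tt)
    overall <- slope_between(pr, tt[1], tt[5])
    expect_gte(st$steepest_pos_slope, overall)
    expect_gte(overall, st$steepest_neg_slope)
  })
})

test_that("replicate summaries take per-time mean or median over covering replicates", {
  txt <- expr_text("ID\tA1\tA2\tA3\tA4\tA5\tA6",
                   "g1\t1\t1\t3\t3\t6\t6")
  lab <- expr_text("Array\tA1\tA2\tA3\tA4\tA5\tA6",
                   "Treatment\ta\ta\ta\ta\ta\ta",
                   "Replicate\t1\t1\t2\t2\t3\t3",
                   "Time\t0\t4\t0\t4\t0\t4")
  ds <- assemble_dataset(read_expression_matrix(textConnection(txt)),
                         read_design_table(textConnection(lab)))
  med <- summarize_replicates(ds, "g1", "a", c(0, 4), "median")
  expect_equal(med$values, c(3, 3))
  mea <- summarize_replicates(ds, "g1", "a", c(0, 4), "mean")
  expect_equal(mea$values, c(10 / 3, 10 / 3))
  # single replicate: identity
  dss <- tiny_dataset()
  s1 <- summarize_replicates(dss, "g1", "alpha", c(0, 4), "median")
  expect_equal(s1$values, get_profile(dss, "g1", "alpha", 1)$values)
  expect_error(summarize_replicates(dss, "g1", "alpha", c(0, 9)), "covers")
})

test_that("relative profiles subtract matched replicates on the grid", {
  ds <- tiny_dataset(paired = TRUE)
  rp <- relative_profile(ds, "g1", "alpha", "control", 1, c(0, 4))
  expect_equal(rp$values, c(1 - 3, 2 - 4))
  same <- relative_profile(ds, "g1", "alpha", "alpha", 1, c(0, 4))
  expect_equal(same$values, c(0, 0))
  dsu <- tiny_dataset(paired = FALSE)
  expect_error(relative_profile(dsu, "g1", "alpha", "control", 1, c(0, 4)),
               "paired")
})

test_that("feature matrix has the documented shape and exclusions", {
  ds <- sim_dataset(n_genes = 5, seed = 9)
  fm <- build_feature_matrix(ds, features = "signed_auc",
                             grid = c(0, 2, 8, 24), treatment = "control")
  expect_equal(dim(fm), c(5L, 1L))
  fm2 <- build_feature_matrix(ds, features = "raw_expression",
                              grid = c(0, 2, 8, 24), treatment = "control")
  expect_equal(ncol(fm2), 4L)
  expect_match(colnames(fm2)[1], "raw_expression_t0")
  expect_error(build_feature_matrix(ds, features = "bogus",
                                    grid = c(0, 24), treatment = "control"),
               "unknown feature")
  # probe with all-missing data is excluded and reported
  txt <- expr_text("ID\tA1\tA2\tA3\tA4",
                   "g1\t1\t2\t3\t4", "g2\t\t\t\t")
  lab <- expr_text("Array\tA1\tA2\tA3\tA4", "Treatment\ta\ta\ta\ta",
                   "Replicate\t1\t1\t2\t2", "Time\t0\t4\t0\t4")
  dsm <- assemble_dataset(read_expression_matrix(textConnection(txt)),
                          read_design_table(textConnection(lab)))
  fm3 <- suppressMessages(build_feature_matrix(
    dsm, features = "signed_auc", grid = c(0, 4), treatment = "a"))
  expect_equal(rownames(fm3), "g1")
  expect_named(attr(fm3, "excluded"), "g2")
})
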
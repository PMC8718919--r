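test_that("the B-spline basis is a partition of unity and interpolates", {
  set.seed(50)
  knots <- c(4.5, 12, 20, 35, 60, 81)
  ages <- runif(200, 4.5, 81)
  B <- spline_basis(ages, knots, degree = 3)
  expect_equal(rowSums(B), rep(1, 200))
  expect_equal(spline_basis(20, knots), spline_basis(20, knots))
  expect_error(spline_basis(90, knots), "outside the knot span")

  # degree-1 basis with no interior knots reproduces linear interpolation
  f <- function(x) 2 + 0.5 * x
  B1 <- spline_basis(ages, c(4.5, 81), degree = 1)
  expect_equal(drop(B1 %*% f(c(4.5, 81))), f(ages))
})

test_that("the penalty null space contains every linear trend", {
  set.seed(51)
  ages <- runif(120, 4.5, 81)
  y <- 1.2 - 0.03 * ages
  for (lam in c(1e-3, 1, 1e3, 1e6)) {
    f <- fit_penalized_spline(ages, y, lam)
    expect_equal(f$fitted, y, tolerance = 1e-8)
  }
})

test_that("heavy smoothing converges to the least-squares line", {
  set.seed(52)
  ages <- runif(150, 4.5, 81)
  y <- 2 - 0.02 * ages + 0.3 * sin(ages / 8) + rnorm(150, 0, 0.2)
  f <- fit_penalized_spline(ages, y, 1e10)
  ols <- lm(y ~ ages)  # closed-form oracle
  expect_equal(f$fitted, unname(fitted(ols)), tolerance = 1e-4)
  expect_equal(f$edf, 2, tolerance = 1e-3)
})

test_that("a small fit matches a dense independent solve", {
  set.seed(53)
  ages <- sort(runif(12, 5, 80))
  y <- rnorm(12)
  knots <- c(5, 30, 55, 80)
  lam <- 2
  f <- fit_penalized_spline(ages, y, lam, knots = knots)
  # brute-force linear-algebra oracle, assembled independently
  B <- spline_basis(ages, knots)
  g <- sapply(seq_len(ncol(B)), function(i) {
    aug <- c(rep(5, 3), knots, rep(80, 3))
    mean(aug[(i + 1):(i + 3)])
  })
  D <- matrix(0, ncol(B) - 2, ncol(B))
  for (i in seq_len(nrow(D))) {
    d1 <- g[i + 1] - g[i]; d2 <- g[i + 2] - g[i + 1]
    w <- 2 / (g[i + 2] - g[i])
    D[i, i:(i + 2)] <- c(w / d1, -w / d1 - w / d2, w / d2)
  }
  coef_direct <- solve(crossprod(B) + lam * crossprod(D), crossprod(B, y))
  expect_equal(f$coef, drop(coef_direct), tolerance = 1e-10)
})

test_that("GCV picks smooth fits for noise and rough fits for structure", {
  grid <- default_lambda_grid()
  set.seed(54)
  ages <- runif(300, 4.5, 81)
  sel_noise <- select_lambda_gcv(ages, rnorm(300, 5, 0.3))
  expect_gte(sel_noise$lambda, grid[length(grid) - 2])
  sel_curve <- select_lambda_gcv(ages, sin(ages / 4))
  expect_lte(sel_curve$lambda, 1)  # small-lambda regime
  expect_gte(sel_noise$lambda / sel_curve$lambda, 1e3)
  # argmin definition and monotone effective dof
  expect_true(all(sel_noise$gcv[which.min(sel_noise$gcv)] <= sel_noise$gcv))
  expect_true(all(diff(sel_noise$edf) <= 1e-8))
  expect_error(select_lambda_gcv(ages, rnorm(300), lambda_grid = 1), "at least 2")
})

test_that("noise-free cohorts are recovered almost exactly", {
  co <- quiet_cohort(150, seed = 55, noise_sd = 0)
  mod <- fit_normative_model(co, "female")
  grid <- seq(mod$age_range[1], mod$age_range[2], length.out = 150)
  for (cell in list(c("theta", "Cz"), c("alpha", "O1"), c("gamma", "F7"))) {
    mu <- predict_mean(mod, grid, cell[1], cell[2])
    truth <- trend_mean_log_power(grid, "female", cell[1], cell[2],
                                  co$config)
    expect_lt(max(abs(mu - truth)), 0.02)
  }
})

test_that("sex stratification ignores the other sex entirely", {
  co <- quiet_cohort(60, seed = 56)
  m1 <- fit_normative_model(co, "male")
  males <- co$demographics$sex == "male"
  m2 <- fit_normative_model(
    powers = co$powers[co$powers$id %in% co$demographics$id[males], ],
    demographics = co$demographics[males, ], sex_mode = "male")
  ages <- c(10, 30, 70)
  expect_equal(predict_mean(m1, ages, "theta", "Cz"),
               predict_mean(m2, ages, "theta", "Cz"))
  expect_error(fit_normative_model(co, "male", min_subjects = 100),
               "training subjects")
})

test_that("predictions are continuous in age and intervals calibrated", {
  co <- quiet_cohort(300, seed = 57)
  mod <- fit_normative_model(co, "male")
  expect_lt(abs(predict_mean(mod, 30.0, "alpha", "Pz") -
                  predict_mean(mod, 30.001, "alpha", "Pz")), 1e-3)
  expect_lt(abs(predict_sd(mod, 30.0, "alpha", "Pz") -
                  predict_sd(mod, 30.001, "alpha", "Pz")), 1e-3)
  # clamping outside the training range, with the flag raised
  hi <- predict_mean(mod, 95, "alpha", "Pz")
  expect_true(attr(hi, "age_clamped"))
  expect_equal(as.numeric(hi),
               as.numeric(predict_mean(mod, mod$age_range[2], "alpha", "Pz")))

  # coverage simulation oracle: 95% PI covers ~95% of fresh subjects
  fresh <- quiet_cohort(1000, seed = 58)
  ids <- fresh$demographics$id[fresh$demographics$sex == "male"]
  covered <- c()
  for (cell in list(c("theta", "Cz"), c("beta", "F3"))) {
    sel <- fresh$powers$id %in% ids & fresh$powers$band == cell[1] &
      fresh$powers$channel == cell[2]
    pw <- fresh$powers[sel, ]
    age <- fresh$demographics$age[match(pw$id, fresh$demographics$id)]
    mu <- predict_mean(mod, age, cell[1], cell[2])
    sd <- predict_sd(mod, age, cell[1], cell[2])
    covered <- c(covered, abs(pw$log_power - mu) <= z_crit_95() * sd)
  }
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("z-scores are centered, linear and guard degenerate input", {
  co <- quiet_cohort(100, seed = 59)
  mod <- fit_normative_model(co, "female")
  demo <- data.frame(id = c("P1", "P2", "P3"), age = c(25, 25, 25),
                     sex = "female")
  mu <- as.numeric(predict_mean(mod, 25, "alpha", "Cz"))
  sd <- as.numeric(predict_sd(mod, 25, "alpha", "Cz"))
  pw <- data.frame(id = demo$id, channel = "Cz", band = "alpha",
                   power_uv2 = c(exp(mu), exp(mu + 2 * sd), -1))
  z <- zscore(mod, pw, demo)
  expect_equal(z$z[1], 0, tolerance = 1e-10)
  expect_equal(z$z[2], 2, tolerance = 1e-10)
  expect_true(is.na(z$z[3]))  # non-positive power flagged, not zeroed
  expect_error(zscore(mod, transform(pw, id = "M1"),
                      data.frame(id = "M1", age = 25, sex = "male")),
               "other sex")
})

test_that("the fitted curve agrees with an independent GAM", {
  co <- quiet_cohort(400, seed = 60)
  mod <- fit_normative_model(co, "male")
  demo <- co$demographics[co$demographics$sex == "male", ]
  sel <- co$powers$id %in% demo$id & co$powers$band == "alpha" &
    co$powers$channel == "Pz"
  pw <- co$powers[sel, ]
  age <- demo$age[match(pw$id, demo$id)]
  ref <- mgcv::gam(y ~ s(age), data = data.frame(age = age,
                                                 y = pw$log_power))
  grid <- seq(quantile(age, 0.05), quantile(age, 0.95), length.out = 50)
  ours <- as.numeric(predict_mean(mod, grid, "alpha", "Pz"))
  theirs <- as.numeric(predict(ref, data.frame(age = grid)))
  expect_lt(max(abs(ours - theirs)), 0.06)
})

test_that("the age-band baseline matches brute-force window statistics", {
  co <- quiet_cohort(120, seed = 61)
  ab <- fit_age_band_model(co, "pooled", half_width = 10)
  demo <- co$demographics
  ci <- which.min(abs(ab$centers - 40))
  w <- ab$half_widths[ci]
  member <- demo$id[abs(demo$age - ab$centers[ci]) <= w]
  sel <- co$powers$id %in% member & co$powers$band == "theta" &
    co$powers$channel == "Cz"
  expect_equal(unname(ab$means["theta|Cz", ci]),
               mean(co$powers$log_power[sel]))
  expect_equal(unname(ab$sds["theta|Cz", ci]),
               sd(co$powers$log_power[sel]))
  expect_true(all(ab$ns >= 30))

  # identical log powers everywhere -> every z is zero
  flat <- co
  flat$powers$log_power <- 1.5
  flat$powers$power_uv2 <- exp(1.5)
  abf <- fit_age_band_model(flat, "pooled", half_width = 10)
  zf <- zscore_age_band(abf, flat$powers, flat$demographics)
  expect_true(all(zf$z == 0))
  expect_error(fit_age_band_model(co, "pooled", half_width = -1), "positive")
})

test_that("age-band z-scores jump at boundaries where the spline does not", {
  co <- quiet_cohort(400, seed = 62)
  gam <- fit_normative_model(co, "pooled")
  ab <- fit_age_band_model(co, "pooled", half_width = 5)
  mid <- (ab$centers[5] + ab$centers[6]) / 2  # a window switch point
  demo <- data.frame(id = c("A", "B"), age = c(mid - 0.1, mid + 0.1),
                     sex = "male")
  pw <- data.frame(id = c("A", "B"), channel = "Cz", band = "theta",
                   log_power = 1.0)
  z_ab <- zscore_age_band(ab, pw, demo)
  z_gam <- zscore(gam, pw, demo)
  expect_gt(abs(diff(z_ab$z)), abs(diff(z_gam$z)))
})

test_that("model JSON round trips losslessly and rejects corrupt files", {
  co <- quiet_cohort(80, seed = 63)
  mod <- fit_normative_model(co, "male")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(mod, path)
  back <- load_model(path)
  grid <- seq(mod$age_range[1], mod$age_range[2], length.out = 100)
  for (cell in list(c("delta", "Fp1"), c("gamma", "O2"))) {
    expect_equal(as.numeric(predict_mean(back, grid, cell[1], cell[2])),
                 as.numeric(predict_mean(mod, grid, cell[1], cell[2])),
                 tolerance = 1e-12)
    expect_equal(as.numeric(predict_sd(back, grid, cell[1], cell[2])),
                 as.numeric(predict_sd(mod, grid, cell[1], cell[2])),
                 tolerance = 1e-12)
  }
  # truncated file -> schema error, not a crash
  txt <- readLines(path)
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 500), trunc_path)
  expect_error(load_model(trunc_path), "schema error")

  ab <- fit_age_band_model(co, "pooled", half_width = 10)
  path2 <- withr::local_tempfile(fileext = ".json")
  save_model(ab, path2)
  ab2 <- load_model(path2)
  z1 <- zscore(ab, co$powers[1:50, ], co$demographics)
  z2 <- zscore(ab2, co$powers[1:50, ], co$demographics)
  expect_equal(z1, z2, tolerance = 1e-12)
})
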
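#' Cubic B-spline design matrix
#'
#' Evaluates a B-spline basis at the given ages. Boundary knots are
#' replicated so the basis spans the closed training range; the rows of the
#' returned matrix sum to one (partition of unity).
#'
#' @param ages evaluation points (years), inside \code{[min(knots),
#'   max(knots)]}.
#' @param knots full knot vector including the two boundary knots (strictly
#'   increasing).
#' @param degree spline degree (default 3, cubic).
#' @return Numeric matrix, \code{length(ages)} rows and
#'   \code{length(knots) + degree - 1} columns.
#' @export
spline_basis <- function(ages, knots, degree = 3) {
  if (is.unsorted(knots, strictly = TRUE)) stop("knots must be strictly increasing")
  if (any(ages < knots[1] | ages > knots[length(knots)]))
    stop("ages outside the knot span [", knots[1], ", ",
         knots[length(knots)], "]")
  aug <- c(rep(knots[1], degree), knots, rep(knots[length(knots)], degree))
  splines::splineDesign(aug, ages, ord = degree + 1, outer.ok = FALSE)
}

# Greville abscissae: the knot averages at which each B-spline coefficient
# "lives"; a linear function has coefficients exactly linear in these.
greville_abscissae <- function(knots, degree = 3) {
  aug <- c(rep(knots[1], degree), knots, rep(knots[length(knots)], degree))
  k <- length(aug) - degree - 1
  vapply(seq_len(k), function(i) mean(aug[(i + 1):(i + degree)]), numeric(1))
}

# Second divided-difference penalty matrix. Using divided differences with
# respect to the Greville abscissae (rather than plain second differences)
# makes the penalty null space exactly the linear functions even for
# unequally spaced (quantile) knots.
difference_penalty <- function(knots, degree = 3) {
  g <- greville_abscissae(knots, degree)
  k <- length(g)
  if (k < 3) stop("need at least 3 basis functions for a second-order penalty")
  D <- matrix(0, nrow = k - 2, ncol = k)
  for (i in seq_len(k - 2)) {
    d1 <- g[i + 1] - g[i]
    d2 <- g[i + 2] - g[i + 1]
    w <- 2 / (g[i + 2] - g[i])
    D[i, i]     <- w / d1
    D[i, i + 1] <- -w / d1 - w / d2
    D[i, i + 2] <- w / d2
  }
  D
}

# Quantile-placed interior knots plus boundary knots at the data range.
make_knots <- function(ages, n_interior = 10) {
  bnd <- range(ages)
  interior <- unique(stats::quantile(ages, probs = seq_len(n_interior) /
                                       (n_interior + 1), names = FALSE))
  interior <- interior[interior > bnd[1] & interior < bnd[2]]
  sort(unique(c(bnd[1], interior, bnd[2])))
}

#' Fit a penalized regression spline
#'
#' Minimizes \eqn{\|y - Bc\|^2 + \lambda \|Dc\|^2}, where \eqn{B} is the
#' B-spline basis on the given knots and \eqn{D} a second-order
#' divided-difference penalty whose null space contains all linear
#' functions of age (so straight-line signals are reproduced exactly at any
#' smoothing level, and the fit tends to the least-squares line as
#' \eqn{\lambda \to \infty}).
#'
#' @param ages predictor (years).
#' @param y response (here, natural-log band power).
#' @param lambda smoothing parameter, \eqn{\ge 0}.
#' @param knots optional knot vector (default: 10 interior knots at age
#'   quantiles).
#' @param degree spline degree (default 3).
#' @return Object of class \code{pspline_fit}: coefficients, knots, degree,
#'   \code{lambda}, effective degrees of freedom \code{edf}, residual SD
#'   \code{sigma} (= sqrt(RSS / (n - edf))), fitted values, the coefficient
#'   cross-product matrix \code{V} used for prediction leverage, and the
#'   training age range.
#' @export
fit_penalized_spline <- function(ages, y, lambda, knots = NULL, degree = 3) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (is.null(knots)) knots <- make_knots(ages)
  B <- spline_basis(ages, knots, degree)
  P <- crossprod(difference_penalty(knots, degree))
  ff <- pspline_engine(B, P, as.matrix(y), lambda)
  n <- length(ages)
  sigma <- sqrt(ff$rss / pmax(n - ff$edf, 1))
  structure(list(coef = drop(ff$coef), knots = knots, degree = degree,
                 lambda = lambda, edf = ff$edf, sigma = drop(sigma),
                 fitted = drop(B %*% ff$coef), V = ff$V, n = n,
                 age_range = range(ages)),
            class = "pspline_fit")
}

# Shared solver: Y may have many columns (one per band x channel component,
# all sharing the same design). Returns coefficients, per-column RSS, the
# effective dof (common to all columns), and V = A BtB A with
# A = (BtB + lambda P)^{-1}, so that the prediction leverage at basis row b
# is b' V b.
pspline_engine <- function(B, P, Y, lambda, BtB = crossprod(B),
                           BtY = crossprod(B, Y)) {
  M <- BtB + lambda * P
  A <- tryCatch(solve(M), error = function(e)
    stop("singular penalized normal equations (too many knots for the ",
         "data at lambda = ", lambda, "); increase lambda", call. = FALSE))
  coef <- A %*% BtY
  fitted <- B %*% coef
  rss <- colSums((Y - fitted)^2)
  edf <- sum(diag(A %*% BtB))
  list(coef = coef, rss = rss, edf = edf, V = A %*% BtB %*% A)
}

#' Select the smoothing parameter by generalized cross-validation
#'
#' Evaluates \eqn{GCV(\lambda) = n \cdot RSS / (n - edf)^2} on a grid and
#' returns the grid minimizer. Pure noise drives the choice toward the
#' smoothest (largest) grid value; strongly curved noiseless signals toward
#' the smallest.
#'
#' @inheritParams fit_penalized_spline
#' @param lambda_grid positive grid values (default logarithmic
#'   \eqn{10^{-3} \dots 10^4}).
#' @return List: \code{lambda} (the minimizer), \code{gcv} (named vector of
#'   scores), \code{edf} (per grid value).
#' @export
select_lambda_gcv <- function(ages, y, lambda_grid = default_lambda_grid(),
                              knots = NULL, degree = 3) {
  if (length(lambda_grid) < 2 || any(lambda_grid <= 0))
    stop("lambda_grid must contain at least 2 positive values")
  if (is.null(knots)) knots <- make_knots(ages)
  B <- spline_basis(ages, knots, degree)
  P <- crossprod(difference_penalty(knots, degree))
  BtB <- crossprod(B)
  Y <- as.matrix(y)
  BtY <- crossprod(B, Y)
  n <- length(ages)
  gcv <- numeric(length(lambda_grid))
  edf <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    ff <- pspline_engine(B, P, Y, lambda_grid[i], BtB, BtY)
    gcv[i] <- n * ff$rss[1] / (n - ff$edf)^2
    edf[i] <- ff$edf
  }
  names(gcv) <- names(edf) <- signif(lambda_grid, 4)
  list(lambda = lambda_grid[which.min(gcv)], gcv = gcv, edf = edf)
}

#' @rdname select_lambda_gcv
#' @export
default_lambda_grid <- function() 10^seq(-3, 4, length.out = 15)

resolve_cohort_tables <- function(cohort, powers, demographics) {
  if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "qeeg_cohort"))
    list(powers = cohort$powers, demographics = cohort$demographics,
         condition = cohort$config$condition)
  } else {
    list(powers = powers, demographics = demographics, condition = "EC")
  }
}

#' Fit the sex-stratified (or pooled) spline normative model
#'
#' The core normative-database fit: for every (band, channel) component,
#' the natural-log band power of the training subjects is regressed on age
#' with a penalized cubic B-spline, the smoothing parameter chosen per
#' component by generalized cross-validation on a shared grid. The
#' homoscedastic residual SD and the coefficient covariance structure are
#' stored so that a predicted mean and predicted SD (hence a 95% prediction
#' interval, and from it a Z-score) are available at every continuous age
#' -- with no discontinuities between successive ages, unlike age-band
#' norms.
#'
#' @param cohort a \code{qeeg_cohort}; alternatively pass \code{powers} and
#'   \code{demographics} directly.
#' @param sex_mode \code{"male"}, \code{"female"} (sex-stratified) or
#'   \code{"pooled"} (both sexes, no sex covariate).
#' @param powers data frame with \code{id}, \code{channel}, \code{band},
#'   \code{log_power}.
#' @param demographics data frame with \code{id}, \code{age}, \code{sex}.
#' @param eligible_ids optional vector of subject ids that passed
#'   screening; if supplied, training is restricted to them.
#' @param n_interior number of interior knots at age quantiles (default
#'   10).
#' @param degree spline degree (default 3).
#' @param lambda_grid GCV grid (default [default_lambda_grid()]).
#' @param min_subjects minimum training subjects for the requested
#'   \code{sex_mode} (default 50).
#' @param min_component_n minimum non-missing observations for a component
#'   to be usable (default 30); smaller components are flagged unusable,
#'   others are unaffected.
#' @return Object of class \code{normative_model}.
#' @export
fit_normative_model <- function(cohort = NULL,
                                sex_mode = c("male", "female", "pooled"),
                                powers = NULL, demographics = NULL,
                                eligible_ids = NULL, n_interior = 10,
                                degree = 3,
                                lambda_grid = default_lambda_grid(),
                                min_subjects = 50, min_component_n = 30) {
  sex_mode <- match.arg(sex_mode)
  tb <- resolve_cohort_tables(cohort, powers, demographics)
  demo <- tb$demographics
  if (!is.null(eligible_ids)) demo <- demo[demo$id %in% eligible_ids, ]
  if (sex_mode != "pooled") demo <- demo[demo$sex == sex_mode, ]
  if (nrow(demo) < min_subjects)
    stop("only ", nrow(demo), " training subjects for sex_mode '", sex_mode,
         "'; need at least ", min_subjects)
  pw <- tb$powers[tb$powers$id %in% demo$id, ]

  ids <- demo$id
  ages <- demo$age[match(ids, demo$id)]
  knots <- make_knots(ages, n_interior)
  B <- spline_basis(ages, knots, degree)
  P <- crossprod(difference_penalty(knots, degree))
  BtB <- crossprod(B)
  n <- length(ids)

  pw$key <- paste(pw$band, pw$channel, sep = "|")
  keys <- unique(pw$key)
  Y <- matrix(NA_real_, nrow = n, ncol = length(keys),
              dimnames = list(ids, keys))
  Y[cbind(match(pw$id, ids), match(pw$key, keys))] <- pw$log_power

  complete_cols <- colSums(is.na(Y)) == 0
  fits <- vector("list", length(keys))
  names(fits) <- keys

  if (any(complete_cols)) {
    Yc <- Y[, complete_cols, drop = FALSE]
    BtY <- crossprod(B, Yc)
    per_lambda <- lapply(lambda_grid, function(l)
      pspline_engine(B, P, Yc, l, BtB, BtY))
    gcv <- vapply(per_lambda, function(ff)
      n * ff$rss / (n - ff$edf)^2, numeric(ncol(Yc)))
    gcv <- matrix(gcv, nrow = ncol(Yc))
    best <- apply(gcv, 1, which.min)
    for (j in seq_len(ncol(Yc))) {
      ff <- per_lambda[[best[j]]]
      key <- colnames(Yc)[j]
      fits[[key]] <- list(
        coef = unname(ff$coef[, j]), lambda = lambda_grid[best[j]],
        sigma = unname(sqrt(ff$rss[j] / (n - ff$edf))), edf = ff$edf,
        V = ff$V, n = n, usable = TRUE)
    }
  }
  for (key in keys[!complete_cols]) {
    ok <- !is.na(Y[, key])
    if (sum(ok) < min_component_n) {
      fits[[key]] <- list(usable = FALSE, n = sum(ok))
      next
    }
    sel <- select_lambda_gcv(ages[ok], Y[ok, key], lambda_grid,
                             knots = knots, degree = degree)
    f <- fit_penalized_spline(ages[ok], Y[ok, key], sel$lambda,
                              knots = knots, degree = degree)
    fits[[key]] <- list(coef = f$coef, lambda = f$lambda, sigma = f$sigma,
                        edf = f$edf, V = f$V, n = f$n, usable = TRUE)
  }

  structure(list(version = 1L, type = "spline",
                 sex_mode = sex_mode, condition = tb$condition,
                 bands = band_definitions(), knots = knots, degree = degree,
                 lambda_grid = lambda_grid, n = n, age_range = range(ages),
                 train_ids = sort(ids), components = fits),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %s (%s), n = %d, ages %.1f-%.1f, %d components\n",
              x$sex_mode, x$condition, x$n, x$age_range[1], x$age_range[2],
              length(x$components)))
  invisible(x)
}

component_for <- function(model, band, channel) {
  key <- paste(band, normalize_channel_label(channel), sep = "|")
  comp <- model$components[[key]]
  if (is.null(comp)) stop("no model component for ", key)
  if (!isTRUE(comp$usable)) stop("component ", key, " is unusable (n = ",
                                 comp$n, ")")
  comp
}

clamp_age <- function(model, age) {
  lo <- model$age_range[1]; hi <- model$age_range[2]
  list(age = pmin(pmax(age, lo), hi), clamped = age < lo | age > hi)
}

#' Predicted mean log power at an age
#'
#' Evaluates the fitted normative curve for one (band, channel) component.
#' Ages outside the training range are clamped to the nearest bound (the
#' conservative extrapolation policy) -- use the \code{age_clamped}
#' attribute to detect this.
#'
#' @param model a \code{normative_model}.
#' @param age years (vectorized).
#' @param band,channel component selectors.
#' @return Predicted mean natural-log power, with attribute
#'   \code{age_clamped}.
#' @export
predict_mean <- function(model, age, band, channel) {
  comp <- component_for(model, band, channel)
  cl <- clamp_age(model, age)
  Bn <- spline_basis(cl$age, model$knots, model$degree)
  structure(drop(Bn %*% comp$coef), age_clamped = cl$clamped)
}

#' Predicted SD of a new observation at an age
#'
#' Half-width of the 95% prediction interval divided by the normal 97.5%
#' quantile: \eqn{\sigma_{pred}(age) = \hat\sigma \sqrt{1 + h(age)}} with
#' \eqn{h} the prediction leverage of the penalized fit, so the interval
#' accounts for residual scatter plus curve-estimation uncertainty. Both
#' the mean and SD are continuous in age.
#'
#' @inheritParams predict_mean
#' @return Predicted SD in natural-log units, with attribute
#'   \code{age_clamped}.
#' @export
predict_sd <- function(model, age, band, channel) {
  comp <- component_for(model, band, channel)
  cl <- clamp_age(model, age)
  Bn <- spline_basis(cl$age, model$knots, model$degree)
  h <- rowSums((Bn %*% comp$V) * Bn)
  structure(comp$sigma * sqrt(1 + h), age_clamped = cl$clamped)
}

#' The 97.5% standard-normal quantile used for prediction intervals
#' @export
z_crit_95 <- function() 1.959964

#' Z-score band powers against a normative model
#'
#' The standardized QEEG index: \eqn{z = (\ln power - \hat\mu(age)) /
#' \hat\sigma_{pred}(age)} per (channel, band). For normative subjects of
#' the model's population, z follows approximately the standard normal
#' distribution, so the score is directly comparable across ages, sexes,
#' channels and bands.
#'
#' @param model a \code{normative_model} (or \code{age_band_model}).
#' @param powers data frame with \code{id}, \code{channel}, \code{band} and
#'   \code{log_power} (or positive \code{power_uv2}).
#' @param demographics data frame with \code{id}, \code{age}, \code{sex}.
#' @return Data frame: \code{id}, \code{channel}, \code{band}, \code{z},
#'   \code{age_clamped}. Cells with non-positive power get \code{NA} z.
#' @export
zscore <- function(model, powers, demographics) {
  if (inherits(model, "age_band_model"))
    return(zscore_age_band(model, powers, demographics))
  stopifnot(inherits(model, "normative_model"))
  if (model$sex_mode != "pooled") {
    sexes <- demographics$sex[match(unique(powers$id), demographics$id)]
    if (any(sexes != model$sex_mode, na.rm = TRUE))
      stop("model sex_mode '", model$sex_mode,
           "' cannot score subjects of the other sex")
  }
  pw <- powers
  if (!"log_power" %in% names(pw))
    pw$log_power <- safe_log(pw$power_uv2)
  m <- match(pw$id, demographics$id)
  if (anyNA(m)) stop("powers contain ids absent from demographics")
  cl <- clamp_age(model, demographics$age[m])
  Bn <- spline_basis(cl$age, model$knots, model$degree)

  pw$key <- paste(pw$band, pw$channel, sep = "|")
  z <- rep(NA_real_, nrow(pw))
  for (key in unique(pw$key)) {
    rows <- which(pw$key == key)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    comp <- component_for(model, parts[1], parts[2])
    Bk <- Bn[rows, , drop = FALSE]
    mu <- drop(Bk %*% comp$coef)
    sd <- comp$sigma * sqrt(1 + rowSums((Bk %*% comp$V) * Bk))
    resid <- pw$log_power[rows] - mu
    zk <- resid / sd
    zk[sd == 0 & resid == 0] <- 0
    z[rows] <- zk
  }
  data.frame(id = pw$id, channel = pw$channel, band = pw$band, z = z,
             age_clamped = cl$clamped, stringsAsFactors = FALSE)
}

#' Fit the sliding-window age-band baseline model
#'
#' The comparison baseline the continuous model replaces: normative mean
#' and SD of log power computed within discrete age windows. A subject is
#' scored against the window whose center is nearest their age, which
#' produces step discontinuities at window midpoints -- two subjects 0.2
#' years apart can be standardized against noticeably different means and
#' SDs.
#'
#' @inheritParams fit_normative_model
#' @param half_width window half-width in years (default 5); windows with
#'   fewer than \code{min_n} subjects are widened symmetrically until
#'   satisfied.
#' @param min_n minimum subjects per window (default 30).
#' @return Object of class \code{age_band_model}.
#' @export
fit_age_band_model <- function(cohort = NULL,
                               sex_mode = c("male", "female", "pooled"),
                               powers = NULL, demographics = NULL,
                               eligible_ids = NULL, half_width = 5,
                               min_n = 30) {
  sex_mode <- match.arg(sex_mode)
  if (half_width <= 0) stop("half_width must be positive")
  tb <- resolve_cohort_tables(cohort, powers, demographics)
  demo <- tb$demographics
  if (!is.null(eligible_ids)) demo <- demo[demo$id %in% eligible_ids, ]
  if (sex_mode != "pooled") demo <- demo[demo$sex == sex_mode, ]
  if (nrow(demo) < min_n)
    stop("cohort too small to form any valid age window")
  pw <- tb$powers[tb$powers$id %in% demo$id, ]
  pw$key <- paste(pw$band, pw$channel, sep = "|")
  keys <- sort(unique(pw$key))
  age_of <- demo$age[match(pw$id, demo$id)]

  centers <- seq(min(demo$age), max(demo$age), by = half_width)
  means <- sds <- matrix(NA_real_, nrow = length(keys),
                         ncol = length(centers),
                         dimnames = list(keys, NULL))
  widths <- numeric(length(centers))
  ns <- integer(length(centers))
  for (ci in seq_along(centers)) {
    w <- half_width
    repeat {
      member_ids <- demo$id[abs(demo$age - centers[ci]) <= w]
      if (length(member_ids) >= min_n ||
          w > diff(range(demo$age)) + half_width) break
      w <- w * 1.25
    }
    if (length(member_ids) < min_n)
      stop("cohort too small to form any valid age window")
    sel <- pw$id %in% member_ids
    means[, ci] <- tapply(pw$log_power[sel], pw$key[sel], mean)[keys]
    sds[, ci] <- tapply(pw$log_power[sel], pw$key[sel], stats::sd)[keys]
    widths[ci] <- w
    ns[ci] <- length(member_ids)
  }
  structure(list(version = 1L, type = "age_band", sex_mode = sex_mode,
                 condition = tb$condition, centers = centers,
                 half_widths = widths, ns = ns, keys = keys,
                 means = means, sds = sds, n = nrow(demo),
                 age_range = range(demo$age), train_ids = sort(demo$id)),
            class = "age_band_model")
}

#' Z-score band powers against the age-band baseline
#'
#' @inheritParams zscore
#' @export
zscore_age_band <- function(model, powers, demographics) {
  stopifnot(inherits(model, "age_band_model"))
  pw <- powers
  if (!"log_power" %in% names(pw))
    pw$log_power <- safe_log(pw$power_uv2)
  m <- match(pw$id, demographics$id)
  if (anyNA(m)) stop("powers contain ids absent from demographics")
  age <- demographics$age[m]
  win <- vapply(age, function(a) which.min(abs(model$centers - a)),
                integer(1))
  key <- paste(pw$band, pw$channel, sep = "|")
  ki <- match(key, model$keys)
  mu <- model$means[cbind(ki, win)]
  sd <- model$sds[cbind(ki, win)]
  resid <- pw$log_power - mu
  z <- resid / sd
  z[sd == 0 & resid == 0] <- 0
  data.frame(id = pw$id, channel = pw$channel, band = pw$band, z = z,
             age_clamped = age < model$age_range[1] |
               age > model$age_range[2],
             stringsAsFactors = FALSE)
}

#' Save a normative model as versioned JSON
#'
#' @param model a \code{normative_model} or \code{age_band_model}.
#' @param path output file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("normative_model", "age_band_model")))
  obj <- unclass(model)
  obj$class <- class(model)[1]
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a normative model from JSON
#'
#' Round trip is lossless: predictions from a reloaded model match the
#' original to full numeric precision. Corrupted or truncated files raise
#' an explicit schema error.
#'
#' @param path model file path.
#' @return The deserialized model object.
#' @export
load_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("model file schema error: not valid JSON (",
                         conditionMessage(e), ")", call. = FALSE))
  if (!is.list(obj) || is.null(obj$class) || is.null(obj$version) ||
      !obj$class %in% c("normative_model", "age_band_model"))
    stop("model file schema error: missing class/version fields")
  if (obj$version != 1L)
    stop("model file schema error: unsupported version ", obj$version)
  cls <- obj$class
  obj$class <- NULL
  if (cls == "normative_model") {
    if (is.null(obj$components) || is.null(obj$knots))
      stop("model file schema error: missing components/knots")
    obj$components <- lapply(obj$components, function(comp) {
      if (isTRUE(comp$usable)) comp$V <- as.matrix(comp$V)
      comp
    })
  } else {
    obj$means <- as.matrix(obj$means)
    obj$sds <- as.matrix(obj$sds)
    rownames(obj$means) <- rownames(obj$sds) <- obj$keys
  }
  structure(obj, class = cls)
}
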
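# Two-group Levene test (classic, mean-centered): one-way ANOVA on the
# absolute deviations from each group's mean. No base-R implementation
# exists, so it is written out here.
levene_test <- function(x, y) {
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  n1 <- length(zx); n2 <- length(zy); N <- n1 + n2
  zbar <- mean(c(zx, zy))
  num <- (N - 2) * (n1 * (mean(zx) - zbar)^2 + n2 * (mean(zy) - zbar)^2)
  den <- sum((zx - mean(zx))^2) + sum((zy - mean(zy))^2)
  if (den == 0) return(list(statistic = NA_real_, p_value = NA_real_))
  f <- num / den
  list(statistic = f, p_value = stats::pf(f, 1, N - 2, lower.tail = FALSE))
}

#' Sex-difference test with assumption-based routing
#'
#' Compares two groups of feature values with the decision tree used for
#' normative sex-difference analysis: if both groups pass the Shapiro-Wilk
#' normality test and Levene's equality-of-variance test at the gate level,
#' Student's t-test is used; if normality holds but variances differ,
#' Welch's t-test; if normality fails in either group, the nonparametric
#' Mann-Whitney U test. Groups with zero variance are routed to
#' Mann-Whitney with a note. The gate p-values are returned so the routing
#' is auditable.
#'
#' @param x,y numeric feature values for the two groups (each n >= 3).
#' @param alpha significance level for the final test (default 0.05).
#' @param gate_alpha level for the two gate tests (default 0.05).
#' @return List: \code{test_used} (\code{"student-t"}, \code{"welch-t"} or
#'   \code{"mann-whitney-u"}), \code{statistic}, \code{p_value},
#'   \code{normality_p} (per group), \code{variance_equality_p},
#'   \code{significant}, \code{alpha}, \code{note}.
#' @export
sex_difference_test <- function(x, y, alpha = 0.05, gate_alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 observations")
  note <- NULL
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    note <- "constant group: routed to Mann-Whitney"
    norm_p <- c(NA_real_, NA_real_); lev_p <- NA_real_
    test_used <- "mann-whitney-u"
  } else {
    sw <- function(v) stats::shapiro.test(
      if (length(v) > 5000) v[seq_len(5000)] else v)$p.value
    norm_p <- c(sw(x), sw(y))
    lev_p <- levene_test(x, y)$p_value
    if (all(norm_p > gate_alpha)) {
      test_used <- if (!is.na(lev_p) && lev_p > gate_alpha) "student-t"
                   else "welch-t"
    } else {
      test_used <- "mann-whitney-u"
    }
  }
  res <- switch(test_used,
    "student-t" = stats::t.test(x, y, var.equal = TRUE),
    "welch-t" = stats::t.test(x, y, var.equal = FALSE),
    "mann-whitney-u" = stats::wilcox.test(x, y, exact = FALSE))
  list(test_used = test_used,
       statistic = unname(res$statistic),
       p_value = res$p.value,
       normality_p = stats::setNames(norm_p, c("x", "y")),
       variance_equality_p = lev_p,
       significant = res$p.value <= alpha,
       alpha = alpha, note = note)
}

#' Per-region sex-difference significance map
#'
#' Runs [sex_difference_test()] for every (channel, band) cell of a
#' feature table (males versus females) and flags cells with p at or below
#' the display threshold. The default threshold of 0.1 mirrors the
#' exploratory visualization convention and is deliberately separate from
#' the inferential gate level.
#'
#' @param cohort a \code{qeeg_cohort}; alternatively supply \code{powers}
#'   and \code{demographics}.
#' @param powers,demographics feature and subject tables (see
#'   [fit_normative_model()]).
#' @param value_col column of \code{powers} to compare (default
#'   \code{"log_power"}).
#' @param threshold display threshold on p (default 0.1).
#' @param adjust \code{"none"} (default; matches the exploratory use) or
#'   \code{"BH"} for Benjamini-Hochberg adjusted p-values.
#' @param gate_alpha level for the routing gate tests.
#' @return Data frame with one row per (channel, band): test used,
#'   statistic, p-value and the \code{significant} mask.
#' @export
sex_difference_map <- function(cohort = NULL, powers = NULL,
                               demographics = NULL,
                               value_col = "log_power", threshold = 0.1,
                               adjust = c("none", "BH"),
                               gate_alpha = 0.05) {
  adjust <- match.arg(adjust)
  tb <- resolve_cohort_tables(cohort, powers, demographics)
  pw <- tb$powers
  sex <- tb$demographics$sex[match(pw$id, tb$demographics$id)]
  key <- paste(pw$band, pw$channel, sep = "|")
  out <- lapply(unique(key), function(k) {
    rows <- key == k
    v <- pw[[value_col]][rows]
    s <- sex[rows]
    res <- sex_difference_test(v[s == "male"], v[s == "female"],
                               gate_alpha = gate_alpha)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(band = parts[1], channel = parts[2],
               test_used = res$test_used, statistic = res$statistic,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$p_value <= threshold
  rownames(out) <- NULL
  out
}

zscore_key_frame <- function(z) {
  data.frame(id = z$id, channel = z$channel, band = z$band,
             stringsAsFactors = FALSE)
}

#' Pearson correlation between two Z-score tables
#'
#' Matches two Z-score tables on (subject, channel, band) and reports the
#' Pearson correlation of the matched z values, overall and per band. Used
#' to compare normative databases that differ in modeling method: a high
#' correlation means the two capture the same normal-state trends.
#'
#' @param z1,z2 Z-score tables from [zscore()] with identical key sets.
#' @return List: \code{overall} (Pearson r), \code{per_band} (named
#'   vector), \code{n} (matched cells with finite z in both).
#' @export
cross_model_correlation <- function(z1, z2) {
  k1 <- with(z1, paste(id, channel, band, sep = "|"))
  k2 <- with(z2, paste(id, channel, band, sep = "|"))
  if (!setequal(k1, k2)) {
    missing <- c(utils::head(setdiff(k1, k2), 5), utils::head(setdiff(k2, k1), 5))
    stop("key mismatch between the two Z-score tables; e.g. ",
         paste(missing, collapse = ", "))
  }
  m <- match(k1, k2)
  a <- z1$z; b <- z2$z[m]
  ok <- is.finite(a) & is.finite(b)
  per_band <- vapply(unique(z1$band), function(bd) {
    sel <- ok & z1$band == bd
    stats::cor(a[sel], b[sel])
  }, numeric(1))
  list(overall = stats::cor(a[ok], b[ok]),
       per_band = per_band, n = sum(ok))
}

#' Calibration report for a Z-score table
#'
#' For normative subjects, the standardized index should follow the
#' standard normal distribution, Z ~ N(0, 1). This reports the sample mean
#' and variance of z pooled over all cells and per (channel, band) group,
#' excluding undefined cells (with the excluded count reported).
#'
#' @param z a Z-score table from [zscore()].
#' @param min_group minimum values per (channel, band) group for the
#'   per-group table (default 20).
#' @return List: \code{pooled} (mean, variance, n), \code{per_cell} (data
#'   frame), \code{n_excluded}.
#' @export
calibration_report <- function(z, min_group = 20) {
  ok <- is.finite(z$z)
  v <- z$z[ok]
  key <- paste(z$band, z$channel, sep = "|")[ok]
  agg <- data.frame(key = unique(key), stringsAsFactors = FALSE)
  agg$mean <- tapply(v, key, mean)[agg$key]
  agg$variance <- tapply(v, key, stats::var)[agg$key]
  agg$n <- as.integer(tapply(v, key, length)[agg$key])
  agg <- agg[agg$n >= min_group, ]
  parts <- strsplit(agg$key, "|", fixed = TRUE)
  agg$band <- vapply(parts, `[`, character(1), 1)
  agg$channel <- vapply(parts, `[`, character(1), 2)
  rownames(agg) <- NULL
  list(pooled = list(mean = mean(v), variance = stats::var(v),
                     n = length(v)),
       per_cell = agg[, c("band", "channel", "mean", "variance", "n")],
       n_excluded = sum(!ok))
}

#' Sex-stratified versus pooled Z-scores of anomalous subjects
#'
#' The accuracy contrast: anomalous subjects are standardized once against
#' the normative model matching their sex and once against the pooled
#' (both-sex) model trained on the same cohort. When the population has a
#' true sex difference, the pooled model's mean is offset and its SD
#' inflated by the between-sex mixture, so the sex-stratified z of an
#' injected anomaly sits farther from zero -- the stratified database
#' detects the abnormality more decisively.
#'
#' @param cohort a \code{qeeg_cohort} whose anomalous subjects were marked
#'   by [inject_anomaly()].
#' @param stratified named list with elements \code{male} and/or
#'   \code{female}: sex-stratified \code{normative_model}s.
#' @param pooled the pooled \code{normative_model}. Must be trained on the
#'   same cohort as the stratified models (training ids are checked).
#' @return List: \code{cells} (per subject x channel x band:
#'   \code{z_stratified}, \code{z_pooled}, \code{abs_diff},
#'   \code{affected}), and \code{summary} with the mean |z| under each
#'   model over affected cells and their difference.
#' @export
anomaly_contrast <- function(cohort, stratified, pooled) {
  stopifnot(inherits(cohort, "qeeg_cohort"))
  spec <- attr(cohort, "anomaly_spec")
  if (is.null(spec)) stop("cohort has no injected anomaly")
  strat_ids <- sort(unique(unlist(lapply(stratified, `[[`, "train_ids"))))
  if (!all(strat_ids %in% pooled$train_ids))
    stop("refusing contrast: stratified and pooled models were trained ",
         "on different cohorts")
  demo <- cohort$demographics
  anom <- demo[demo$is_anomalous, ]
  if (nrow(anom) == 0) stop("no anomalous subjects in cohort")
  pw <- cohort$powers[cohort$powers$id %in% anom$id, ]

  zs <- do.call(rbind, lapply(intersect(c("male", "female"),
                                        unique(anom$sex)), function(sx) {
    ids <- anom$id[anom$sex == sx]
    mod <- stratified[[sx]]
    if (is.null(mod)) stop("missing stratified model for sex ", sx)
    zscore(mod, pw[pw$id %in% ids, ], demo)
  }))
  zp <- zscore(pooled, pw, demo)
  key_s <- with(zs, paste(id, channel, band, sep = "|"))
  key_p <- with(zp, paste(id, channel, band, sep = "|"))
  zs$z_pooled <- zp$z[match(key_s, key_p)]
  cells <- data.frame(id = zs$id, channel = zs$channel, band = zs$band,
                      z_stratified = zs$z, z_pooled = zs$z_pooled,
                      abs_diff = abs(zs$z) - abs(zs$z_pooled),
                      affected = zs$band == spec$band &
                        zs$channel %in% spec$channels,
                      stringsAsFactors = FALSE)
  aff <- cells[cells$affected, ]
  list(cells = cells,
       summary = list(
         mean_abs_stratified = mean(abs(aff$z_stratified)),
         mean_abs_pooled = mean(abs(aff$z_pooled)),
         difference = mean(abs(aff$z_stratified)) -
           mean(abs(aff$z_pooled)),
         n_affected_cells = nrow(aff)))
}
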
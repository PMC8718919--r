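#' Default age-trend parameters for log band power
#'
#' Each band's mean log power (natural log of absolute power in µV²) follows
#' a piecewise trajectory in age: an exponential-decay segment over childhood
#' and adolescence joined continuously at age 20 to a linear adult segment,
#'
#'   mu(age) = a + b * exp(-r * (min(age, 20) - 4.5)) + s * max(age - 20, 0).
#'
#' Defaults encode the three qualitative trends seen in normative EEG
#' cohorts: slow waves (delta, theta) decline sharply from early childhood
#' to about age 19 and are near-flat in adulthood; alpha declines steadily
#' after 20; beta-range power rises steadily after 20.
#'
#' @return Named list (one element per band) of lists with components
#'   \code{a} (adult asymptote, log µV²), \code{b} (childhood excess),
#'   \code{r} (decay rate per year), \code{slope} (adult slope per year).
#' @export
default_trend_params <- function() {
  list(
    delta = list(a = 2.2,  b = 1.5, r = 0.22, slope = -0.002),
    theta = list(a = 1.6,  b = 1.4, r = 0.22, slope = -0.002),
    alpha = list(a = 1.9,  b = 0.5, r = 0.15, slope = -0.012),
    beta  = list(a = 0.9,  b = 0.6, r = 0.20, slope =  0.008),
    beta3 = list(a = 0.1,  b = 0.4, r = 0.20, slope =  0.008),
    gamma = list(a = -0.4, b = 0.3, r = 0.20, slope =  0.005)
  )
}

#' Cohort generator configuration
#'
#' Bundles every setting of the synthetic cohort generator. The defaults
#' are the generator's stated world: ages uniform on 4.5--81 years, a
#' residual SD of 0.3 natural-log units around the band trends (so ±2 SD
#' spans roughly a 3.3-fold power range), a sex offset of 0.15 log units on
#' theta only (females above the pooled trend by half the offset, males
#' below by half), and roughly 10% of subjects failing at least one
#' normative screening rule.
#'
#' @param n_per_sex subjects per sex (>= 2).
#' @param age_range numeric length 2, years; must lie within \code{[4.5, 81]}
#'   with \code{min < max} unless \code{allow_extended_age = TRUE}.
#' @param trend_params per-band trend coefficients, see
#'   [default_trend_params()].
#' @param sex_offset named numeric, per-band female-minus-male shift of mean
#'   log power (natural-log units). Bands not named get offset 0.
#' @param noise_sd SD of the Gaussian residual on log power (> 0 allowed to
#'   be 0 only for degenerate noise-free checks).
#' @param screening_fail_fraction proportion in \code{[0, 1)} of subjects
#'   given at least one failing screening feature.
#' @param condition recording condition, \code{"EC"} or \code{"EO"}.
#' @param seed integer RNG seed; the whole cohort is a pure function of the
#'   config including this seed.
#' @param allow_extended_age set TRUE to generate validation subjects
#'   outside the default normative age span.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_sex = 400,
                          age_range = c(4.5, 81),
                          trend_params = default_trend_params(),
                          sex_offset = c(theta = 0.15),
                          noise_sd = 0.3,
                          screening_fail_fraction = 0.1,
                          condition = c("EC", "EO"),
                          seed = 1L,
                          allow_extended_age = FALSE) {
  condition <- match.arg(condition)
  if (n_per_sex < 2) stop("n_per_sex must be at least 2")
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("age_range must be (min, max) with min < max")
  if (!allow_extended_age && (age_range[1] < 4.5 || age_range[2] > 81))
    stop("age_range must lie within [4.5, 81] for normative cohorts")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (screening_fail_fraction < 0 || screening_fail_fraction >= 1)
    stop("screening_fail_fraction must be in [0, 1)")
  missing_bands <- setdiff(band_names(), names(trend_params))
  if (length(missing_bands))
    stop("trend_params missing band(s): ", paste(missing_bands, collapse = ", "))
  if (length(sex_offset) && is.null(names(sex_offset)))
    stop("sex_offset must be a named vector (band = offset)")
  check_band(names(sex_offset))
  structure(
    list(n_per_sex = as.integer(n_per_sex), age_range = age_range,
         trend_params = trend_params, sex_offset = sex_offset,
         noise_sd = noise_sd,
         screening_fail_fraction = screening_fail_fraction,
         condition = condition, seed = as.integer(seed)),
    class = "cohort_config")
}

sex_offset_for <- function(config, band) {
  off <- config$sex_offset
  ifelse(band %in% names(off), unname(off[band]), 0)
}

#' Generative mean log band power at a given age and sex
#'
#' Evaluates the generator's smooth age trend for one band, plus the
#' sex-specific half-offset (female = trend + offset/2, male = trend -
#' offset/2, so the pooled mean stays on the trend). The trend is the same
#' at every channel of the montage; the channel argument is validated so
#' configuration mistakes surface early.
#'
#' @param age years, vectorized.
#' @param sex \code{"male"} or \code{"female"}.
#' @param band band name, see [band_definitions()].
#' @param channel a 10-20 channel label.
#' @param config a [cohort_config()].
#' @return Numeric vector of mean natural-log power (log µV²).
#' @export
trend_mean_log_power <- function(age, sex, band, channel,
                                 config = cohort_config()) {
  sex <- match.arg(sex, c("male", "female"))
  check_band(band)
  normalize_channel_label(channel)
  p <- config$trend_params[[band]]
  base <- p$a + p$b * exp(-p$r * (pmin(age, 20) - 4.5)) +
    p$slope * pmax(age - 20, 0)
  off <- sex_offset_for(config, band)
  base + if (sex == "female") off / 2 else -off / 2
}

#' Generate a synthetic normative-screening cohort
#'
#' Draws a cohort of subjects with demographics, screening scores and
#' band-power features having the statistical structure the normative
#' pipeline assumes: log band power = age/sex trend + iid Gaussian residual
#' (hence lognormal absolute power), ages uniform over the configured range,
#' and a configurable fraction of subjects carrying at least one failing
#' screening feature (with the ground-truth eligibility label retained for
#' oracle checks).
#'
#' @param config a [cohort_config()].
#' @return An object of class \code{qeeg_cohort}: a list with elements
#'   \code{config}, \code{demographics} (id, age, sex, condition,
#'   is_anomalous, truth_eligible), \code{screening} (one row per subject of
#'   instrument scores) and \code{powers} (one row per subject x channel x
#'   band with \code{power_uv2}, \code{log_power} and the generative
#'   \code{truth_mean}).
#' @export
sample_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old_seed), add = TRUE)
  set.seed(config$seed)

  n <- config$n_per_sex
  demographics <- data.frame(
    id = sprintf("S%04d", seq_len(2L * n)),
    age = stats::runif(2L * n, config$age_range[1], config$age_range[2]),
    sex = rep(c("male", "female"), each = n),
    condition = config$condition,
    is_anomalous = FALSE,
    stringsAsFactors = FALSE
  )

  channels <- montage_1020()
  bands <- band_names()
  powers <- expand.grid(band = bands, channel = channels,
                        id = demographics$id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  powers <- powers[, c("id", "channel", "band")]
  ord <- match(powers$id, demographics$id)
  age <- demographics$age[ord]
  sexnum <- ifelse(demographics$sex[ord] == "female", 0.5, -0.5)

  p <- config$trend_params
  a <- vapply(p, `[[`, numeric(1), "a")[powers$band]
  b <- vapply(p, `[[`, numeric(1), "b")[powers$band]
  r <- vapply(p, `[[`, numeric(1), "r")[powers$band]
  s <- vapply(p, `[[`, numeric(1), "slope")[powers$band]
  off <- sex_offset_for(config, powers$band)
  truth <- a + b * exp(-r * (pmin(age, 20) - 4.5)) + s * pmax(age - 20, 0) +
    sexnum * off

  powers$truth_mean <- truth
  powers$log_power <- truth +
    if (config$noise_sd > 0) stats::rnorm(nrow(powers), 0, config$noise_sd) else 0
  powers$power_uv2 <- exp(powers$log_power)
  rownames(powers) <- NULL

  screening <- generate_screening_scores(demographics,
                                         config$screening_fail_fraction)
  demographics$truth_eligible <- screening$truth_eligible

  structure(list(config = config, demographics = demographics,
                 screening = screening[, setdiff(names(screening),
                                                 "truth_eligible")],
                 powers = powers),
            class = "qeeg_cohort")
}

restore_rng <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# Screening-score generator: passing subjects get scores safely inside every
# normative band; a Bernoulli(fail_fraction) subset gets one failing feature
# drawn from the rule families applicable at their age.
generate_screening_scores <- function(demographics, fail_fraction) {
  n <- nrow(demographics)
  age <- demographics$age
  sc <- data.frame(id = demographics$id, stringsAsFactors = FALSE)

  kw_tests <- paste0("kwppsi_", c("block", "maze", "picture", "vocabulary",
                                  "similarity", "digit_span"))
  cn_tests <- paste0("cnsvs_", c("symbol_digit", "reasoning",
                                 "shift_attention", "verbal_memory",
                                 "visual_memory"))
  for (col in c(kw_tests, cn_tests, "mmse", "stai_state", "stai_trait",
                "cdi", "bdi", "kcbcl_depression_pct", "kcbcl_anxiety_pct"))
    sc[[col]] <- NA_real_
  sc$behavioral_expert_pass <- NA
  sc$history_flags <- ""

  grp <- vapply(age, assign_age_group, character(1))
  is_infant <- grp == "infant"
  is_child  <- grp == "child"
  is_minor  <- is_infant | is_child
  is_adult2 <- grp == "adult2"

  clipped_iq <- function(k) pmin(pmax(round(stats::rnorm(k, 105, 12)), 85), 160)

  for (t in kw_tests) sc[[t]][is_infant] <- clipped_iq(sum(is_infant))
  for (t in cn_tests) sc[[t]][!is_infant] <- clipped_iq(sum(!is_infant))
  sc$mmse[is_adult2] <- sample(26:30, sum(is_adult2), replace = TRUE)
  sc$stai_state[!is_infant] <- sample(20:50, sum(!is_infant), replace = TRUE)
  sc$stai_trait[!is_infant] <- sample(20:50, sum(!is_infant), replace = TRUE)
  sc$cdi[is_child] <- sample(0:18, sum(is_child), replace = TRUE)
  sc$bdi[!is_minor] <- sample(0:9, sum(!is_minor), replace = TRUE)
  sc$kcbcl_depression_pct[is_infant] <- stats::runif(sum(is_infant), 5, 85)
  sc$kcbcl_anxiety_pct[is_infant] <- stats::runif(sum(is_infant), 5, 85)
  sc$behavioral_expert_pass[is_minor] <- TRUE

  fail <- stats::runif(n) < fail_fraction
  for (i in which(fail)) {
    modes <- c("prescreen", "cognitive", "emotional",
               if (is_minor[i]) "behavioral")
    mode <- sample(modes, 1)
    if (mode == "prescreen") {
      sc$history_flags[i] <- sample(c("head_trauma", "epilepsy",
                                      "psychiatric_history"), 1)
    } else if (mode == "cognitive") {
      t <- if (is_infant[i]) sample(kw_tests, 1) else sample(cn_tests, 1)
      sc[[t]][i] <- 60  # percentile < 2%
    } else if (mode == "emotional") {
      if (is_infant[i]) sc$kcbcl_depression_pct[i] <- 99
      else if (is_child[i]) sc$cdi[i] <- 30
      else sc$bdi[i] <- 30
    } else {
      sc$behavioral_expert_pass[i] <- FALSE
    }
  }
  sc$truth_eligible <- !fail
  sc
}

#' Inject a band-power anomaly into cohort subjects
#'
#' Raises the log band power of the named subjects by \code{shift} times the
#' generator's residual SD in one band over a set of channels, emulating
#' clinical excesses such as elevated theta in developmental disorders and
#' amnestic MCI, or elevated high beta (beta3) in anxiety. All other cells
#' are untouched; affected subjects are flagged \code{is_anomalous}.
#'
#' @param cohort a \code{qeeg_cohort}.
#' @param ids subject ids to modify.
#' @param band single band name.
#' @param channels non-empty subset of the montage.
#' @param shift effect size in units of the generator's \code{noise_sd}
#'   (so the injected effect is interpretable as a target z-score).
#' @return The modified cohort.
#' @export
inject_anomaly <- function(cohort, ids, band, channels, shift) {
  stopifnot(inherits(cohort, "qeeg_cohort"))
  if (length(channels) == 0) stop("channels must be a non-empty set")
  if (!is.finite(shift)) stop("shift must be finite")
  check_band(band)
  channels <- normalize_channel_label(channels)
  missing_ids <- setdiff(ids, cohort$demographics$id)
  if (length(missing_ids))
    stop("unknown subject id(s): ", paste(missing_ids, collapse = ", "))

  delta <- shift * cohort$config$noise_sd
  hit <- cohort$powers$id %in% ids & cohort$powers$band == band &
    cohort$powers$channel %in% channels
  cohort$powers$log_power[hit] <- cohort$powers$log_power[hit] + delta
  cohort$powers$power_uv2[hit] <- exp(cohort$powers$log_power[hit])
  cohort$demographics$is_anomalous[cohort$demographics$id %in% ids] <- TRUE
  attr(cohort, "anomaly_spec") <- list(ids = ids, band = band,
                                       channels = channels, shift = shift)
  cohort
}

#' Synthesize multichannel EEG matching target band powers
#'
#' Builds a surrogate resting-state recording as a sum of independent
#' band-limited Gaussian noise components, one per band, each scaled so its
#' variance (hence its integrated spectral power) equals the subject's
#' target absolute power in that band. Only the spectral-power structure is
#' emulated; no physiological morphology (spindles, blinks, reactivity).
#'
#' @param target_powers numeric matrix of absolute power (µV²), channels in
#'   rows (rownames = montage labels), bands in columns (colnames = band
#'   names). Alternatively a subset of a cohort \code{powers} table for one
#'   subject.
#' @param fs sampling rate in Hz (>= 100; default 250).
#' @param duration seconds (default 240, i.e. a 4-minute resting run).
#' @param subject_id id stored on the recording.
#' @param condition \code{"EC"} or \code{"EO"}.
#' @param bands band definition table; edges must lie below Nyquist.
#' @param edge_margin Hz by which each component is inset inside its
#'   nominal band (default 0.5, one bin of the default 2-s spectral
#'   window). Spectral estimation smears a hard band edge by roughly the
#'   window resolution; the inset keeps the component's estimated power
#'   inside its own band so the synthesize-then-extract round trip closes.
#' @return An [eeg_recording()] object.
#' @export
synthesize_eeg <- function(target_powers, fs = 250, duration = 240,
                           subject_id = "synthetic", condition = "EC",
                           bands = band_definitions(), edge_margin = 0.5) {
  if (is.data.frame(target_powers)) {
    stopifnot(all(c("channel", "band", "power_uv2") %in% names(target_powers)))
    target_powers <- stats::xtabs(power_uv2 ~ channel + band,
                                  data = target_powers)
    target_powers <- unclass(target_powers)
  }
  if (fs < 100) stop("fs must be at least 100 Hz")
  if (any(bands$high > fs / 2))
    stop("band edges above the Nyquist frequency ", fs / 2, " Hz")
  n <- round(duration * fs)
  channels <- rownames(target_powers)
  if (is.null(channels)) stop("target_powers must have channel rownames")
  channels <- normalize_channel_label(channels)
  used_bands <- intersect(bands$band, colnames(target_powers))
  if (!length(used_bands)) stop("no recognized band columns in target_powers")

  freqs <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  freqs <- pmin(freqs, fs - freqs)  # two-sided |f|
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  for (ci in seq_along(channels)) {
    x <- numeric(n)
    for (b in used_bands) {
      p <- target_powers[ci, b]
      if (p <= 0) next
      lo <- bands$low[bands$band == b] + edge_margin
      hi <- bands$high[bands$band == b] - edge_margin
      if (hi <= lo)
        stop("band ", b, " narrower than twice the edge margin")
      w <- stats::rnorm(n)
      W <- stats::fft(w)
      W[!(freqs >= lo & freqs < hi)] <- 0
      comp <- Re(stats::fft(W, inverse = TRUE)) / n
      v <- stats::var(comp)
      if (v > 0) x <- x + comp * sqrt(p / v)
    }
    data[ci, ] <- x
  }
  eeg_recording(data, fs = fs, channel_labels = channels,
                condition = condition, subject_id = subject_id)
}
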
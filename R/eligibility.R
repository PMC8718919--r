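#' Assign the screening age group
#'
#' Normative screening uses four age groups: infants (4--6 y), children and
#' adolescents (7--19 y), Adult 1 (20--49 y), Adult 2 (>= 50 y). Boundaries
#' are half-open so a 6.9-year-old is an infant and a 19.99-year-old a
#' child.
#'
#' @param age years (vectorized). Ages below 4 are outside the protocol.
#' @return Character vector: \code{"infant"}, \code{"child"},
#'   \code{"adult1"} or \code{"adult2"}.
#' @export
assign_age_group <- function(age) {
  if (any(age < 4)) stop("age below 4 is outside the screening protocol")
  c("infant", "child", "adult1", "adult2")[
    findInterval(age, c(4, 7, 20, 50))]
}

#' Intelligence-scale score classification (preschool battery)
#'
#' Standard-score categories for the preschool intelligence battery
#' (mean 100, SD 15): <=69 Extremely Low, 70--79 Borderline, 80--89 Low
#' Average, 90--109 Average, 110--119 High Average, 120--129 Superior,
#' >= 130 Very Superior. The printed "70 or less" / "70--79" overlap is
#' resolved by keeping the categories disjoint: 70 is Borderline.
#'
#' @param score non-negative standard score (vectorized).
#' @return Character vector of category labels.
#' @export
classify_kwppsi <- function(score) {
  if (any(score < 0)) stop("score must be non-negative")
  c("Extremely Low", "Borderline", "Low Average", "Average",
    "High Average", "Superior", "Very Superior")[
      findInterval(score, c(70, 80, 90, 110, 120, 130)) + 1]
}

#' Computerized neurocognitive battery score classification
#'
#' Standard-score categories: >= 109 Above Average (74th percentile and
#' up), 90--108 Average, 80--89 Low Average, 70--79 Low, < 70 Very Low
#' (below the 2nd percentile).
#'
#' @param score non-negative standard score (vectorized).
#' @return Character vector of category labels.
#' @export
classify_cnsvs <- function(score) {
  if (any(score < 0)) stop("score must be non-negative")
  c("Very Low", "Low", "Low Average", "Average", "Above Average")[
    findInterval(score, c(70, 80, 90, 109)) + 1]
}

#' Percentile equivalent of a standard score (mean 100, SD 15)
#'
#' The screening batteries report standard scores; exclusion rules are
#' phrased in percentiles. This converts with the normal-distribution
#' convention the instruments use (raw 70 is the 2nd percentile, raw 80 the
#' 9th, raw 90 the 25th, raw 109 about the 73rd).
#'
#' @param score standard score (vectorized).
#' @return Percentile in \code{[0, 100]}.
#' @export
standard_score_percentile <- function(score) {
  100 * stats::pnorm((score - 100) / 15)
}

#' Mini-Mental State Examination classification
#'
#' 24--30 Normal, 20--23 Mild Dementia, 10--19 Moderate Dementia, <= 9
#' Severe Dementia.
#'
#' @param score integer 0--30 (vectorized).
#' @return Character vector of category labels.
#' @export
classify_mmse <- function(score) {
  if (any(score < 0 | score > 30)) stop("MMSE score must lie in [0, 30]")
  c("Severe Dementia", "Moderate Dementia", "Mild Dementia", "Normal")[
    findInterval(score, c(10, 20, 24)) + 1]
}

# State/trait anxiety thresholds: (risk onset, high-risk onset) by subscale,
# age bracket and sex. A score below the risk onset is normal; at or above
# the high-risk onset it is high-risk; in between it is at-risk (the printed
# risk bands, e.g. 59-63 risk / 64- high-risk, are inclusive of both ends).
stai_thresholds <- function(subscale, age, sex) {
  bracket <- findInterval(age, c(7, 20, 30))  # 1: 7-19, 2: 20-29, 3: 30+
  tab <- list(
    state = list(male = rbind(c(59, 64), c(58, 63), c(56, 61)),
                 female = rbind(c(62, 67), c(62, 67), c(56, 61))),
    trait = list(male = rbind(c(63, 68), c(58, 63), c(60, 65)),
                 female = rbind(c(65, 70), c(62, 67), c(60, 65)))
  )
  tab[[subscale]][[sex]][bracket, ]
}

#' State-Trait Anxiety Inventory classification
#'
#' Classifies a state- or trait-anxiety score into normal / risk /
#' high-risk using the age- and sex-specific thresholds of the instrument
#' (age brackets 7--19, 20--29, and 30 and over). The maximum score is 80;
#' the instrument does not apply below age 7.
#'
#' @param score raw score (<= 80).
#' @param subscale \code{"state"} or \code{"trait"}.
#' @param age years.
#' @param sex \code{"male"} or \code{"female"}.
#' @return \code{"normal"}, \code{"risk"} or \code{"high-risk"}.
#' @export
classify_stai <- function(score, subscale = c("state", "trait"), age, sex) {
  subscale <- match.arg(subscale)
  sex <- match.arg(sex, c("male", "female"))
  if (score > 80) stop("STAI score cannot exceed 80")
  if (age < 7) stop("STAI is not applicable below age 7")
  th <- stai_thresholds(subscale, age, sex)
  if (score >= th[2]) "high-risk" else if (score >= th[1]) "risk" else "normal"
}

#' Children's Depression Inventory classification
#'
#' <= 21 Normal (the printed ranges leave 21 unassigned between "below 21"
#' and "22 to 25"; it is read as Normal), 22--25 Mild, 26--28 Risk, >= 29
#' High-risk. Maximum score 54.
#'
#' @param score raw score (vectorized).
#' @return Character vector of category labels.
#' @export
classify_cdi <- function(score) {
  if (any(score < 0 | score > 54)) stop("CDI score must lie in [0, 54]")
  c("Normal", "Mild", "Risk", "High-risk")[
    findInterval(score, c(22, 26, 29)) + 1]
}

#' Beck Depression Inventory classification
#'
#' <= 9 Normal, 10--15 Mild, 16--23 Risk, >= 24 High-risk. Maximum score 63.
#'
#' @param score raw score (vectorized).
#' @return Character vector of category labels.
#' @export
classify_bdi <- function(score) {
  if (any(score < 0 | score > 63)) stop("BDI score must lie in [0, 63]")
  c("Normal", "Mild", "Risk", "High-risk")[
    findInterval(score, c(10, 16, 24)) + 1]
}

#' Child-behavior checklist percentile classification
#'
#' Percentile above 98 is Clinical Range, 93--98 Borderline Clinical Range,
#' below 93 Normal range.
#'
#' @param percentile in \code{[0, 100]} (vectorized).
#' @return Character vector of category labels.
#' @export
classify_kcbcl <- function(percentile) {
  if (any(percentile < 0 | percentile > 100))
    stop("percentile must lie in [0, 100]")
  ifelse(percentile > 98, "Clinical Range",
         ifelse(percentile >= 93, "Borderline Clinical Range", "Normal range"))
}

kwppsi_cols <- function() paste0("kwppsi_", c("block", "maze", "picture",
                                              "vocabulary", "similarity",
                                              "digit_span"))
cnsvs_cols <- function() paste0("cnsvs_", c("symbol_digit", "reasoning",
                                            "shift_attention",
                                            "verbal_memory", "visual_memory"))

require_scores <- function(scores, cols, instrument) {
  vals <- unlist(scores[cols])
  if (anyNA(vals))
    stop("incomplete record: missing ", instrument, " score(s): ",
         paste(cols[is.na(vals)], collapse = ", "))
  vals
}

#' Cognitive exclusion rule
#'
#' A subject is excluded on cognitive grounds if at least one required test
#' falls below the 2nd percentile, or at least three required tests fall
#' below the 7th percentile. Required tests by age group: infants, the six
#' preschool subtests; children and Adult 1, the five neurocognitive
#' subtests; Adult 2, the five neurocognitive subtests plus the MMSE. The
#' MMSE has no printed 2nd-percentile anchor, so it participates only in
#' the below-7th-percentile tally (a raw score below 25 counts, 25 being
#' the printed 7th-percentile anchor).
#'
#' @param scores one subject's screening scores (named list or one-row data
#'   frame with the columns produced by [sample_cohort()]).
#' @param age_group one of the groups from [assign_age_group()].
#' @return Logical: \code{TRUE} if excluded.
#' @export
cognitive_exclusion <- function(scores, age_group) {
  age_group <- match.arg(age_group, c("infant", "child", "adult1", "adult2"))
  if (age_group == "infant") {
    pct <- standard_score_percentile(
      require_scores(scores, kwppsi_cols(), "K-WPPSI"))
    mmse_lt7 <- 0L
  } else {
    pct <- standard_score_percentile(
      require_scores(scores, cnsvs_cols(), "CNSVS"))
    mmse_lt7 <- 0L
    if (age_group == "adult2") {
      mmse <- require_scores(scores, "mmse", "MMSE")
      mmse_lt7 <- as.integer(mmse < 25)
    }
  }
  any(pct < 2) || (sum(pct < 7) + mmse_lt7) >= 3
}

#' Emotional exclusion rule
#'
#' Infants are excluded if the behavior-checklist depression or anxiety
#' percentile exceeds 98. Older subjects are scored on three subdomains --
#' state anxiety, trait anxiety, and depression (children's inventory below
#' 20 y, adult inventory from 20 y) -- and excluded if any subdomain is
#' high-risk or at least two are at-risk.
#'
#' @inheritParams cognitive_exclusion
#' @param age years.
#' @param sex \code{"male"} or \code{"female"} (needed for the
#'   anxiety-inventory thresholds).
#' @return Logical: \code{TRUE} if excluded.
#' @export
emotional_exclusion <- function(scores, age_group, age, sex) {
  age_group <- match.arg(age_group, c("infant", "child", "adult1", "adult2"))
  if (age_group == "infant") {
    pct <- require_scores(scores, c("kcbcl_depression_pct",
                                    "kcbcl_anxiety_pct"), "K-CBCL")
    return(any(pct > 98))
  }
  st <- classify_stai(require_scores(scores, "stai_state", "STAI state"),
                      "state", age, sex)
  tr <- classify_stai(require_scores(scores, "stai_trait", "STAI trait"),
                      "trait", age, sex)
  dep <- if (age_group == "child")
    classify_cdi(require_scores(scores, "cdi", "CDI"))
  else
    classify_bdi(require_scores(scores, "bdi", "BDI"))
  lev <- c(st, tr, tolower(dep))
  n_high <- sum(lev == "high-risk")
  n_risk <- sum(lev == "risk")
  n_high >= 1 || n_risk >= 2
}

#' Behavioral exclusion rule
#'
#' Infants and children/adolescents require a passing expert behavioral
#' evaluation (checklist-based clinician or guardian report); adults have
#' no behavioral criterion.
#'
#' @inheritParams cognitive_exclusion
#' @return Logical: \code{TRUE} if excluded.
#' @export
behavioral_exclusion <- function(scores, age_group) {
  age_group <- match.arg(age_group, c("infant", "child", "adult1", "adult2"))
  if (age_group %in% c("adult1", "adult2")) return(FALSE)
  pass <- scores[["behavioral_expert_pass"]]
  if (is.null(pass) || is.na(pass))
    stop("incomplete record: missing behavioral expert evaluation")
  !isTRUE(as.logical(pass))
}

#' Pre-screening exclusion
#'
#' Any recorded exclusionary history (psychiatric or neurological disease,
#' head trauma, epilepsy, conduct disorder, brain-affecting treatment)
#' excludes the subject.
#'
#' @inheritParams cognitive_exclusion
#' @return Logical: \code{TRUE} if excluded.
#' @export
prescreen_exclusion <- function(scores) {
  flags <- scores[["history_flags"]]
  !is.null(flags) && !is.na(flags) && nzchar(trimws(flags))
}

#' Screen one subject against all four normative criteria
#'
#' Composes the pre-screening, cognitive, emotional and behavioral rules
#' for the subject's age group. A subject is eligible for the normative
#' database if and only if no exclusion flag is set.
#'
#' @param age years.
#' @param sex \code{"male"} or \code{"female"}.
#' @param scores the subject's screening scores (named list or one-row data
#'   frame).
#' @return A list with \code{age_group}, the four exclusion flags and
#'   \code{eligible}.
#' @export
screen_subject <- function(age, sex, scores) {
  grp <- assign_age_group(age)
  pre <- prescreen_exclusion(scores)
  cog <- cognitive_exclusion(scores, grp)
  emo <- emotional_exclusion(scores, grp, age, sex)
  beh <- behavioral_exclusion(scores, grp)
  list(age_group = grp,
       prescreen_excluded = pre, cognitive_excluded = cog,
       emotional_excluded = emo, behavioral_excluded = beh,
       eligible = !(pre || cog || emo || beh))
}

#' Screen a whole cohort
#'
#' Applies [screen_subject()] to every row of a cohort's demographics and
#' screening tables.
#'
#' @param cohort a \code{qeeg_cohort}, or a data frame containing columns
#'   \code{id}, \code{age}, \code{sex} plus the screening-score columns.
#' @return Data frame: one row per subject with the age group, the four
#'   exclusion flags and the eligibility verdict.
#' @export
screen_cohort <- function(cohort) {
  if (inherits(cohort, "qeeg_cohort")) {
    df <- merge(cohort$demographics[, c("id", "age", "sex")],
                cohort$screening, by = "id", sort = FALSE)
  } else {
    df <- cohort
  }
  res <- lapply(seq_len(nrow(df)), function(i) {
    as.data.frame(screen_subject(df$age[i], df$sex[i], df[i, ]),
                  stringsAsFactors = FALSE)
  })
  out <- cbind(id = df$id, do.call(rbind, res), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
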
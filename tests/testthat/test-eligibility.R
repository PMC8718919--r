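test_that("age groups match the half-open protocol intervals", {
  expect_identical(assign_age_group(6.9), "infant")
  expect_identical(assign_age_group(50.0), "adult2")
  expect_identical(assign_age_group(19.99), "child")
  expect_error(assign_age_group(3.9), "outside")

  # exhaustive boundary oracle over the whole protocol age range
  ages <- seq(4, 81, by = 0.01)
  oracle <- ifelse(ages < 7, "infant",
                   ifelse(ages < 20, "child",
                          ifelse(ages < 50, "adult1", "adult2")))
  expect_identical(assign_age_group(ages), oracle)
})

test_that("instrument classifiers reproduce the printed cut-offs", {
  cases <- list(
    list(classify_kwppsi, 69, "Extremely Low"),
    list(classify_kwppsi, 70, "Borderline"),
    list(classify_kwppsi, 130, "Very Superior"),
    list(classify_cnsvs, 109, "Above Average"),
    list(classify_cnsvs, 89, "Low Average"),
    list(classify_cnsvs, 0, "Very Low"),
    list(classify_mmse, 24, "Normal"),
    list(classify_mmse, 9, "Severe Dementia"),
    list(classify_mmse, 0, "Severe Dementia"),
    list(classify_cdi, 29, "High-risk"),
    list(classify_cdi, 21, "Normal"),
    list(classify_bdi, 9, "Normal"),
    list(classify_bdi, 0, "Normal"),
    list(classify_bdi, 24, "High-risk"),
    list(classify_kcbcl, 98.5, "Clinical Range"),
    list(classify_kcbcl, 93, "Borderline Clinical Range"),
    list(classify_kcbcl, 0, "Normal range")
  )
  for (cs in cases) expect_identical(cs[[1]](cs[[2]]), cs[[3]])

  # anxiety inventory, male aged 25 (printed state bands 58-62 / 63-)
  expect_identical(classify_stai(58, "state", 25, "male"), "risk")
  expect_identical(classify_stai(63, "state", 25, "male"), "high-risk")
  expect_identical(classify_stai(0, "state", 25, "male"), "normal")
  expect_identical(classify_stai(0, "trait", 12, "female"), "normal")
  expect_error(classify_stai(81, "state", 25, "male"), "exceed 80")
  expect_error(classify_stai(40, "state", 6, "male"), "not applicable")
})

test_that("classifiers are total and monotone on their printed domains", {
  check_total_monotone <- function(f, domain, levels_best_last) {
    labs <- f(domain)
    expect_true(all(labs %in% levels_best_last))
    ranks <- match(labs, levels_best_last)
    expect_true(all(diff(ranks) >= 0))
  }
  check_total_monotone(classify_kwppsi, 0:160,
                       c("Extremely Low", "Borderline", "Low Average",
                         "Average", "High Average", "Superior",
                         "Very Superior"))
  check_total_monotone(classify_cnsvs, 0:160,
                       c("Very Low", "Low", "Low Average", "Average",
                         "Above Average"))
  check_total_monotone(classify_mmse, 0:30,
                       c("Severe Dementia", "Moderate Dementia",
                         "Mild Dementia", "Normal"))
  # higher depression/anxiety scores never yield a better category
  check_total_monotone(function(x) classify_cdi(54 - x), 0:54,
                       rev(c("Normal", "Mild", "Risk", "High-risk")))
  check_total_monotone(function(x) classify_bdi(63 - x), 0:63,
                       rev(c("Normal", "Mild", "Risk", "High-risk")))
  for (sub in c("state", "trait")) for (sex in c("male", "female"))
    for (age in c(10, 25, 45)) {
      labs <- vapply(0:80, function(s) classify_stai(s, sub, age, sex),
                     character(1))
      ranks <- match(labs, c("normal", "risk", "high-risk"))
      expect_true(all(!is.na(ranks)) && all(diff(ranks) >= 0),
                  info = paste(sub, sex, age))
    }
})

test_that("cognitive exclusion matches a brute-force rule evaluator", {
  # printed worked example: one test below the 2nd percentile excludes
  sc <- passing_scores("child")
  sc$cnsvs_reasoning <- 65   # percentile ~ 1%
  expect_true(cognitive_exclusion(sc, "child"))
  expect_false(cognitive_exclusion(passing_scores("child"), "child"))

  # literal brute-force oracle over random score vectors
  kw <- paste0("kwppsi_", c("block", "maze", "picture", "vocabulary",
                            "similarity", "digit_span"))
  cn <- paste0("cnsvs_", c("symbol_digit", "reasoning", "shift_attention",
                           "verbal_memory", "visual_memory"))
  oracle <- function(sc, grp) {
    tests <- if (grp == "infant") unlist(sc[kw]) else unlist(sc[cn])
    pct <- 100 * pnorm((tests - 100) / 15)
    n2 <- 0; n7 <- 0
    for (p in pct) {
      if (p < 2) n2 <- n2 + 1
      if (p < 7) n7 <- n7 + 1
    }
    if (grp == "adult2" && sc$mmse < 25) n7 <- n7 + 1
    n2 >= 1 || n7 >= 3
  }
  set.seed(77)
  for (i in 1:300) {
    grp <- sample(c("infant", "child", "adult1", "adult2"), 1)
    sc <- passing_scores(grp)
    for (t in c(kw, cn)) sc[[t]] <- round(runif(1, 50, 130))
    sc$mmse <- sample(0:30, 1)
    expect_identical(cognitive_exclusion(sc, grp), oracle(sc, grp),
                     info = paste("case", i, grp))
  }
})

test_that("emotional exclusion matches the subdomain-combination rule", {
  # adult worked example: one high-risk subdomain excludes
  sc <- passing_scores("adult1")
  sc$bdi <- 30
  expect_true(emotional_exclusion(sc, "adult1", 30, "male"))
  expect_false(emotional_exclusion(passing_scores("adult1"), "adult1",
                                   30, "male"))

  # exhaustive 3^3 enumeration for an adult male aged 25:
  # state risk band 58-62 (high 63-), trait risk 58-62 (high 63-)
  stai_by_level <- c(normal = 40, risk = 60, `high-risk` = 70)
  bdi_by_level <- c(normal = 5, risk = 20, `high-risk` = 30)
  levels <- c("normal", "risk", "high-risk")
  for (st in levels) for (tr in levels) for (dp in levels) {
    sc <- passing_scores("adult1")
    sc$stai_state <- stai_by_level[[st]]
    sc$stai_trait <- stai_by_level[[tr]]
    sc$bdi <- bdi_by_level[[dp]]
    want <- sum(c(st, tr, dp) == "high-risk") >= 1 ||
      sum(c(st, tr, dp) == "risk") >= 2
    expect_identical(emotional_exclusion(sc, "adult1", 25, "male"), want,
                     info = paste(st, tr, dp))
  }

  # infants: checklist percentile above 98 excludes
  sc <- passing_scores("infant")
  sc$kcbcl_anxiety_pct <- 99
  expect_true(emotional_exclusion(sc, "infant", 5, "female"))
  sc$kcbcl_anxiety_pct <- 98
  expect_false(emotional_exclusion(sc, "infant", 5, "female"))
})

test_that("screen_subject composes the four criteria and is pure", {
  for (grp in c("infant", "child", "adult1", "adult2")) {
    age <- age_for_group(grp)
    res <- screen_subject(age, "female", passing_scores(grp))
    expect_true(res$eligible, info = grp)
    expect_identical(res$age_group, grp)

    flagged <- passing_scores(grp)
    flagged$history_flags <- "epilepsy"
    expect_false(screen_subject(age, "female", flagged)$eligible)
  }
  # behavioral expert evaluation binds only for minors
  sc <- passing_scores("child")
  sc$behavioral_expert_pass <- FALSE
  expect_false(screen_subject(12, "male", sc)$eligible)

  # missing required instrument names the instrument
  sc <- passing_scores("adult2")
  sc$mmse <- NA
  expect_error(screen_subject(60, "male", sc), "MMSE")
  sc2 <- passing_scores("child")
  sc2$cdi <- NA
  expect_error(screen_subject(12, "male", sc2), "CDI")

  # purity: identical record, identical verdict
  r1 <- screen_subject(33.3, "male", passing_scores("adult1"))
  r2 <- screen_subject(33.3, "male", passing_scores("adult1"))
  expect_identical(r1, r2)
})

test_that("generated cohorts fail screening at the configured rate", {
  co <- quiet_cohort(500, seed = 101, fail_fraction = 0.2)
  verdict <- screen_cohort(co)
  # the verdicts reproduce the generator's ground-truth labels exactly
  expect_identical(verdict$eligible,
                   co$demographics$truth_eligible[
                     match(verdict$id, co$demographics$id)])
  # and the eligible fraction lies within the binomial 99% CI of 0.8
  n <- nrow(verdict)
  ci <- 0.8 + c(-1, 1) * qnorm(0.995) * sqrt(0.8 * 0.2 / n)
  expect_gt(mean(verdict$eligible), ci[1])
  expect_lt(mean(verdict$eligible), ci[2])
})
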
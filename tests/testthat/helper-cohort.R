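# Screening-score fixtures: a record that passes every rule for the given
# age group, built in code so tests can perturb single fields.
passing_scores <- function(age_group) {
  base <- list(
    kwppsi_block = 100, kwppsi_maze = 100, kwppsi_picture = 100,
    kwppsi_vocabulary = 100, kwppsi_similarity = 100,
    kwppsi_digit_span = 100,
    cnsvs_symbol_digit = 100, cnsvs_reasoning = 100,
    cnsvs_shift_attention = 100, cnsvs_verbal_memory = 100,
    cnsvs_visual_memory = 100,
    mmse = 29, stai_state = 35, stai_trait = 35, cdi = 5, bdi = 5,
    kcbcl_depression_pct = 50, kcbcl_anxiety_pct = 50,
    behavioral_expert_pass = TRUE, history_flags = ""
  )
  base
}

# Representative age per group (used when only the group matters).
age_for_group <- function(age_group) {
  switch(age_group, infant = 5, child = 12, adult1 = 30, adult2 = 60)
}

quiet_cohort <- function(n_per_sex, seed, noise_sd = 0.3,
                         fail_fraction = 0, ...) {
  sample_cohort(cohort_config(n_per_sex = n_per_sex, seed = seed,
                              noise_sd = noise_sd,
                              screening_fail_fraction = fail_fraction, ...))
}

# Sample skewness (used for the log-transform skew-reduction checks).
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2)^1.5)
}
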
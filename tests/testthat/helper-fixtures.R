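# Shared fixtures: study-sample mean curves and small synthetic cohorts.

# Early-gestation (V1) marginal mean curves of the calibration targets;
# insulin and C-peptide back-transformed from their log / square-root means.
v1_mean_curves <- function() {
  tg <- visit_targets_default()$V1
  list(glucose = tg$g$mean,
       insulin = exp(tg$log_i$mean),
       cpeptide = tg$sqrt_cp$mean^2,
       age = tg$age[["mean"]],
       bmi = exp(tg$log_bmi[["mean"]]))
}

# One complete synthetic subject-visit row built from the V1 mean curves.
mean_visit_row <- function() {
  cu <- v1_mean_curves()
  row <- data.frame(subject_id = "S0001", visit = "V1",
                    age = cu$age, bmi = cu$bmi,
                    t(stats::setNames(cu$glucose, paste0("g", OGTT_TIMES))),
                    t(stats::setNames(cu$insulin, paste0("i", OGTT_TIMES))),
                    t(stats::setNames(cu$cpeptide, paste0("cp", OGTT_TIMES))),
                    gdm = "NGT", primiparous = TRUE, family_history = FALSE,
                    history_gdm = FALSE)
  rownames(row) <- NULL
  row
}

small_cohort <- function(n = 67, seed = 1, ...) {
  generate_cohort(generator_config(n_subjects = n, seed = seed, ...))
}
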
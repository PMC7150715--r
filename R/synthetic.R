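# Synthetic longitudinal OGTT cohort generator.
#
# Subjects carry three lognormal latent traits — peripheral insulin
# sensitivity (si), beta-cell function (beta), and a fasting/hepatic insulin
# resistance axis (hf) that moves fasting insulin, C-peptide and (weakly)
# fasting glucose without changing the dynamic response.  The product
# si * beta (the disposition) drives the glucose excursion; insulin is a
# secretion response increasing in beta and in the relative glucose
# excursion; C-peptide is the secretion signal smoothed by a slow
# exponential kernel (its slower peripheral kinetics).
# Visit-specific target curves carry the population pregnancy effects
# (glycaemia higher in late gestation, fasting glucose higher post partum),
# while the per-subject sensitivity trajectory is recorded as si * shift_v
# with shift(V2) < shift(V1) < shift(V3).

#' Default per-visit marginal targets for the generator
#'
#' Marginal means and standard deviations per variable and visit for a
#' pregnancy OGTT study sample (visits at early gestation V1, 24-28 weeks V2,
#' and post partum V3): glucose in mg/dl, insulin as natural-log uU/ml,
#' C-peptide as square-root ng/ml, BMI as natural-log kg/m2, age in years.
#'
#' @return named list with one element per visit (`V1`,`V2`,`V3`), each a list
#'   with `age`, `log_bmi`, `g`, `log_i`, `sqrt_cp` (each `c(mean= , sd= )`
#'   or 5-vectors `mean`/`sd` for the curves).
#' @export
visit_targets_default <- function() {
  list(
    V1 = list(
      age = c(mean = 29.8, sd = 5.1),
      log_bmi = c(mean = 3.24, sd = 0.18),
      g = list(mean = c(76.8, 125.1, 118.5, 102.8, 97.1),
               sd = c(7.5, 25.5, 33.4, 29.6, 24.5)),
      log_i = list(mean = c(1.84, 3.62, 3.63, 3.29, 3.28),
                   sd = c(0.83, 1.34, 1.24, 1.38, 1.35)),
      sqrt_cp = list(mean = c(1.30, 2.48, 2.80, 2.71, 2.61),
                     sd = c(0.25, 0.43, 0.53, 0.59, 0.61))
    ),
    V2 = list(
      age = c(mean = 30.1, sd = 4.8),
      log_bmi = c(mean = 3.31, sd = 0.16),
      g = list(mean = c(77.8, 129.7, 131.9, 114.5, 102.7),
               sd = c(9.3, 25.4, 31.8, 29.8, 25.6)),
      log_i = list(mean = c(1.86, 3.46, 3.63, 3.60, 3.50),
                   sd = c(1.04, 1.57, 1.32, 1.28, 1.14)),
      sqrt_cp = list(mean = c(1.43, 2.60, 3.10, 3.06, 2.94),
                     sd = c(0.27, 0.50, 0.55, 0.63, 0.62))
    ),
    V3 = list(
      age = c(mean = 31.9, sd = 5.4),
      log_bmi = c(mean = 3.22, sd = 0.14),
      g = list(mean = c(83.0, 126.4, 110.4, 91.9, 94.0),
               sd = c(9.3, 21.8, 29.6, 20.8, 18.0)),
      log_i = list(mean = c(1.00, 3.00, 3.14, 3.04, 2.52),
                   sd = c(1.41, 1.30, 1.09, 1.06, 1.04)),
      sqrt_cp = list(mean = c(1.30, 2.34, 2.62, 2.59, 2.47),
                     sd = c(0.27, 0.34, 0.34, 0.38, 0.44))
    )
  )
}

#' Generator configuration
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed; every random draw in the generator flows from it.
#' @param targets per-visit marginal targets, default [visit_targets_default()].
#' @param retention per-visit retention probabilities (default 67/67, 57/67,
#'   23/67: the attrition pattern of a pregnancy cohort of 67 women).
#' @param rho latent correlation between log sensitivity and log beta-cell
#'   function (default -0.3: physiological compensation).
#' @param sd_log_si,sd_log_beta,sd_log_hf latent log-scale standard
#'   deviations (`hf` is the fasting/hepatic insulin resistance axis,
#'   independent of the other two).
#' @param visit_si_shift multiplicative per-visit change in sensitivity,
#'   `V2 < V1 < V3`.
#' @param gdm_fraction intended fraction of GDM (design target ~ 6/67; the
#'   realized fraction, attached to the cohort, emerges from the IADPSG
#'   thresholds applied to the generated curves).
#' @param missing_cells number of post-load OGTT cells set missing by
#'   [inject_missingness()] when the pipeline is run (default 5).
#' @param link link strengths from the latents to the observables (`hf_i0`,
#'   `hf_g0`, `hf_cp0` act on the fasting samples only).
#' @param noise log-scale measurement/biological noise SDs; `subject_frac`
#'   gives the fraction of the `amp` and `g0` noise VARIANCE that is stable
#'   within subject across visits (trait-like) rather than per-occasion.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 67, seed = 1,
                             targets = visit_targets_default(),
                             retention = c(V1 = 1, V2 = 57 / 67, V3 = 23 / 67),
                             rho = -0.3,
                             sd_log_si = 0.45, sd_log_beta = 0.45,
                             sd_log_hf = 0.5,
                             visit_si_shift = c(V1 = 1, V2 = 0.75, V3 = 1.5),
                             gdm_fraction = 6 / 67,
                             missing_cells = 5,
                             link = list(amp = 0.7, g0 = 0.12,
                                         ins_beta = 0.6, ins_si = 0.4,
                                         ins_glu = 1.5,
                                         cp_beta = 0.5, cp_si = 0.2,
                                         cp_glu = 1.0, cp_tau = 60,
                                         hf_i0 = 1.1, hf_g0 = 0.08,
                                         hf_cp0 = 0.7),
                             noise = list(amp = 0.20, g0 = 0.05, g = 0.08,
                                          i = 0.40, cp = 0.12,
                                          subject_frac = c(amp = 0.75,
                                                           g0 = 0.6))) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("`n_subjects` must be >= 2", call. = FALSE)
  if (gdm_fraction < 0 || gdm_fraction >= 1)
    stop("`gdm_fraction` must be in [0, 1)", call. = FALSE)
  if (sd_log_si <= 0 || sd_log_beta <= 0 || sd_log_hf <= 0)
    stop("latent SDs must be > 0", call. = FALSE)
  for (v in names(targets)) {
    tg <- targets[[v]]
    sds <- c(tg$age[["sd"]], tg$log_bmi[["sd"]], tg$g$sd, tg$log_i$sd,
             tg$sqrt_cp$sd)
    if (any(sds <= 0)) stop("target SDs must be > 0", call. = FALSE)
  }
  if (!(visit_si_shift[["V2"]] < visit_si_shift[["V1"]] &&
        visit_si_shift[["V1"]] < visit_si_shift[["V3"]]))
    stop("visit_si_shift must satisfy V2 < V1 < V3", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 targets = targets, retention = retention, rho = rho,
                 sd_log_si = sd_log_si, sd_log_beta = sd_log_beta,
                 sd_log_hf = sd_log_hf,
                 visit_si_shift = visit_si_shift,
                 gdm_fraction = gdm_fraction,
                 missing_cells = as.integer(missing_cells),
                 link = link, noise = noise),
            class = "generator_config")
}

#' Noise-free OGTT curves for given latent traits
#'
#' The deterministic core of the generator: mean glucose, insulin and
#' C-peptide curves for a subject with sensitivity `si` and beta-cell function
#' `beta` at a given visit, with all noise terms at zero.  The glucose
#' excursion scales as `(si * beta)^-amp`; insulin increases in `beta` and in
#' the relative glucose excursion; C-peptide is the secretion signal smoothed
#' with an exponential kernel of time constant `cp_tau` minutes.
#'
#' @param si,beta,hf latent traits (> 0; population geometric mean 1).
#' @param visit `"V1"`, `"V2"` or `"V3"`.
#' @param config a [generator_config()].
#' @return list with `glucose` (mg/dl), `insulin` (uU/ml), `cpeptide` (ng/ml)
#'   at minutes 0/30/60/90/120.
#' @export
ogtt_curves <- function(si, beta, hf = 1, visit = "V1",
                        config = generator_config()) {
  stopifnot(si > 0, beta > 0, hf > 0)
  .gen_curves(log(si), log(beta), log(hf), visit, config,
              eps = list(amp = 0, g0 = 0, g = numeric(5), i = numeric(5),
                         cp = numeric(5)),
              normalize = FALSE)
}

# Internal curve builder.  `eps` holds the log-scale noise draws; with
# `normalize = TRUE` the lognormal latent/noise factors on glucose are mean
# centred (E[factor] = 1) so population means match the visit targets.
.gen_curves <- function(lsi, lbeta, lhf, visit, config, eps,
                        normalize = TRUE) {
  tg <- config$targets[[visit]]
  lk <- config$link
  d <- lsi + lbeta                                   # log disposition
  var_d <- config$sd_log_si^2 + config$sd_log_beta^2 +
    2 * config$rho * config$sd_log_si * config$sd_log_beta

  # fasting glucose: weakly decreasing in disposition, raised by fasting
  # insulin resistance
  la_g0 <- -lk$g0 * d + lk$hf_g0 * lhf + eps$g0
  cent_g0 <- if (normalize)
    (lk$g0^2 * var_d + (lk$hf_g0 * config$sd_log_hf)^2 +
       config$noise$g0^2) / 2 else 0
  g0 <- tg$g$mean[1] * exp(la_g0 - cent_g0)

  # excursion amplitude: decreasing in disposition
  la_amp <- -lk$amp * d + eps$amp
  cent_amp <- if (normalize)
    (lk$amp^2 * var_d + config$noise$amp^2) / 2 else 0
  relamp <- exp(la_amp - cent_amp)
  exc <- (tg$g$mean - tg$g$mean[1]) * relamp *
    exp(eps$g - if (normalize) config$noise$g^2 / 2 else 0)
  glucose <- g0 + exc
  glucose <- pmax(glucose, 40)                       # physiological floor

  # relative glycaemia vs the visit mean curve drives secretion
  lrel <- log(glucose / tg$g$mean)

  # fasting axis acts on the basal samples and fades with the dynamic response
  hf_w <- c(1, 0.15, 0.05, 0.05, 0.05)
  insulin <- exp(tg$log_i$mean + lk$ins_beta * lbeta - lk$ins_si * lsi +
                   lk$hf_i0 * hf_w * lhf + lk$ins_glu * lrel + eps$i)

  u <- exp(lk$cp_beta * lbeta - lk$cp_si * lsi + lk$cp_glu * lrel +
             lk$hf_cp0 * hf_w * lhf)
  smooth_u <- .exp_smooth(u, OGTT_TIMES, tau = lk$cp_tau)
  cpeptide <- (tg$sqrt_cp$mean)^2 * smooth_u * exp(eps$cp)

  list(glucose = glucose, insulin = insulin, cpeptide = cpeptide)
}

# Exponential-kernel smoothing of a sampled signal: the solution of
# tau * dy/dt = u - y with steady-state initial condition y(0) = u(0),
# u linearly interpolated between samples, read back at the sample times.
.exp_smooth <- function(u, times, tau) {
  dt <- 1
  fine_t <- seq(min(times), max(times), by = dt)
  uf <- stats::approx(times, u, xout = fine_t)$y
  y <- numeric(length(fine_t))
  y[1] <- uf[1]
  ee <- exp(-dt / tau)
  for (j in seq_along(fine_t)[-1])
    y[j] <- y[j - 1] * ee + (uf[j - 1] + uf[j]) / 2 * (1 - ee)
  y[match(times, fine_t)]
}

#' Generate a longitudinal synthetic OGTT cohort
#'
#' Draws latent traits, builds per-visit OGTT curves, classifies GDM with the
#' IADPSG thresholds applied to the generated early-gestation curves, and
#' applies per-visit retention.  Deterministic given `config$seed`.
#'
#' @param config a [generator_config()].
#' @return data frame with columns `subject_id, visit, age, bmi, g0..g120,
#'   i0..i120, cp0..cp120, gdm, primiparous, family_history, history_gdm`.
#'   Attributes: `latents` (per-subject `si`, `beta`, and per-visit shifted
#'   sensitivities), `config`, and `gdm_fraction_realized`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n_subjects
  tg1 <- config$targets$V1
  age <- pmax(stats::rnorm(n, tg1$age[["mean"]], tg1$age[["sd"]]), 18)

  z <- MASS::mvrnorm(n, mu = c(0, 0),
                     Sigma = matrix(c(1, config$rho, config$rho, 1), 2))
  lsi <- config$sd_log_si * z[, 1] - 0.02 * (age - tg1$age[["mean"]])
  lbeta <- config$sd_log_beta * z[, 2]
  lhf <- stats::rnorm(n, 0, config$sd_log_hf)

  lbmi_dev <- -0.15 * lsi +
    stats::rnorm(n, 0, sqrt(max(tg1$log_bmi[["sd"]]^2 - (0.15 * config$sd_log_si)^2,
                                1e-4)))

  primiparous <- stats::runif(n) < 45 / 67
  family_history <- ifelse(stats::runif(n) < 1 / 67, NA,
                           stats::runif(n) < 23 / 67)
  d_c <- lsi + lbeta
  history_gdm <- !primiparous &
    stats::runif(n) < stats::plogis(stats::qlogis(0.15) - 1.2 * d_c)

  visits <- c("V1", "V2", "V3")
  age_offset <- c(V1 = 0, V2 = 0.16, V3 = 0.9)
  keep <- cbind(V1 = rep(TRUE, n),
                V2 = stats::runif(n) < config$retention[["V2"]],
                V3 = stats::runif(n) < config$retention[["V3"]])

  # trait-like (subject-level) components of the amplitude and basal noise
  sf <- config$noise$subject_frac
  amp_subj <- stats::rnorm(n, 0, config$noise$amp * sqrt(sf[["amp"]]))
  g0_subj <- stats::rnorm(n, 0, config$noise$g0 * sqrt(sf[["g0"]]))
  amp_occ_sd <- config$noise$amp * sqrt(1 - sf[["amp"]])
  g0_occ_sd <- config$noise$g0 * sqrt(1 - sf[["g0"]])

  rows <- vector("list", n * 3)
  for (s in seq_len(n)) {
    for (vi in seq_along(visits)) {
      v <- visits[vi]
      tg <- config$targets[[v]]
      eps <- list(amp = amp_subj[s] + stats::rnorm(1, 0, amp_occ_sd),
                  g0 = g0_subj[s] + stats::rnorm(1, 0, g0_occ_sd),
                  g = c(0, stats::rnorm(4, 0, config$noise$g)),
                  i = stats::rnorm(5, 0, config$noise$i),
                  cp = stats::rnorm(5, 0, config$noise$cp))
      cur <- .gen_curves(lsi[s], lbeta[s], lhf[s], v, config, eps)
      rows[[(s - 1) * 3 + vi]] <- data.frame(
        subject_id = sprintf("S%04d", s), visit = v,
        age = age[s] + age_offset[[v]],
        bmi = exp(tg$log_bmi[["mean"]] + lbmi_dev[s]),
        t(stats::setNames(cur$glucose, .glucose_cols)),
        t(stats::setNames(cur$insulin, .insulin_cols)),
        t(stats::setNames(cur$cpeptide, .cpeptide_cols)),
        primiparous = primiparous[s],
        family_history = family_history[s],
        history_gdm = history_gdm[s])
    }
  }
  cohort <- do.call(rbind, rows)

  # GDM status per subject from the prepartum visits (IADPSG thresholds)
  cls <- function(v) {
    rows_v <- cohort[cohort$visit == v, ]
    stats::setNames(classify_gdm_iadpsg(rows_v$g0, rows_v$g60, rows_v$g120),
                    rows_v$subject_id)
  }
  c1 <- cls("V1"); c2 <- cls("V2")
  ids <- sprintf("S%04d", seq_len(n))
  gdm <- ifelse(c1[ids] == "GDM" | c2[ids] == "GDM", "GDM", "NGT")
  cohort$gdm <- gdm[cohort$subject_id]
  cohort <- cohort[, c("subject_id", "visit", "age", "bmi", .ogtt_cols,
                       "gdm", "primiparous", "family_history", "history_gdm")]

  keep_row <- keep[cbind(match(cohort$subject_id, ids),
                         match(cohort$visit, visits))]
  cohort <- cohort[keep_row, ]
  rownames(cohort) <- NULL

  shifts <- config$visit_si_shift
  attr(cohort, "latents") <- data.frame(
    subject_id = ids, si = exp(lsi), beta = exp(lbeta), hf = exp(lhf),
    si_v1 = exp(lsi) * shifts[["V1"]],
    si_v2 = exp(lsi) * shifts[["V2"]],
    si_v3 = exp(lsi) * shifts[["V3"]])
  attr(cohort, "config") <- config
  attr(cohort, "gdm_fraction_realized") <- mean(gdm == "GDM")
  cohort
}

#' Set a fixed number of post-load OGTT cells missing, completely at random
#'
#' Only post-load (minutes 30-120) glucose, insulin and C-peptide cells are
#' eligible; fasting samples and covariates are never blanked.
#'
#' @param cohort a cohort data frame.
#' @param n_cells number of cells to blank.
#' @param seed integer seed.
#' @return the cohort with exactly `n_cells` additional `NA` measurement
#'   cells; reproducible under `seed`.
#' @export
inject_missingness <- function(cohort, n_cells = 5, seed = 1) {
  eligible_cols <- setdiff(.ogtt_cols, c("g0", "i0", "cp0"))
  cells <- expand.grid(row = seq_len(nrow(cohort)), col = eligible_cols,
                       stringsAsFactors = FALSE)
  observed <- !mapply(function(r, cl) is.na(cohort[r, cl]),
                      cells$row, cells$col)
  cells <- cells[observed, ]
  if (n_cells < 0 || n_cells > nrow(cells))
    stop("`n_cells` must be between 0 and the number of eligible cells (",
         nrow(cells), ")", call. = FALSE)
  if (n_cells == 0) return(cohort)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  pick <- cells[sample.int(nrow(cells), n_cells), ]
  for (k in seq_len(nrow(pick)))
    cohort[pick$row[k], pick$col[k]] <- NA_real_
  cohort
}
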
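# C-peptide based reconstruction of insulin secretion, and the regression
# surrogates of beta-cell glucose sensitivity and rate sensitivity.

#' Population two-compartment C-peptide kinetic constants
#'
#' Van Cauter-type population kinetics for C-peptide in normal adults:
#' biexponential disposal with fast half-life 4.95 min (fraction 0.76) and
#' slow half-life 33 min, and a central distribution volume affine in body
#' surface area (`Vd = 1.92 * BSA + 0.64` litres).
#'
#' @param half_life_fast,half_life_slow disposal half-lives, minutes.
#' @param fraction_fast fraction of the bolus decay on the fast exponential.
#' @param vd_slope,vd_intercept distribution volume regression on BSA
#'   (litres per m2, litres).
#' @return a constants record (list) with derived first-order rate constants
#'   `k01` (irreversible loss), `k21`, `k12` (exchange) in min^-1 and a
#'   citation string.
#' @export
cpeptide_kinetics_normal <- function(half_life_fast = 4.95,
                                     half_life_slow = 33,
                                     fraction_fast = 0.76,
                                     vd_slope = 1.92, vd_intercept = 0.64) {
  stopifnot(half_life_fast > 0, half_life_slow > half_life_fast,
            fraction_fast > 0, fraction_fast < 1, vd_slope > 0)
  a <- log(2) / half_life_fast
  b <- log(2) / half_life_slow
  k12 <- fraction_fast * b + (1 - fraction_fast) * a
  k01 <- a * b / k12
  k21 <- a + b - k12 - k01
  list(half_life_fast = half_life_fast, half_life_slow = half_life_slow,
       fraction_fast = fraction_fast,
       vd_slope = vd_slope, vd_intercept = vd_intercept,
       k01 = k01, k21 = k21, k12 = k12,
       citation = "Van Cauter E, Mestrez F, Sturis J, Polonsky KS. Diabetes 1992;41:368-377 (population parameters, normal adults)")
}

#' Insulin secretion rate and total insulin secretion from C-peptide
#'
#' Reconstructs the prehepatic insulin secretion rate (ISR) by deconvolution
#' of peripheral C-peptide through a two-compartment kinetic model with
#' population constants, assuming a basal steady state at time 0 and
#' piecewise-linear concentrations between samples.  Total insulin secretion
#' (TIS) is the trapezoid integral of ISR over 0-120 min.
#'
#' @param cpeptide C-peptide concentrations at `times`.
#' @param times sampling grid in minutes, default [OGTT_TIMES].
#' @param bsa body surface area, m2 (default 1.73).
#' @param params kinetic constants from [cpeptide_kinetics_normal()].
#' @param per_m2 if `TRUE` (default) ISR and TIS are normalized per m2 BSA;
#'   otherwise they are whole-body rates/amounts.
#' @param policy a [unit_policy()].
#' @return list with `isr` (nmol/min/m2 at `times`), `tis` (nmol/m2) and the
#'   `params` record used.  At a constant concentration C the steady state
#'   gives `ISR = k01 * Vd * C` exactly.
#' @export
isr_deconvolution <- function(cpeptide, times = OGTT_TIMES, bsa = 1.73,
                              params = cpeptide_kinetics_normal(),
                              per_m2 = TRUE, policy = unit_policy()) {
  cp <- convert_cpeptide(cpeptide, policy$cpeptide, "ng/ml")
  if (any(!is.finite(cp)) || any(cp < 0))
    stop("C-peptide concentrations must be finite and non-negative",
         call. = FALSE)
  if (length(cp) != length(times) || length(cp) < 3)
    stop("need C-peptide at >= 3 sampling times", call. = FALSE)
  c1 <- cp * CPEPTIDE_NMOL_PER_NG          # nmol/l in the central pool
  vd <- params$vd_slope * bsa + params$vd_intercept   # litres
  # Steady state at t = 0: dC1/dt = 0 and dC2/dt = 0.
  c2_0 <- params$k21 / params$k12 * c1[1]
  # Integrate the peripheral pool forward on a fine grid with C1 linearly
  # interpolated, then read ISR(t) = Vd * (dC1/dt + (k01+k21) C1 - k12 C2)
  # at the sampling times; dC1/dt uses the piecewise-linear slopes, with the
  # mean of adjacent slopes at interior points and one-sided slopes at the ends.
  dt <- 0.25
  fine_t <- seq(min(times), max(times), by = dt)
  c1_fine <- stats::approx(times, c1, xout = fine_t)$y
  c2_fine <- numeric(length(fine_t))
  c2_fine[1] <- c2_0
  for (j in seq_along(fine_t)[-1]) {
    # exact step for dC2/dt = k21*C1 - k12*C2 with C1 held at interval mean
    c1_bar <- (c1_fine[j - 1] + c1_fine[j]) / 2
    ee <- exp(-params$k12 * dt)
    c2_fine[j] <- c2_fine[j - 1] * ee +
      (params$k21 / params$k12) * c1_bar * (1 - ee)
  }
  c2 <- c2_fine[match(times, fine_t)]
  slopes <- diff(c1) / diff(times)
  dc1 <- c(slopes[1],
           (slopes[-length(slopes)] + slopes[-1]) / 2,
           slopes[length(slopes)])
  # c1 in nmol/l times vd in litres gives nmol, so these are nmol/min.
  isr <- vd * (dc1 + (params$k01 + params$k21) * c1 - params$k12 * c2)
  if (per_m2) isr <- isr / bsa
  tis <- auc_trapezoid(isr, times)
  list(isr = isr, tis = tis, params = params, per_m2 = per_m2)
}

#' Beta-cell glucose sensitivity and rate sensitivity (regression surrogates)
#'
#' Simple regression surrogates of the dose-response model quantities:
#' `g_sens` is the least-squares slope of ISR on concurrent glucose across the
#' OGTT samples (secretion per unit glucose), and `rate_sens` relates the early
#' (0-30 min) incremental ISR to the early rate of change of glucose.  These
#' are surrogates of the full model-based beta-cell parameters, not fits of a
#' dose-response model, and are labelled as such in all outputs.
#'
#' @param glucose glucose at `times` (units per `policy`).
#' @param isr insulin secretion rate series from [isr_deconvolution()].
#' @param times sampling grid, default [OGTT_TIMES].
#' @param policy a [unit_policy()].
#' @return list with `g_sens` (nmol min^-1 m^-2 per mmol/l) and `rate_sens`
#'   (nmol m^-2 per mmol/l/min); a constant glucose profile makes the slope
#'   undefined: both are `NA` with attribute `flag = "constant_glucose"`.
#' @export
gsens_ratesens <- function(glucose, isr, times = OGTT_TIMES,
                           policy = unit_policy()) {
  g <- convert_glucose(glucose, policy$glucose, "mg/dl") /
    GLUCOSE_MGDL_PER_MMOL                 # mmol/l
  if (length(g) != length(isr) || length(g) < 3)
    stop("need >= 3 paired glucose/ISR points", call. = FALSE)
  if (stats::sd(g) == 0) {
    out <- list(g_sens = NA_real_, rate_sens = NA_real_)
    attr(out, "flag") <- "constant_glucose"
    return(out)
  }
  g_sens <- stats::cov(g, isr) / stats::var(g)
  dgdt <- (g[2] - g[1]) / (times[2] - times[1])       # mmol/l per min
  d_isr <- isr[2] - isr[1]
  rate_sens <- if (dgdt == 0) NA_real_ else d_isr / dgdt
  list(g_sens = g_sens, rate_sens = rate_sens)
}
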
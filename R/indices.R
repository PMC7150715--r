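# Fasting and dynamic indices of insulin action and secretion from a
# standard 75 g / 120 min OGTT sampled at 0, 30, 60, 90 and 120 minutes.

#' Canonical OGTT sampling grid (minutes)
#' @export
OGTT_TIMES <- c(0, 30, 60, 90, 120)

.check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop(sprintf("`%s` must be finite and strictly positive", name),
         call. = FALSE)
  invisible(x)
}

#' Trapezoidal area under a sampled curve
#'
#' Exact trapezoid-rule integral of a piecewise-linear curve over a window
#' whose endpoints lie on the sampling grid.
#'
#' @param values numeric vector of measurements.
#' @param times sampling times in minutes, strictly increasing, same length
#'   as `values`.
#' @param t_start,t_end window endpoints; must be elements of `times`.
#'
#' @return The area in `value * min` units.
#' @examples
#' auc_trapezoid(rep(2, 5), OGTT_TIMES)            # 240
#' auc_trapezoid(OGTT_TIMES, OGTT_TIMES)           # 7200 (linear ramp)
#' @export
auc_trapezoid <- function(values, times, t_start = min(times),
                          t_end = max(times)) {
  if (length(values) != length(times))
    stop("`values` and `times` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  i0 <- match(t_start, times)
  i1 <- match(t_end, times)
  if (is.na(i0) || is.na(i1))
    stop("window endpoints must lie on the sampling grid", call. = FALSE)
  if (i1 <= i0) stop("`t_end` must exceed `t_start`", call. = FALSE)
  idx <- i0:i1
  sum(diff(times[idx]) * (values[idx][-1] + values[idx][-length(idx)]) / 2)
}

#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' `HOMA-IR = (G0[mmol/l] * I0[uU/ml]) / 22.5`.  Higher values indicate more
#' fasting insulin resistance; the normalization point (5 mmol/l, 4.5 uU/ml)
#' maps to 1.
#'
#' @param g0 fasting glucose.
#' @param i0 fasting insulin.
#' @param policy a [unit_policy()] describing the input units.
#' @return numeric, dimensionless.
#' @examples
#' homa_ir(90.08, 4.5)  # 1
#' @export
homa_ir <- function(g0, i0, policy = unit_policy()) {
  u <- .to_conventional(glucose = g0, insulin = i0, policy = policy)
  .check_positive(u$glucose, "g0"); .check_positive(u$insulin, "i0")
  (u$glucose / GLUCOSE_MGDL_PER_MMOL) * u$insulin / 22.5
}

#' Quantitative insulin sensitivity check index (QUICKI)
#'
#' `QUICKI = 1 / (ln G0 + ln I0)` with glucose in mg/dl and insulin in uU/ml.
#' Natural logarithms are used throughout this package, which places typical
#' values near 0.15-0.20.
#'
#' @inheritParams homa_ir
#' @return numeric, dimensionless.
#' @export
quicki <- function(g0, i0, policy = unit_policy()) {
  u <- .to_conventional(glucose = g0, insulin = i0, policy = policy)
  .check_positive(u$glucose, "g0"); .check_positive(u$insulin, "i0")
  den <- log(u$glucose) + log(u$insulin)
  if (any(den == 0)) stop("log(g0) + log(i0) must be nonzero", call. = FALSE)
  1 / den
}

#' Matsuda whole-body insulin sensitivity index
#'
#' `10000 / sqrt(G0 * I0 * Gmean * Imean)` using all five OGTT time points,
#' glucose in mg/dl and insulin in uU/ml.
#'
#' @param glucose,insulin numeric vectors of length 5 (minutes 0..120).
#' @inheritParams homa_ir
#' @return numeric, dimensionless.
#' @examples
#' matsuda(rep(100, 5), rep(10, 5))  # 10
#' @export
matsuda <- function(glucose, insulin, policy = unit_policy()) {
  u <- .to_conventional(glucose = glucose, insulin = insulin, policy = policy)
  .check_positive(u$glucose, "glucose"); .check_positive(u$insulin, "insulin")
  if (length(u$glucose) != 5L || length(u$insulin) != 5L)
    stop("matsuda() expects the five standard OGTT samples", call. = FALSE)
  10000 / sqrt(u$glucose[1] * u$insulin[1] * mean(u$glucose) * mean(u$insulin))
}

# Constants of the published 2-hour OGIS formula (model-derived oral glucose
# insulin sensitivity; Mari et al., Diabetes Care 2001).  Units: glucose
# mg/dl, insulin uU/ml, dose g/m2, output ml min^-1 m^-2.
OGIS_2H_CONSTANTS <- list(
  p1 = 650, p2 = 325, p3 = 81300, p4 = 132, p5 = 652e-6, p6 = 173,
  v = 1e4,    # glucose distribution volume, ml/m2
  g_clamp = 90,  # reference clamp glucose, mg/dl
  delta_t = 30,  # G(120)-G(90) slope window, min
  citation = "Mari A, Pacini G, Murphy E, Ludvik B, Nolan JJ. Diabetes Care 2001;24:539-548 (2-h OGTT parameter set)"
)

#' Oral glucose insulin sensitivity (OGIS), 2-hour variant
#'
#' Model-derived glucose clearance during an OGTT, comparable to clamp glucose
#' clearance, from glucose at 0/90/120 min and insulin at 0/90 min.
#'
#' @param g0,g90,g120 glucose at 0, 90 and 120 minutes.
#' @param i0,i90 insulin at 0 and 90 minutes.
#' @param dose oral glucose dose in grams (default 75).
#' @param bsa body surface area in m2 (default 1.73).
#' @inheritParams homa_ir
#' @return OGIS in ml min^-1 m^-2.
#' @export
ogis_2h <- function(g0, g90, g120, i0, i90, dose = 75, bsa = 1.73,
                    policy = unit_policy()) {
  g <- .to_conventional(glucose = c(g0, g90, g120), policy = policy)$glucose
  i <- .to_conventional(insulin = c(i0, i90), policy = policy)$insulin
  .check_positive(g, "glucose"); .check_positive(i, "insulin")
  .check_positive(dose, "dose"); .check_positive(bsa, "bsa")
  k <- OGIS_2H_CONSTANTS
  d0 <- dose / bsa
  a <- k$p4 * ((k$p1 * d0 - k$v * (g[3] - g[2]) / k$delta_t) / g[2] +
                 k$p3 / g[1]) / (i[2] - i[1] + k$p2)
  b <- (k$p5 * (g[2] - k$g_clamp) + 1) * a
  (b + sqrt(b^2 + 4 * k$p5 * k$p6 * (g[2] - k$g_clamp) * a)) / 2
}

# Demographic OGTT regression formulas of Stumvoll et al. (Diabetes Care
# 2000;23:295-301 and 2001;24:796-797).  Units: insulin pmol/l, glucose
# mmol/l, BMI kg/m2.  MCR in ml kg^-1 min^-1, ISI in umol kg^-1 min^-1 per
# pmol/l, PH1/PH2 in pmol/l.
STUMVOLL_CONSTANTS <- list(
  mcr = c(intercept = 18.8, bmi = -0.271, i120 = -0.0052, g90 = -0.27),
  isi = c(intercept = 0.226, bmi = -0.0032, i120 = -0.0000645, g90 = -0.0037),
  ph1 = c(intercept = 1283, i30 = 1.829, g30 = -138.7, i0 = 3.772),
  ph2 = c(intercept = 286, i30 = 0.416, g30 = -25.94, i0 = 0.926),
  citation = "Stumvoll M et al. Diabetes Care 2000;23:295-301; Diabetes Care 2001;24:796-797 (formulas with demographics)"
)

#' Stumvoll OGTT estimates of insulin sensitivity and secretion
#'
#' The four demographic regression formulas: metabolic clearance rate (MCR),
#' insulin sensitivity index (ISI), and first- and second-phase insulin
#' response (PH1, PH2).  Inputs are taken in the units declared by `policy`
#' and converted internally to the pmol/l / mmol/l scales the published
#' coefficients expect.
#'
#' @param g30,g90 glucose at 30 and 90 minutes.
#' @param i0,i30,i120 insulin at 0, 30 and 120 minutes.
#' @param bmi body mass index, kg/m2.
#' @inheritParams homa_ir
#' @return A list with components `mcr`, `isi`, `ph1`, `ph2`.
#' @export
stumvoll_indices <- function(g30, g90, i0, i30, i120, bmi,
                             policy = unit_policy()) {
  g <- .to_conventional(glucose = c(g30, g90), policy = policy)$glucose /
    GLUCOSE_MGDL_PER_MMOL
  i <- .to_conventional(insulin = c(i0, i30, i120), policy = policy)$insulin *
    INSULIN_PMOL_PER_UU
  .check_positive(g, "glucose"); .check_positive(i, "insulin")
  .check_positive(bmi, "bmi")
  k <- STUMVOLL_CONSTANTS
  list(
    mcr = k$mcr[["intercept"]] + k$mcr[["bmi"]] * bmi +
      k$mcr[["i120"]] * i[3] + k$mcr[["g90"]] * g[2],
    isi = k$isi[["intercept"]] + k$isi[["bmi"]] * bmi +
      k$isi[["i120"]] * i[3] + k$isi[["g90"]] * g[2],
    ph1 = k$ph1[["intercept"]] + k$ph1[["i30"]] * i[2] +
      k$ph1[["g30"]] * g[1] + k$ph1[["i0"]] * i[1],
    ph2 = k$ph2[["intercept"]] + k$ph2[["i30"]] * i[2] +
      k$ph2[["g30"]] * g[1] + k$ph2[["i0"]] * i[1]
  )
}

#' Insulinogenic indices of the insulin response to glucose
#'
#' Early response `(I30 - I0) / (G30 - G0)`, late response
#' `AUC_I(60-120) / AUC_G(60-120)` and total response
#' `AUC_I(0-120) / AUC_G(0-120)` (trapezoid areas).
#'
#' @inheritParams matsuda
#' @param times sampling grid, default [OGTT_TIMES].
#' @return list with `sec_early`, `sec_late`, `sec_total`.  When
#'   `G30 == G0` the early index is undefined and returned as `NA` with
#'   attribute `flag = "sec_early_undefined"`.
#' @export
insulinogenic <- function(glucose, insulin, times = OGTT_TIMES,
                          policy = unit_policy()) {
  u <- .to_conventional(glucose = glucose, insulin = insulin, policy = policy)
  .check_positive(u$glucose, "glucose"); .check_positive(u$insulin, "insulin")
  g <- u$glucose; i <- u$insulin
  out <- list(
    sec_early = if (g[2] == g[1]) NA_real_ else (i[2] - i[1]) / (g[2] - g[1]),
    sec_late = auc_trapezoid(i, times, 60, 120) /
      auc_trapezoid(g, times, 60, 120),
    sec_total = auc_trapezoid(i, times, 0, 120) /
      auc_trapezoid(g, times, 0, 120)
  )
  if (is.na(out$sec_early))
    attr(out, "flag") <- "sec_early_undefined"
  out
}

#' Insulin secretion-sensitivity index 2 (oral disposition index)
#'
#' The exact product of the Matsuda index and the total insulinogenic index
#' (`AUC_I / AUC_G` over 0-120 min): a measure of beta-cell compensation for
#' ambient insulin resistance.
#'
#' @param matsuda,sec_total finite numerics.
#' @return numeric product.
#' @export
issi2 <- function(matsuda, sec_total) {
  if (any(!is.finite(matsuda)) || any(!is.finite(sec_total)))
    stop("issi2() requires finite inputs", call. = FALSE)
  matsuda * sec_total
}

#' IADPSG classification of gestational diabetes from OGTT glucose
#'
#' GDM if fasting glucose >= 5.1 mmol/l, or 1-h glucose >= 10.0 mmol/l, or
#' 2-h glucose >= 8.5 mmol/l (75 g load); thresholds inclusive.  Vectorized.
#'
#' @param g0,g60,g120 glucose at 0, 60 and 120 min.
#' @inheritParams homa_ir
#' @return character vector in `{"GDM", "NGT", "unknown"}`; a comparison that
#'   cannot be decided because of missing values yields `"unknown"`.
#' @examples
#' classify_gdm_iadpsg(92, 100, 100)   # "GDM" (fasting criterion)
#' classify_gdm_iadpsg(80, 181, 100)   # "GDM" (1-hour criterion)
#' @export
classify_gdm_iadpsg <- function(g0, g60, g120, policy = unit_policy()) {
  g0 <- convert_glucose(g0, policy$glucose, "mg/dl")
  g60 <- convert_glucose(g60, policy$glucose, "mg/dl")
  g120 <- convert_glucose(g120, policy$glucose, "mg/dl")
  thr <- c(5.1, 10.0, 8.5) * GLUCOSE_MGDL_PER_MMOL
  pos <- (!is.na(g0) & g0 >= thr[1]) | (!is.na(g60) & g60 >= thr[2]) |
    (!is.na(g120) & g120 >= thr[3])
  neg <- !is.na(g0) & g0 < thr[1] & !is.na(g60) & g60 < thr[2] &
    !is.na(g120) & g120 < thr[3]
  ifelse(pos, "GDM", ifelse(neg, "NGT", "unknown"))
}
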
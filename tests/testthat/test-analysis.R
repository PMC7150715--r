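# Statistical stage: contingency tests, Welch, logistic, forests, LMM.

test_that("chi-squared equals the hand-computed sum of (O-E)^2/E", {
  set.seed(14)
  for (k in 1:50) {
    tab <- matrix(stats::rpois(4, 20) + 1, 2)
    res <- pearson_chi2(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$chi2, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(res$p, stats::pchisq(res$chi2, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # perfectly proportional table carries no association
  prop <- pearson_chi2(matrix(c(10, 5, 10, 5), 2))
  expect_equal(prop$chi2, 0)
  expect_equal(prop$p, 1)
  expect_error(pearson_chi2(matrix(c(1, -1, 2, 2), 2)), "non-negative")
  expect_error(pearson_chi2(matrix(c(0, 0, 2, 2), 2)), "margin")
  expect_error(pearson_chi2(matrix(1:9, 3)), "2x2")
})

test_that("Fisher exact p equals exhaustive hypergeometric enumeration", {
  set.seed(15)
  for (k in 1:30) {
    tab <- matrix(stats::rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- fisher_exact(tab)
    # condition on the margins and sum P(table) <= P(observed)
    m <- sum(tab[1, ]); n2 <- sum(tab[2, ]); k1 <- sum(tab[, 1])
    support <- max(0, k1 - n2):min(m, k1)
    probs <- stats::dhyper(support, m, n2, k1)
    p_obs <- stats::dhyper(tab[1, 1], m, n2, k1)
    expect_equal(res$p, sum(probs[probs <= p_obs * (1 + 1e-7)]),
                 tolerance = 1e-10)
  }
})

test_that("contingency tests reproduce the reference cohort tables", {
  # reference values are printed to 3 decimals, so compare absolutely
  # parity: 41/61 primiparous without GDM vs 4/6 with GDM
  expect_lt(abs(pearson_chi2(matrix(c(41, 4, 20, 2), 2))$p - 0.978), 0.002)
  # family history of type 2 diabetes: 20/60 vs 3/6
  expect_lt(abs(pearson_chi2(matrix(c(20, 3, 40, 3), 2))$p - 0.413), 0.002)
  # GDM history among multiparous women: 3/20 vs 2/2 (exact test)
  expect_lt(abs(fisher_exact(matrix(c(3, 2, 17, 0), 2))$p - 0.043), 0.002)
})

test_that("Welch test agrees between raw samples and their summaries", {
  set.seed(16)
  x <- stats::rnorm(40, 1, 2); y <- stats::rnorm(25, 0, 1)
  a <- welch_t(x = x, y = y)
  b <- welch_t(mean(x), stats::sd(x), 40, mean(y), stats::sd(y), 25)
  expect_equal(a[c("t", "df", "p")], b[c("t", "df", "p")], tolerance = 1e-12)
  # and with stats::t.test on the raw samples
  tt <- stats::t.test(x, y)
  expect_equal(a$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(a$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  expect_error(welch_t(1, 1, 1, 0, 1, 10), "n >= 2")
  expect_error(welch_t(1, 0, 5, 0, 1, 10), "SDs")
})

test_that("Welch on the age summaries gives the hand-computed statistic", {
  # 29.08 +/- 4.68 (n=61) vs 36.67 +/- 4.63 (n=6)
  w <- welch_t(29.08, 4.68, 61, 36.67, 4.63, 6)
  expect_equal(abs(w$t), 3.83, tolerance = 0.01)
  expect_equal(w$df, 6.05, tolerance = 0.05)
  # the unequal-variance p at these tiny group sizes is ~0.009, far from
  # the pooled-variance p < 0.001 sometimes quoted for these summaries
  expect_true(w$p > 0.005 && w$p < 0.012)
})

test_that("logistic regression recovers planted coefficients at scale", {
  set.seed(17)
  n <- 1e4
  x <- stats::rnorm(n)
  b_true <- -2
  y <- stats::rbinom(n, 1, stats::plogis(-1 + b_true * x))
  fit <- fit_logistic_univariable(y, x)
  expect_lt(abs(fit$coef - b_true) / fit$se, 3)
  expect_false(fit$separation)
  # OR per `scale` units is exp(coef * scale)
  fit01 <- fit_logistic_univariable(y, x, scale = 0.01)
  expect_equal(fit01$or, exp(fit$coef * 0.01), tolerance = 1e-10)
  expect_equal(fit01$coef, fit$coef, tolerance = 1e-12)
  # profile CI covers the truth and brackets the estimate
  expect_true(fit$ci[1] < exp(b_true) && exp(b_true) < fit$ci[2])
  expect_true(fit$ci[1] < fit$or && fit$or < fit$ci[2])
})

test_that("a null predictor yields a near-unit odds ratio", {
  set.seed(18)
  n <- 1e4
  y <- stats::rbinom(n, 1, 0.3)
  fit <- fit_logistic_univariable(y, stats::rnorm(n))
  expect_true(fit$or > 0.9 && fit$or < 1.1)
})

test_that("logistic null type-I error is nominal at 5 percent", {
  set.seed(19)
  reps <- 2000
  p <- vapply(seq_len(reps), function(r) {
    y <- stats::rbinom(200, 1, 0.25)
    if (sum(y) == 0 || sum(y) == 200) return(NA_real_)
    fit_logistic_univariable(y, stats::rnorm(200))$p
  }, numeric(1))
  expect_true(mean(p < 0.05, na.rm = TRUE) > 0.03 &&
                mean(p < 0.05, na.rm = TRUE) < 0.07)
})

test_that("complete separation is flagged rather than fatal", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  fit <- fit_logistic_univariable(y, x)
  expect_true(fit$separation)
  expect_error(fit_logistic_univariable(rep(0, 20), rnorm(20)), "event")
  expect_error(fit_logistic_univariable(rep(c(0, 1), 10), rep(1, 20)),
               "constant")
})

test_that("random forest ranks a planted signal first and is reproducible", {
  set.seed(20)
  n <- 400
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(signal = stats::rnorm(n, mean = 1.5 * y),
                  matrix(stats::rnorm(n * 9), ncol = 9))
  imp <- rf_importance(X, y, ntree = 2000, seed = 4)
  expect_identical(imp$predictor[1], "signal")
  expect_gt(imp$importance[1], max(imp$importance[-1]) * 2)
  imp2 <- rf_importance(X, y, ntree = 2000, seed = 4)
  expect_identical(imp, imp2)
  expect_identical(attr(imp, "ntree"), 2000)
  expect_error(rf_importance(X, y, ntree = 10), ">= 100")
  expect_error(rf_importance(X, rep(1, n)), "single class")
})

test_that("a pure-noise forest gives near-zero importance everywhere", {
  set.seed(23)
  n <- 300
  X <- data.frame(matrix(stats::rnorm(n * 6), ncol = 6))
  imp <- rf_importance(X, stats::rbinom(n, 1, 0.5), ntree = 1000, seed = 2)
  expect_true(all(abs(imp$importance) < 0.02))
})

test_that("Spearman map recovers exact monotone relations and flags constants", {
  n <- 60
  set.seed(24)
  base <- data.frame(subject_id = sprintf("S%03d", 1:n),
                     visit = rep(c("V1", "V2"), each = n / 2))
  x <- stats::runif(n)
  scores <- cbind(base, PCS1 = x, PCS2 = -x)
  panels <- cbind(base, up = exp(3 * x), flat = rep(1, n))
  m <- spearman_map(scores, panels)
  get <- function(v, s, ix) m[m$visit == v & m$score == s & m$index == ix, ]
  expect_equal(get("pooled", "PCS1", "up")$rho, 1)
  expect_equal(get("V1", "PCS1", "up")$rho, 1)
  expect_equal(get("pooled", "PCS2", "up")$rho, -1)
  expect_identical(get("pooled", "PCS1", "flat")$flag, "constant")
  expect_true(is.na(get("pooled", "PCS1", "flat")$rho))
  expect_setequal(unique(m$visit), c("V1", "V2", "pooled"))
  expect_true(all(get("pooled", "PCS1", "up")$n == n))
})

test_that("disposition-index regression is exact on a linear response", {
  set.seed(25)
  n <- 80
  pcs <- data.frame(PCS1 = stats::rnorm(n), PCS2 = stats::rnorm(n),
                    PCS3 = stats::rnorm(n))
  y <- 2 + 3 * pcs$PCS1 - 1.5 * pcs$PCS2 + 0.5 * pcs$PCS3
  # an exactly linear response triggers R's "essentially perfect fit" note
  fit <- suppressWarnings(fit_issi2_model(y, pcs))
  est <- fit$coefficients$estimate
  expect_equal(est, c(2, 3, -1.5, 0.5), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  # log response option models log(y)
  fit_log <- suppressWarnings(fit_issi2_model(exp(y), pcs,
                                              log_response = TRUE))
  expect_equal(fit_log$coefficients$estimate, c(2, 3, -1.5, 0.5),
               tolerance = 1e-8)
  expect_error(fit_issi2_model(y, pcs[, 1:2]), "PCS1")
  expect_error(fit_issi2_model(c(NA, y[-1]), pcs), "missing")
})

test_that("the mixed model recovers planted visit effects within 3 SE", {
  set.seed(26)
  n <- 500
  u <- stats::rnorm(n, 0, 1)
  dat <- expand.grid(subject = seq_len(n), visit = c("V1", "V2", "V3"))
  shift <- c(V1 = 0, V2 = -1, V3 = 0.5)
  dat$y <- 5 + shift[dat$visit] + u[dat$subject] + stats::rnorm(nrow(dat), 0, 0.5)
  fit <- lmm_random_intercept(dat$y, dat$visit, dat$subject)
  fx <- fit$fixed
  expect_lt(abs(fx["visitV2", "Estimate"] - (-1)) / fx["visitV2", "Std. Error"], 3)
  expect_lt(abs(fx["visitV3", "Estimate"] - 0.5) / fx["visitV3", "Std. Error"], 3)
  expect_lt(fit$global_p, 1e-10)
  expect_equal(fit$random_intercept_sd, 1, tolerance = 0.15)
})

test_that("without repeated measures the visit model falls back to OLS", {
  set.seed(27)
  n <- 90
  visit <- rep(c("V1", "V2", "V3"), each = n / 3)
  y <- stats::rnorm(n) + (visit == "V2")
  expect_warning(fit <- lmm_random_intercept(y, visit, seq_len(n)),
                 "no repeated measures")
  expect_equal(fit$random_intercept_sd, 0)
  expect_true(is.finite(fit$global_p))
})
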
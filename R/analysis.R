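# Statistical stage: group comparisons, correlation maps, univariable
# logistic models for GDM, random-forest variable importance, the oral
# disposition index regression, and visit effects under a random intercept.

#' Welch's t-test from summary statistics or raw samples
#'
#' Unequal-variance two-sample t-test with Satterthwaite degrees of freedom.
#' Provide either the six summary statistics or two raw samples `x`, `y`
#' (summaries are then computed from them, so both routes agree exactly).
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @param x,y alternatively, raw numeric samples.
#' @return list with `t`, `df`, `p` (two-sided), and the group summaries.
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("provide both samples", call. = FALSE)
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("group SDs must be > 0", call. = FALSE)
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df),
       mean1 = mean1, sd1 = sd1, n1 = n1, mean2 = mean2, sd2 = sd2, n2 = n2)
}

#' Pearson chi-squared and Fisher exact tests for a 2x2 table
#'
#' `pearson_chi2` is the uncorrected (no continuity correction) chi-squared
#' test with one degree of freedom; `fisher_exact` the two-sided exact test
#' summing all tables with probability at most that observed.
#'
#' @param table a 2x2 matrix of non-negative integer counts.
#' @return `pearson_chi2`: list with `chi2`, `df`, `p`; `fisher_exact`: list
#'   with `p` and the conditional odds ratio estimate.
#' @examples
#' pearson_chi2(matrix(c(41, 4, 20, 2), 2))  # p = 0.978
#' @export
pearson_chi2 <- function(table) {
  .check_2x2(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an empty margin", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' @rdname pearson_chi2
#' @export
fisher_exact <- function(table) {
  .check_2x2(table)
  res <- stats::fisher.test(table)
  list(p = res$p.value, odds_ratio = unname(res$estimate))
}

.check_2x2 <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == 2))
    stop("expected a 2x2 matrix of counts", call. = FALSE)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
}

#' Spearman correlation map between scores and index panels
#'
#' Rank correlation (average ranks for ties, two-sided asymptotic p) of every
#' score column against every index column, per visit and pooled.
#'
#' @param scores data frame with `subject_id`, `visit` and score columns
#'   (e.g. `PCS1..PCS3`).
#' @param panels data frame with `subject_id`, `visit` and numeric index
#'   columns (as from [compute_index_panels()]).
#' @param score_cols,index_cols columns to correlate; defaults: every numeric
#'   column of each input.
#' @return long data frame with `visit` (`"pooled"` included), `score`,
#'   `index`, `rho`, `p`, `n`; a constant column yields `NA` rho with a
#'   `flag` of `"constant"`.
#' @export
spearman_map <- function(scores, panels, score_cols = NULL, index_cols = NULL) {
  merged <- merge(scores, panels, by = c("subject_id", "visit"))
  if (is.null(score_cols))
    score_cols <- setdiff(names(scores)[vapply(scores, is.numeric, TRUE)],
                          c("subject_id", "visit"))
  if (is.null(index_cols))
    index_cols <- setdiff(names(panels)[vapply(panels, is.numeric, TRUE)],
                          c("subject_id", "visit"))
  groups <- c(as.list(unique(merged$visit)), list(NULL))
  out <- list()
  for (g in groups) {
    sub <- if (is.null(g)) merged else merged[merged$visit == g, ]
    label <- if (is.null(g)) "pooled" else g
    for (sc in score_cols) for (ix in index_cols) {
      ok <- stats::complete.cases(sub[[sc]], sub[[ix]])
      n <- sum(ok)
      if (n < 5) next
      constant <- stats::sd(sub[[sc]][ok]) == 0 || stats::sd(sub[[ix]][ok]) == 0
      if (constant) {
        out[[length(out) + 1]] <- data.frame(
          visit = label, score = sc, index = ix, rho = NA_real_,
          p = NA_real_, n = n, flag = "constant")
      } else {
        ct <- suppressWarnings(
          stats::cor.test(sub[[sc]][ok], sub[[ix]][ok], method = "spearman",
                          exact = FALSE))
        out[[length(out) + 1]] <- data.frame(
          visit = label, score = sc, index = ix, rho = unname(ct$estimate),
          p = ct$p.value, n = n, flag = "")
      }
    }
  }
  do.call(rbind, out)
}

#' Univariable logistic regression with profile-likelihood intervals
#'
#' Maximum-likelihood logistic fit of a binary outcome on one predictor; the
#' odds ratio is reported per `scale` predictor units with a 95% confidence
#' interval from the profile likelihood (likelihood-ratio statistic).
#' Quasi-complete separation is detected and flagged rather than crashing.
#'
#' @param outcome binary vector (logical, 0/1, or factor with 2 levels; the
#'   second level / `TRUE` / `1` is the event).
#' @param predictor numeric vector.
#' @param scale predictor units per reported odds ratio (e.g. `0.01` reports
#'   the OR per 0.01 units).
#' @return list of class `logistic_fit`: `or`, `ci` (length 2), `p`
#'   (likelihood-ratio test), `coef` (log-odds per original unit), `n`,
#'   `events`, `separation` (logical flag).
#' @export
fit_logistic_univariable <- function(outcome, predictor, scale = 1) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L
  else as.integer(as.logical(outcome))
  ok <- stats::complete.cases(y, predictor)
  y <- y[ok]; x <- predictor[ok]
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  sep <- !fit$converged || any(abs(fit$coefficients) > 1e3) ||
    max(summary(fit)$coefficients[, "Std. Error"]) > 1e3
  null_fit <- stats::glm(y ~ 1, family = stats::binomial())
  lrt <- stats::anova(null_fit, fit, test = "LRT")
  ci_raw <- tryCatch(
    suppressWarnings(suppressMessages(stats::confint(fit, parm = "x",
                                                     level = 0.95))),
    error = function(e) c(NA_real_, NA_real_))
  b <- unname(fit$coefficients["x"])
  structure(list(or = exp(b * scale),
                 ci = exp(unname(ci_raw) * scale),
                 p = lrt$`Pr(>Chi)`[2],
                 coef = b, se = summary(fit)$coefficients["x", "Std. Error"],
                 scale = scale, n = length(y), events = sum(y),
                 separation = sep),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("OR per %g units: %.3f (95%% CI %.3f-%.3f), p = %.3g [n=%d, events=%d]%s\n",
              x$scale, x$or, x$ci[1], x$ci[2], x$p, x$n, x$events,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Random-forest permutation variable importance
#'
#' Classification forest with out-of-bag permutation importance: the mean
#' decrease in predictive accuracy when a predictor is permuted, averaged over
#' trees (unscaled).  Returned in descending importance order.
#'
#' @param predictors data frame of candidate predictors (numeric or factor).
#' @param outcome binary outcome (coerced to factor).
#' @param ntree number of trees (>= 100; default 1e4).
#' @param seed integer seed.
#' @return data frame of class `importance_table` with `predictor`,
#'   `importance` (mean accuracy decrease), ordered by decreasing importance;
#'   attributes `ntree` and `seed`.
#' @export
rf_importance <- function(predictors, outcome, ntree = 1e4, seed = 1) {
  if (ntree < 100) stop("`ntree` must be >= 100", call. = FALSE)
  y <- factor(outcome)
  if (nlevels(y) < 2) stop("outcome has a single class", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fit <- randomForest::randomForest(x = predictors, y = y, ntree = ntree,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)
  out <- data.frame(predictor = rownames(imp), importance = imp[, 1],
                    row.names = NULL)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  attr(out, "ntree") <- ntree
  attr(out, "seed") <- seed
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Regress the oral disposition index on the three scores
#'
#' Ordinary least squares of ISSI-2 (raw scale by default; optionally natural
#' log) on PCS1-3, reporting coefficients with Wald 95% intervals and the
#' fraction of variance explained.
#'
#' @param issi2 numeric response.
#' @param pcs matrix or data frame with columns `PCS1`, `PCS2`, `PCS3`.
#' @param log_response if `TRUE`, model `log(issi2)`.
#' @return list with `coefficients` (data frame: term, estimate, ci_low,
#'   ci_high, p), `r_squared`, `n`.
#' @export
fit_issi2_model <- function(issi2, pcs, log_response = FALSE) {
  pcs <- as.data.frame(pcs)
  need <- c("PCS1", "PCS2", "PCS3")
  if (!all(need %in% names(pcs)))
    stop("`pcs` must have columns PCS1, PCS2, PCS3", call. = FALSE)
  if (length(issi2) < 10) stop("need >= 10 rows", call. = FALSE)
  if (anyNA(issi2) || anyNA(pcs[need])) stop("missing values", call. = FALSE)
  y <- if (log_response) log(issi2) else issi2
  dat <- data.frame(y = y, pcs[need])
  fit <- stats::lm(y ~ PCS1 + PCS2 + PCS3, data = dat)
  if (any(!is.finite(stats::coef(fit))) || anyNA(stats::coef(fit)))
    stop("collinear scores: coefficients not estimable", call. = FALSE)
  ci <- stats::confint(fit)
  sm <- summary(fit)
  list(coefficients = data.frame(term = rownames(ci),
                                 estimate = stats::coef(fit),
                                 ci_low = ci[, 1], ci_high = ci[, 2],
                                 p = sm$coefficients[, 4],
                                 row.names = NULL),
       r_squared = sm$r.squared, n = length(y))
}

#' Visit effects under a per-subject random intercept
#'
#' Linear mixed model `response ~ visit + (1 | subject)` fitted by REML for
#' the estimates and by ML for the global likelihood-ratio test of any visit
#' effect (the "V1 vs V2 vs V3" hypothesis).  If no subject has repeated
#' visits the model reduces to ordinary least squares with a warning.
#'
#' @param response numeric vector.
#' @param visit factor/character of visit labels.
#' @param subject subject identifiers.
#' @return list with `fixed` (coefficient table), `global_p` (LRT p for the
#'   visit factor), `random_intercept_sd`, `fit`.
#' @export
lmm_random_intercept <- function(response, visit, subject) {
  dat <- data.frame(y = response, visit = factor(visit),
                    subject = factor(subject))
  dat <- dat[stats::complete.cases(dat), ]
  if (!any(duplicated(dat$subject))) {
    warning("no repeated measures; fitting ordinary least squares")
    fit <- stats::lm(y ~ visit, data = dat)
    an <- stats::anova(fit)
    return(list(fixed = summary(fit)$coefficients,
                global_p = an$`Pr(>F)`[1],
                random_intercept_sd = 0, fit = fit))
  }
  fit <- lme4::lmer(y ~ visit + (1 | subject), data = dat, REML = TRUE)
  full_ml <- lme4::lmer(y ~ visit + (1 | subject), data = dat, REML = FALSE)
  null_ml <- lme4::lmer(y ~ 1 + (1 | subject), data = dat, REML = FALSE)
  lrt <- stats::anova(null_ml, full_ml)
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(fixed = stats::coef(summary(fit)),
       global_p = lrt$`Pr(>Chisq)`[2],
       random_intercept_sd = vc$sdcor[vc$grp == "subject"],
       fit = fit)
}
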
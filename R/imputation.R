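# Chained-equation imputation of sporadically missing OGTT measurements.

#' Imputation configuration
#'
#' @param m number of completed data sets whose average fills each missing
#'   cell (default 50).
#' @param maxit sweeps of the chained equations per completed data set.
#' @param seed integer seed.
#' @param method `"norm"` for stochastic normal-linear regression on the
#'   transformed scales, or `"pmm"` for predictive mean matching among the
#'   `donors` closest observed values.
#' @param donors donor pool size for `"pmm"`.
#' @return list of class `imputation_config`.
#' @export
imputation_config <- function(m = 50, maxit = 5, seed = 1,
                              method = c("norm", "pmm"), donors = 5) {
  method <- match.arg(method)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  structure(list(m = as.integer(m), maxit = as.integer(maxit),
                 seed = as.integer(seed), method = method,
                 donors = as.integer(donors)),
            class = "imputation_config")
}

#' Impute missing OGTT measurements by chained equations
#'
#' Multivariate imputation by chained equations on the measurement columns,
#' run on normalizing scales (insulin log, C-peptide square root): each
#' incomplete column is regressed on all other measurement columns plus age
#' and BMI; missing entries are replaced by draws from the conditional
#' predictive distribution (or by predictive-mean-matched donors), the sweep
#' is iterated, and the whole procedure repeated for `m` completed data sets
#' whose average is returned.  Observed cells are never altered.
#'
#' @param cohort cohort data frame, missing values only in OGTT measurement
#'   columns.
#' @param config an [imputation_config()].
#' @return the completed cohort, with attribute `imputed_cells` (data frame of
#'   row/column positions filled).
#' @export
impute_chained <- function(cohort, config = imputation_config()) {
  meas_cols <- .ogtt_cols
  miss <- which(is.na(as.matrix(cohort[meas_cols])), arr.ind = TRUE)
  if (nrow(miss) == 0) return(cohort)
  other <- setdiff(names(cohort), c(meas_cols, "age", "bmi"))
  if (anyNA(cohort[setdiff(other, "family_history")]))
    stop("missingness outside OGTT measurement columns is not supported",
         call. = FALSE)

  # transformed working matrix: measurements + age + log(bmi)
  W0 <- vapply(meas_cols, function(cl) .feature_transform(cl, cohort[[cl]]),
               numeric(nrow(cohort)))
  W0 <- cbind(W0, age = cohort$age, bmi = log(cohort$bmi))
  incomplete <- meas_cols[colSums(is.na(W0[, meas_cols, drop = FALSE])) > 0]
  if (any(colSums(!is.na(W0[, incomplete, drop = FALSE])) < ncol(W0)))
    stop("too few observed values in a column to fit its conditional model",
         call. = FALSE)

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  fill_sum <- matrix(0, nrow(miss), 1)
  for (rep_i in seq_len(config$m)) {
    W <- W0
    # initialize missing cells at the column means
    for (cl in incomplete) {
      na_r <- is.na(W[, cl])
      W[na_r, cl] <- mean(W[, cl], na.rm = TRUE)
    }
    for (it in seq_len(config$maxit)) {
      for (cl in incomplete) {
        na_r <- is.na(W0[, cl])
        X <- W[, setdiff(colnames(W), cl), drop = FALSE]
        fit <- stats::lm.fit(cbind(1, X[!na_r, , drop = FALSE]), W0[!na_r, cl])
        dfres <- sum(!na_r) - length(fit$coefficients)
        sigma <- sqrt(sum(fit$residuals^2) / max(dfres, 1))
        co <- fit$coefficients
        co[is.na(co)] <- 0
        pred_mis <- drop(cbind(1, X[na_r, , drop = FALSE]) %*% co)
        if (config$method == "norm") {
          W[na_r, cl] <- pred_mis + stats::rnorm(sum(na_r), 0, sigma)
        } else {
          pred_obs <- drop(cbind(1, X[!na_r, , drop = FALSE]) %*% co)
          obs_vals <- W0[!na_r, cl]
          W[na_r, cl] <- vapply(pred_mis, function(p) {
            ord <- order(abs(pred_obs - p))[seq_len(min(config$donors,
                                                        length(obs_vals)))]
            obs_vals[sample(ord, 1)]
          }, numeric(1))
        }
      }
    }
    fill_sum <- fill_sum + W[miss]
  }
  fill <- fill_sum / config$m

  out <- cohort
  for (k in seq_len(nrow(miss))) {
    cl <- meas_cols[miss[k, "col"]]
    val <- fill[k]
    # back-transform to the measurement scale
    val <- if (grepl("^i[0-9]", cl)) exp(val)
    else if (grepl("^cp", cl)) val^2
    else val
    out[miss[k, "row"], cl] <- val
  }
  attr(out, "imputed_cells") <- data.frame(row = miss[, "row"],
                                           column = meas_cols[miss[, "col"]])
  out
}
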
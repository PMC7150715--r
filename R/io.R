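# Cohort CSV interchange and the end-to-end pipeline.

.cohort_cols <- function() {
  c("subject_id", "visit", "age", "bmi", .ogtt_cols,
    "gdm", "primiparous", "family_history", "history_gdm")
}

#' Read / write a cohort CSV
#'
#' One row per subject-visit with the canonical header `subject_id, visit,
#' age, bmi, g0..g120, i0..i120, cp0..cp120, gdm, primiparous,
#' family_history, history_gdm`; missing values are empty fields.  Values
#' round-trip to at least 12 significant digits.
#'
#' @param path file path.
#' @param cohort a cohort data frame.
#' @return `read_cohort` returns the validated cohort data frame;
#'   `write_cohort` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("empty cohort file: ", path, call. = FALSE)
  canon <- .cohort_cols()
  unknown <- setdiff(names(df), canon)
  if (length(unknown))
    stop("unknown cohort columns: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  absent <- setdiff(canon, names(df))
  if (length(absent))
    stop("missing mandatory cohort columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  df <- df[canon]
  for (cl in .ogtt_cols) {
    bad <- which(!is.na(df[[cl]]) & df[[cl]] <= 0)
    if (length(bad))
      stop("non-positive concentration in `", cl, "` at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  for (cl in c("primiparous", "history_gdm", "family_history"))
    df[[cl]] <- as.logical(df[[cl]])
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  df <- cohort[.cohort_cols()]
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    out <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
    out[is.na(x)] <- ""
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param cohort_path path to a cohort CSV, or `NULL` to simulate one with
#'   `generator` instead.
#' @param generator a [generator_config()] used when `cohort_path` is `NULL`.
#' @param loadings_path path to a loading CSV; `NULL` derives loadings from
#'   the (imputed) cohort itself.
#' @param stats_path path to standardization stats; `NULL` self-standardizes.
#' @param out_dir output directory for the report bundle.
#' @param seed integer master seed (imputation and forest seeds derive from
#'   it; recorded in the report).
#' @param policy a [unit_policy()].
#' @param m imputations per missing cell.
#' @param ntree random-forest size.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_path = NULL,
                            generator = generator_config(),
                            loadings_path = NULL, stats_path = NULL,
                            out_dir = tempfile("ogttpcs_run_"),
                            seed = 1, policy = unit_policy(),
                            m = 50, ntree = 1e4) {
  for (p in c(cohort_path, loadings_path, stats_path))
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p,
                                             call. = FALSE)
  structure(list(cohort_path = cohort_path, generator = generator,
                 loadings_path = loadings_path, stats_path = stats_path,
                 out_dir = out_dir, seed = as.integer(seed), policy = policy,
                 m = m, ntree = ntree),
            class = "pipeline_config")
}

#' Run the full pipeline: cohort -> imputation -> indices -> scores -> analysis
#'
#' Stages, in order: load or simulate the cohort; impute sporadic OGTT
#' missingness by chained equations; compute the index panels; build the
#' feature matrix; derive or load the 17 x 3 loading matrix; project and
#' rescale the scores; and run the analysis stage (score-index Spearman map,
#' NGT/GDM comparison of first-visit scores, univariable logistic GDM models
#' per 0.01 score units, random-forest importance, ISSI-2 regression, and the
#' visit-effect mixed models).  Every stage's output is written to
#' `config$out_dir`; row counts and seeds are logged.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with all stage results and the bundle file paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("ogttpcs pipeline | seed %d | %s", config$seed,
                         as.character(utils::packageVersion("ogttpcs"))))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  cohort <- if (is.null(config$cohort_path)) {
    note("stage simulate: n_subjects=%d generator_seed=%d",
         config$generator$n_subjects, config$generator$seed)
    co <- generate_cohort(config$generator)
    co <- inject_missingness(co, config$generator$missing_cells,
                             seed = config$seed)
    co
  } else {
    note("stage load: %s", config$cohort_path)
    read_cohort(config$cohort_path)
  }
  note("cohort rows: %d (missing OGTT cells: %d)", nrow(cohort),
       sum(is.na(cohort[.ogtt_cols])))

  cohort <- impute_chained(cohort, imputation_config(m = config$m,
                                                     seed = config$seed))
  note("stage impute: m=%d, rows: %d", config$m, nrow(cohort))
  f_cohort <- file.path(config$out_dir, "cohort_imputed.csv")
  write_cohort(cohort, f_cohort)

  panels <- compute_index_panels(cohort, policy = config$policy)
  note("stage indices: rows: %d", nrow(panels))
  f_panels <- file.path(config$out_dir, "indices.csv")
  utils::write.csv(panels, f_panels, row.names = FALSE)

  stats <- if (is.null(config$stats_path)) standardization_stats(cohort)
  else read_standardization(config$stats_path)
  A <- build_feature_matrix(cohort, stats)
  loadings <- if (is.null(config$loadings_path)) derive_loadings(A)
  else read_loadings(config$loadings_path)
  note("stage loadings: %s (top-%d variance fraction: %s)",
       loadings$provenance, ncol(loadings$V),
       if (is.null(loadings$variance_fraction)) "unknown"
       else sprintf("%.3f", sum(loadings$variance_fraction)))
  f_load <- file.path(config$out_dir, "loadings.csv")
  write_loadings(loadings, f_load)

  sc <- project_scores(A, loadings)
  scores <- data.frame(subject_id = cohort$subject_id, visit = cohort$visit,
                       sc$PCS)
  note("stage scores: rows: %d", nrow(scores))
  f_scores <- file.path(config$out_dir, "scores.csv")
  utils::write.csv(scores, f_scores, row.names = FALSE)

  # ---- analysis stage ----
  cmap <- spearman_map(scores, panels,
                       index_cols = c("homa_ir", "quicki", "matsuda", "ogis",
                                      "sec_early", "sec_late", "sec_total",
                                      "issi2", "tis", "g_mean"))
  v1 <- cohort$visit == "V1"
  gdm_v1 <- cohort$gdm[v1] == "GDM"
  welch <- lapply(paste0("PCS", 1:3), function(p) {
    s <- scores[[p]][v1]
    welch_t(x = s[!gdm_v1], y = s[gdm_v1])
  })
  names(welch) <- paste0("PCS", 1:3)
  logit <- lapply(paste0("PCS", 1:3), function(p)
    fit_logistic_univariable(gdm_v1, scores[[p]][v1], scale = 0.01))
  names(logit) <- paste0("PCS", 1:3)

  pred_v1 <- data.frame(PCS1 = scores$PCS1[v1], PCS2 = scores$PCS2[v1],
                        PCS3 = scores$PCS3[v1],
                        age = cohort$age[v1], bmi = cohort$bmi[v1],
                        g0 = cohort$g0[v1],
                        g_mean = panels$g_mean[v1], ogis = panels$ogis[v1],
                        tis = panels$tis[v1])
  vimp <- rf_importance(pred_v1, gdm_v1, ntree = config$ntree,
                        seed = config$seed)
  note("stage analysis: rf ntree=%d seed=%d", config$ntree, config$seed)

  issi2_fit <- fit_issi2_model(panels$issi2[v1],
                               scores[v1, c("PCS1", "PCS2", "PCS3")])
  lmm <- lapply(paste0("PCS", 1:3), function(p)
    lmm_random_intercept(scores[[p]], scores$visit, scores$subject_id))
  names(lmm) <- paste0("PCS", 1:3)

  report <- list(
    seed = config$seed,
    n_rows = nrow(cohort),
    gdm_fraction = mean(cohort$gdm[v1] == "GDM"),
    welch_v1 = lapply(welch, function(w) w[c("t", "df", "p")]),
    logistic = lapply(logit, function(l)
      list(or = l$or, ci = l$ci, p = l$p, separation = l$separation)),
    rf_importance = vimp,
    issi2_model = issi2_fit[c("coefficients", "r_squared")],
    visit_effect_global_p = lapply(lmm, `[[`, "global_p"))
  f_report <- file.path(config$out_dir, "analysis.json")
  jsonlite::write_json(report, f_report, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  f_cmap <- file.path(config$out_dir, "correlation_map.csv")
  utils::write.csv(cmap, f_cmap, row.names = FALSE)

  writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  invisible(list(cohort = cohort, panels = panels, loadings = loadings,
                 scores = scores, correlation_map = cmap, welch = welch,
                 logistic = logit, rf_importance = vimp,
                 issi2_model = issi2_fit, lmm = lmm, report = report,
                 files = c(cohort = f_cohort, indices = f_panels,
                           loadings = f_load, scores = f_scores,
                           analysis = f_report, correlation_map = f_cmap)))
}
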
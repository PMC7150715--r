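# Principal component scores of glucose homeostasis (PCS1-3): variable
# transforms, standardization, loading derivation, and score projection
# S = A %*% V rescaled to PCS = (S + 100) / 17.

#' Canonical feature columns of the score model
#'
#' The 17 variables entering the principal component scores, in fixed order:
#' five glucose, five insulin and five C-peptide OGTT samples plus age and
#' BMI.
#' @return character vector of length 17.
#' @export
feature_columns <- function() {
  c(paste0("g", OGTT_TIMES), paste0("i", OGTT_TIMES),
    paste0("cp", OGTT_TIMES), "age", "bmi")
}

# Per-variable normalizing transforms: glucose and age untouched, insulin and
# BMI natural-log, C-peptide square-root.
.feature_transform <- function(name, x) {
  if (grepl("^i[0-9]", name) || name == "bmi") {
    if (any(x <= 0, na.rm = TRUE))
      stop("non-positive value under log transform in `", name, "`",
           call. = FALSE)
    log(x)
  } else if (grepl("^cp", name)) {
    if (any(x < 0, na.rm = TRUE))
      stop("negative value under sqrt transform in `", name, "`",
           call. = FALSE)
    sqrt(x)
  } else {
    x
  }
}

#' Transform cohort variables to the score model's scales
#'
#' @param cohort cohort data frame containing the [feature_columns()].
#' @return n x 17 numeric matrix of transformed (not yet standardized)
#'   values, with `subject_id:visit` rownames.
#' @export
transform_features <- function(cohort) {
  cols <- feature_columns()
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks feature columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  m <- vapply(cols, function(cl) .feature_transform(cl, cohort[[cl]]),
              numeric(nrow(cohort)))
  m <- matrix(m, nrow = nrow(cohort),
              dimnames = list(paste(cohort$subject_id, cohort$visit, sep = ":"),
                              cols))
  m
}

#' Standardization statistics of a training source
#'
#' Per-variable mean and standard deviation of the transformed training data;
#' these constants define the centering and scaling of the feature matrix A.
#' Scoring a new cohort against a fixed training source (rather than against
#' itself) mirrors the use of previously derived eigenvectors on new data.
#'
#' @param training a cohort data frame used as the training source.
#' @return data frame with columns `variable`, `mean`, `sd` (17 rows), class
#'   `standardization_stats`.
#' @export
standardization_stats <- function(training) {
  m <- transform_features(training)
  if (anyNA(m)) stop("training data contain missing values", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds <= 0))
    stop("zero-variance training column(s): ",
         paste(colnames(m)[sds <= 0], collapse = ", "), call. = FALSE)
  structure(data.frame(variable = colnames(m), mean = colMeans(m), sd = sds,
                       row.names = NULL),
            class = c("standardization_stats", "data.frame"))
}

#' Build the centered, standardized feature matrix A
#'
#' `A[i, j] = (transform_j(x[i, j]) - mean_j) / sd_j` with the transforms of
#' [transform_features()] and the training constants in `stats`.
#'
#' @param cohort cohort data frame to score.
#' @param stats a `standardization_stats` object; when `NULL` the cohort is
#'   standardized against itself (self-standardization).
#' @return n x 17 matrix with column order [feature_columns()].
#' @export
build_feature_matrix <- function(cohort, stats = NULL) {
  m <- transform_features(cohort)
  if (anyNA(m))
    stop("feature matrix has missing entries; impute upstream", call. = FALSE)
  if (is.null(stats)) stats <- standardization_stats(cohort)
  if (!all(stats$variable == colnames(m)))
    stop("standardization stats do not match the canonical variable order",
         call. = FALSE)
  if (any(stats$sd <= 0)) stop("standardization SDs must be > 0", call. = FALSE)
  sweep(sweep(m, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' Derive a loading matrix from a training feature matrix
#'
#' Eigendecomposition of the correlation-scale covariance `t(A) A / (n - 1)`
#' of a standardized feature matrix; the top `k` unit eigenvectors are the
#' loadings.  Sign convention (signs of eigenvectors are arbitrary): each
#' component is anchored on a variable whose direction fixes the score's
#' meaning — component 1 has a negative loading on fasting insulin (`i0`), so
#' higher first scores mean higher insulin sensitivity; component 2 a positive
#' loading on 1-h glucose (`g60`), so higher second scores mean higher
#' glycaemia; component 3 a positive loading on fasting insulin, so higher
#' third scores mean more fasting insulin resistance.  Components beyond the
#' third (and any anchor loading that is numerically zero) fall back to
#' making the largest-magnitude loading positive.
#'
#' @param A standardized feature matrix from [build_feature_matrix()].
#' @param k number of components (default 3).
#' @return object of class `loading_matrix`: list with `V` (17 x k matrix,
#'   named rows/cols), `eigenvalues` (all 17), `variance_fraction` (per kept
#'   component), and `provenance = "derived-from-cohort"`.
#' @export
derive_loadings <- function(A, k = 3) {
  if (nrow(A) <= ncol(A))
    stop("need more rows than feature columns to derive loadings",
         call. = FALSE)
  cm <- crossprod(A) / (nrow(A) - 1)
  eg <- eigen(cm, symmetric = TRUE)
  if (eg$values[k] <= 1e-12) stop("rank-deficient feature matrix", call. = FALSE)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(V) <- colnames(A)
  colnames(V) <- paste0("PC", seq_len(k))
  anchors <- list(c("i0", -1), c("g60", 1), c("i0", 1))
  for (j in seq_len(k)) {
    a <- if (j <= length(anchors)) anchors[[j]] else NULL
    if (!is.null(a) && abs(V[a[[1]], j]) > 1e-8) {
      if (sign(V[a[[1]], j]) != as.numeric(a[[2]])) V[, j] <- -V[, j]
    } else {
      lead <- which.max(abs(V[, j]))
      if (V[lead, j] < 0) V[, j] <- -V[, j]
    }
  }
  structure(list(V = V,
                 eigenvalues = eg$values,
                 variance_fraction = eg$values[seq_len(k)] / sum(eg$values),
                 provenance = "derived-from-cohort"),
            class = "loading_matrix")
}

#' @export
print.loading_matrix <- function(x, ...) {
  cat("Loading matrix (", nrow(x$V), "variables x", ncol(x$V),
      "components,", x$provenance, ")\n")
  cat("eigenvalues:", signif(x$eigenvalues[seq_len(ncol(x$V))], 4), "\n")
  cat("variance fractions:", signif(x$variance_fraction, 4),
      "| cumulative:", signif(sum(x$variance_fraction), 4), "\n")
  invisible(x)
}

#' Project principal component scores
#'
#' `S = A %*% V`, then rescaled elementwise to `PCS = (S + 100) / 17`.
#' Variables are matched by NAME: `V`'s rows are reordered to `A`'s columns,
#' and any mismatch is a hard error.
#'
#' @param A standardized feature matrix ([build_feature_matrix()]).
#' @param loadings a `loading_matrix` (from [derive_loadings()] or
#'   [read_loadings()]).
#' @return list of class `score_matrix` with `S` (raw scores) and `PCS`
#'   (rescaled) — both n x k matrices with columns `PCS1..PCSk` — and the
#'   loading provenance.
#' @export
project_scores <- function(A, loadings) {
  V <- loadings$V
  if (is.null(rownames(V)) || is.null(colnames(A)))
    stop("both A's columns and V's rows must be named", call. = FALSE)
  if (!setequal(rownames(V), colnames(A)))
    stop("loading variables do not match feature columns", call. = FALSE)
  V <- V[colnames(A), , drop = FALSE]
  S <- A %*% V
  PCS <- (S + 100) / 17
  colnames(S) <- colnames(PCS) <- paste0("PCS", seq_len(ncol(V)))
  structure(list(S = S, PCS = PCS, provenance = loadings$provenance),
            class = "score_matrix")
}

#' Check score orthogonality on a derivation cohort
#'
#' Scores projected with loadings derived from the same standardized cohort
#' are exactly uncorrelated; this check returns the maximum absolute pairwise
#' Pearson correlation among score columns.  For scores projected with
#' external loadings the property does not hold in general, and the check is
#' skipped with a warning.
#'
#' @param scores a `score_matrix` from [project_scores()].
#' @return maximum absolute off-diagonal correlation (0 for a single
#'   component), or `NA` with a warning for external loadings.
#' @export
score_orthogonality_check <- function(scores) {
  if (!identical(scores$provenance, "derived-from-cohort")) {
    warning("scores use external loadings; orthogonality is not expected ",
            "and the check is skipped")
    return(NA_real_)
  }
  if (ncol(scores$S) < 2) return(0)
  cc <- stats::cor(scores$S)
  max(abs(cc[upper.tri(cc)]))
}
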
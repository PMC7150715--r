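# Plain-CSV serialization of loading matrices and standardization statistics.

#' Write / read a loading matrix as CSV
#'
#' Layout: an optional comment header `#eigenvalue,<l1>,<l2>,...` followed by
#' a `variable,PC1,...,PCk` table with one named row per feature variable.
#' Reading reorders rows to the canonical [feature_columns()] order, so a
#' shuffled but correctly named file yields identical scores.
#'
#' @param loadings a `loading_matrix`.
#' @param path file path.
#' @return `write_loadings` returns `path` invisibly; `read_loadings` a
#'   `loading_matrix` with provenance `"external-file"` (eigenvalues and
#'   variance fractions only if present in the file header).
#' @export
write_loadings <- function(loadings, path) {
  V <- loadings$V
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(loadings$eigenvalues))
    writeLines(paste0("#eigenvalue,",
                      paste(format(loadings$eigenvalues, digits = 17),
                            collapse = ",")), con)
  df <- data.frame(variable = rownames(V), V, row.names = NULL,
                   check.names = FALSE)
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_loadings
#' @export
read_loadings <- function(path) {
  lines <- readLines(path)
  eig <- NULL
  if (length(lines) && startsWith(lines[1], "#eigenvalue")) {
    eig <- as.numeric(strsplit(lines[1], ",")[[1]][-1])
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE)
  if (!"variable" %in% names(df))
    stop("loading CSV must have a `variable` column", call. = FALSE)
  canon <- feature_columns()
  if (!setequal(df$variable, canon))
    stop("loading CSV variables do not match the canonical 17 names; ",
         "unknown/missing: ",
         paste(c(setdiff(df$variable, canon), setdiff(canon, df$variable)),
               collapse = ", "), call. = FALSE)
  V <- as.matrix(df[match(canon, df$variable), -1, drop = FALSE])
  if (!is.numeric(V) || anyNA(V))
    stop("loading CSV contains non-numeric cells", call. = FALSE)
  rownames(V) <- canon
  structure(list(V = V,
                 eigenvalues = eig,
                 variance_fraction = if (is.null(eig)) NULL else
                   eig[seq_len(ncol(V))] / sum(eig),
                 provenance = "external-file"),
            class = "loading_matrix")
}

#' Write / read standardization statistics as CSV
#'
#' Table with columns `variable,mean,sd`, one row per feature variable.
#'
#' @param stats a `standardization_stats` object.
#' @param path file path.
#' @export
write_standardization <- function(stats, path) {
  utils::write.csv(format(as.data.frame(stats), digits = 17, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_standardization
#' @export
read_standardization <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("variable", "mean", "sd") %in% names(df)))
    stop("standardization CSV must have variable, mean, sd columns",
         call. = FALSE)
  canon <- feature_columns()
  if (!setequal(df$variable, canon))
    stop("standardization CSV variables do not match the canonical 17 names",
         call. = FALSE)
  df <- df[match(canon, df$variable), c("variable", "mean", "sd")]
  rownames(df) <- NULL
  if (any(df$sd <= 0)) stop("standardization SDs must be > 0", call. = FALSE)
  structure(df, class = c("standardization_stats", "data.frame"))
}
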
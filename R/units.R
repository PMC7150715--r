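# Centralized unit handling for OGTT analytes.
#
# All index formulas in this package state the units they expect; conversions
# happen here and nowhere else.  Molar conversion factors:
#   glucose   1 mmol/l = 18.016 mg/dl
#   insulin   1 uU/ml  = 6.0 pmol/l
#   C-peptide 1 ng/ml  = 0.331 nmol/l

GLUCOSE_MGDL_PER_MMOL <- 18.016
INSULIN_PMOL_PER_UU <- 6.0
CPEPTIDE_NMOL_PER_NG <- 0.331

#' Unit policy for OGTT measurements
#'
#' Declares the units in which glucose, insulin and C-peptide concentrations
#' are supplied.  All index functions convert internally from these units to
#' whatever their published formula requires, so conversions are applied
#' exactly once.
#'
#' @param glucose `"mg/dl"` or `"mmol/l"`.
#' @param insulin `"uU/ml"` or `"pmol/l"`.
#' @param cpeptide `"ng/ml"` or `"nmol/l"`.
#'
#' @return An object of class `unit_policy`.
#' @examples
#' unit_policy()                     # conventional US units (package default)
#' unit_policy(glucose = "mmol/l")   # SI glucose
#' @export
unit_policy <- function(glucose = "mg/dl", insulin = "uU/ml",
                        cpeptide = "ng/ml") {
  glucose <- match.arg(glucose, c("mg/dl", "mmol/l"))
  insulin <- match.arg(insulin, c("uU/ml", "pmol/l"))
  cpeptide <- match.arg(cpeptide, c("ng/ml", "nmol/l"))
  structure(list(glucose = glucose, insulin = insulin, cpeptide = cpeptide),
            class = "unit_policy")
}

#' @export
print.unit_policy <- function(x, ...) {
  cat("OGTT unit policy: glucose", x$glucose, "| insulin", x$insulin,
      "| C-peptide", x$cpeptide, "\n")
  invisible(x)
}

#' Convert concentrations between units
#'
#' @param x numeric vector of concentrations.
#' @param from,to unit strings as accepted by [unit_policy()].
#'
#' @return `x` expressed in `to` units.  Each conversion is an involution:
#'   converting there and back reproduces the input to floating point accuracy.
#' @examples
#' convert_glucose(90.08, from = "mg/dl", to = "mmol/l")  # 5.0
#' @export
convert_glucose <- function(x, from, to) {
  .convert(x, from, to, c("mg/dl", "mmol/l"), GLUCOSE_MGDL_PER_MMOL)
}

#' @rdname convert_glucose
#' @export
convert_insulin <- function(x, from, to) {
  .convert(x, from, to, c("pmol/l", "uU/ml"), INSULIN_PMOL_PER_UU)
}

#' @rdname convert_glucose
#' @export
convert_cpeptide <- function(x, from, to) {
  .convert(x, from, to, c("nmol/l", "ng/ml"), CPEPTIDE_NMOL_PER_NG)
}

# units[1] = units[2] * factor; e.g. mg/dl = mmol/l * 18.016
.convert <- function(x, from, to, units, factor) {
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) return(x)
  if (from == units[2]) x * factor else x / factor
}

# Internal: bring a list of curves into the canonical internal units
# (glucose mg/dl, insulin uU/ml, C-peptide ng/ml).
.to_conventional <- function(glucose = NULL, insulin = NULL, cpeptide = NULL,
                             policy = unit_policy()) {
  stopifnot(inherits(policy, "unit_policy"))
  list(
    glucose = if (is.null(glucose)) NULL else
      convert_glucose(glucose, policy$glucose, "mg/dl"),
    insulin = if (is.null(insulin)) NULL else
      convert_insulin(insulin, policy$insulin, "uU/ml"),
    cpeptide = if (is.null(cpeptide)) NULL else
      convert_cpeptide(cpeptide, policy$cpeptide, "ng/ml")
  )
}
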
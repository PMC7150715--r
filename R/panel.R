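# Per subject-visit aggregation of all indices into one panel.

.glucose_cols <- paste0("g", OGTT_TIMES)
.insulin_cols <- paste0("i", OGTT_TIMES)
.cpeptide_cols <- paste0("cp", OGTT_TIMES)
.ogtt_cols <- c(.glucose_cols, .insulin_cols, .cpeptide_cols)

#' Compute the full index panel for one OGTT occasion
#'
#' Applies every index in the package to a single complete subject-visit row
#' (glucose, insulin and C-peptide at minutes 0/30/60/90/120 plus BMI).
#' Unit conversion happens once, centrally, according to `policy`.
#'
#' @param visit_row a one-row data frame (or named list) with the cohort
#'   schema columns `g0..g120`, `i0..i120`, `cp0..cp120`, `bmi`.
#' @param policy a [unit_policy()].
#' @param bsa body surface area in m2 used for OGIS and TIS (default 1.73).
#' @return a named list (class `index_panel`) with elements `homa_ir`,
#'   `quicki`, `matsuda`, `ogis`, `mcr`, `isi_stumvoll`, `ph1`, `ph2`,
#'   `sec_early`, `sec_late`, `sec_total`, `issi2`, `tis`, `g_sens`,
#'   `rate_sens`, `g_mean`, plus a character vector `flags` naming any
#'   quantity that is undefined for this row (empty when all are defined).
#' @export
compute_panel <- function(visit_row, policy = unit_policy(), bsa = 1.73) {
  row <- as.list(visit_row)
  need <- c(.ogtt_cols, "bmi")
  missing_cols <- setdiff(need, names(row))
  if (length(missing_cols))
    stop("visit row lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  vals <- unlist(row[need])
  if (any(is.na(vals)))
    stop("visit row has missing measurements; impute before computing panels",
         call. = FALSE)
  g <- unname(unlist(row[.glucose_cols]))
  i <- unname(unlist(row[.insulin_cols]))
  cp <- unname(unlist(row[.cpeptide_cols]))
  bmi <- row$bmi

  flags <- character(0)
  ins <- insulinogenic(g, i, policy = policy)
  if (!is.null(attr(ins, "flag"))) flags <- c(flags, attr(ins, "flag"))
  mats <- matsuda(g, i, policy = policy)
  stum <- stumvoll_indices(g30 = g[2], g90 = g[4], i0 = i[1], i30 = i[2],
                           i120 = i[5], bmi = bmi, policy = policy)
  dec <- isr_deconvolution(cp, bsa = bsa, policy = policy)
  gr <- gsens_ratesens(g, dec$isr, policy = policy)
  if (!is.null(attr(gr, "flag"))) flags <- c(flags, attr(gr, "flag"))
  g_mgdl <- convert_glucose(g, policy$glucose, "mg/dl")

  structure(list(
    homa_ir = homa_ir(g[1], i[1], policy = policy),
    quicki = quicki(g[1], i[1], policy = policy),
    matsuda = mats,
    ogis = ogis_2h(g[1], g[4], g[5], i[1], i[4], bsa = bsa, policy = policy),
    mcr = stum$mcr,
    isi_stumvoll = stum$isi,
    ph1 = stum$ph1,
    ph2 = stum$ph2,
    sec_early = ins$sec_early,
    sec_late = ins$sec_late,
    sec_total = ins$sec_total,
    issi2 = issi2(mats, ins$sec_total),
    tis = dec$tis,
    g_sens = gr$g_sens,
    rate_sens = gr$rate_sens,
    g_mean = mean(g_mgdl),
    flags = flags
  ), class = "index_panel")
}

#' Compute index panels for a whole cohort
#'
#' @param cohort a cohort data frame (schema of [generate_cohort()] /
#'   [read_cohort()]), with complete OGTT measurements.
#' @inheritParams compute_panel
#' @return a data frame with `subject_id`, `visit`, one column per panel
#'   field and a `flags` column (`""` when none; `;`-separated otherwise).
#' @export
compute_index_panels <- function(cohort, policy = unit_policy(), bsa = 1.73) {
  fields <- c("homa_ir", "quicki", "matsuda", "ogis", "mcr", "isi_stumvoll",
              "ph1", "ph2", "sec_early", "sec_late", "sec_total", "issi2",
              "tis", "g_sens", "rate_sens", "g_mean")
  panels <- lapply(seq_len(nrow(cohort)), function(r) {
    p <- compute_panel(cohort[r, , drop = FALSE], policy = policy, bsa = bsa)
    c(lapply(p[fields], as.numeric), list(flags = paste(p$flags, collapse = ";")))
  })
  out <- data.frame(subject_id = cohort$subject_id, visit = cohort$visit,
                    do.call(rbind.data.frame, panels))
  rownames(out) <- NULL
  out
}
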
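#' Is an exam a prior relative to a biopsy?
#'
#' A prior mammogram is one taken strictly more than `min_gap_days` days
#' (default 270, i.e. nine months) before the tissue biopsy. A gap of
#' exactly 270 days is not a prior; an exam after the biopsy is not a prior
#' (and not an error).
#'
#' @param exam_date,biopsy_date `Date` vectors (recycled).
#' @param min_gap_days Strict threshold in calendar days.
#' @return Logical vector.
#' @export
#' @examples
#' is_prior(as.Date("2014-01-01"), as.Date("2014-09-29"))  # 271 days: TRUE
#' is_prior(as.Date("2014-01-01"), as.Date("2014-09-28"))  # 270 days: FALSE
is_prior <- function(exam_date, biopsy_date, min_gap_days = 270) {
  as.numeric(biopsy_date - exam_date, units = "days") > min_gap_days
}

CATEGORIES <- c("actionable", "non_actionable", "excluded", "de_novo")
EXCLUDED_REASONS <- c("ipsilateral_prior_lumpectomy", "tomo_or_synthesized")

#' Read a cohort table
#'
#' One row per exam: `patient_id`, `biopsy_outcomes` (semicolon-joined subset
#' of `cancer`/`benign`), `biopsy_date`, `exam_id`, `exam_date`,
#' `retrospective_finding` (0/1/empty), `category`
#' (`actionable`/`non_actionable`/`excluded`/`de_novo`/empty) and
#' `excluded_reason`. Patients with no exam at all appear with an empty
#' `exam_id`. Actionability is an input label assigned by the validating
#' radiologists, never inferred here.
#'
#' @param path Path to `cohort.csv`.
#' @return Tibble of exams.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_cadreader(paste0("file not found: ", path), "cadreader_io")
  ch <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", biopsy_outcomes = "c", biopsy_date = readr::col_date(),
    exam_id = "c", exam_date = readr::col_date(),
    retrospective_finding = "i", category = "c", excluded_reason = "c"),
    progress = FALSE)
  check_parse(ch, path)
  bad <- !(ch$category %in% CATEGORIES | is.na(ch$category) | ch$category == "")
  if (any(bad)) {
    stop_cadreader(sprintf("unknown category token at row %s",
                           paste(head(which(bad), 5), collapse = ", ")),
                   "cadreader_parse")
  }
  ch
}

#' Select the Earliest Actionable prior exam per patient
#'
#' Among a patient's actionable prior exams (category `actionable` and exam
#' strictly more than 270 days before biopsy), returns the one with the
#' minimum exam date — the oldest actionable prior. Ties on the date are
#' broken by lexicographic `exam_id` with a warning.
#'
#' @param cohort Cohort tibble as returned by [read_cohort()]; may contain
#'   one or many patients.
#' @return Tibble with one row per patient having at least one actionable
#'   prior: `patient_id`, `exam_id`, `exam_date`, `biopsy_date`,
#'   `lead_time_days`.
#' @export
select_earliest_actionable <- function(cohort) {
  act <- cohort[!is.na(cohort$category) & cohort$category == "actionable" &
                  !is.na(cohort$exam_date) &
                  is_prior(cohort$exam_date, cohort$biopsy_date), , drop = FALSE]
  if (!nrow(act)) {
    return(tibble::tibble(patient_id = character(), exam_id = character(),
                          exam_date = as.Date(character()),
                          biopsy_date = as.Date(character()),
                          lead_time_days = numeric()))
  }
  act <- act[order(act$patient_id, act$exam_date, act$exam_id), ]
  ties <- stats::aggregate(exam_date ~ patient_id, act,
                           function(d) sum(d == min(d)) > 1)
  if (any(ties$exam_date)) {
    warn(sprintf("tied earliest actionable exam date for patient(s) %s; tie broken by exam_id",
                 paste(ties$patient_id[ties$exam_date], collapse = ", ")))
  }
  sel <- act[!duplicated(act$patient_id), ]
  tibble::tibble(
    patient_id = sel$patient_id, exam_id = sel$exam_id,
    exam_date = sel$exam_date, biopsy_date = sel$biopsy_date,
    lead_time_days = as.numeric(sel$biopsy_date - sel$exam_date, units = "days"))
}

#' Build the subject-group accounting ledger
#'
#' Reproduces the cohort filtering ladder of a retrospective prior-mammogram
#' study: total patients, biopsy-outcome breakdown, cancer patients with
#' prior exams, patients with retrospective findings vs de novo cancers, the
#' actionable / non-actionable / excluded split, and the Earliest Actionable
#' exam list with lead-time statistics (reported to biopsy, in years of
#' 365.25 days). Partition identities are asserted on every run:
#' `actionable + non_actionable + excluded = retrospective` and
#' `retrospective + de_novo = with_priors`.
#'
#' Percentages are displayed to the nearest integer, half away from zero.
#'
#' @param cohort Cohort tibble ([read_cohort()] / [simulate_cohort()]).
#' @return A `ledger_report` list of counts, percentages and the earliest
#'   actionable selection.
#' @export
build_ledger <- function(cohort) {
  per_pat <- function(ids) length(unique(ids))
  outcomes <- split_components(cohort$biopsy_outcomes)
  pat <- tibble::tibble(patient_id = cohort$patient_id,
                        cancer = vapply(outcomes, function(o) "cancer" %in% o, logical(1)),
                        benign = vapply(outcomes, function(o) "benign" %in% o, logical(1)))
  pat <- dplyr::summarise(dplyr::group_by(pat, .data$patient_id),
                          cancer = any(.data$cancer), benign = any(.data$benign))

  n_total  <- nrow(pat)
  n_cancer <- sum(pat$cancer)
  n_benign <- sum(pat$benign)
  n_both   <- sum(pat$cancer & pat$benign)

  cc <- cohort[cohort$patient_id %in% pat$patient_id[pat$cancer], , drop = FALSE]
  has_exam <- !is.na(cc$exam_date)
  prior <- has_exam & is_prior(cc$exam_date, cc$biopsy_date)
  n_with_priors <- per_pat(cc$patient_id[prior])

  retro_pat <- unique(cc$patient_id[prior & !is.na(cc$retrospective_finding) &
                                      cc$retrospective_finding == 1L])
  n_retro <- length(retro_pat)
  n_de_novo <- n_with_priors - n_retro

  cat_of <- function(what) {
    per_pat(cc$patient_id[prior & !is.na(cc$category) & cc$category == what])
  }
  n_act <- cat_of("actionable"); n_non <- cat_of("non_actionable"); n_exc <- cat_of("excluded")

  if (n_act + n_non + n_exc != n_retro) {
    stop_cadreader(sprintf(
      "category partition violated: actionable %d + non_actionable %d + excluded %d != retrospective %d",
      n_act, n_non, n_exc, n_retro), "cadreader_invariant")
  }
  if (n_retro + n_de_novo != n_with_priors) {
    stop_cadreader("retrospective + de_novo != with-priors count", "cadreader_invariant")
  }

  earliest <- select_earliest_actionable(cc)
  lead_years <- earliest$lead_time_days / 365.25
  pct <- function(num, den) if (den > 0) display_pct(num / den) else NA_real_

  structure(list(
    counts = list(
      total_patients = n_total, cancer_biopsy = n_cancer, benign_biopsy = n_benign,
      both_biopsy = n_both, with_priors = n_with_priors,
      retrospective = n_retro, de_novo = n_de_novo,
      actionable = n_act, non_actionable = n_non, excluded = n_exc),
    percentages = list(
      retrospective_of_with_priors = pct(n_retro, n_with_priors),
      de_novo_of_with_priors = pct(n_de_novo, n_with_priors),
      actionable_of_retrospective = pct(n_act, n_retro)),
    earliest_actionable = earliest,
    lead_time_years = if (nrow(earliest)) {
      list(mean = mean(lead_years), min = min(lead_years), max = max(lead_years))
    } else NULL
  ), class = "ledger_report")
}

#' @export
print.ledger_report <- function(x, ...) {
  cn <- x$counts
  cat("Cohort ledger\n")
  cat(sprintf("  patients: %d (cancer %d, benign %d, both %d)\n",
              cn$total_patients, cn$cancer_biopsy, cn$benign_biopsy, cn$both_biopsy))
  cat(sprintf("  cancer patients with priors: %d\n", cn$with_priors))
  cat(sprintf("  retrospective findings: %d (%s%%) | de novo: %d\n",
              cn$retrospective, fmt_or_na(x$percentages$retrospective_of_with_priors),
              cn$de_novo))
  cat(sprintf("  actionable: %d (%s%%) | non-actionable: %d | excluded: %d\n",
              cn$actionable, fmt_or_na(x$percentages$actionable_of_retrospective),
              cn$non_actionable, cn$excluded))
  if (!is.null(x$lead_time_years)) {
    cat(sprintf("  earliest-actionable lead time to biopsy: mean %.1f y, range %.2f-%.1f y\n",
                x$lead_time_years$mean, x$lead_time_years$min, x$lead_time_years$max))
  }
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else format(v)

#' @rdname build_ledger
#' @param x A `ledger_report`.
#' @param path Output JSON path.
#' @export
write_ledger <- function(x, path) {
  out <- list(counts = x$counts, percentages = x$percentages,
              lead_time_years = x$lead_time_years,
              earliest_actionable = x$earliest_actionable)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
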
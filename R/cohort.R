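#' Cohort table schema and validation
#'
#' The cohort is an ordinary data.frame with one row per patient and a fixed
#' set of clinical columns, plus lesion features derived from the masks by
#' [derive_lesion_features()]. Unknown values are `NA`.
#'
#' Columns: `patient_id`, `sex` ("female"/"male"), `age_at_scan` (years),
#' `age_at_onset` (years), `duration` (years, scan minus onset),
#' `ever_mri_negative` (logical), `scanner` (1.5 or 3, tesla),
#' `histopathology` ("I","IIA","IIB","III" or NA), `operated` (logical),
#' `seizure_free` (logical or NA; Engel class I with >= 1 year follow-up),
#' `follow_up` (years or NA), `lesion_hemisphere` ("left"/"right");
#' derived: `lesion_size_pct`, `lobe`, `eloquent_overlap`.
#'
#' @param df data.frame to validate.
#' @return the validated data.frame, with class `cohort_table` prepended.
#' @export
cohort_table <- function(df) {
  required <- c("patient_id", "sex", "age_at_scan", "age_at_onset",
                "duration", "ever_mri_negative", "scanner",
                "histopathology", "operated", "seizure_free",
                "follow_up", "lesion_hemisphere")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  problems <- validate_cohort(df)
  if (length(problems))
    stop("cohort validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  class(df) <- unique(c("cohort_table", class(df)))
  df
}

#' Row-level cohort invariant checks
#'
#' Checks duration = age_at_scan - age_at_onset (within 0.51 years, so
#' whole-year reporting passes), that seizure_free is only recorded for
#' operated patients with at least one year of follow-up, and that lesion
#' size lies in \[0, 100\].
#'
#' @param df cohort data.frame.
#' @return character vector of problems (empty when valid).
#' @export
validate_cohort <- function(df) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (any(rows, na.rm = TRUE))
      c(problems, paste0("row(s) ", paste(which(rows), collapse = ","),
                         ": ", msg))
    else problems
  }
  dur_gap <- abs(df$duration - (df$age_at_scan - df$age_at_onset))
  problems <- note(dur_gap > 0.51,
                   "duration inconsistent with age_at_scan - age_at_onset")
  has_out <- !is.na(df$seizure_free)
  problems <- note(has_out & !(df$operated %in% TRUE),
                   "seizure_free recorded for non-operated patient")
  problems <- note(has_out & (is.na(df$follow_up) | df$follow_up < 1),
                   "seizure_free recorded with follow-up < 1 year")
  if ("lesion_size_pct" %in% names(df))
    problems <- note(df$lesion_size_pct < 0 | df$lesion_size_pct > 100,
                     "lesion_size_pct outside [0, 100]")
  problems
}

#' Derive per-lesion features into the cohort table
#'
#' Adds/overwrites `lesion_size_pct` (percentage of hemisphere vertices),
#' `lobe` (lobar categorisation with the cingulate/insula reassignment
#' rule), and `eloquent_overlap` (fraction of the lesion inside eloquent
#' cortex, hemisphere-specific language labels respected).
#'
#' @param cohort a [cohort_table()] (or plain data.frame with the schema).
#' @param masks list of [lesion_mask()], one per cohort row, same order.
#' @param parc the template [parcellation()].
#' @return the cohort with derived columns filled in.
#' @export
derive_lesion_features <- function(cohort, masks, parc) {
  stopifnot(nrow(cohort) == length(masks))
  elo <- list(left = eloquent_mask(parc, "left"),
              right = eloquent_mask(parc, "right"))
  cohort$lesion_size_pct <- vapply(masks, lesion_size_pct, numeric(1))
  cohort$lobe <- vapply(masks, assign_lobe, character(1), parc = parc)
  cohort$eloquent_overlap <- vapply(seq_along(masks), function(i) {
    eloquent_overlap(masks[[i]], elo[[masks[[i]]$hemisphere]])
  }, numeric(1))
  cohort
}
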
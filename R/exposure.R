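#' Clean a prescription dispensing stream
#'
#' Removes ambiguous records before treatment-episode construction: records
#' whose drug code does not match the class filter, or whose quantity /
#' daily dose is missing or non-positive (coverage cannot be computed).
#' Every dropped record carries a machine-readable reason, and
#' `kept` plus `dropped` partition the input exactly.
#'
#' @param records data.frame with columns `person_id`, `dispense_day`
#'   (integer day offset), `drug_code`, `quantity`, `daily_dose`.
#' @param code_filter string prefix the drug code must start with, e.g. the
#'   BNF antidepressant paragraph `"040303"` or ATC class `"N06A"`. `NULL`
#'   disables code filtering.
#' @return list of data.frames `kept` and `dropped` (the latter with a
#'   `reason` column: `"code-filter"`, `"missing-quantity"`,
#'   `"missing-dose"`, `"nonpositive-quantity"`, `"nonpositive-dose"`).
#' @export
clean_prescriptions <- function(records, code_filter = "040303") {
  cols <- c("person_id", "dispense_day", "drug_code", "quantity", "daily_dose")
  if (length(records) == 0 || nrow(records) == 0) {
    empty <- stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 5)), cols)
    return(list(kept = empty, dropped = cbind(empty, reason = character(0))))
  }
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("prescription table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  reason <- rep(NA_character_, nrow(records))
  if (!is.null(code_filter)) {
    bad <- !startsWith(as.character(records$drug_code), code_filter)
    reason[is.na(reason) & bad] <- "code-filter"
  }
  reason[is.na(reason) & is.na(records$quantity)] <- "missing-quantity"
  reason[is.na(reason) & is.na(records$daily_dose)] <- "missing-dose"
  reason[is.na(reason) & records$quantity <= 0] <- "nonpositive-quantity"
  reason[is.na(reason) & records$daily_dose <= 0] <- "nonpositive-dose"
  keep <- is.na(reason)
  dropped <- records[!keep, cols, drop = FALSE]
  dropped$reason <- reason[!keep]
  list(kept = records[keep, cols, drop = FALSE], dropped = dropped)
}

#' Merge one person's dispensings into active treatment periods
#'
#' Each record covers `ceil(quantity / daily_dose)` days from its dispensing
#' day. Scanning in date order, a record joins the current period when its
#' dispensing day falls within the period's end plus a grace gap (allowed
#' slack for imperfect adherence / early refills), extending the period's end;
#' otherwise it starts a new period. The result is the set of disjoint
#' intervals during which the person is assumed continuously on drug.
#'
#' @param records cleaned records of a single person (data.frame with
#'   `dispense_day`, `quantity`, `daily_dose`; `person_id` optional).
#' @param grace_days non-negative integer gap tolerated between the end of
#'   covered supply and the next dispensing (default 30).
#' @return data.frame with `person_id`, `start_day`, `end_day`,
#'   `n_prescriptions`, one row per period, sorted and disjoint.
#' @export
build_treatment_periods <- function(records, grace_days = 30) {
  if (length(grace_days) != 1 || is.na(grace_days) || grace_days < 0)
    stop("grace_days must be a single non-negative number")
  pid <- if ("person_id" %in% names(records) && nrow(records) > 0)
    records$person_id[1] else NA_character_
  out0 <- data.frame(person_id = character(0), start_day = numeric(0),
                     end_day = numeric(0), n_prescriptions = integer(0),
                     stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(out0)
  if ("person_id" %in% names(records) &&
      length(unique(records$person_id)) > 1)
    stop("build_treatment_periods expects records of a single person")
  o <- order(records$dispense_day)
  day <- records$dispense_day[o]
  cover <- ceiling(records$quantity[o] / records$daily_dose[o])
  start <- day[1]; end <- day[1] + cover[1]; npres <- 1L
  periods <- list()
  if (length(day) > 1) for (i in 2:length(day)) {
    if (day[i] <= end + grace_days) {
      end <- max(end, day[i] + cover[i]); npres <- npres + 1L
    } else {
      periods[[length(periods) + 1L]] <- c(start, end, npres)
      start <- day[i]; end <- day[i] + cover[i]; npres <- 1L
    }
  }
  periods[[length(periods) + 1L]] <- c(start, end, npres)
  pm <- do.call(rbind, periods)
  data.frame(person_id = pid, start_day = pm[, 1], end_day = pm[, 2],
             n_prescriptions = as.integer(pm[, 3]), stringsAsFactors = FALSE)
}

#' Classify exposure status at blood draw
#'
#' Three-state classification against a person's treatment periods:
#' \describe{
#'   \item{EXPOSED}{the draw falls at least `lead_days` after some period's
#'     start and strictly before its end plus `tail_days` — long enough on
#'     drug for a biological signature, and not long enough off it to have
#'     washed out.}
#'   \item{UNEXPOSED}{no prescriptions on record at all.}
#'   \item{EXCLUDED}{prescriptions exist but the draw satisfies neither
#'     window (too early in a period, or in a gap/after washout) — an
#'     ambiguous exposure state removed from analysis.}
#' }
#' Time in treatment is defined only when the draw lies inside the covering
#' period (`draw_day <= end_day`); a draw caught by the tail window alone is
#' EXPOSED with `time_in_treatment_days = NA`.
#'
#' @param periods data.frame from [build_treatment_periods()].
#' @param has_any_prescription logical: did this person have any dispensing
#'   on record (before or after cleaning-independent; drives UNEXPOSED)?
#' @param draw_day integer day of the blood draw.
#' @param lead_days,tail_days the lead/tail windows in days (default 7 each).
#' @return list: `status`, `time_in_treatment_days`, `period_index`.
#' @export
classify_exposure <- function(periods, has_any_prescription, draw_day,
                              lead_days = 7, tail_days = 7) {
  if (nrow(periods) > 1) {
    o <- order(periods$start_day)
    periods <- periods[o, , drop = FALSE]
    if (any(periods$start_day[-1] <= periods$end_day[-nrow(periods)]))
      stop("treatment periods overlap; invariant violated")
  }
  if (!has_any_prescription)
    return(list(status = "UNEXPOSED", time_in_treatment_days = NA_real_,
                period_index = NA_integer_))
  hit <- which(draw_day >= periods$start_day + lead_days &
               draw_day < periods$end_day + tail_days)
  if (length(hit) == 0)
    return(list(status = "EXCLUDED", time_in_treatment_days = NA_real_,
                period_index = NA_integer_))
  i <- hit[1]
  tit <- if (draw_day <= periods$end_day[i])
    draw_day - periods$start_day[i] else NA_real_
  list(status = "EXPOSED", time_in_treatment_days = tit, period_index = i)
}

#' Derive the exposure phenotype for a whole cohort
#'
#' Orchestrates [clean_prescriptions()], [build_treatment_periods()] and
#' [classify_exposure()] over all samples. Persons absent from the
#' prescription table are UNEXPOSED.
#'
#' @param prescriptions prescription data.frame (see [clean_prescriptions()]).
#' @param draw_days named numeric vector: blood-draw day per person id.
#' @param code_filter,grace_days,lead_days,tail_days tuning knobs passed
#'   through; all are recorded in the `params` attribute of the result.
#' @return data.frame: `person_id`, `status`, `time_in_treatment_days`,
#'   `period_start`, `period_end`, `n_periods`; attribute `params`.
#' @export
derive_exposure <- function(prescriptions, draw_days, code_filter = "040303",
                            grace_days = 30, lead_days = 7, tail_days = 7) {
  ids <- names(draw_days)
  if (is.null(ids)) stop("draw_days must be named by person id")
  cleaned <- clean_prescriptions(prescriptions, code_filter)
  # "on record" means any dispensing of a matching drug code, even one later
  # dropped as ambiguous: such persons are never UNEXPOSED
  on_record <- if (nrow(prescriptions) == 0) character(0)
  else if (is.null(code_filter)) as.character(prescriptions$person_id)
  else as.character(prescriptions$person_id)[
    startsWith(as.character(prescriptions$drug_code), code_filter)]
  has_rx <- ids %in% unique(on_record)
  kept_by_person <- split(cleaned$kept,
                          as.character(cleaned$kept$person_id))
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    recs <- kept_by_person[[id]]
    periods <- if (is.null(recs))
      build_treatment_periods(data.frame(person_id = character(0),
                                         dispense_day = numeric(0),
                                         quantity = numeric(0),
                                         daily_dose = numeric(0)))
    else build_treatment_periods(recs, grace_days)
    cl <- classify_exposure(periods, has_rx[i], draw_days[i],
                            lead_days, tail_days)
    k <- cl$period_index
    data.frame(person_id = id, status = cl$status,
               time_in_treatment_days = cl$time_in_treatment_days,
               period_start = if (is.na(k)) NA_real_ else periods$start_day[k],
               period_end = if (is.na(k)) NA_real_ else periods$end_day[k],
               n_periods = nrow(periods), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "params") <- list(code_filter = code_filter,
                              grace_days = grace_days,
                              lead_days = lead_days, tail_days = tail_days,
                              coverage = "ceiling(quantity / daily_dose)")
  out
}

#' Select the MDD subgroup from a phenotype table
#'
#' Lifetime major-depression cases excluding anyone meeting bipolar criteria.
#'
#' @param phenotypes data.frame with logical/0-1 columns `lifetime_MDD` and
#'   `bipolar`.
#' @return logical vector marking subgroup membership.
#' @export
mdd_subgroup <- function(phenotypes) {
  as.logical(phenotypes$lifetime_MDD) & !as.logical(phenotypes$bipolar)
}
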
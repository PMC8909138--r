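#' Validated survival records
#'
#' @param sample_id Sample identifiers.
#' @param time Non-negative follow-up times (unit-agnostic).
#' @param event 1 = death observed, 0 = censored.
#' @param stratum Stratum label per sample (e.g. "high"/"low").
#' @return A data.frame of class `SurvivalRecords`. Records with time 0 and
#'   no event carry no information and are dropped with a warning.
#' @export
survival_records <- function(sample_id, time, event, stratum = "all") {
  if (any(time < 0)) stop("negative survival times")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  df <- data.frame(sample_id = as.character(sample_id), time = time,
                   event = as.integer(event),
                   stratum = as.character(stratum))
  drop <- df$time == 0 & df$event == 0
  if (any(drop)) {
    warning(sum(drop), " records with time 0 and no event dropped")
    df <- df[!drop, ]
  }
  class(df) <- c("SurvivalRecords", "data.frame")
  df
}

#' Read a clinical table (TSV) into survival records
#'
#' Expects columns `sample_id`, `time`, `event`; any further columns
#' (subtype, age, gender, ...) are kept as annotation.
#'
#' @param path Path to the TSV.
#' @param stratum Optional column name to use as stratum.
#' @return A `SurvivalRecords` data.frame.
#' @export
read_clinical <- function(path, stratum = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "")
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table lacks columns: ",
                         paste(miss, collapse = ", "))
  strat <- if (!is.null(stratum)) df[[stratum]] else "all"
  out <- survival_records(df$sample_id, df$time, df$event, strat)
  extra <- setdiff(names(df), need)
  for (cn in extra) out[[cn]] <- df[[cn]][match(out$sample_id, df$sample_id)]
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate over all records (ignoring strata). Deaths are
#' processed before censorings at tied times, the standard convention.
#'
#' @param records A `SurvivalRecords` data.frame.
#' @return A `KmCurve` data.frame: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`.
#' @export
km_estimate <- function(records) {
  stopifnot(nrow(records) >= 1)
  if (any(records$time < 0)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("KmCurve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df) between exactly two strata, each of
#' which must contain at least one observed event; the variance uses the
#' hypergeometric form with tie correction. P-value is the chi-square(1)
#' upper tail (two-sided).
#'
#' @param records A `SurvivalRecords` data.frame with exactly two strata.
#' @return List with elements `chi2`, `p`, and the per-stratum observed and
#'   expected event counts.
#' @export
logrank_test <- function(records) {
  strata <- unique(records$stratum)
  if (length(strata) != 2)
    stop("logrank_test needs exactly 2 strata; got ", length(strata))
  for (s in strata) {
    sub <- records[records$stratum == s, ]
    if (nrow(sub) == 0) stop("stratum '", s, "' is empty")
    if (sum(sub$event) == 0) stop("stratum '", s, "' has no observed events")
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                            data = records)
  list(chi2 = unname(sd_$chisq),
       p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
       observed = sd_$obs, expected = sd_$exp)
}

#' Write a KM curve as a TSV step function
#'
#' @param curve A `KmCurve`.
#' @param path Output path.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
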
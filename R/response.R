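#' Group-level treatment-response comparison
#'
#' Takes per-patient pre/post tumor metrics and compares responders with
#' non-responders: percentage change in tDV and absolute changes of the
#' four gADC histogram parameters (median, variance, skewness, excess
#' kurtosis). Per the standard assumption that successful treatment can
#' only raise tumor ADC, the change in median gADC is tested one-sided
#' (responders greater); every other metric two-sided. Mann-Whitney
#' throughout; p <= 0.05 is flagged significant.
#'
#' @param cohort a data.frame with columns `patient_id`, `group`
#'   (`"responder"` / `"non-responder"`), and either metric columns
#'   `pre_tdv_ml`, `post_tdv_ml`, `pre_gadc_median`, `post_gadc_median`,
#'   `pre_gadc_variance`, `post_gadc_variance`, `pre_gadc_skewness`,
#'   `post_gadc_skewness`, `pre_gadc_kurtosis`, `post_gadc_kurtosis`, or
#'   path columns `pre_metrics_path` / `post_metrics_path` pointing to
#'   [write_metrics()] JSON files.
#' @return An object of class `response_comparison`: list with `patients`
#'   (per-patient change table), `group_summary` (medians and ranges per
#'   group and metric), `tests` (data.frame metric / U / p / tail /
#'   significant), and `small_sample` flag (smallest group < 3 patients).
#' @export
response_report <- function(cohort) {
  cohort <- as.data.frame(cohort)
  if (!all(c("patient_id", "group") %in% names(cohort)))
    stop("cohort needs patient_id and group columns")
  if ("pre_metrics_path" %in% names(cohort)) {
    cohort <- load_cohort_metrics(cohort)
  }
  fields <- c("tdv_ml", "gadc_median", "gadc_variance", "gadc_skewness",
              "gadc_kurtosis")
  need <- c(paste0("pre_", fields), paste0("post_", fields))
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort missing columns: ", paste(missing_cols, collapse = ", "))

  complete <- complete.cases(cohort[, need])
  if (any(!complete)) {
    warning(sprintf("excluding %d patient(s) with a missing timepoint: %s",
                    sum(!complete),
                    paste(cohort$patient_id[!complete], collapse = ", ")))
    cohort <- cohort[complete, ]
  }
  bad_pre <- cohort$pre_tdv_ml <= 0
  if (any(bad_pre)) {
    warning("excluding patient(s) with pre-treatment tDV = 0 (percent change undefined)")
    cohort <- cohort[!bad_pre, ]
  }
  if (!nrow(cohort)) stop("no complete patients in cohort")

  patients <- data.frame(
    patient_id = cohort$patient_id,
    group = cohort$group,
    percent_change_tdv = 100 * (cohort$post_tdv_ml - cohort$pre_tdv_ml) /
      cohort$pre_tdv_ml,
    delta_gadc_median = cohort$post_gadc_median - cohort$pre_gadc_median,
    delta_gadc_variance = cohort$post_gadc_variance - cohort$pre_gadc_variance,
    delta_gadc_skewness = cohort$post_gadc_skewness - cohort$pre_gadc_skewness,
    delta_gadc_kurtosis = cohort$post_gadc_kurtosis - cohort$pre_gadc_kurtosis
  )

  metrics <- c(percent_change_tdv = "two_sided",
               delta_gadc_median = "one_sided_greater",
               delta_gadc_variance = "two_sided",
               delta_gadc_skewness = "two_sided",
               delta_gadc_kurtosis = "two_sided")
  resp <- patients$group == "responder"
  if (!any(resp) || all(resp)) stop("need both responder and non-responder patients")

  tests <- do.call(rbind, lapply(names(metrics), function(m) {
    mw <- mann_whitney(patients[[m]][resp], patients[[m]][!resp],
                       tail = metrics[[m]])
    data.frame(metric = m, U = mw$U, p = mw$p, tail = mw$tail,
               method = mw$method, significant = mw$p <= 0.05)
  }))

  summarise <- function(vals) {
    c(median = median(vals), min = min(vals), max = max(vals))
  }
  group_summary <- do.call(rbind, lapply(names(metrics), function(m) {
    r <- summarise(patients[[m]][resp]); n <- summarise(patients[[m]][!resp])
    data.frame(metric = m,
               responder_median = r["median"], responder_min = r["min"],
               responder_max = r["max"],
               nonresponder_median = n["median"], nonresponder_min = n["min"],
               nonresponder_max = n["max"], row.names = NULL)
  }))

  structure(list(patients = patients, group_summary = group_summary,
                 tests = tests,
                 n_responders = sum(resp), n_nonresponders = sum(!resp),
                 small_sample = min(sum(resp), sum(!resp)) < 3),
            class = "response_comparison")
}

load_cohort_metrics <- function(cohort) {
  fields <- c("tdv_ml", "gadc_median", "gadc_variance", "gadc_skewness",
              "gadc_kurtosis")
  for (tp in c("pre", "post")) {
    paths <- cohort[[paste0(tp, "_metrics_path")]]
    for (f in fields) cohort[[paste0(tp, "_", f)]] <- NA_real_
    for (i in seq_along(paths)) {
      if (!file.exists(paths[i])) next
      m <- jsonlite::read_json(paths[i], simplifyVector = TRUE)
      for (f in fields)
        cohort[[paste0(tp, "_", f)]][i] <- as.numeric(m[[f]])
    }
  }
  cohort
}

#' Write a response comparison to CSV and JSON
#' @param report a `response_comparison`.
#' @param prefix output path prefix; writes `<prefix>_patients.csv`,
#'   `<prefix>_tests.csv` and `<prefix>.json`.
#' @return The paths, invisibly.
#' @export
write_response_report <- function(report, prefix) {
  stopifnot(inherits(report, "response_comparison"))
  p1 <- paste0(prefix, "_patients.csv")
  p2 <- paste0(prefix, "_tests.csv")
  p3 <- paste0(prefix, ".json")
  write.csv(report$patients, p1, row.names = FALSE)
  write.csv(report$tests, p2, row.names = FALSE)
  jsonlite::write_json(list(group_summary = report$group_summary,
                            tests = report$tests,
                            n_responders = report$n_responders,
                            n_nonresponders = report$n_nonresponders,
                            small_sample = report$small_sample),
                       p3, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(p1, p2, p3))
}

#' @export
print.response_comparison <- function(x, ...) {
  cat(sprintf("response_comparison: %d responders vs %d non-responders%s\n",
              x$n_responders, x$n_nonresponders,
              if (x$small_sample) " [small-sample caveat]" else ""))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
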
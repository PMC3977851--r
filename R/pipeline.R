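#' Run the four-stage pipeline on in-memory station data
#'
#' Station fusion (corrections estimated on the low-b volume and reused
#' for the high-b volume, so ADC is invariant to the joint gain), ADC and
#' computed-DWI estimation, threshold + MRF segmentation, connected
#' components with optional superior cutoff, and tDV/gADC metrics.
#'
#' @param stations_low,stations_high lists of [station_volume()]s (e.g.
#'   from [generate_study()] or [read_station_series()]).
#' @param threshold computed-DWI threshold (required; the workflow's
#'   manually chosen value).
#' @param computed_b virtual b-value for the computed DWI (default 950
#'   s/mm^2). Display-oriented workflows often tune this much higher
#'   (e.g. 1355) for visual contrast; the quantitative default stays close
#'   to the acquired high b-value because large extrapolations amplify the
#'   log-ratio noise of low-SNR background voxels.
#' @param mrf an [mrf_params()]; `NULL` skips MRF smoothing.
#' @param cutoff_slice optional superior cutoff (1-based slice index).
#' @param search_radius fusion shift search radius.
#' @return List with `metrics` (a `tumor_metrics`), `voiset`, `mask`,
#'   `adc`, `cdwi`, `fused_low`, `fused_high`, `corrections`.
#' @export
run_study_pipeline <- function(stations_low, stations_high, threshold,
                               computed_b = 950, mrf = mrf_params(),
                               cutoff_slice = NULL, search_radius = 5) {
  fused_low <- fuse_stations(stations_low, search_radius = search_radius)
  corrections <- attr(fused_low, "corrections")
  fused_high <- fuse_stations(stations_high, corrections = corrections)
  study <- dwi_study(fused_low, fused_high)
  adc <- compute_adc(study)
  cdwi <- compute_cdwi(study, adc, computed_b)
  mask <- threshold_volume(cdwi, threshold)
  if (!is.null(mrf)) mask <- mrf_smooth(cdwi, mask, mrf)
  voiset <- connected_components(mask)
  if (!is.null(cutoff_slice)) voiset <- apply_superior_cutoff(voiset, cutoff_slice)
  metrics <- gadc_statistics(adc, voiset, fused_low$geometry)
  list(metrics = metrics, voiset = voiset, mask = mask, adc = adc,
       cdwi = cdwi, fused_low = fused_low, fused_high = fused_high,
       corrections = corrections)
}

#' Run the full pipeline from a configuration
#'
#' File-based orchestration: reads the station NIfTIs declared in the
#' study config, runs [run_study_pipeline()], and writes every
#' intermediate (fused volumes, ADC, computed DWI, mask, VOI labels),
#' the metrics JSON and a provenance record into `out_dir`. Deterministic
#' given identical inputs and parameters. On a stage failure the error
#' names the stage and already-written outputs are preserved.
#'
#' @param config a list or YAML/JSON path with fields: `study` (study
#'   config path, see [read_study_config()]), `threshold`, and optionally
#'   `computed_b`, `mrf_beta`, `mrf_neighborhood`, `cutoff_slice`,
#'   `search_radius`, `out_dir`.
#' @param out_dir output directory (overrides the config field).
#' @return The `tumor_metrics`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  for (key in c("study", "threshold"))
    if (is.null(config[[key]])) stop("pipeline config missing field: ", key)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("pipeline config missing field: out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cb <- if (is.null(config$computed_b)) 950 else as.numeric(config$computed_b)
  mrf <- if (isFALSE(config$mrf)) NULL else mrf_params(
    beta = if (is.null(config$mrf_beta)) 1.5 else as.numeric(config$mrf_beta),
    neighborhood = if (is.null(config$mrf_neighborhood)) 6
                   else as.integer(config$mrf_neighborhood))
  sr <- if (is.null(config$search_radius)) 5 else as.integer(config$search_radius)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  series <- stage("read", read_station_series(config$study))
  res <- stage("fuse/cdwi/segment",
               run_study_pipeline(series$low, series$high,
                                  threshold = as.numeric(config$threshold),
                                  computed_b = cb, mrf = mrf,
                                  cutoff_slice = config$cutoff_slice,
                                  search_radius = sr))
  stage("write", {
    geom <- res$fused_low$geometry
    write_volume(res$fused_low, file.path(out_dir, "fused_low.nii.gz"))
    write_volume(res$fused_high, file.path(out_dir, "fused_high.nii.gz"))
    adc_out <- res$adc$values; adc_out[!res$adc$valid] <- 0
    write_volume(adc_out, file.path(out_dir, "adc.nii.gz"), geometry = geom)
    write_volume(res$cdwi$values, file.path(out_dir, "cdwi.nii.gz"),
                 geometry = geom)
    write_volume(array(as.numeric(res$mask), dim = dim(res$mask)),
                 file.path(out_dir, "mask.nii.gz"), geometry = geom)
    write_volume(array(as.numeric(res$voiset$labels), dim = dim(res$voiset$labels)),
                 file.path(out_dir, "vois.nii.gz"), geometry = geom)
    write_metrics(res$metrics, file.path(out_dir, "metrics.json"))
    write.csv(data.frame(adc = res$metrics$histogram$breaks[-1],
                         count = res$metrics$histogram$counts),
              file.path(out_dir, "histogram.csv"), row.names = FALSE)
    provenance <- list(
      package_version = as.character(utils::packageVersion("wbdwi")),
      parameters = list(threshold = config$threshold, computed_b = cb,
                        mrf_beta = if (is.null(mrf)) NA else mrf$beta,
                        mrf_neighborhood = if (is.null(mrf)) NA else mrf$neighborhood,
                        cutoff_slice = config$cutoff_slice,
                        search_radius = sr),
      corrections = res$corrections,
      inputs = lapply(read_study_config(config$study)$stations, function(st)
        lapply(st, function(p) unname(tools::md5sum(p)))))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  })
  invisible(res$metrics)
}

#' Run the pipeline over a simulated cohort and compare groups
#'
#' Generates every patient's pre/post study from a [generate_cohort()]
#' object, pushes each through [run_study_pipeline()], and feeds the
#' per-patient metrics to [response_report()].
#'
#' @param cohort a `wbdwi_cohort`.
#' @param threshold,computed_b,mrf,cutoff_slice,search_radius passed to
#'   [run_study_pipeline()].
#' @return List with `report` (a `response_comparison`) and `table` (the
#'   per-patient metrics data.frame).
#' @export
analyze_cohort <- function(cohort, threshold = 20, computed_b = 950,
                           mrf = mrf_params(), cutoff_slice = NULL,
                           search_radius = 5) {
  stopifnot(inherits(cohort, "wbdwi_cohort"))
  rows <- lapply(cohort$patients, function(pat) {
    one <- function(spec, seed) {
      st <- generate_study(spec, seed = seed)
      run_study_pipeline(st$stations_low, st$stations_high, threshold,
                         computed_b, mrf, cutoff_slice, search_radius)$metrics
    }
    pre <- one(pat$pre_spec, pat$pre_seed)
    post <- one(pat$post_spec, pat$post_seed)
    data.frame(patient_id = pat$patient_id, group = pat$group,
               pre_tdv_ml = pre$tdv_ml, post_tdv_ml = post$tdv_ml,
               pre_gadc_median = pre$gadc_median,
               post_gadc_median = post$gadc_median,
               pre_gadc_variance = pre$gadc_variance,
               post_gadc_variance = post$gadc_variance,
               pre_gadc_skewness = pre$gadc_skewness,
               post_gadc_skewness = post$gadc_skewness,
               pre_gadc_kurtosis = pre$gadc_kurtosis,
               post_gadc_kurtosis = post$gadc_kurtosis)
  })
  table <- do.call(rbind, rows)
  list(report = response_report(table), table = table)
}
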
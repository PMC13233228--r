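# End-to-end study driver: phantom cohort -> perfusion maps -> arT -> paired
# evaluation -> cohort tables, plus a report validator. These functions are
# the package's orchestration surface; inst/cli/artroi.R wraps them for the
# shell.

#' Run a complete phantom validation study
#'
#' Generates an `n_subjects` cohort from `spec`, computes perfusion maps,
#' runs the arT pipeline against the generic template ROIs, evaluates every
#' native/generic ROI pair, and writes the cohort summary tables. With the
#' defaults (36 subjects, 7 ROIs) the study evaluates 252 ROI pairs. Output
#' is fully reproducible from (`spec`, `config`).
#'
#' @param out_dir output directory (created); `NULL` skips writing.
#' @param n_subjects cohort size.
#' @param spec a `PhantomSpec`.
#' @param config an `ArtConfig`.
#' @param verbose print per-subject progress.
#' @return a `StudyReport` list: `records` (one row per subject x ROI),
#'   `summary` (see [summarize_cohort()]), `filter_reports`, `outliers`
#'   (flagged subject/ROI rows), `spec`, `config`.
#' @export
run_study <- function(out_dir = NULL, n_subjects = 36L, spec = phantom_spec(),
                      config = art_config(), verbose = FALSE) {
  template <- make_template(spec)
  records <- list()
  freports <- list()
  for (i in seq_len(n_subjects)) {
    subj <- make_subject(spec, template, subject_index = i)
    maps <- compute_perfusion_maps(subj$dsc)
    art <- run_art(subj, template$rois, config)
    rec <- evaluate_pair(subj$rois_truth_dsc, art$rois_generic_native, maps)
    rec <- cbind(subject = i, rec)
    fr <- cbind(subject = i, art$filter_report)
    records[[i]] <- rec
    freports[[i]] <- fr
    if (verbose)
      message(sprintf("subject %d/%d: median SDI %.3f", i, n_subjects,
                      median(rec$sdi, na.rm = TRUE)))
    rm(subj, maps, art)
  }
  records <- do.call(rbind, records)
  freports <- do.call(rbind, freports)
  summary <- summarize_cohort(records)
  outliers <- freports[freports$flagged, , drop = FALSE]
  report <- structure(list(records = records, summary = summary,
                           filter_reports = freports, outliers = outliers,
                           spec = spec, config = config),
                      class = "StudyReport")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

study_schema <- list(
  records = c("subject", "label", "roi", "missing", "v_native", "v_generic",
              "ve", "sdi", "svr", "stdttp_nat", "stdttp_gen", "cbv_nat",
              "cbv_gen"),
  spatial = c("roi", "n", "v_mean_median", "v_mean_mad", "svr_median",
              "svr_mad", "ve_pct_median", "ve_pct_mad", "sdi_median",
              "sdi_mad"),
  parameter = c("roi", "n", "nat_median", "nat_mad", "gen_median", "gen_mad",
                "bias_median", "bias_mad", "pcc", "ccc"),
  filter = c("subject", "label", "roi", "n_before", "n_after", "n_removed",
             "frac_removed", "flagged"))

#' Write a study report to disk
#'
#' CSV tables (`records.csv`, `table_spatial.csv`, `table_stdttp.csv`,
#' `table_cbv.csv`, `filter_report.csv`) plus `agreement.json` (pooled
#' Bland-Altman/regression statistics, correlations, outlier flags) and
#' `provenance.json` (spec, config, package version). Differences are
#' generic minus native throughout.
#'
#' @param report a `StudyReport`.
#' @param out_dir directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) write.csv(df, file.path(out_dir, name),
                                     row.names = FALSE)
  wr(report$records, "records.csv")
  wr(report$summary$spatial, "table_spatial.csv")
  wr(report$summary$stdttp, "table_stdttp.csv")
  wr(report$summary$cbv, "table_cbv.csv")
  wr(report$filter_reports, "filter_report.csv")
  jsonlite::write_json(
    list(sign_convention = "generic - native",
         stdttp = report$summary$agreement_stdttp,
         cbv = report$summary$agreement_cbv,
         correlations = report$summary$correlations,
         n_outlier_flags = nrow(report$outliers),
         outliers = report$outliers),
    file.path(out_dir, "agreement.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    list(package = "artroi",
         version = as.character(utils::packageVersion("artroi")),
         n_subjects = length(unique(report$records$subject)),
         spec = unclass(report$spec),
         config = unclass(report$config)),
    file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Validate a written study report
#'
#' Re-checks the invariants every study must satisfy: the exact column
#' schemas, SDI within \[0, 1\], |VE| <= 2, |CCC| <= |PCC| in the parameter
#' tables, ordered limits of agreement, and a filter report that never adds
#' voxels. Returns a machine-readable pass/fail table.
#'
#' @param report_dir directory written by [write_study_report()].
#' @return data.frame with `check` and `pass`; attribute `"ok"` is the
#'   conjunction.
#' @export
validate_study <- function(report_dir) {
  need <- c("records.csv", "table_spatial.csv", "table_stdttp.csv",
            "table_cbv.csv", "filter_report.csv", "agreement.json")
  missing <- need[!file.exists(file.path(report_dir, need))]
  if (length(missing))
    stop("validation error: missing report files: ",
         paste(missing, collapse = ", "), call. = FALSE)
  records <- read.csv(file.path(report_dir, "records.csv"))
  spatial <- read.csv(file.path(report_dir, "table_spatial.csv"))
  tstd <- read.csv(file.path(report_dir, "table_stdttp.csv"))
  tcbv <- read.csv(file.path(report_dir, "table_cbv.csv"))
  filt <- read.csv(file.path(report_dir, "filter_report.csv"))
  agree <- jsonlite::read_json(file.path(report_dir, "agreement.json"),
                               simplifyVector = TRUE)
  checks <- list(
    schema_records = identical(names(records), study_schema$records),
    schema_spatial = identical(names(spatial), study_schema$spatial),
    schema_parameter = identical(names(tstd), study_schema$parameter) &&
      identical(names(tcbv), study_schema$parameter),
    schema_filter = identical(names(filt), study_schema$filter),
    sdi_bounds = all(records$sdi >= 0 & records$sdi <= 1, na.rm = TRUE),
    ve_bounds = all(abs(records$ve) <= 2, na.rm = TRUE),
    ccc_le_pcc = all(abs(tstd$ccc) <= abs(tstd$pcc) + 1e-12, na.rm = TRUE) &&
      all(abs(tcbv$ccc) <= abs(tcbv$pcc) + 1e-12, na.rm = TRUE),
    loa_ordered = agree$stdttp$loa[1] <= agree$stdttp$loa[2] &&
      agree$cbv$loa[1] <= agree$cbv$loa[2],
    filter_monotone = all(filt$n_after <= filt$n_before))
  out <- data.frame(check = names(checks),
                    pass = unlist(checks, use.names = FALSE))
  attr(out, "ok") <- all(out$pass)
  out
}
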
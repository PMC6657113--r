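# Orchestration: per-subject end-to-end run (velocity + mask -> energetics
# + volumetrics) and cohort-level rest-vs-stress reporting.

#' Run the full per-subject analysis for one condition
#'
#' Reads the velocity triplet and mask named in the config block for
#' `condition` (`rest` or `stress`), optionally unwraps aliased velocities
#' and applies a rigid transform to the mask, then computes the energetics
#' time series, phase averages, volumetrics and SV-normalized values.
#' Deterministic given its inputs; the returned `provenance` records the
#' physical parameters and partition used.
#'
#' @param config A subject configuration list (see
#'   [read_subject_config()]) with blocks `rest` / `stress`, each holding
#'   `velocity_paths` (3 files), `mask_path`, `venc`, `rr_ms`,
#'   `heart_rate_bpm`, `systole_frames`, `diastole_frames`, and optionally
#'   `rigid_transform` (12 numbers) and `unwrap` (logical).
#'   Top-level `rho` / `mu` override the physical defaults.
#' @param condition `"rest"` or `"stress"`.
#' @return A list with `series`, `summary`, `normalized`, `volumetrics`
#'   and `provenance`.
#' @export
run_subject <- function(config, condition = c("rest", "stress")) {
  condition <- match.arg(condition)
  cc <- config[[condition]]
  if (is.null(cc))
    stop(sprintf("config error: no '%s' block in subject config", condition),
         call. = FALSE)
  for (p in c(unlist(cc$velocity_paths), cc$mask_path))
    if (!file.exists(p))
      stop(sprintf("config error [%s]: input file not found: %s",
                   condition, p), call. = FALSE)
  params <- energetics_params(rho = config$rho %||% 1.025,
                              mu = config$mu %||% 4.0e-3)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s stage [%s]: %s", name, condition,
                   conditionMessage(e)), call. = FALSE))
  }
  field <- stage("read_velocity",
    read_velocity_nifti(unlist(cc$velocity_paths), venc = cc$venc,
                        rr_ms = cc$rr_ms %||% 1000))
  mask <- stage("read_mask",
    read_mask_nifti(cc$mask_path, rr_ms = cc$rr_ms %||% 1000))
  if (!is.null(cc$rigid_transform))
    mask <- stage("rigid_alignment",
      apply_rigid_to_mask(mask, config_transform(cc$rigid_transform)))
  if (isTRUE(cc$unwrap))
    field <- stage("unwrap", unwrap_velocity(field, mask))
  partition <- stage("partition",
    phase_partition(unlist(cc$systole_frames), unlist(cc$diastole_frames),
                    field$grid$nt))
  series <- stage("energetics", energetics_series(field, mask, params))
  summ <- phase_average(series, partition)
  vols <- stage("volumetrics", volumetrics(mask, cc$heart_rate_bpm))
  sv <- vols$summary[["sv_ml"]]
  normalized <- if (sv > 0) normalize_by_sv(summ, sv)
    else c(ke_cycle_per_sv = NA_real_, el_cycle_per_sv = NA_real_,
           vortvol_cycle_per_sv = NA_real_)  # non-beating mask: SV = 0
  list(series = series, summary = summ,
       normalized = normalized,
       volumetrics = vols,
       provenance = list(condition = condition, rho_g_ml = params$rho,
                         mu_pa_s = params$mu, venc_m_s = cc$venc,
                         systole_frames = partition$systole_frames,
                         diastole_frames = partition$diastole_frames,
                         stencil = "central, one-sided at mask boundary",
                         package_version =
                           as.character(utils::packageVersion("ventriflow"))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort-level rest-vs-stress study report
#'
#' Takes a paired cohort table (one row per subject with `<metric>_rest`
#' and `<metric>_stress` columns plus `vo2max`), runs the normality-gated
#' paired comparison for every metric and correlates each metric's
#' relative rest-stress difference with VO2max. Subjects with incomplete
#' rest/stress data are excluded, never silently: the exclusion table is
#' part of the report.
#'
#' @param table Data frame, e.g. from [simulate_cohort()] or assembled
#'   from [run_subject()] outputs.
#' @param metrics Metric name stems; default: every column pair
#'   `<stem>_rest` / `<stem>_stress` present.
#' @param vo2max_col Name of the VO2max column (set `NULL` to skip the
#'   correlation stage).
#' @return An object of class `study_report`: list with `subjects`
#'   (per-subject rest/stress/difference/relative-difference table),
#'   `comparisons` (per-metric [paired_compare()] results and a formatted
#'   summary data frame), `correlations` (per-metric [correlate()] of
#'   relative difference vs VO2max), and `exclusions`.
#' @export
run_study <- function(table, metrics = NULL, vo2max_col = "vo2max") {
  stopifnot(is.data.frame(table))
  if (is.null(metrics)) {
    stems <- sub("_rest$", "", grep("_rest$", names(table), value = TRUE))
    metrics <- stems[paste0(stems, "_stress") %in% names(table)]
  }
  if (length(metrics) == 0L)
    stop("no <metric>_rest / <metric>_stress column pairs found",
         call. = FALSE)
  need <- c(paste0(metrics, "_rest"), paste0(metrics, "_stress"))
  if (!is.null(vo2max_col)) need <- c(need, vo2max_col)
  complete <- stats::complete.cases(table[need])
  ids <- if ("subject_id" %in% names(table)) table$subject_id
         else as.character(seq_len(nrow(table)))
  exclusions <- data.frame(subject_id = ids[!complete],
                           reason = rep("missing rest/stress or VO2max value",
                                        sum(!complete)),
                           stringsAsFactors = FALSE)
  tab <- table[complete, , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("need at least 3 subjects with complete rest/stress data",
         call. = FALSE)

  subj <- data.frame(subject_id = ids[complete], stringsAsFactors = FALSE)
  comparisons <- list(); correlations <- list()
  rows <- list()
  for (m in metrics) {
    rest <- tab[[paste0(m, "_rest")]]
    stress <- tab[[paste0(m, "_stress")]]
    rel <- relative_difference(rest, stress)
    subj[[paste0(m, "_rest")]] <- rest
    subj[[paste0(m, "_stress")]] <- stress
    subj[[paste0(m, "_diff")]] <- stress - rest
    subj[[paste0(m, "_rel_diff_pct")]] <- rel
    cmp <- paired_compare(rest, stress)
    comparisons[[m]] <- cmp
    rows[[m]] <- data.frame(
      metric = m,
      rest = describe(rest)$label, stress = describe(stress)$label,
      difference = cmp$diff$label,
      difference_pct = if (is.null(cmp$relative_diff)) NA_character_
                       else cmp$relative_diff$label,
      p_value = cmp$p_value, test = cmp$test_used,
      stringsAsFactors = FALSE)
    if (!is.null(vo2max_col)) {
      vo2 <- tab[[vo2max_col]]
      correlations[[m]] <- if (stats::sd(rel, na.rm = TRUE) == 0 ||
                               stats::sd(vo2) == 0)
        # degenerate (e.g. no rest-stress effect at all): undefined r
        structure(list(n = sum(!is.na(rel)), r = NA_real_,
                       p_value = NA_real_, method = NA_character_,
                       strength_label = NA_character_),
                  class = "correlation_result")
      else correlate(rel, vo2)
    }
  }
  comparison_table <- do.call(rbind, rows)
  rownames(comparison_table) <- NULL
  correlation_table <- if (length(correlations))
    data.frame(metric = names(correlations),
               r = vapply(correlations, `[[`, numeric(1), "r"),
               p_value = vapply(correlations, `[[`, numeric(1), "p_value"),
               method = vapply(correlations, `[[`, character(1), "method"),
               strength = vapply(correlations, `[[`, character(1),
                                 "strength_label"),
               row.names = NULL, stringsAsFactors = FALSE)
  else NULL
  structure(list(subjects = subj, comparisons = comparisons,
                 comparison_table = comparison_table,
                 correlations = correlations,
                 correlation_table = correlation_table,
                 exclusions = exclusions),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("rest-stress study report: %d subjects, %d excluded\n",
              nrow(x$subjects), nrow(x$exclusions)))
  print(x$comparison_table)
  if (!is.null(x$correlation_table)) {
    cat("\nrelative difference vs VO2max:\n")
    print(x$correlation_table)
  }
  invisible(x)
}

#' Write a study report to CSV/JSON files
#'
#' Writes `subjects.csv`, `comparisons.csv`, `correlations.csv` (if
#' present), `exclusions.csv` and a machine-readable `report.json`.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparison_table,
                   file.path(dir, "comparisons.csv"), row.names = FALSE)
  if (!is.null(report$correlation_table))
    utils::write.csv(report$correlation_table,
                     file.path(dir, "correlations.csv"), row.names = FALSE)
  utils::write.csv(report$exclusions, file.path(dir, "exclusions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(comparisons = report$comparison_table,
         correlations = report$correlation_table,
         exclusions = report$exclusions),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a paired cohort table from CSV
#'
#' Expects one row per subject with `subject_id`, `vo2max` and
#' `<metric>_rest` / `<metric>_stress` columns.
#'
#' @param path CSV file.
#' @return A data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_cohort_csv
#' @param table Cohort data.frame.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
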
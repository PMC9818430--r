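# Delimited-text interchange format: comma-separated, header row, UTF-8,
# "." decimal, booleans as 0/1, times in weeks from the first chemotherapy
# cycle.
#
# longitudinal: patient_id, t_weeks, ca125_iu_ml, cycles_completed,
#               paracenteses_cum
# baseline:     patient_id, ps, pc_epigastric, ascites, n_cycles_total,
#               n_paracenteses_total, decision_time_weeks, resectable

LONG_COLS <- c("patient_id", "t_weeks", "ca125_iu_ml",
               "cycles_completed", "paracenteses_cum")
BASE_COLS <- c("patient_id", "ps", "pc_epigastric", "ascites",
               "n_cycles_total", "n_paracenteses_total",
               "decision_time_weeks", "resectable")

#' Read and validate the cohort tables
#'
#' Reads the two comma-delimited tables and enforces every schema
#' invariant: required columns; strictly positive CA-125; per-patient
#' measurement times strictly increasing with nondecreasing cumulative
#' cycle and paracentesis counts; decision time at or after the last
#' measurement; and identical patient sets in both tables. Each violation
#' raises a distinct condition class naming the offending rows.
#'
#' @param longitudinal_path,baseline_path Paths to the two CSV files.
#' @return A list with validated tibbles `longitudinal` and `baseline`.
#' @export
read_ca125_tables <- function(longitudinal_path, baseline_path) {
  longitudinal <- readr::read_csv(longitudinal_path, show_col_types = FALSE,
                                  progress = FALSE)
  baseline <- readr::read_csv(baseline_path, show_col_types = FALSE,
                              progress = FALSE)
  validate_ca125_tables(longitudinal, baseline)
}

#' @rdname read_ca125_tables
#' @param longitudinal,baseline In-memory tables to validate.
#' @export
validate_ca125_tables <- function(longitudinal, baseline) {
  miss_l <- setdiff(LONG_COLS, names(longitudinal))
  miss_b <- setdiff(BASE_COLS, names(baseline))
  if (length(miss_l) || length(miss_b)) {
    rlang::abort(paste0("missing column(s): ",
                        paste(c(miss_l, miss_b), collapse = ", ")),
                 class = "ca125jm_error_schema")
  }
  for (col in c("pc_epigastric", "ascites", "resectable")) {
    baseline[[col]] <- as.logical(baseline[[col]])
  }
  if (nrow(longitudinal)) {
    bad <- which(!is.finite(longitudinal$ca125_iu_ml) |
                   longitudinal$ca125_iu_ml <= 0)
    if (length(bad)) {
      rlang::abort(paste0("non-positive CA-125 in longitudinal row(s): ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   class = "ca125jm_error_ca125")
    }
    by_pat <- split(seq_len(nrow(longitudinal)), longitudinal$patient_id)
    for (id in names(by_pat)) {
      idx <- by_pat[[id]]
      tt <- longitudinal$t_weeks[idx]
      if (is.unsorted(tt, strictly = TRUE)) {
        rlang::abort(paste0("measurement times not strictly increasing for patient ", id),
                     class = "ca125jm_error_times")
      }
      if (is.unsorted(longitudinal$cycles_completed[idx]) ||
          is.unsorted(longitudinal$paracenteses_cum[idx])) {
        rlang::abort(paste0("cumulative counts decrease for patient ", id),
                     class = "ca125jm_error_counts")
      }
      i <- match(id, baseline$patient_id)
      if (is.na(i)) {
        rlang::abort(paste0("patient ", id, " has measurements but no baseline row"),
                     class = "ca125jm_error_orphan")
      }
      if (baseline$decision_time_weeks[i] < max(tt) - 1e-9) {
        rlang::abort(paste0("decision time before last measurement for patient ", id),
                     class = "ca125jm_error_decision_time")
      }
    }
    orphan_b <- setdiff(baseline$patient_id, longitudinal$patient_id)
    if (length(orphan_b)) {
      rlang::abort(paste0("baseline patient(s) without measurements: ",
                          paste(orphan_b, collapse = ", ")),
                   class = "ca125jm_error_orphan")
    }
  }
  if (any(baseline$decision_time_weeks <= 0)) {
    rlang::abort("decision times must be positive.",
                 class = "ca125jm_error_decision_time")
  }
  list(longitudinal = tibble::as_tibble(longitudinal),
       baseline = tibble::as_tibble(baseline))
}

#' Write the cohort tables
#'
#' @param longitudinal,baseline Tables to write (booleans stored as 0/1).
#' @param longitudinal_path,baseline_path Destination CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_ca125_tables <- function(longitudinal, baseline,
                               longitudinal_path, baseline_path) {
  base_out <- dplyr::mutate(baseline,
                            dplyr::across(dplyr::where(is.logical), as.integer))
  readr::write_csv(longitudinal, longitudinal_path, progress = FALSE)
  readr::write_csv(base_out, baseline_path, progress = FALSE)
  invisible(c(longitudinal_path, baseline_path))
}
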
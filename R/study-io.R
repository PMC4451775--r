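#' Study-level dataset I/O and validation
#'
#' A study dataset is a tibble with one row per (study, disease, SNP)
#' record of a case-control genotype meta-analysis. Required columns are
#' `study_id`, `year`, `country`, `ethnicity` (`"Asians"`/`"Caucasians"`),
#' `disease` (`"UC"`/`"CD"`), `snp`, `control_group_id`, `n_case`, `n_ctrl`.
#' Optional columns carry genotype counts (`n_case_ww`, `n_case_wm`,
#' `n_case_mm`, `n_ctrl_ww`, `n_ctrl_wm`, `n_ctrl_mm`) and
#' `genotyping_method`. `control_group_id` marks control groups reused
#' across rows of the same study (e.g. one healthy panel compared against
#' both the ulcerative colitis and the Crohn's disease cases); rows sharing
#' it at the same SNP must carry identical control counts.
#'
#' In a count-free dataset (such as the packaged cohort table, where the
#' source publication prints sample sizes but not genotype counts) the
#' `snp` column may hold several SNP identifiers separated by `";"` to
#' record coverage; rows with genotype counts must name exactly one SNP.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param require_counts If `TRUE`, fail unless all six genotype-count
#'   columns are present and filled.
#' @return `read_study_data()` returns a tibble of validated records with
#'   attribute `counts_present`; `has_counts()` reports whether a dataset
#'   carries complete genotype counts.
#' @examples
#' studies <- tlr4_ibd_studies()
#' count_summary(studies)
#' @name study_io
NULL

required_cols <- c("study_id", "year", "country", "ethnicity", "disease",
                   "snp", "control_group_id", "n_case", "n_ctrl")
count_cols <- c("n_case_ww", "n_case_wm", "n_case_mm",
                "n_ctrl_ww", "n_ctrl_wm", "n_ctrl_mm")

#' @rdname study_io
#' @export
read_study_data <- function(path, require_counts = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("dataset file not found: ", path), class = "snpmeta_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("missing required column(s): ", paste(missing, collapse = ", ")),
          class = "snpmeta_schema_error")
  }
  data <- dplyr::mutate(
    data,
    dplyr::across(dplyr::any_of(c("study_id", "country", "ethnicity",
                                  "disease", "snp", "control_group_id")),
                  as.character),
    dplyr::across(dplyr::any_of(c("year", "n_case", "n_ctrl", count_cols)),
                  as.numeric)
  )
  report <- validate_study_data(data, require_counts = require_counts)
  errors <- dplyr::filter(report, .data$severity == "error")
  if (nrow(errors) > 0) {
    msgs <- paste0("row ", errors$row, " [", errors$column, "]: ", errors$message)
    abort(paste0("invalid study dataset:\n", paste(utils::head(msgs, 10), collapse = "\n")),
          class = "snpmeta_validation_error")
  }
  for (w in dplyr::filter(report, .data$severity == "warning")$message) warn(w)
  attr(data, "counts_present") <- has_counts(data)
  data
}

#' @rdname study_io
#' @param data A study dataset tibble.
#' @export
has_counts <- function(data) {
  all(count_cols %in% names(data)) &&
    nrow(data) > 0 &&
    !anyNA(data[count_cols])
}

#' Validate a study dataset
#'
#' Checks the dataset against the schema invariants: non-negative counts,
#' positive case totals, unique (study, disease, SNP) keys, consistent
#' shared control groups, and known factor levels. Returns a report rather
#' than failing, so callers can distinguish fatal errors from advisories.
#'
#' @inheritParams study_io
#' @param data A study dataset tibble.
#' @return A tibble with columns `severity` (`"error"`/`"warning"`), `row`
#'   (index into `data`, `NA` for dataset-level issues), `column`, and
#'   `message`. The dataset is accepted iff no row has severity `"error"`.
#' @export
validate_study_data <- function(data, require_counts = FALSE) {
  issues <- list()
  note <- function(severity, row, column, message) {
    issues[[length(issues) + 1]] <<-
      tibble::tibble(severity = severity, row = row, column = column,
                     message = message)
  }

  missing <- setdiff(required_cols, names(data))
  for (col in missing) note("error", NA_integer_, col, "required column missing")
  counts_here <- all(count_cols %in% names(data))
  if (require_counts && !counts_here) {
    note("error", NA_integer_, "counts",
         "genotype-count columns required but absent")
  }
  if (length(missing) > 0) {
    return(dplyr::bind_rows(issues))
  }

  for (i in seq_len(nrow(data))) {
    row <- data[i, ]
    if (!row$ethnicity %in% the_ethnicities)
      note("error", i, "ethnicity", paste0("unknown ethnicity '", row$ethnicity, "'"))
    if (!row$disease %in% the_diseases)
      note("error", i, "disease", paste0("unknown disease '", row$disease, "'"))
    snps <- strsplit(row$snp, ";", fixed = TRUE)[[1]]
    if (length(snps) == 0 || !all(snps %in% the_snps))
      note("error", i, "snp", paste0("unknown SNP '", row$snp, "'"))
    for (col in c("n_case", "n_ctrl")) {
      v <- row[[col]]
      if (is.na(v) || v < 0) note("error", i, col, "sample size missing or negative")
    }
    if (counts_here) {
      vals <- unlist(row[count_cols])
      if (anyNA(vals)) {
        if (require_counts)
          note("error", i, "counts", "genotype counts incomplete")
      } else {
        for (col in count_cols) {
          if (row[[col]] < 0) note("error", i, col, "negative genotype count")
        }
        if (all(vals >= 0)) {
          if (sum(vals[1:3]) <= 0)
            note("error", i, "n_case_ww", "case genotype total must be positive")
          if (length(snps) != 1)
            note("error", i, "snp",
                 "rows with genotype counts must name exactly one SNP")
          if (!is.na(row$n_case) && sum(vals[1:3]) != row$n_case)
            note("warning", i, "n_case",
                 paste0("row ", i, ": n_case differs from case genotype total"))
          if (!is.na(row$n_ctrl) && sum(vals[4:6]) != row$n_ctrl)
            note("warning", i, "n_ctrl",
                 paste0("row ", i, ": n_ctrl differs from control genotype total"))
        }
      }
    }
  }

  key <- paste(data$study_id, data$disease, data$snp, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup)
    note("error", i, "study_id",
         paste0("duplicate (study_id, disease, snp) key: ", data$study_id[i],
                "/", data$disease[i], "/", data$snp[i]))

  # shared control groups: identical control data within (group, snp)
  share_cols <- c("n_ctrl", intersect(count_cols[4:6], names(data)))
  grp <- paste(data$control_group_id, data$snp, sep = "\r")
  for (g in unique(grp[duplicated(grp)])) {
    rows <- which(grp == g)
    block <- data[rows, share_cols, drop = FALSE]
    if (nrow(dplyr::distinct(block)) > 1)
      note("error", rows[2], "control_group_id",
           paste0("rows sharing control group '", data$control_group_id[rows[1]],
                  "' disagree on control counts"))
  }

  out <- dplyr::bind_rows(issues)
  if (nrow(out) == 0) {
    out <- tibble::tibble(severity = character(), row = integer(),
                          column = character(), message = character())
  }
  out
}

#' @rdname study_io
#' @export
write_study_data <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Cohort table of the TLR4/IBD meta-analysis
#'
#' The baseline-characteristics table of a published meta-analysis of the
#' TLR4 rs4986790A>G and rs4986791C>T polymorphisms and inflammatory bowel
#' disease: 22 records (one per study and disease subtype) from 13
#' case-control studies, with per-row case/control sample sizes, ethnicity,
#' genotyping method and SNP coverage. The source table prints sample sizes
#' only, so the dataset carries no genotype counts; it anchors aggregation
#' checks and provides the template for [simulate_tlr4_cohort()].
#'
#' @return A study dataset tibble with 22 rows (`counts_present` false).
#' @export
tlr4_ibd_studies <- function() {
  path <- system.file("extdata", "tlr4_ibd_studies.csv", package = "snpmeta",
                      mustWork = TRUE)
  suppressWarnings(read_study_data(path))
}

#' Aggregate subject and study totals of a dataset
#'
#' Bookkeeping follows the convention of published meta-analysis cohort
#' tables: the unit is the (study, disease) row, so a case group genotyped
#' at two SNPs is counted once, while a control panel shared between the UC
#' and CD rows of a study is counted once *per row*. The headline control
#' total therefore double-counts shared panels; `controls_unique` counts
#' each control group once and is reported alongside as the statistical
#' caveat.
#'
#' @param data A study dataset tibble.
#' @return An object of class `count_summary`: a list with scalar totals
#'   (`n_records`, `n_rows`, `n_studies`, `cases_total`, `controls_rowwise`,
#'   `controls_unique`, `controls_duplicated`) and breakdown tibbles
#'   (`cases_by_disease`, `studies_by_ethnicity`, `studies_by_snp`).
#' @export
count_summary <- function(data) {
  stopifnot(all(required_cols %in% names(data)))
  units <- data |>
    dplyr::group_by(.data$study_id, .data$disease) |>
    dplyr::summarise(n_case = .data$n_case[1], n_ctrl = .data$n_ctrl[1],
                     control_group_id = .data$control_group_id[1],
                     ethnicity = .data$ethnicity[1], .groups = "drop")
  ctrl_groups <- units |>
    dplyr::group_by(.data$control_group_id) |>
    dplyr::summarise(n_ctrl = .data$n_ctrl[1], .groups = "drop")
  snp_cov <- data |>
    dplyr::mutate(snp = strsplit(.data$snp, ";", fixed = TRUE)) |>
    tidyr::unnest("snp") |>
    dplyr::distinct(.data$study_id, .data$snp) |>
    dplyr::count(.data$snp, name = "n_studies")

  out <- list(
    n_records = nrow(data),
    n_rows = nrow(units),
    n_studies = dplyr::n_distinct(data$study_id),
    cases_total = sum(units$n_case),
    controls_rowwise = sum(units$n_ctrl),
    controls_unique = sum(ctrl_groups$n_ctrl),
    controls_duplicated = sum(units$n_ctrl) - sum(ctrl_groups$n_ctrl),
    cases_by_disease = units |>
      dplyr::group_by(.data$disease) |>
      dplyr::summarise(n_rows = dplyr::n(), cases = sum(.data$n_case),
                       .groups = "drop"),
    studies_by_ethnicity = data |>
      dplyr::distinct(.data$study_id, .data$ethnicity) |>
      dplyr::count(.data$ethnicity, name = "n_studies"),
    studies_by_snp = snp_cov
  )
  structure(out, class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat("Study dataset summary\n")
  cat(sprintf("  %d records, %d study-disease rows, %d studies\n",
              x$n_records, x$n_rows, x$n_studies))
  cat(sprintf("  cases: %d (%s)\n", x$cases_total,
              paste(sprintf("%s %d", x$cases_by_disease$disease,
                            x$cases_by_disease$cases), collapse = ", ")))
  cat(sprintf("  controls: %d per-row (%d unique control subjects)\n",
              x$controls_rowwise, x$controls_unique))
  cat(sprintf("  studies by ethnicity: %s\n",
              paste(sprintf("%s %d", x$studies_by_ethnicity$ethnicity,
                            x$studies_by_ethnicity$n_studies), collapse = ", ")))
  cat(sprintf("  studies by SNP: %s\n",
              paste(sprintf("%s %d", x$studies_by_snp$snp,
                            x$studies_by_snp$n_studies), collapse = ", ")))
  invisible(x)
}
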
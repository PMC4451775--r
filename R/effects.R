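#' Odds ratio of a single 2x2 table
#'
#' Computes the sample odds ratio `ad/bc` with the Woolf log-scale
#' standard error `sqrt(1/a + 1/b + 1/c + 1/d)`. When any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to all four cells of that table so
#' the odds ratio and its variance stay estimable.
#'
#' @param a,b,c,d Cell counts: case exposed / case unexposed /
#'   control exposed / control unexposed.
#' @param correction `"affected"` adds 0.5 to all cells of a table that
#'   contains a zero (the dominant convention); `"all"` corrects every
#'   table unconditionally; `"none"` refuses tables with zero cells.
#' @return A one-row tibble: `log_or`, `se`, `or`, `ci_low`, `ci_high`
#'   (95%, on the OR scale), and `corrected`.
#' @examples
#' table_effect(20, 80, 10, 90)   # OR = 2.25
#' table_effect(0, 10, 5, 5)      # Haldane-corrected
#' @export
table_effect <- function(a, b, c, d, correction = c("affected", "all", "none")) {
  correction <- match.arg(correction)
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0)) {
    abort("cells must be non-negative counts", class = "snpmeta_effect_error")
  }
  if (a + b == 0 || c + d == 0) {
    abort("inestimable effect: a margin (all cases or all controls) is zero",
          class = "snpmeta_inestimable_effect")
  }
  corrected <- FALSE
  if (any(cells == 0) || correction == "all") {
    if (correction == "none") {
      abort("zero cell with correction = \"none\"",
            class = "snpmeta_inestimable_effect")
    }
    cells <- cells + 0.5
    corrected <- TRUE
  }
  log_or <- log(cells[1] * cells[4] / (cells[2] * cells[3]))
  se <- sqrt(sum(1 / cells))
  tibble::tibble(log_or = log_or, se = se, or = exp(log_or),
                 ci_low = exp(log_or - Z_95 * se),
                 ci_high = exp(log_or + Z_95 * se),
                 corrected = corrected)
}

#' Per-study odds ratios under a genetic model
#'
#' Builds the 2x2 contrast of every record of a counted dataset under one
#' genetic model and estimates its log odds ratio. Records whose contrast
#' is degenerate (an exposure arm empty in both cases and controls, e.g.
#' no MM homozygote anywhere for the recessive model) cannot contribute an
#' effect and are dropped with a warning naming them.
#'
#' @param data A study dataset tibble with genotype counts (see
#'   [read_study_data()]).
#' @param model One of [genetic_models()].
#' @inheritParams table_effect
#' @return A tibble with one row per estimable record: identifying columns
#'   (`study_id`, `disease`, `snp`, `ethnicity`, `control_group_id`,
#'   `n_case`, `n_ctrl`), the contrast cells, and the [table_effect()]
#'   columns.
#' @examples
#' sim <- simulate_studies(sim_config(k = 5, theta = log(1.5), seed = 7))
#' study_effects(sim, "allele")
#' @export
study_effects <- function(data, model = genetic_models(),
                          correction = c("affected", "all", "none")) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  if (!has_counts(data)) {
    abort("dataset carries no genotype counts; effects are inestimable",
          class = "snpmeta_no_counts")
  }
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    ct <- tryCatch(
      build_contrast(c(row$n_case_ww, row$n_case_wm, row$n_case_mm),
                     c(row$n_ctrl_ww, row$n_ctrl_wm, row$n_ctrl_mm),
                     model),
      snpmeta_degenerate_contrast = function(e) NULL)
    if (is.null(ct)) return(NULL)
    eff <- tryCatch(table_effect(ct$a, ct$b, ct$c, ct$d, correction),
                    snpmeta_inestimable_effect = function(e) NULL)
    if (is.null(eff)) return(NULL)
    dplyr::bind_cols(
      row[intersect(c("study_id", "year", "disease", "snp", "ethnicity",
                      "control_group_id", "n_case", "n_ctrl"), names(row))],
      ct, eff)
  })
  dropped <- purrr::map_lgl(rows, is.null)
  if (any(dropped)) {
    keys <- paste(data$study_id[dropped], data$disease[dropped],
                  data$snp[dropped], sep = "/")
    warn(paste0("dropped ", sum(dropped), " record(s) with degenerate '",
                model, "' contrast: ", paste(keys, collapse = ", ")))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort(paste0("no estimable effects under the '", model, "' model"),
          class = "snpmeta_no_effects")
  }
  out
}
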
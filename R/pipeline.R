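#' Run the full meta-analysis pipeline
#'
#' For every SNP and genetic model in scope: per-study effects, model
#' selection, overall pooling, subgroup pooling (ethnicity, disease),
#' leave-one-out sensitivity, Egger and fail-safe-N publication-bias
#' tests, and funnel/forest exports; plus univariate and multivariate
#' meta-regression (per genetic model, across SNPs) with permutation
#' p-values. Stages whose preconditions fail (a degenerate contrast, fewer
#' than 2 studies for heterogeneity and sensitivity, fewer than 3 for
#' Egger) are skipped and recorded in `skipped`, never silently. The
#' report is a pure function of the input data, the options and the seed.
#'
#' @param data A study dataset tibble with genotype counts.
#' @param models Genetic models to analyse, see [genetic_models()].
#' @param rule Model-selection rule, see [select_model()].
#' @param subgroups Stratification variables for subgroup pooling.
#' @param moderators Moderators for the meta-regression, see
#'   [meta_regress()].
#' @param n_perm Permutations for the meta-regression Monte Carlo
#'   p-values (`NULL` to skip).
#' @param alpha Significance level used for reporting.
#' @param seed Integer seed for the permutation draws.
#' @param input Optional provenance string naming the input file.
#' @return An object of class `meta_report`: a list of tibbles `results`
#'   (per snp/model/stratum pooled estimates), `loo`, `metareg`, `bias`,
#'   `forest`, `funnel`, `skipped`, and `provenance`.
#' @export
run_meta_analysis <- function(data,
                              models = c("allele", "dominant", "recessive",
                                         "homozygous", "heterozygous"),
                              rule = c("conventional", "paper"),
                              subgroups = c("ethnicity", "disease"),
                              moderators = c("sample_size", "ethnicity",
                                             "disease", "snp"),
                              n_perm = NULL, alpha = 0.05, seed = 1,
                              input = NA_character_) {
  rule <- match.arg(rule)
  models <- match.arg(models, choices = genetic_models(), several.ok = TRUE)
  if (!has_counts(data)) {
    abort("pipeline stage 'effects': dataset carries no genotype counts",
          class = "snpmeta_no_counts")
  }
  snps <- sort(unique(data$snp))
  skipped <- list()
  skip <- function(stage, key, reason) {
    skipped[[length(skipped) + 1]] <<-
      tibble::tibble(stage = stage, key = key, reason = reason)
    warn(paste0("skipping ", stage, " for ", key, ": ", reason))
  }

  results <- list(); loo <- list(); bias <- list()
  forest <- list(); funnel <- list(); all_effects <- list()

  for (s in snps) {
    sub_data <- data[data$snp == s, , drop = FALSE]
    for (m in models) {
      key <- paste0(s, "/", m)
      eff <- tryCatch(
        suppressWarnings(study_effects(sub_data, m)),
        snpmeta_no_effects = function(e) NULL)
      if (is.null(eff)) {
        skip("effects", key, "no estimable contrasts")
        next
      }
      all_effects[[key]] <- dplyr::mutate(eff, model = m)

      strata <- purrr::map_dfr(subgroups, function(v) {
        subgroup_pool(eff, by = v, rule = rule)
      })
      strata <- dplyr::distinct(
        dplyr::bind_rows(
          dplyr::mutate(strata[strata$level == "overall", ][1, ],
                        variable = "overall"),
          strata[strata$level != "overall", ]))
      results[[key]] <- dplyr::bind_cols(
        tibble::tibble(snp = s, model = m), strata)

      pooled <- meta_pool(eff, rule = rule)
      forest[[key]] <- dplyr::mutate(tidy(pooled), model = m,
                                     .after = dplyr::any_of("snp"))

      if (nrow(eff) >= 2) {
        loo[[key]] <- dplyr::bind_cols(tibble::tibble(snp = s, model = m),
                                       leave_one_out(eff, rule = rule))
      } else {
        skip("leave_one_out", key, "fewer than 2 studies")
      }

      fsn <- fail_safe_n(eff)
      eg <- tryCatch(egger_test(eff),
                     snpmeta_bias_error = function(e) NULL)
      if (is.null(eg)) skip("egger_test", key, "fewer than 3 studies or identical se")
      bias[[key]] <- tibble::tibble(
        snp = s, model = m, k = nrow(eff),
        egger_intercept = if (is.null(eg)) NA_real_ else eg$intercept,
        egger_t = if (is.null(eg)) NA_real_ else eg$t,
        egger_p = if (is.null(eg)) NA_real_ else eg$p,
        fail_safe_n = fsn$n_fs, z_combined = fsn$z_combined)

      fd <- funnel_data(eff, pooled)
      funnel[[key]] <- dplyr::mutate(fd$points, model = m,
                                     .after = dplyr::any_of("snp"))
    }
  }
  if (length(results) == 0) {
    abort("pipeline stage 'effects': no estimable effects for any snp/model",
          class = "snpmeta_pipeline_error")
  }

  metareg <- list()
  for (m in models) {
    key <- paste0("all-snps/", m)
    eff <- dplyr::bind_rows(all_effects[paste0(snps, "/", m)])
    if (nrow(eff) < length(moderators) + 3) {
      skip("meta_regression", key, "too few studies for the design")
      next
    }
    for (mode in c("univariate", "multivariate")) {
      fit <- tryCatch(
        suppressWarnings(meta_regress(eff, moderators, mode = mode,
                                      n_perm = n_perm, seed = seed)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        skip("meta_regression", paste0(key, "/", mode), conditionMessage(fit))
        next
      }
      metareg[[paste0(key, "/", mode)]] <- dplyr::bind_cols(
        tibble::tibble(model = m, mode = mode, k = fit$k), tidy(fit))
    }
  }

  structure(list(
    results = dplyr::bind_rows(results),
    loo = dplyr::bind_rows(loo),
    metareg = dplyr::bind_rows(metareg),
    bias = dplyr::bind_rows(bias),
    forest = dplyr::bind_rows(forest),
    funnel = dplyr::bind_rows(funnel),
    skipped = if (length(skipped) > 0) dplyr::bind_rows(skipped) else
      tibble::tibble(stage = character(), key = character(), reason = character()),
    provenance = list(
      input = input, models = models, rule = rule, subgroups = subgroups,
      moderators = moderators, n_perm = n_perm, alpha = alpha, seed = seed,
      package = "snpmeta",
      version = as.character(utils::packageVersion("snpmeta")))
  ), class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  cat(sprintf("meta-analysis report: %d pooled strata, %d SNP/model pairs\n",
              nrow(x$results), nrow(x$bias)))
  print(x$results[x$results$variable == "overall",
                  c("snp", "model", "k", "or", "ci_low", "ci_high", "p",
                    "i2", "model_effects")], ...)
  invisible(x)
}

# Table-style display: 3 decimals, p-values floored at "<0.001".
display_round <- function(df) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
  for (col in intersect(c("p", "p_q", "egger_p", "permutation_p"), names(df))) {
    df[[paste0(col, "_display")]] <- format_p(df[[col]])
  }
  df
}

#' Write the report tables
#'
#' Renders the report to plain-text tables: `results.tsv` (pooled
#' estimates per genetic model and stratum, models in the conventional
#' allele / dominant / homozygous / heterozygous / recessive order),
#' `metareg.tsv`, `bias.tsv`, `loo.tsv`, `forest.csv`, `funnel.csv`, and
#' `report.json` (the full-precision report). Table values are rounded to
#' 3 decimals; p-values additionally get a display column floored at
#' `<0.001`. Every number is taken from the report — nothing is recomputed
#' at render time.
#'
#' @param report A `meta_report`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "meta_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model_order <- c("allele", "dominant", "homozygous", "heterozygous",
                   "heterozygous_conventional", "recessive")
  results <- report$results |>
    dplyr::arrange(match(.data$model, model_order), .data$snp,
                   match(.data$variable, c("overall", "ethnicity", "disease")),
                   .data$level)
  paths <- c(
    results = file.path(out_dir, "results.tsv"),
    metareg = file.path(out_dir, "metareg.tsv"),
    bias = file.path(out_dir, "bias.tsv"),
    loo = file.path(out_dir, "loo.tsv"),
    forest = file.path(out_dir, "forest.csv"),
    funnel = file.path(out_dir, "funnel.csv"),
    report = file.path(out_dir, "report.json"))
  readr::write_tsv(display_round(results), paths["results"], progress = FALSE)
  readr::write_tsv(display_round(report$metareg), paths["metareg"], progress = FALSE)
  readr::write_tsv(display_round(report$bias), paths["bias"], progress = FALSE)
  readr::write_tsv(display_round(report$loo), paths["loo"], progress = FALSE)
  forest <- report$forest |>
    dplyr::mutate(source = paste(.data$study_id, .data$disease, sep = "/")) |>
    dplyr::select(dplyr::all_of(c("snp", "model", "source", "log_or", "se")),
                  or_ = "or", dplyr::all_of(c("ci_low", "ci_high", "weight_pct")))
  readr::write_csv(forest, paths["forest"], progress = FALSE)
  readr::write_csv(report$funnel, paths["funnel"], progress = FALSE)
  jsonlite::write_json(unclass(report), paths["report"], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}
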
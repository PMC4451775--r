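#' Genetic-model 2x2 contrasts
#'
#' Each genetic model maps genotype counts (WW, WM, MM, with W the
#' wild-type and M the mutant allele) to an exposed/unexposed 2x2 table:
#'
#' * `allele`: M allele vs W allele, counting chromosomes (2 per person)
#' * `dominant`: WM + MM vs WW
#' * `recessive`: MM vs WW + WM
#' * `homozygous`: MM vs WW (heterozygotes excluded)
#' * `heterozygous`: WM vs MM (WW excluded) — the contrast used in the
#'   TLR4/IBD analysis this package accompanies
#' * `heterozygous_conventional`: WM vs WW (MM excluded), the textbook
#'   heterozygote contrast, offered as an escape hatch
#'
#' The allele model treats the two chromosomes of a person as independent
#' observations, the standard convention in this literature; the
#' within-person correlation it ignores is a documented caveat, not
#' corrected here.
#'
#' @param case_counts,control_counts Numeric length-3 vectors of genotype
#'   counts `(ww, wm, mm)`.
#' @param model One of `genetic_models()`.
#' @return A one-row tibble with the 2x2 cells `a` (case exposed), `b`
#'   (case unexposed), `c` (control exposed), `d` (control unexposed), the
#'   model name, and `excluded_cases`/`excluded_controls` (subjects dropped
#'   by the homozygous/heterozygous contrasts).
#' @examples
#' build_contrast(c(50, 40, 10), c(60, 35, 5), "allele")
#' build_contrast(c(50, 40, 10), c(60, 35, 5), "dominant")
#' @export
build_contrast <- function(case_counts, control_counts, model = genetic_models()) {
  model <- match.arg(model)
  check_genotype_counts(case_counts, "case_counts")
  check_genotype_counts(control_counts, "control_counts")
  if (sum(case_counts) == 0 || sum(control_counts) == 0) {
    abort("each arm needs at least one subject", class = "snpmeta_contrast_error")
  }
  cells <- function(g) {
    ww <- g[1]; wm <- g[2]; mm <- g[3]
    switch(model,
      allele       = c(2 * mm + wm, 2 * ww + wm, 0),
      dominant     = c(wm + mm, ww, 0),
      recessive    = c(mm, ww + wm, 0),
      homozygous   = c(mm, ww, wm),
      heterozygous = c(wm, mm, ww),
      heterozygous_conventional = c(wm, ww, mm))
  }
  cc <- cells(case_counts)
  ct <- cells(control_counts)
  if (cc[1] + ct[1] == 0 || cc[2] + ct[2] == 0) {
    abort(paste0("degenerate contrast: a '", model,
                 "'-model arm is empty in both cases and controls"),
          class = "snpmeta_degenerate_contrast")
  }
  tibble::tibble(a = cc[1], b = cc[2], c = ct[1], d = ct[2],
                 model = model, excluded_cases = cc[3],
                 excluded_controls = ct[3])
}

#' @rdname build_contrast
#' @export
genetic_models <- function() the_models

check_genotype_counts <- function(g, what) {
  if (length(g) != 3 || anyNA(g) || any(g < 0)) {
    abort(paste0(what, " must be three non-negative counts (ww, wm, mm)"),
          class = "snpmeta_contrast_error")
  }
}

#' Hardy-Weinberg equilibrium test on control genotype counts
#'
#' Pearson chi-square (1 df) of observed control genotype counts against
#' the Hardy-Weinberg expectations at the observed allele frequency.
#' Used as advisory quality control only: deviation flags possible
#' genotyping error or population stratification in a study's control
#' panel, but no study is excluded on its account.
#'
#' @param control_counts Numeric length-3 vector `(ww, wm, mm)`.
#' @return A one-row tibble with `chi2`, `df`, `p`, `maf` (control
#'   minor-allele frequency, oriented into `[0, 0.5]`) and `monomorphic`.
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HWE at allele frequency 0.5
#' @export
hwe_test <- function(control_counts) {
  check_genotype_counts(control_counts, "control_counts")
  n <- sum(control_counts)
  if (n <= 0) abort("no control subjects", class = "snpmeta_contrast_error")
  q <- (2 * control_counts[3] + control_counts[2]) / (2 * n)  # M-allele freq
  maf <- min(q, 1 - q)
  if (maf == 0) {
    return(tibble::tibble(chi2 = 0, df = 1L, p = 1, maf = 0, monomorphic = TRUE))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((control_counts - expected)^2 / expected)
  tibble::tibble(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE),
                 maf = maf, monomorphic = FALSE)
}

#' Hardy-Weinberg QC over a dataset
#'
#' Runs [hwe_test()] on each distinct (control group, SNP) panel of a
#' counted dataset and flags departures at `alpha`.
#'
#' @param data A study dataset tibble with genotype counts.
#' @param alpha Flagging threshold for the HWE p-value.
#' @return A tibble with one row per (control_group_id, snp) and the
#'   [hwe_test()] columns plus `flagged`.
#' @export
hwe_screen <- function(data, alpha = 0.05) {
  stopifnot(has_counts(data))
  data |>
    dplyr::distinct(.data$control_group_id, .data$snp,
                    .data$n_ctrl_ww, .data$n_ctrl_wm, .data$n_ctrl_mm) |>
    dplyr::rowwise() |>
    dplyr::mutate(hwe_test(c(.data$n_ctrl_ww, .data$n_ctrl_wm, .data$n_ctrl_mm))) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = .data$p < alpha) |>
    dplyr::select(!dplyr::all_of(c("n_ctrl_ww", "n_ctrl_wm", "n_ctrl_mm")))
}
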
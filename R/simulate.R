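#' Configuration for the genotype-count simulator
#'
#' Truth parameters for [simulate_studies()]. Control genotypes are drawn
#' under Hardy-Weinberg equilibrium at a study-specific minor-allele
#' frequency `q_i ~ Uniform(maf_range)`; each study carries a true log
#' odds ratio `theta_i ~ Normal(theta, tau2)` (per unit of genetic score);
#' case genotype probabilities are the Hardy-Weinberg probabilities tilted
#' by `exp(theta_i * score(g))` — the logistic disease model conditional
#' on genotype under the rare-disease approximation, so the estimators'
#' odds-ratio parameterization is exactly the generative one. For the
#' allelic score the tilted distribution is again Hardy-Weinberg at a
#' shifted allele frequency, making the allele-model contrast estimator
#' exactly consistent for `exp(theta_i)`.
#'
#' @param k Number of independent studies.
#' @param theta True pooled log odds ratio per unit genetic score.
#' @param tau2 Between-study variance of the study log odds ratios.
#' @param maf_range Bounds (low, high) of the uniform law for the control
#'   minor-allele frequency; both in (0, 0.5). The default is a
#'   low-frequency variant typical of the TLR4 coding SNPs (HapMap CEU
#'   MAF 0.033).
#' @param n_case_range,n_ctrl_range Integer bounds for per-row case and
#'   control sample sizes.
#' @param score_model How genotype maps to exposure score: `"allelic"`
#'   (0/1/2 copies), `"dominant"` (0/1/1) or `"recessive"` (0/0/1).
#' @param shared_controls If `TRUE`, each study contributes a UC and a CD
#'   row sharing one control group (the structure of published IBD cohort
#'   tables); if `FALSE`, one row per study with disease alternating.
#' @param ethnicity,snp Labels recycled across studies (metadata only;
#'   they do not alter the generative law).
#' @param seed Root integer seed. One per-study substream is spawned from
#'   it, so extending `k` never perturbs earlier studies' data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(k = 20, theta = 0, tau2 = 0,
                       maf_range = c(0.02, 0.05),
                       n_case_range = c(100, 500), n_ctrl_range = c(100, 500),
                       score_model = c("allelic", "dominant", "recessive"),
                       shared_controls = FALSE,
                       ethnicity = "Caucasians", snp = "rs4986790",
                       seed = 1) {
  score_model <- match.arg(score_model)
  if (k < 1) abort("k must be at least 1", class = "snpmeta_config_error")
  if (tau2 < 0) abort("tau2 must be non-negative", class = "snpmeta_config_error")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range bounds must satisfy 0 < low <= high < 0.5",
          class = "snpmeta_config_error")
  }
  for (r in list(n_case_range, n_ctrl_range)) {
    if (length(r) != 2 || any(r < 1) || r[1] > r[2]) {
      abort("sample-size ranges must be positive (low, high) pairs",
            class = "snpmeta_config_error")
    }
  }
  structure(list(k = k, theta = theta, tau2 = tau2, maf_range = maf_range,
                 n_case_range = n_case_range, n_ctrl_range = n_ctrl_range,
                 score_model = score_model, shared_controls = shared_controls,
                 ethnicity = ethnicity, snp = snp, seed = seed),
            class = "sim_config")
}

genotype_scores <- function(score_model) {
  switch(score_model,
         allelic = c(0, 1, 2),
         dominant = c(0, 1, 1),
         recessive = c(0, 0, 1))
}

hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

draw_genotypes <- function(n, probs) drop(rmultinom(1, n, probs))

case_probs <- function(q, theta_i, score_model) {
  p <- hwe_probs(q) * exp(theta_i * genotype_scores(score_model))
  p / sum(p)
}

#' Simulate a genotype-count meta-analysis dataset
#'
#' @param config A [sim_config()] object.
#' @return A study dataset tibble with genotype counts (one row per study,
#'   or per study and disease when `shared_controls` is set), deterministic
#'   under the configured seed.
#' @examples
#' sim <- simulate_studies(sim_config(k = 4, theta = log(2), seed = 42))
#' study_effects(sim, "allele")
#' @export
simulate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  study_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max - 1, config$k))
  ethnicity <- rep_len(config$ethnicity, config$k)
  snp <- rep_len(config$snp, config$k)
  rows <- purrr::map(seq_len(config$k), function(i) {
    withr::with_seed(study_seeds[i], {
      q <- runif(1, config$maf_range[1], config$maf_range[2])
      theta_i <- rnorm(1, config$theta, sqrt(config$tau2))
      n_ctrl <- sample(config$n_ctrl_range[1]:config$n_ctrl_range[2], 1)
      ctrl <- draw_genotypes(n_ctrl, hwe_probs(q))
      pc <- case_probs(q, theta_i, config$score_model)
      diseases <- if (config$shared_controls) c("UC", "CD") else
        the_diseases[(i - 1) %% 2 + 1]
      purrr::map_dfr(diseases, function(dz) {
        n_case <- sample(config$n_case_range[1]:config$n_case_range[2], 1)
        cases <- draw_genotypes(n_case, pc)
        tibble::tibble(
          study_id = sprintf("S%02d", i), year = 2010, country = "simulated",
          ethnicity = ethnicity[i], disease = dz, snp = snp[i],
          control_group_id = sprintf("S%02d", i),
          n_case = n_case, n_ctrl = n_ctrl,
          n_case_ww = cases[1], n_case_wm = cases[2], n_case_mm = cases[3],
          n_ctrl_ww = ctrl[1], n_ctrl_wm = ctrl[2], n_ctrl_mm = ctrl[3],
          genotyping_method = "simulated")
      })
    })
  })
  dplyr::bind_rows(rows)
}

#' Simulate a TLR4/IBD-shaped cohort
#'
#' Generates genotype counts on the exact skeleton of the packaged cohort
#' table ([tlr4_ibd_studies()]): the same 13 studies, disease rows, SNP
#' coverage (37 study-disease-SNP records), ethnicities and case/control
#' sample sizes, with one control group per study and SNP shared between
#' its UC and CD rows. Truth parameters mirror the published pooled
#' estimate: common log odds ratio `log(1.27)` with between-study variance
#' `tau2 = 0.01` (one `theta_i` per study, shared by its rows), allelic
#' score, and control minor-allele frequencies of 0.05 for Caucasian and
#' 0.03 for Asian panels.
#'
#' @param seed Root integer seed (per-study substreams as in
#'   [simulate_studies()]).
#' @param theta,tau2 Truth parameters, overridable for calibration runs.
#' @return A study dataset tibble with 37 counted records whose
#'   [count_summary()] reproduces the published subject totals (4409
#'   cases: 1997 UC + 2412 CD; 5693 per-row controls).
#' @export
simulate_tlr4_cohort <- function(seed, theta = log(1.27), tau2 = 0.01) {
  template <- tlr4_ibd_studies() |>
    dplyr::mutate(snp = strsplit(.data$snp, ";", fixed = TRUE)) |>
    tidyr::unnest("snp")
  studies <- unique(template$study_id)
  study_seeds <- withr::with_seed(seed,
                                  sample.int(.Machine$integer.max - 1,
                                             length(studies)))
  maf_by_ethnicity <- c(Caucasians = 0.05, Asians = 0.03)
  rows <- purrr::map(seq_along(studies), function(i) {
    block <- template[template$study_id == studies[i], , drop = FALSE]
    withr::with_seed(study_seeds[i], {
      theta_i <- rnorm(1, theta, sqrt(tau2))
      q <- maf_by_ethnicity[[block$ethnicity[1]]]
      purrr::map_dfr(unique(block$snp), function(s) {
        sub <- block[block$snp == s, , drop = FALSE]
        ctrl <- draw_genotypes(sub$n_ctrl[1], hwe_probs(q))
        pc <- case_probs(q, theta_i, "allelic")
        purrr::map_dfr(seq_len(nrow(sub)), function(j) {
          cases <- draw_genotypes(sub$n_case[j], pc)
          dplyr::mutate(sub[j, ],
                        n_case_ww = cases[1], n_case_wm = cases[2],
                        n_case_mm = cases[3],
                        n_ctrl_ww = ctrl[1], n_ctrl_wm = ctrl[2],
                        n_ctrl_mm = ctrl[3])
        })
      })
    })
  })
  dplyr::bind_rows(rows)
}
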
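# Small constructors used across the suite.

eff_tbl <- function(log_or, se, ...) {
  tibble::tibble(log_or = log_or, se = se, ...)
}

# Effects drawn under the null (true log OR 0, no between-study variance).
null_effects <- function(k, se_range = c(0.1, 0.4)) {
  se <- runif(k, se_range[1], se_range[2])
  eff_tbl(log_or = rnorm(k, 0, se), se = se)
}

# Minimal counted dataset rows for pipeline tests.
counted_row <- function(study_id, disease, snp, case, ctrl,
                        ethnicity = "Caucasians") {
  tibble::tibble(
    study_id = study_id, year = 2010, country = "x", ethnicity = ethnicity,
    disease = disease, snp = snp, control_group_id = study_id,
    n_case = sum(case), n_ctrl = sum(ctrl),
    n_case_ww = case[1], n_case_wm = case[2], n_case_mm = case[3],
    n_ctrl_ww = ctrl[1], n_ctrl_wm = ctrl[2], n_ctrl_mm = ctrl[3],
    genotyping_method = "test")
}
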
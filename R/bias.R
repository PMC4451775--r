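#' Egger's linear regression test for funnel-plot asymmetry
#'
#' The classic 1997 formulation: ordinary least squares of the
#' standardized effect `log_or/se` on precision `1/se`; the intercept
#' estimates the asymmetry (small-study effect) and is tested with a t
#' statistic on k - 2 degrees of freedom. Weighted variants are not used.
#'
#' @inheritParams pool_fixed
#' @return A one-row tibble: `intercept`, `intercept_se`, `t`, `df`, `p`
#'   (two-sided), `slope` (the precision coefficient, an estimate of the
#'   underlying pooled effect), `k`.
#' @examples
#' eff <- tibble::tibble(log_or = c(0.2, 0.5, 0.9), se = c(0.1, 0.25, 0.4))
#' egger_test(eff)
#' @export
egger_test <- function(effects) {
  check_effects(effects)
  k <- nrow(effects)
  if (k < 3) {
    abort("Egger's test needs at least 3 studies", class = "snpmeta_bias_error")
  }
  if (length(unique(effects$se)) == 1) {
    abort("Egger's test is degenerate when all standard errors are identical",
          class = "snpmeta_bias_error")
  }
  z <- effects$log_or / effects$se
  precision <- 1 / effects$se
  fit <- lm(z ~ precision)
  s <- summary(fit)$coefficients
  tibble::tibble(intercept = s[1, 1], intercept_se = s[1, 2],
                 t = s[1, 3], df = k - 2L,
                 p = 2 * pt(-abs(s[1, 3]), k - 2),
                 slope = s[2, 1], k = k)
}

#' Rosenthal's classic fail-safe N
#'
#' The number of unpublished null studies that would be needed to raise
#' the combined (Stouffer) p-value above the significance criterion:
#' `N_fs = floor((sum z_i)^2 / z_c^2 - k)`, clipped at zero, with
#' `z_i = log_or_i / se_i` and criterion `z_c = 1.644854` (one-tailed 0.05,
#' Rosenthal's classic choice) or `1.959964` (two-tailed).
#'
#' @inheritParams pool_fixed
#' @param alpha_mode `"one_tailed_05"` (default) or `"two_tailed_05"`.
#' @return A one-row tibble: `n_fs`, `z_combined` (Stouffer's combined z),
#'   `z_criterion`, `k`.
#' @examples
#' eff <- tibble::tibble(log_or = c(0.4, 0.4, 0.4), se = c(0.2, 0.2, 0.2))
#' fail_safe_n(eff)  # each z_i = 2 -> N_fs = 10
#' @export
fail_safe_n <- function(effects, alpha_mode = c("one_tailed_05", "two_tailed_05")) {
  alpha_mode <- match.arg(alpha_mode)
  check_effects(effects)
  z <- effects$log_or / effects$se
  z_c <- if (alpha_mode == "one_tailed_05") 1.644854 else Z_95
  k <- nrow(effects)
  n_fs <- max(0, floor(sum(z)^2 / z_c^2 - k))
  tibble::tibble(n_fs = as.integer(n_fs), z_combined = sum(z) / sqrt(k),
                 z_criterion = z_c, k = k)
}

#' Funnel-plot data
#'
#' One point per study (log OR against its standard error) plus the pooled
#' reference line and the pseudo 95% limits `pooled +/- 1.959964 * se`
#' evaluated on a standard-error grid from 0 to the largest observed se.
#' Under no publication bias the points scatter symmetrically inside the
#' funnel; a point lies within the limits iff
#' `|log_or_i - pooled| <= 1.959964 * se_i`.
#'
#' @inheritParams pool_fixed
#' @param pooled A `meta_pooled` object computed on the same effects.
#' @param grid_n Number of grid points for the pseudo-limit lines.
#' @return An object of class `funnel_data`: list with `points` (per-study
#'   tibble including `within_limits`) and `limits` (the grid tibble).
#' @export
funnel_data <- function(effects, pooled, grid_n = 50) {
  check_effects(effects)
  stopifnot(inherits(pooled, "meta_pooled"))
  if (pooled$k != nrow(effects)) {
    abort("pooled result was not computed on these effects",
          class = "snpmeta_bias_error")
  }
  id_cols <- intersect(c("study_id", "disease", "snp"), names(effects))
  points <- dplyr::bind_cols(
    effects[, c(id_cols, "log_or", "se")],
    tibble::tibble(
      within_limits = abs(effects$log_or - pooled$log_or) <= Z_95 * effects$se))
  se_grid <- seq(0, max(effects$se), length.out = grid_n)
  limits <- tibble::tibble(
    se = se_grid,
    lower = pooled$log_or - Z_95 * se_grid,
    upper = pooled$log_or + Z_95 * se_grid)
  structure(list(points = points, limits = limits, pooled_log_or = pooled$log_or),
            class = "funnel_data")
}

#' @export
print.funnel_data <- function(x, ...) {
  cat(sprintf("funnel data: %d studies, pooled log OR %.4f, %d within pseudo-limits\n",
              nrow(x$points), x$pooled_log_or, sum(x$points$within_limits)))
  invisible(x)
}
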
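#' Heterogeneity of a set of study effects
#'
#' Cochran's Q against the inverse-variance fixed-effect estimate, its
#' chi-square p-value on k-1 degrees of freedom, Higgins' I2 (the share of
#' total variability attributed to between-study heterogeneity, 0% none to
#' 100% maximal), and the DerSimonian-Laird moment estimate of the
#' between-study variance tau2.
#'
#' @param effects A tibble of per-study effects with columns `log_or` and
#'   `se` (as returned by [study_effects()]).
#' @return A one-row tibble: `q`, `df`, `p_q`, `i2` (percent), `tau2`.
#' @examples
#' eff <- tibble::tibble(log_or = c(0.6931, 0), se = c(0.2, 0.2))
#' heterogeneity(eff)  # Q ~ 6.005, I2 ~ 83.35%, tau2 ~ 0.2002
#' @export
heterogeneity <- function(effects) {
  check_effects(effects)
  k <- nrow(effects)
  if (k < 2) {
    abort("heterogeneity is undefined for fewer than 2 studies (df = 0)",
          class = "snpmeta_heterogeneity_error")
  }
  w <- 1 / effects$se^2
  theta_f <- sum(w * effects$log_or) / sum(w)
  q <- sum(w * (effects$log_or - theta_f)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  tau2 <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  tibble::tibble(q = q, df = df,
                 p_q = pchisq(q, df = df, lower.tail = FALSE),
                 i2 = i2, tau2 = tau2)
}

#' Pool study effects
#'
#' `pool_fixed()` is the inverse-variance (Woolf) fixed-effect model:
#' weights 1/se^2, pooled log OR the weighted mean, Wald Z test for the
#' overall effect. `pool_random()` is the DerSimonian-Laird random-effects
#' model: the same machinery with weights 1/(se^2 + tau2), tau2 estimated
#' by the moment estimator of [heterogeneity()] (tau2 = 0 when k = 1, where
#' both models reduce to the single study's estimate). `meta_pool()`
#' computes heterogeneity, picks the model by [select_model()] (or takes it
#' as given), and pools.
#'
#' @inheritParams heterogeneity
#' @param method `"auto"` selects fixed vs random from the heterogeneity
#'   statistics via `rule`; `"fixed"`/`"random"` force the model.
#' @param rule Model-selection rule, see [select_model()].
#' @return An object of class `meta_pooled` with the pooled OR and 95% CI,
#'   Z and p, the heterogeneity tibble (`NULL` when k = 1), relative
#'   weights, and the input effects. [tidy()] gives the per-study table,
#'   [glance()] the one-row summary.
#' @examples
#' eff <- tibble::tibble(log_or = c(0.6931, 0), se = c(0.2, 0.2))
#' glance(pool_fixed(eff))
#' glance(pool_random(eff))
#' @export
pool_fixed <- function(effects) {
  check_effects(effects)
  new_pooled(effects, tau2 = 0, model_effects = "fixed",
             het = safe_heterogeneity(effects))
}

#' @rdname pool_fixed
#' @export
pool_random <- function(effects) {
  check_effects(effects)
  het <- safe_heterogeneity(effects)
  tau2 <- if (is.null(het)) 0 else het$tau2
  new_pooled(effects, tau2 = tau2, model_effects = "random", het = het)
}

#' @rdname pool_fixed
#' @export
meta_pool <- function(effects, method = c("auto", "fixed", "random"),
                      rule = c("conventional", "paper")) {
  method <- match.arg(method)
  rule <- match.arg(rule)
  check_effects(effects)
  if (method == "auto") {
    het <- safe_heterogeneity(effects)
    method <- if (is.null(het)) "fixed" else select_model(het, rule)
  }
  switch(method, fixed = pool_fixed(effects), random = pool_random(effects))
}

#' Choose between fixed- and random-effects pooling
#'
#' The conventional rule pools under random effects when heterogeneity is
#' significant (Q-test p < 0.05 or I2 > 50%) and under fixed effects
#' otherwise. The source analysis this package accompanies states the rule
#' the other way around; its results nevertheless behave conventionally
#' (fixed effects adopted where heterogeneity is absent), so
#' `"conventional"` is the default and `"paper"` applies the literal
#' reversed wording for fidelity.
#'
#' @param het A one-row heterogeneity tibble from [heterogeneity()].
#' @param rule `"conventional"` or `"paper"` (the literal reversed rule).
#' @return `"fixed"` or `"random"`.
#' @export
select_model <- function(het, rule = c("conventional", "paper")) {
  rule <- match.arg(rule)
  stopifnot(is.data.frame(het), all(c("p_q", "i2") %in% names(het)))
  significant <- het$p_q < 0.05 || het$i2 > 50
  if (rule == "conventional") {
    if (significant) "random" else "fixed"
  } else {
    if (significant) "fixed" else "random"
  }
}

check_effects <- function(effects) {
  if (!is.data.frame(effects) || nrow(effects) == 0) {
    abort("no effects to pool", class = "snpmeta_no_effects")
  }
  if (!all(c("log_or", "se") %in% names(effects))) {
    abort("effects need columns 'log_or' and 'se'", class = "snpmeta_no_effects")
  }
  if (anyNA(effects$log_or) || anyNA(effects$se) || any(effects$se <= 0)) {
    abort("effects require finite log_or and positive se",
          class = "snpmeta_no_effects")
  }
  invisible(effects)
}

safe_heterogeneity <- function(effects) {
  if (nrow(effects) < 2) NULL else heterogeneity(effects)
}

new_pooled <- function(effects, tau2, model_effects, het) {
  w <- 1 / (effects$se^2 + tau2)
  log_or <- sum(w * effects$log_or) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- log_or / se
  structure(list(
    model_effects = model_effects,
    k = nrow(effects),
    log_or = log_or, se = se,
    or = exp(log_or),
    ci_low = exp(log_or - Z_95 * se),
    ci_high = exp(log_or + Z_95 * se),
    z = z, p = 2 * pnorm(-abs(z)),
    het = het, tau2_used = tau2,
    weights = w / sum(w),
    effects = effects
  ), class = "meta_pooled")
}

#' @export
print.meta_pooled <- function(x, ...) {
  cat(sprintf("%s-effects pooled OR over k = %d studies\n",
              x$model_effects, x$k))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), Z = %.3f, p = %s\n",
              x$or, x$ci_low, x$ci_high, x$z, format_p(x$p)))
  if (!is.null(x$het)) {
    cat(sprintf("  heterogeneity: Q = %.3f (df %d, p = %s), I2 = %.3f%%, tau2 = %.4f\n",
                x$het$q, x$het$df, format_p(x$het$p_q), x$het$i2, x$het$tau2))
  }
  invisible(x)
}

format_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' @export
tidy.meta_pooled <- function(x, ...) {
  id_cols <- intersect(c("study_id", "disease", "snp", "ethnicity", "model"),
                       names(x$effects))
  dplyr::bind_cols(
    x$effects[, c(id_cols,
                  intersect(c("log_or", "se", "or", "ci_low", "ci_high",
                              "corrected"), names(x$effects)))],
    tibble::tibble(weight = x$weights, weight_pct = 100 * x$weights))
}

#' @export
glance.meta_pooled <- function(x, ...) {
  het <- x$het %||%
    tibble::tibble(q = NA_real_, df = NA_integer_, p_q = NA_real_,
                   i2 = NA_real_, tau2 = NA_real_)
  tibble::tibble(model_effects = x$model_effects, k = x$k,
                 or = x$or, ci_low = x$ci_low, ci_high = x$ci_high,
                 log_or = x$log_or, se = x$se, z = x$z, p = x$p,
                 q = het$q, df_q = het$df, p_q = het$p_q, i2 = het$i2,
                 tau2 = het$tau2)
}
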
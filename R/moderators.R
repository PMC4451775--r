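#' Subgroup pooling
#'
#' Pools effects independently within each level of a grouping variable
#' (ethnicity, disease subtype, SNP), applying the same model-selection
#' rule in every stratum, and includes the overall pooled result under
#' level `"overall"`.
#'
#' @inheritParams pool_fixed
#' @param by Name of a column of `effects` to stratify on.
#' @inheritParams meta_pool
#' @return A tibble with one row per level (plus `"overall"`): `variable`,
#'   `level`, and the [glance()] columns of the pooled result.
#' @examples
#' sim <- simulate_studies(sim_config(k = 8, theta = log(1.3), seed = 3))
#' eff <- study_effects(sim, "allele")
#' subgroup_pool(eff, by = "disease")
#' @export
subgroup_pool <- function(effects, by, method = c("auto", "fixed", "random"),
                          rule = c("conventional", "paper")) {
  check_effects(effects)
  if (!by %in% names(effects)) {
    abort(paste0("no column '", by, "' in effects"), class = "snpmeta_subgroup_error")
  }
  levels <- c("overall", sort(unique(as.character(effects[[by]]))))
  purrr::map_dfr(levels, function(lv) {
    sub <- if (lv == "overall") effects else
      effects[as.character(effects[[by]]) == lv, , drop = FALSE]
    dplyr::bind_cols(tibble::tibble(variable = by, level = lv),
                     glance(meta_pool(sub, method, rule)))
  })
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools after omitting each effect row in turn, to assess whether any
#' single study drives the overall conclusion. When the full-data CI
#' excludes OR = 1, `conclusion_stable` records whether the CI without the
#' study still does; it is `NA` when the full-data CI already includes 1.
#'
#' @inheritParams subgroup_pool
#' @return A tibble with one row per omitted effect: its identifying
#'   columns (prefixed `omitted_`), the [glance()] columns of the re-pooled
#'   result, and `conclusion_stable`.
#' @export
leave_one_out <- function(effects, method = c("auto", "fixed", "random"),
                          rule = c("conventional", "paper")) {
  check_effects(effects)
  k <- nrow(effects)
  if (k < 2) {
    abort("sensitivity analysis needs at least 2 studies",
          class = "snpmeta_sensitivity_error")
  }
  full <- meta_pool(effects, method, rule)
  full_excludes_1 <- full$ci_low > 1 || full$ci_high < 1
  id_cols <- intersect(c("study_id", "disease", "snp"), names(effects))
  purrr::map_dfr(seq_len(k), function(i) {
    fit <- meta_pool(effects[-i, , drop = FALSE], method, rule)
    ids <- effects[i, id_cols, drop = FALSE]
    names(ids) <- paste0("omitted_", names(ids))
    dplyr::bind_cols(
      ids, glance(fit),
      tibble::tibble(conclusion_stable = if (full_excludes_1)
        fit$ci_low > 1 || fit$ci_high < 1 else NA))
  })
}

# Standard 0/1 encodings for the cohort moderators; sample size is the
# total number of subjects contributing to the row.
moderator_matrix <- function(effects, moderators) {
  if (is.data.frame(moderators) || is.matrix(moderators)) {
    m <- as.data.frame(moderators)
    stopifnot(nrow(m) == nrow(effects))
    return(m)
  }
  encoders <- list(
    sample_size = function(e) e$n_case + e$n_ctrl,
    ethnicity = function(e) as.numeric(e$ethnicity == "Caucasians"),
    disease = function(e) as.numeric(e$disease == "CD"),
    snp = function(e) as.numeric(e$snp == "rs4986791"),
    year = function(e) e$year
  )
  unknown <- setdiff(moderators, names(encoders))
  if (length(unknown) > 0) {
    abort(paste0("unknown moderator(s): ", paste(unknown, collapse = ", ")),
          class = "snpmeta_metareg_error")
  }
  out <- purrr::map(moderators, function(nm) encoders[[nm]](effects))
  names(out) <- moderators
  as.data.frame(out)
}

# Weighted least squares of effects on a design with intercept, with the
# method-of-moments residual tau2 (reduces to DerSimonian-Laird for the
# intercept-only design). Returns per-coefficient stats with t reference
# distribution on k - p df.
fit_wls <- function(X, theta, v) {
  k <- length(theta)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    abort("singular (collinear) moderator design", class = "snpmeta_singular_design")
  }
  if (k <= p + 1) {
    abort("too few studies for the moderator design (need k > p + 1)",
          class = "snpmeta_metareg_error")
  }
  w1 <- 1 / v
  xtw <- t(X * w1)
  A <- xtw %*% X
  beta1 <- solve(A, xtw %*% theta)
  resid1 <- theta - drop(X %*% beta1)
  qe <- sum(w1 * resid1^2)
  trace_term <- sum(diag(solve(A, t(X * w1^2) %*% X)))
  tau2 <- max(0, (qe - (k - p)) / (sum(w1) - trace_term))

  w <- 1 / (v + tau2)
  xtw <- t(X * w)
  A <- xtw %*% X
  beta <- unname(drop(solve(A, xtw %*% theta)))
  covb <- solve(A)
  se <- unname(sqrt(diag(covb)))
  tval <- beta / se
  df <- k - p
  list(beta = beta, se = se, t = tval, df = df,
       p = 2 * pt(-abs(tval), df), tau2 = tau2, qe = qe,
       crit = stats::qt(0.975, df))
}

#' Weighted meta-regression of study effects on moderators
#'
#' Regresses per-study log odds ratios on moderators by weighted least
#' squares with weights 1/(se^2 + tau2), where the residual between-study
#' variance tau2 is estimated by the method of moments from the residual Q
#' (the DerSimonian-Laird estimator when only the intercept is fitted).
#' Coefficients are tested with t statistics on k - p df (p = number of
#' fitted coefficients including the intercept). Moderators are named
#' columns derived from the effects table with the standard encodings —
#' `sample_size` (cases + controls), `ethnicity` (Caucasians = 1),
#' `disease` (CD = 1), `snp` (rs4986791 = 1) — or a caller-supplied numeric
#' data frame. Constant moderators are dropped with a warning; no
#' multiplicity adjustment is applied by default (`adjust = "bonferroni"`
#' is available).
#'
#' An optional permutation test reassigns the moderator rows to effects
#' `n_perm` times and reports the Monte Carlo p-value
#' `(1 + #(|t*| >= |t|)) / (n_perm + 1)` per moderator, a
#' distribution-free confirmation of the parametric t tests.
#'
#' @inheritParams pool_fixed
#' @param moderators Character vector of moderator names, or a numeric
#'   data frame with one row per effect.
#' @param mode `"multivariate"` fits all moderators jointly;
#'   `"univariate"` fits each separately.
#' @param n_perm Number of permutations for the Monte Carlo p-values
#'   (`NULL` to skip; minimum 99).
#' @param seed Integer seed for the permutations (required with `n_perm`).
#' @param adjust `"none"` or `"bonferroni"` for the reported p-values.
#' @return An object of class `meta_regression`; [tidy()] returns the
#'   coefficient table (term, coefficient, se, t, df, p, ci_low, ci_high,
#'   and `permutation_p` when computed), [glance()] the fit summary.
#' @export
meta_regress <- function(effects,
                         moderators = c("sample_size", "ethnicity", "disease", "snp"),
                         mode = c("multivariate", "univariate"),
                         n_perm = NULL, seed = NULL,
                         adjust = c("none", "bonferroni")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  check_effects(effects)
  M <- moderator_matrix(effects, moderators)
  constant <- vapply(M, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    warn(paste0("dropping constant moderator(s): ",
                paste(names(M)[constant], collapse = ", ")))
    M <- M[, !constant, drop = FALSE]
  }
  if (ncol(M) == 0) {
    abort("no usable (non-constant) moderators", class = "snpmeta_metareg_error")
  }
  theta <- effects$log_or
  v <- effects$se^2
  k <- length(theta)

  fit_terms <- function(M) {
    X <- cbind(intercept = 1, as.matrix(M))
    fit <- fit_wls(X, theta, v)
    terms <- tibble::tibble(
      term = colnames(X), coefficient = fit$beta, se = fit$se,
      t = fit$t, df = fit$df, p = fit$p,
      ci_low = fit$beta - fit$crit * fit$se,
      ci_high = fit$beta + fit$crit * fit$se)
    list(terms = terms, tau2 = fit$tau2, qe = fit$qe)
  }

  if (mode == "multivariate") {
    fit <- fit_terms(M)
    terms <- fit$terms
    tau2 <- fit$tau2
    qe <- fit$qe
  } else {
    fits <- purrr::map(names(M), function(nm) fit_terms(M[, nm, drop = FALSE]))
    terms <- purrr::map_dfr(fits, function(f) f$terms[-1, , drop = FALSE])
    tau2 <- purrr::map_dbl(fits, "tau2")
    qe <- purrr::map_dbl(fits, "qe")
  }
  if (adjust == "bonferroni") {
    idx <- terms$term != "intercept"
    terms$p[idx] <- pmin(1, terms$p[idx] * sum(idx))
  }
  if (!is.null(n_perm)) {
    terms$permutation_p <- permute_pvalues(effects, M, mode = mode,
                                           n_perm = n_perm, seed = seed)$p
  }
  structure(list(terms = terms, mode = mode, k = k, tau2 = tau2,
                 qe = qe, moderators = names(M), adjust = adjust),
            class = "meta_regression")
}

#' Permutation p-values for meta-regression moderators
#'
#' @inheritParams meta_regress
#' @return A tibble with columns `term` and `p`.
#' @export
permute_pvalues <- function(effects, moderators, mode = c("multivariate", "univariate"),
                            n_perm = 1000, seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 99) {
    abort("n_perm must be at least 99", class = "snpmeta_metareg_error")
  }
  if (is.null(seed)) {
    abort("a seed is required for reproducible permutation p-values",
          class = "snpmeta_metareg_error")
  }
  check_effects(effects)
  M <- moderator_matrix(effects, moderators)
  theta <- effects$log_or
  v <- effects$se^2
  k <- length(theta)

  tstats <- function(M) {
    if (mode == "multivariate") {
      X <- cbind(1, as.matrix(M))
      fit_wls(X, theta, v)$t[-1]
    } else {
      vapply(names(M), function(nm) {
        fit_wls(cbind(1, as.matrix(M[, nm, drop = FALSE])), theta, v)$t[2]
      }, numeric(1))
    }
  }
  t_obs <- abs(tstats(M))
  exceed <- rep(0L, length(t_obs))
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      Mb <- M[sample.int(k), , drop = FALSE]
      exceed <- exceed + as.integer(abs(tstats(Mb)) >= t_obs)
    }
  })
  tibble::tibble(term = names(M), p = (1 + exceed) / (n_perm + 1))
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("%s meta-regression, k = %d\n", x$mode, x$k))
  print(x$terms, ...)
  invisible(x)
}

#' @export
tidy.meta_regression <- function(x, ...) x$terms

#' @export
glance.meta_regression <- function(x, ...) {
  tibble::tibble(mode = x$mode, k = x$k,
                 n_moderators = length(x$moderators),
                 tau2 = if (x$mode == "multivariate") x$tau2 else NA_real_,
                 qe = if (x$mode == "multivariate") x$qe else NA_real_)
}
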
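# Logistic modelling of documentation propensity with spline age.

#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline design columns for a continuous
#' covariate: the linear term plus k - 2 nonlinear terms built from
#' truncated cubes, constrained so the function is linear beyond the
#' boundary knots. Nonlinear terms are scaled by 1 / (t_k - t_1)^2, the
#' convention of the usual regression-spline software, which keeps the
#' columns on roughly the scale of x. Knots default to the 0.10 / 0.50 /
#' 0.90 quantiles of `x` for k = 3 (equally spaced quantiles between 0.10
#' and 0.90 for larger k).
#'
#' @param x numeric vector
#' @param knots strictly increasing knot locations; overrides `k`
#' @param k number of knots when `knots` is not given (>= 3)
#' @return matrix with k - 1 columns, attribute `"knots"`
#' @examples
#' rcs_basis(seq(20, 90, by = 5))
#' @export
rcs_basis <- function(x, knots = NULL, k = 3) {
  if (is.null(knots)) {
    if (k < 3) abort("a restricted cubic spline needs k >= 3 knots.")
    probs <- seq(0.10, 0.90, length.out = k)
    knots <- unname(quantile(x, probs, na.rm = TRUE, type = 7))
  }
  knots <- sort(knots)
  if (any(diff(knots) <= 0)) {
    abort("knots must be strictly increasing (too few distinct x values?).")
  }
  k <- length(knots)
  if (length(unique(x[!is.na(x)])) < k) {
    abort("degenerate basis: fewer distinct x values than knots.")
  }
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  cols <- vapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (cube(x - tj) -
       cube(x - tk1) * (tk - tj) / (tk - tk1) +
       cube(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }, numeric(length(x)))
  out <- cbind(x, matrix(cols, nrow = length(x)))
  colnames(out) <- c("rcs1", paste0("rcs", 1 + seq_len(k - 2)))
  attr(out, "knots") <- knots
  out
}

#' Fit the documentation-propensity logistic model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, relative convergence 1e-8, at most 100 iterations) of the
#' per-patient documentation outcome on sex, age as a restricted cubic
#' spline, cancer group, hospital, and the number of reports of each
#' type as linear terms; optionally metastatic status at diagnosis.
#' Standard errors come from the observed information; confidence
#' intervals are Wald, reported as odds ratios.
#'
#' @param cohort cohort tibble (see [build_cohort()] or
#'   [simulate_cohort_table()])
#' @param include_metastatic add metastatic_at_dx as a covariate
#' @param cancer_ref,hospital_ref,sex_ref reference levels; hospital
#'   defaults to the largest hospital in the data, sex to `"F"`, cancer
#'   group to `"Breast"` (falling back to the largest observed level when
#'   a stated reference is absent)
#' @param knots,k spline knots for age, as in [rcs_basis()]
#' @return a `ps_fit` object; see [tidy.ps_fit()] and [glance.ps_fit()]
#' @examples
#' cohort <- simulate_cohort_table(generator_config(n_patients = 500, seed = 1))
#' fit <- fit_ps_model(cohort)
#' tidy(fit)
#' @export
fit_ps_model <- function(cohort, include_metastatic = FALSE,
                         cancer_ref = "Breast", hospital_ref = NULL,
                         sex_ref = "F", knots = NULL, k = 3) {
  if (length(unique(cohort$has_ps)) < 2) {
    abort("the outcome must have both classes.")
  }
  pick_ref <- function(values, wanted) {
    tab <- sort(table(values), decreasing = TRUE)
    if (!is.null(wanted) && wanted %in% names(tab)) wanted else names(tab)[1]
  }
  cancer_ref <- pick_ref(cohort$cancer_group, cancer_ref)
  hospital_ref <- pick_ref(cohort$hospital_id, hospital_ref)
  sex_ref <- pick_ref(cohort$sex, sex_ref)

  dat <- cohort
  dat$sex <- stats::relevel(factor(dat$sex), ref = sex_ref)
  dat$cancer_group <- stats::relevel(factor(dat$cancer_group),
                                     ref = cancer_ref)
  dat$hospital_id <- stats::relevel(factor(dat$hospital_id),
                                    ref = hospital_ref)
  basis <- rcs_basis(dat$age_at_dx, knots = knots, k = k)
  spline_cols <- paste0("age_", colnames(basis))
  dat[spline_cols] <- as.data.frame(unclass(basis))

  terms <- c(
    if (nlevels(dat$sex) > 1) "sex",
    spline_cols,
    if (nlevels(dat$cancer_group) > 1) "cancer_group",
    if (nlevels(dat$hospital_id) > 1) "hospital_id",
    "n_mdt", "n_consult", "n_hosp",
    if (include_metastatic) "metastatic_at_dx"
  )
  form <- as.formula(paste("has_ps ~", paste(terms, collapse = " + ")))
  out <- fit_logistic(form, dat)
  out$knots <- attr(basis, "knots")
  out$include_metastatic <- include_metastatic
  out$references <- c(sex = sex_ref, cancer_group = cancer_ref,
                      hospital_id = hospital_ref)
  out
}

#' Maximum-likelihood logistic fit with Wald odds-ratio table
#'
#' The fitting core behind [fit_ps_model()], usable with any formula:
#' binomial GLM by iteratively reweighted least squares (relative
#' convergence 1e-8, at most 100 iterations), standard errors from the
#' observed information, Wald 95% intervals on the odds-ratio scale.
#' Rank deficiency is an error naming the collinear terms; coefficients
#' beyond 15 on the log-odds scale are flagged as probable separation
#' with a warning.
#'
#' @param formula model formula with a logical/0-1 outcome
#' @param data data frame
#' @return a `ps_fit` object
#' @examples
#' d <- data.frame(y = c(1, 1, 0, 0), x = c(1, 0, 1, 0))
#' fit_logistic(y ~ x, d)
#' @export
fit_logistic <- function(formula, data) {
  fit <- glm(formula, family = binomial(), data = data,
             control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  est <- coef(fit)
  if (anyNA(est)) {
    abort(sprintf("rank-deficient design; collinear terms: %s.",
                  paste(names(est)[is.na(est)], collapse = ", ")))
  }
  se <- sqrt(diag(vcov(fit)))
  tab <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std_error = unname(se),
    odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est) - 1.96 * unname(se)),
    ci_high = exp(unname(est) + 1.96 * unname(se)),
    separation = abs(unname(est)) > 15
  )
  if (any(tab$separation)) {
    warn(sprintf("possible separation (|log-odds| > 15) for: %s.",
                 paste(tab$term[tab$separation], collapse = ", ")))
  }
  structure(
    list(
      fit = fit,
      coefficients = tab,
      knots = NULL,
      include_metastatic = NA,
      references = NULL,
      n_obs = nrow(stats::model.frame(fit)),
      converged = fit$converged,
      log_likelihood = as.numeric(logLik(fit))
    ),
    class = "ps_fit"
  )
}

#' @rdname fit_ps_model
#' @param x,object a `ps_fit`
#' @param ... unused
#' @export
tidy.ps_fit <- function(x, ...) x$coefficients

#' @rdname fit_ps_model
#' @export
glance.ps_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs,
    log_likelihood = x$log_likelihood,
    converged = x$converged,
    df = length(coef(x$fit)),
    include_metastatic = x$include_metastatic
  )
}

#' @rdname fit_ps_model
#' @export
print.ps_fit <- function(x, ...) {
  if (is.na(x$include_metastatic)) {
    cat("Logistic fit\n")
  } else {
    cat(sprintf(
      "Documentation-propensity logistic model (%s metastatic status)\n",
      if (x$include_metastatic) "with" else "without"
    ))
  }
  cat(sprintf("  n = %d, logLik = %.1f, converged: %s\n",
              x$n_obs, x$log_likelihood, x$converged))
  if (!is.null(x$references)) {
    cat(sprintf("  references: sex %s, cancer %s, hospital %s\n",
                x$references["sex"], x$references["cancer_group"],
                x$references["hospital_id"]))
  }
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname fit_ps_model
#' @export
autoplot.ps_fit <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Fit the model with and without metastatic status
#'
#' Fits the documentation model twice — excluding then including
#' metastatic status at diagnosis — and tabulates, term by term, how much
#' each odds ratio moves between the two fits. A ratio near 1 for the
#' non-metastatic terms means the adjustment leaves other associations
#' untouched.
#'
#' @param cohort cohort tibble with `metastatic_at_dx`
#' @param ... passed to [fit_ps_model()]
#' @return list of class `ps_model_comparison`: `without`, `with`
#'   (`ps_fit` objects) and `stability`, a tibble of paired odds ratios
#' @export
compare_ps_models <- function(cohort, ...) {
  f0 <- fit_ps_model(cohort, include_metastatic = FALSE, ...)
  f1 <- fit_ps_model(cohort, include_metastatic = TRUE, ...)
  stability <- dplyr::inner_join(
    dplyr::select(f0$coefficients, "term", or_without = "odds_ratio"),
    dplyr::select(f1$coefficients, "term", or_with = "odds_ratio"),
    by = "term"
  ) |>
    dplyr::mutate(or_ratio = .data$or_with / .data$or_without)
  structure(list(without = f0, with = f1, stability = stability),
            class = "ps_model_comparison")
}

#' @rdname compare_ps_models
#' @param x a `ps_model_comparison`
#' @param ... unused
#' @export
print.ps_model_comparison <- function(x, ...) {
  cat("Model comparison: documentation propensity with vs without metastatic status\n")
  met <- dplyr::filter(x$with$coefficients,
                       .data$term == "metastatic_at_dxTRUE")
  if (nrow(met) == 1) {
    cat(sprintf("  metastatic OR %.2f [%.2f; %.2f]\n",
                met$odds_ratio, met$ci_low, met$ci_high))
  }
  cat(sprintf("  max |OR shift| among shared terms: %.1f%%\n",
              100 * max(abs(x$stability$or_ratio - 1))))
  invisible(x)
}
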
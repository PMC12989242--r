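# Documentation-prevalence descriptives.

prevalence_tab <- function(data, outcome, by) {
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_with_ps = sum({{ outcome }}),
      n_total = dplyr::n(),
      proportion = sum({{ outcome }}) / dplyr::n(),
      .groups = "drop"
    )
  structure(out, class = c("ps_crosstab", class(out)),
            stratifiers = by)
}

#' Patient-level documentation prevalence
#'
#' Proportion of cohort patients with a documented performance status,
#' overall (`by = NULL`) or stratified by any combination of cohort
#' columns (cancer_group, hospital_id, sex, ...). Strata are the observed
#' combinations, so empty strata are omitted by construction.
#'
#' @param cohort cohort tibble with a logical `has_ps` column
#' @param by character vector of stratifier column names (default none)
#' @return a `ps_crosstab` tibble: stratifiers, n_with_ps, n_total,
#'   proportion
#' @examples
#' cohort <- tibble::tibble(cancer_group = c("Lung", "Lung", "Skin"),
#'                          has_ps = c(TRUE, FALSE, TRUE))
#' patient_prevalence(cohort, by = "cancer_group")
#' @export
patient_prevalence <- function(cohort, by = NULL) {
  if (nrow(cohort) == 0) abort("`cohort` must be non-empty.")
  prevalence_tab(cohort, .data$has_ps, by)
}

#' Document-level documentation prevalence
#'
#' Proportion of reports containing a performance status, stratified by
#' document type (default) or any document columns. With
#' `restrict_cancer_stay = TRUE` the table is computed over
#' hospitalization reports linked to a cancer-coded stay only.
#'
#' @param documents document tibble with logical `has_ps` (and
#'   `cancer_coded_stay` when restricting)
#' @param by stratifier column names, default `"doc_type"`
#' @param restrict_cancer_stay restrict to cancer-coded hospitalization
#'   reports
#' @return a `ps_crosstab` tibble
#' @export
document_prevalence <- function(documents, by = "doc_type",
                                restrict_cancer_stay = FALSE) {
  if (restrict_cancer_stay) {
    documents <- dplyr::filter(
      documents,
      .data$doc_type == "HOSPITALIZATION",
      !is.na(.data$cancer_coded_stay) & .data$cancer_coded_stay
    )
  }
  if (nrow(documents) == 0) abort("no documents to tabulate.")
  prevalence_tab(documents, .data$has_ps, by)
}

#' Spearman correlation between hospital volume and documentation
#'
#' Rank correlation (average ranks for ties) between per-hospital document
#' counts and the per-hospital proportion of documents containing a
#' performance status. The two-sided p-value uses the t approximation
#' t = rho * sqrt((n - 2) / (1 - rho^2)) on n - 2 degrees of freedom, the
#' convention of standard statistical software at the handful-of-hospitals
#' scale this is used at. `exact = TRUE` switches to a full permutation
#' null (supported for n <= 8).
#'
#' @param volumes numeric vector of per-hospital document counts
#' @param proportions numeric vector of per-hospital documentation
#'   proportions, aligned with `volumes`
#' @param exact use the exact permutation p-value (n <= 8 only)
#' @return tibble with rho, p_value, n, method
#' @examples
#' spearman_volume_correlation(c(100, 200, 300, 400), c(.1, .2, .25, .4))
#' @export
spearman_volume_correlation <- function(volumes, proportions, exact = FALSE) {
  n <- length(volumes)
  if (length(proportions) != n) abort("inputs must have equal length.")
  if (n < 3) abort("need at least 3 hospitals to estimate a correlation.")
  rx <- rank(volumes)
  ry <- rank(proportions)
  if (length(unique(rx)) == 1 || length(unique(ry)) == 1) {
    abort("Spearman's rho is undefined: all values tied in one input.")
  }
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 8) abort("exact permutation p-value supported for n <= 8 only.")
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(p) cor(rx[p], ry))
    p_value <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else if (abs(rho) >= 1 - 1e-12) {
    p_value <- 0
    method <- "t approximation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_value <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = p_value, n = n, method = method)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' One-year mortality by documentation status
#'
#' The proportion of patients dying within one year of index, among those
#' with and without a documented performance status. A gap between the
#' two is the signature of informative presence: scores get written down
#' for sicker patients.
#'
#' @param cohort cohort tibble with logical `has_ps` and `died_within_1y`
#' @return tibble: has_ps, n_died, n_total, proportion
#' @export
mortality_by_documentation <- function(cohort) {
  cohort |>
    dplyr::group_by(.data$has_ps) |>
    dplyr::summarise(
      n_died = sum(.data$died_within_1y),
      n_total = dplyr::n(),
      proportion = sum(.data$died_within_1y) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$has_ps))
}

#' Dot plot of a prevalence cross-tab
#'
#' @param object a `ps_crosstab`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.ps_crosstab <- function(object, ...) {
  by <- attr(object, "stratifiers")
  if (is.null(by) || length(by) == 0) {
    abort("nothing to plot: the cross-tab has no stratifier.")
  }
  df <- tibble::as_tibble(object)
  df$stratum <- do.call(paste, c(df[by], sep = " / "))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$proportion,
    y = stats::reorder(.data$stratum, .data$proportion)
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, NA)) +
    ggplot2::labs(x = "Documented performance status", y = NULL) +
    ggplot2::theme_minimal()
}
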
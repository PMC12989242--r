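#' Evaluate document-level extraction against gold labels
#'
#' Standard binary-classification metrics for the document-level
#' "contains a performance status" decision, computed per document type
#' and overall: accuracy, precision/recall/F1 for each class (status
#' present / absent), the support-weighted F1, and the macro (unweighted)
#' F1. Undefined ratios (empty denominator) are reported as 0.
#'
#' @param predicted tibble with `doc_id` and logical `has_ps`
#' @param gold tibble with `doc_id`, logical `gold_has_ps`, and
#'   `doc_type`
#' @return tibble with one row per document type plus an `"overall"` row:
#'   doc_type, n_docs, accuracy, precision_pos, recall_pos, f1_pos,
#'   precision_neg, recall_neg, f1_neg, macro_f1, weighted_f1
#' @examples
#' gold <- tibble::tibble(doc_id = c("a", "b"), doc_type = "MDT",
#'                        gold_has_ps = c(TRUE, FALSE))
#' pred <- tibble::tibble(doc_id = c("a", "b"), has_ps = c(TRUE, FALSE))
#' evaluate_extraction(pred, gold)
#' @export
evaluate_extraction <- function(predicted, gold) {
  stopifnot(all(c("doc_id", "has_ps") %in% names(predicted)),
            all(c("doc_id", "gold_has_ps", "doc_type") %in% names(gold)))
  if (!setequal(predicted$doc_id, gold$doc_id) ||
      anyDuplicated(predicted$doc_id) || anyDuplicated(gold$doc_id)) {
    abort("`predicted` and `gold` must align 1:1 on doc_id.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(gold, "doc_id", "doc_type", "gold_has_ps"),
    dplyr::select(predicted, "doc_id", "has_ps"),
    by = "doc_id"
  )
  per_type <- joined |>
    dplyr::group_by(doc_type = .data$doc_type) |>
    dplyr::group_modify(~ binary_metrics(.x$has_ps, .x$gold_has_ps)) |>
    dplyr::ungroup()
  overall <- binary_metrics(joined$has_ps, joined$gold_has_ps) |>
    dplyr::mutate(doc_type = "overall", .before = 1)
  dplyr::bind_rows(per_type, overall)
}

binary_metrics <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  n <- tp + fp + fn + tn
  safe <- function(num, den) if (den == 0) 0 else num / den
  prec_pos <- safe(tp, tp + fp)
  rec_pos <- safe(tp, tp + fn)
  f1_pos <- safe(2 * prec_pos * rec_pos, prec_pos + rec_pos)
  prec_neg <- safe(tn, tn + fn)
  rec_neg <- safe(tn, tn + fp)
  f1_neg <- safe(2 * prec_neg * rec_neg, prec_neg + rec_neg)
  support_pos <- tp + fn
  support_neg <- tn + fp
  tibble::tibble(
    n_docs = n,
    accuracy = safe(tp + tn, n),
    precision_pos = prec_pos, recall_pos = rec_pos, f1_pos = f1_pos,
    precision_neg = prec_neg, recall_neg = rec_neg, f1_neg = f1_neg,
    macro_f1 = (f1_pos + f1_neg) / 2,
    weighted_f1 = safe(support_pos * f1_pos + support_neg * f1_neg,
                       support_pos + support_neg)
  )
}
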
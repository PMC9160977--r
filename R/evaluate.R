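# Evaluation of predicted gene-mutation matches against gold annotations,
# and the curator-facing structured report writer.

#' Build an evaluation report from raw counts
#'
#' Metrics follow the usual identities: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 their harmonic mean; a metric whose denominator is zero is
#' undefined (`NA`), never 0. Printed percentages are truncated (not
#' rounded) at two decimals, so the displayed precision never overstates the
#' computed fraction.
#'
#' @param tp,fp,fn Non-negative counts; `fn` may be `NA` when no gold set
#'   exists.
#' @return An object of class `eval_report` with fields `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1` (fractions in `[0, 1]` or `NA`).
#' @export
#' @examples
#' eval_report(tp = 807, fp = 170)
eval_report <- function(tp, fp, fn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, is.na(fn) || fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (!is.na(fn) && tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp),
         fn = if (is.na(fn)) NA_integer_ else as.integer(fn),
         precision = precision, recall = recall, f1 = f1),
    class = "eval_report"
  )
}

#' Evaluate predicted gene-mutation matches against gold annotations
#'
#' The unit of evaluation is the (document, gene, canonical mutation)
#' triple. A prediction is a true positive iff an identical triple exists in
#' gold (exact match on the canonical string, case-insensitive on the gene
#' symbol); unmatched predictions are false positives and unmatched gold
#' rows false negatives. Both sides are reduced to distinct triples first.
#'
#' @param predicted A tibble with columns `doc_id`, `gene_symbol`,
#'   `canonical` (e.g. the output of [pair_and_validate()]).
#' @param gold A gold tibble (see [read_gold()]).
#' @return An `eval_report`; the mismatch detail is attached as tibbles
#'   `$false_positives` and `$false_negatives`.
#' @export
evaluate_matches <- function(predicted, gold) {
  triple <- function(d, g, m) paste(d, tolower(g), m, sep = "\r")
  p <- unique(triple(predicted$doc_id, predicted$gene_symbol,
                     predicted$canonical))
  g <- unique(triple(gold$doc_id, gold$gene_symbol, gold$mutation))
  tp <- sum(p %in% g)
  rep <- eval_report(tp = tp, fp = length(p) - tp, fn = length(g) - sum(g %in% p))
  unsplit3 <- function(x) {
    parts <- stringr::str_split_fixed(x, "\r", 3)
    tibble::tibble(doc_id = parts[, 1], gene_symbol = parts[, 2],
                   mutation = parts[, 3])
  }
  rep$false_positives <- unsplit3(setdiff(p, g))
  rep$false_negatives <- unsplit3(setdiff(g, p))
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Gene-mutation match evaluation\n")
  cat(sprintf("  TP: %d  FP: %d  FN: %s\n", x$tp, x$fp,
              ifelse(is.na(x$fn), "-", x$fn)))
  cat(sprintf("  Precision: %s  Recall: %s  F1: %s\n",
              format_pct(100 * x$precision), format_pct(100 * x$recall),
              format_pct(100 * x$f1)))
  invisible(x)
}

#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("tp", "fp", "fn", "precision", "recall", "f1"),
    value = c(x$tp, x$fp, x$fn, x$precision, x$recall, x$f1)
  )
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn,
                 precision = x$precision, recall = x$recall, f1 = x$f1)
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tibble::tibble(
    metric = factor(c("precision", "recall", "f1"),
                    levels = c("precision", "recall", "f1")),
    value = c(object$precision, object$recall, object$f1)
  )
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Gene-mutation match evaluation") +
    ggplot2::theme_minimal()
}

report_columns <- c(
  "doc_id", "gene_id", "gene_symbol", "mutation", "position",
  "valid_isoforms", "cds_corroborated", "mention_count",
  "candidate_gene_count", "similar_mutations", "strains", "alleles",
  "methods", "sentences"
)

flatten_records <- function(matches) {
  collapse <- function(x) {
    vapply(x, function(v) paste(v, collapse = "; "), character(1))
  }
  matches |>
    dplyr::rename(mutation = "canonical") |>
    dplyr::mutate(
      valid_isoforms = collapse(.data$valid_isoforms),
      similar_mutations = collapse(.data$similar_mutations),
      sentences = collapse(.data$sentences)
    ) |>
    dplyr::arrange(.data$doc_id, .data$gene_symbol, .data$position) |>
    dplyr::select(dplyr::all_of(report_columns))
}

#' Write curator-facing structured output
#'
#' One row per validated gene-mutation match, ordered by (document, gene,
#' position), with list fields collapsed by `"; "` in TSV; JSON is an array
#' of objects with stable key order. Re-running on identical input yields a
#' byte-identical file.
#'
#' @param matches Output of [pair_and_validate()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(matches, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rec <- flatten_records(matches)
  if (format == "tsv") {
    readr::write_tsv(rec, path, na = "")
  } else {
    json <- jsonlite::toJSON(rec, dataframe = "rows", na = "null",
                             auto_unbox = TRUE, pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
  }
  invisible(path)
}
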
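# The end-to-end pipeline: documents -> mentions -> canonical mutations ->
# entities -> validated matches -> curator records (+ optional evaluation).

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full curation pipeline
#'
#' Loads and segments documents, extracts mutation mentions with the gated
#' hybrid block, normalizes them to canonical form, matches dictionary
#' entities, validates every candidate gene-mutation pair against the
#' proteome, and (when gold annotations are supplied) scores the validated
#' matches. Per-stage counts are kept so a run summary reads like a curation
#' accounting: total mentions per block, normalized vs discarded, validated
#' matches.
#'
#' @param doc_paths Character vector of document `.txt` paths.
#' @param proteome_fasta Protein FASTA path (headers `gene_id|isoform_id`).
#' @param dict_paths Character vector of dictionary TSV paths.
#' @param cds_fasta Optional CDS FASTA path.
#' @param gold_path Optional gold TSV path.
#' @inheritParams extract_mentions
#' @param quiet Suppress informational log lines.
#' @return An object of class `mm_run`: a list with `sentences`, `mentions`,
#'   `normalized`, `accounting`, `entities`, `matches`, `records`
#'   (flattened curation rows), `report` (an `eval_report` or `NULL`) and
#'   `counts`.
#' @export
run_pipeline <- function(doc_paths, proteome_fasta, dict_paths,
                         cds_fasta = NULL, gold_path = NULL,
                         patterns = default_patterns(),
                         lexicon = default_lexicon(),
                         use_nl_block = TRUE, plugin = NULL, quiet = FALSE) {
  sentences <- run_stage("corpus_io", read_documents(doc_paths))
  proteome <- run_stage("corpus_io", read_proteome(proteome_fasta, cds_fasta))
  dict <- run_stage("entities", load_dictionaries(dict_paths))
  mentions <- run_stage("extraction",
                        extract_mentions(sentences, patterns, lexicon,
                                         use_nl_block = use_nl_block,
                                         plugin = plugin))
  normalized <- run_stage("normalize", normalize_mentions(mentions))
  accounting <- run_stage("normalize", discard_accounting(normalized, mentions))
  entities <- run_stage("entities", match_entities(sentences, dict))
  matches <- run_stage("validate",
                       pair_and_validate(normalized, entities, proteome,
                                         sentences = sentences, quiet = quiet))
  report <- NULL
  if (!is.null(gold_path)) {
    gold <- run_stage("corpus_io", read_gold(gold_path))
    report <- run_stage("evaluate", evaluate_matches(matches, gold))
  }
  total_row <- accounting[accounting$source_block == "total", ]
  counts <- list(
    n_documents = length(unique(sentences$doc_id)),
    n_sentences = nrow(sentences),
    n_mentions = nrow(mentions),
    n_regex = sum(mentions$source_block == "regex"),
    n_natural_language = sum(mentions$source_block %in%
                               c("natural_language", "plugin")),
    n_normalized = if (nrow(total_row)) total_row$n_normalized else 0L,
    n_discarded = if (nrow(total_row)) total_row$n_discarded else 0L,
    pct_discarded = if (nrow(total_row)) total_row$pct_discarded_of_total
                    else NA_real_,
    n_validated = nrow(matches)
  )
  if (!quiet) {
    message(sprintf(
      "%d document(s), %d sentence(s); %d mention(s) (%d regex, %d natural language); %d normalized, %d discarded (%s of all mentions); %d validated match(es)",
      counts$n_documents, counts$n_sentences, counts$n_mentions,
      counts$n_regex, counts$n_natural_language, counts$n_normalized,
      counts$n_discarded, format_pct(counts$pct_discarded, 1L),
      counts$n_validated))
  }
  structure(
    list(sentences = sentences, mentions = mentions, normalized = normalized,
         accounting = accounting, entities = entities, matches = matches,
         records = flatten_records(matches), report = report, counts = counts),
    class = "mm_run"
  )
}

#' @export
print.mm_run <- function(x, ...) {
  c0 <- x$counts
  cat("Mutation-mining run\n")
  cat(sprintf("  Corpus: %d document(s), %d sentence(s)\n",
              c0$n_documents, c0$n_sentences))
  cat(sprintf("  Mentions: %d total (%d regex, %d natural language)\n",
              c0$n_mentions, c0$n_regex, c0$n_natural_language))
  cat(sprintf("  Normalized: %d; discarded: %d (%s of all mentions)\n",
              c0$n_normalized, c0$n_discarded,
              format_pct(c0$pct_discarded, 1L)))
  cat(sprintf("  Validated gene-mutation matches: %d\n", c0$n_validated))
  if (!is.null(x$report)) {
    cat(sprintf("  Evaluation: TP %d, FP %d, FN %d; precision %s, recall %s\n",
                x$report$tp, x$report$fp, x$report$fn,
                format_pct(100 * x$report$precision),
                format_pct(100 * x$report$recall)))
  }
  invisible(x)
}

#' @method tidy mm_run
#' @export
tidy.mm_run <- function(x, ...) x$records

#' @method glance mm_run
#' @export
glance.mm_run <- function(x, ...) {
  tibble::as_tibble(x$counts)
}

#' @method autoplot mm_run
#' @export
autoplot.mm_run <- function(object, ...) {
  df <- object$normalized |>
    dplyr::count(.data$source_block, .data$status)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$source_block, y = .data$n,
                                   fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "extraction block", y = "mentions",
                  title = "Mutation mentions by block and outcome") +
    ggplot2::theme_minimal()
}
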
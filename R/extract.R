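# Mention extraction: the regex block, the rule-based natural-language
# block, and the per-sentence gate between them.

finish_mentions <- function(cand, sent, source_block) {
  if (nrow(cand) == 0L) return(mention_cols())
  tibble::tibble(
    doc_id = sent$doc_id,
    sentence_id = sent$sentence_id,
    start = cand$start,
    end = cand$end,
    raw_text = cand$match,
    source_block = source_block,
    mention_kind = cand$mention_kind,
    pattern_id = cand$pattern_id,
    ref = cand$ref,
    pos = as.integer(cand$pos),
    alt = cand$alt
  )
}

match_pattern_rows <- function(text, patterns) {
  purrr::pmap(patterns, function(pattern_id, mention_kind, pattern, priority, ...) {
    hits <- re_match_all(text, pattern)
    if (nrow(hits) == 0L) return(NULL)
    hits$pattern_id <- pattern_id
    hits$mention_kind <- mention_kind
    hits$priority <- priority
    hits
  }) |> dplyr::bind_rows()
}

#' Extract structured mutation mentions with the regex block
#'
#' Runs the ordered pattern set over each sentence and returns all
#' non-overlapping matches; overlaps are resolved longest-match-first, ties
#' by leftmost start and then by pattern order. Positions in the parsed
#' components are 1-based residue/codon numbers as written by the authors.
#'
#' @param sentences A sentence tibble (see [segment_sentences()]).
#' @param patterns A pattern tibble (see [read_patterns()]).
#' @return A mention tibble: `doc_id`, `sentence_id`, `start`, `end`
#'   (sentence-relative, 0-based half-open), `raw_text`, `source_block`
#'   (`"regex"`), `mention_kind`, `pattern_id`, and parsed components
#'   `ref`, `pos`, `alt` (`NA` where a pattern captures none).
#' @export
#' @examples
#' s <- segment_sentences("The same mutation G359A was studied.")
#' extract_regex(s)
extract_regex <- function(sentences, patterns = default_patterns()) {
  out <- purrr::map(seq_len(nrow(sentences)), function(i) {
    sent <- sentences[i, ]
    cand <- match_pattern_rows(sent$text, patterns)
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    finish_mentions(resolve_overlaps(cand), sent, "regex")
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) return(mention_cols())
  dplyr::arrange(out, .data$doc_id, .data$sentence_id, .data$start)
}

# Template grammars for natural-language substitutions, composed from the
# lexicon. Both argument orders are covered: ref-first active/passive forms
# and the alt-first "Y for X substitution" form.
nl_patterns <- function(lexicon = default_lexicon()) {
  aa <- amino_acid_table()
  names_full <- c(setdiff(aa$full_name, "stop"),
                  dplyr::filter(lexicon, .data$role == "aa_synonym")$term)
  stops <- dplyr::filter(lexicon, .data$role == "stop_name")$term
  aan <- paste(c(names_full, stops)[order(-nchar(c(names_full, stops)))],
               collapse = "|")
  noun <- paste(dplyr::filter(lexicon, .data$role == "sub_noun")$term, collapse = "|")
  verb <- paste(dplyr::filter(lexicon, .data$role == "sub_verb")$term, collapse = "|")
  posw <- paste(dplyr::filter(lexicon, .data$role == "pos_word")$term, collapse = "|")
  at <- sprintf("at\\s+(?:the\\s+)?(?:%s)\\s+(?<pos>[1-9][0-9]*)", posw)
  tibble::tibble(
    pattern_id = c("nl_active", "nl_passive", "nl_of", "nl_for", "nl_del", "nl_ins"),
    mention_kind = c(rep("natural_language_substitution", 4), "deletion", "insertion"),
    pattern = c(
      sprintf("(?i)\\b(?<ref>%s)[\\s-]+(?:to|into)[\\s-]+(?<alt>%s)\\s+(?:%s)s?\\s+%s",
              aan, aan, noun, at),
      sprintf(paste0("(?i)\\b(?<ref>%s)\\s+(?:was\\s+|is\\s+|were\\s+|has\\s+been\\s+|",
                     "had\\s+been\\s+)?(?:%s)\\s+(?:by|with|to|for)\\s+(?<alt>%s)\\s+%s"),
              aan, verb, aan, at),
      sprintf("(?i)\\b(?:%s)\\s+of\\s+(?<ref>%s)\\s+(?:by|with|for|to|into)\\s+(?<alt>%s)\\s+%s",
              noun, aan, aan, at),
      sprintf("(?i)\\b(?<alt>%s)\\s+for\\s+(?<ref>%s)\\s+(?:%s)\\s+%s",
              aan, aan, noun, at),
      "(?i)\\bdeletions?\\s+of\\s+\\S[^.;:]*",
      "(?i)\\binsertions?\\s+of\\s+\\S[^.;:]*"
    ),
    priority = 1:6
  )
}

#' Extract natural-language mutation mentions
#'
#' The rule-based stand-in for a learned tagger: template grammars of the
#' form `<amino-acid name> {to|by|with|for} <amino-acid name>
#' {substitution|substituted|replaced|changed} at {codon|residue|position}
#' <integer>`, in both argument orders, matched case-insensitively. In the
#' passive form "X was substituted by Y at residue N" the named-first residue
#' X is the reference and Y the alternate. Deletion/insertion phrases
#' ("deletion of ... residues ...") are flagged as component-less `deletion`
#' / `insertion` mentions; downstream normalization discards them with an
#' explicit reason.
#'
#' @inheritParams extract_regex
#' @param lexicon Lexicon tibble (see [read_lexicon()]).
#' @return A mention tibble with `source_block = "natural_language"`.
#' @export
#' @examples
#' s <- segment_sentences("We found a glycine to arginine substitution at codon 20.")
#' extract_natural_language(s)
extract_natural_language <- function(sentences, lexicon = default_lexicon()) {
  patterns <- nl_patterns(lexicon)
  out <- purrr::map(seq_len(nrow(sentences)), function(i) {
    sent <- sentences[i, ]
    cand <- match_pattern_rows(sent$text, patterns)
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    finish_mentions(resolve_overlaps(cand), sent, "natural_language")
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) return(mention_cols())
  dplyr::arrange(out, .data$doc_id, .data$sentence_id, .data$start)
}

#' Extract all mutation mentions from segmented documents
#'
#' The hybrid block with its gate: each sentence first goes through the regex
#' block; if and only if that yields zero mentions is the sentence handed to
#' the natural-language block (or to a registered plugin tagger). No sentence
#' ever contributes mentions from both blocks.
#'
#' @inheritParams extract_natural_language
#' @param use_nl_block If `FALSE`, sentences without regex hits are left
#'   untagged rather than passed to the natural-language block.
#' @param plugin Optional tagger: a function taking a one-row sentence tibble
#'   and returning a mention tibble; its output replaces the shipped
#'   natural-language block and is labelled `source_block = "plugin"`.
#' @return A mention tibble ordered by (`doc_id`, `sentence_id`, `start`).
#' @export
extract_mentions <- function(sentences, patterns = default_patterns(),
                             lexicon = default_lexicon(),
                             use_nl_block = TRUE, plugin = NULL) {
  rx <- extract_regex(sentences, patterns)
  hit <- dplyr::distinct(rx, .data$doc_id, .data$sentence_id)
  rest <- dplyr::anti_join(sentences, hit, by = c("doc_id", "sentence_id"))
  nl <- mention_cols()
  if (nrow(rest) > 0L) {
    if (!is.null(plugin)) {
      nl <- purrr::map(seq_len(nrow(rest)),
                       function(i) plugin(rest[i, ])) |> dplyr::bind_rows()
      if (nrow(nl) > 0L) nl$source_block <- "plugin"
    } else if (use_nl_block) {
      nl <- extract_natural_language(rest, lexicon)
    }
  }
  dplyr::bind_rows(rx, nl) |>
    dplyr::arrange(.data$doc_id, .data$sentence_id, .data$start)
}
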
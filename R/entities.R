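# Dictionary-based entity recognition for genes, strains, alleles,
# variation types and generation methods.

entity_classes <- c("gene", "strain", "allele", "variation_type",
                    "generation_method")

#' Load and merge entity dictionaries
#'
#' Each dictionary is a TSV with header `surface_form`, `canonical_id`,
#' `entity_class`. Exact duplicate rows collapse; the same
#' (surface form, class) mapping to two different ids is an error naming
#' both rows.
#'
#' @param paths Character vector of dictionary TSV paths.
#' @return A tibble with columns `surface_form`, `canonical_id`,
#'   `entity_class`.
#' @export
load_dictionaries <- function(paths) {
  need <- c("surface_form", "canonical_id", "entity_class")
  dict <- purrr::map(paths, function(p) {
    d <- readr::read_tsv(p, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    if (!all(need %in% names(d))) {
      stop("dictionary ", p, " must have columns: ", paste(need, collapse = ", "))
    }
    d[need]
  }) |> dplyr::bind_rows() |> dplyr::distinct()
  bad <- setdiff(unique(dict$entity_class), entity_classes)
  if (length(bad)) stop("unknown entity_class: ", paste(bad, collapse = ", "))
  if (any(!nzchar(dict$surface_form) | is.na(dict$surface_form))) {
    stop("empty surface_form in dictionary")
  }
  conflict <- dict |>
    dplyr::group_by(.data$surface_form, .data$entity_class) |>
    dplyr::filter(dplyr::n_distinct(.data$canonical_id) > 1) |>
    dplyr::ungroup()
  if (nrow(conflict)) {
    stop("conflicting dictionary rows for: ",
         paste(unique(paste0(conflict$surface_form, " [", conflict$entity_class,
                             "] -> ", conflict$canonical_id)), collapse = "; "))
  }
  tibble::as_tibble(dict)
}

# Acronym rule: variation types / generation methods written in all caps
# (EMS, ENU) match case-sensitively; everything else case-insensitively.
dict_case_sensitive <- function(surface_form, entity_class) {
  entity_class %in% c("variation_type", "generation_method") &
    surface_form == toupper(surface_form) &
    grepl("[A-Z]", surface_form)
}

#' Match dictionary entities in sentences
#'
#' Whole-token matches only: a hit may not sit inside a longer alphanumeric
#' token (so "EMS" never fires inside "EMSA"). Genes, strains and alleles
#' match case-insensitively but are reported with the dictionary's casing;
#' all-caps variation-type/generation-method acronyms match case-sensitively.
#' Overlapping hits are resolved longest-first; the result does not depend
#' on dictionary row order.
#'
#' @param sentences A sentence tibble (see [segment_sentences()]).
#' @param dict An entity dictionary (see [load_dictionaries()]).
#' @return A tibble: `doc_id`, `sentence_id`, `start`, `end`
#'   (sentence-relative, 0-based half-open), `matched_text` (the literal
#'   slice), `surface_form` (dictionary casing), `canonical_id`,
#'   `entity_class`.
#' @export
match_entities <- function(sentences, dict) {
  empty <- tibble::tibble(
    doc_id = character(), sentence_id = integer(), start = integer(),
    end = integer(), matched_text = character(), surface_form = character(),
    canonical_id = character(), entity_class = character()
  )
  if (nrow(sentences) == 0L || nrow(dict) == 0L) return(empty)
  dict <- dplyr::arrange(dict, .data$entity_class, .data$surface_form,
                         .data$canonical_id)
  cs <- dict_case_sensitive(dict$surface_form, dict$entity_class)
  rx <- paste0(ifelse(cs, "", "(?i)"),
               "(?<![A-Za-z0-9])", rx_escape(dict$surface_form),
               "(?![A-Za-z0-9])")
  out <- purrr::map(seq_len(nrow(sentences)), function(i) {
    sent <- sentences[i, ]
    cand <- purrr::map(seq_len(nrow(dict)), function(j) {
      hits <- re_match_all(sent$text, rx[j])
      if (nrow(hits) == 0L) return(NULL)
      tibble::tibble(
        start = hits$start, end = hits$end, matched_text = hits$match,
        surface_form = dict$surface_form[j],
        canonical_id = dict$canonical_id[j],
        entity_class = dict$entity_class[j],
        priority = j
      )
    }) |> dplyr::bind_rows()
    if (is.null(cand) || nrow(cand) == 0L) return(NULL)
    kept <- resolve_overlaps(cand)
    tibble::tibble(
      doc_id = sent$doc_id, sentence_id = sent$sentence_id,
      start = kept$start, end = kept$end, matched_text = kept$matched_text,
      surface_form = kept$surface_form, canonical_id = kept$canonical_id,
      entity_class = kept$entity_class
    )
  }) |> dplyr::bind_rows()
  if (nrow(out) == 0L) return(empty)
  dplyr::arrange(out, .data$doc_id, .data$sentence_id, .data$start)
}
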
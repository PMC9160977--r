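# Document loading, sentence segmentation and gold-annotation IO.
#
# Offsets convention: all spans are 0-based, half-open [start, end) character
# offsets into the parent string. Sentence spans index the document text;
# mention and entity spans index the sentence text.

abbreviation_stoplist <- c(
  "fig.", "figs.", "eq.", "eqs.", "e.g.", "i.e.", "eg.", "ie.", "cf.",
  "approx.", "vs.", "al.", "etc.", "no.", "ca.", "ref.", "refs.", "ver."
)

#' Segment text into sentences with stable offsets
#'
#' Rule-based splitter: a run of terminal punctuation (`.!?`) followed by
#' whitespace or end-of-text ends a sentence, unless the preceding token is
#' on an abbreviation stop-list (Fig., et al., e.g., ...), is a single-letter
#' initial (so "C. elegans" stays intact), or the next word starts lowercase.
#' Deterministic; no model, no randomness.
#'
#' @param text A single character string (the full document text).
#' @param doc_id Document identifier carried into the output.
#' @return A tibble with one row per sentence: `doc_id`, `sentence_id`
#'   (0-based), `start`, `end` (0-based half-open offsets into `text`),
#'   `text` (the exact slice, whitespace-trimmed).
#' @export
#' @examples
#' segment_sentences("We isolated e1234. It carries G109E.", "p1")
segment_sentences <- function(text, doc_id = "doc") {
  stopifnot(is.character(text), length(text) == 1L)
  out <- tibble::tibble(doc_id = character(), sentence_id = integer(),
                        start = integer(), end = integer(), text = character())
  if (is.na(text) || !nzchar(text)) return(out)

  n <- nchar(text)
  m <- gregexpr("[.!?]+(?=\\s|$)", text, perl = TRUE)[[1L]]
  bounds <- integer(0)
  if (m[1L] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # 1-based last punct
    for (e in ends) {
      token <- stringr::str_extract(substr(text, 1L, e), "\\S+$")
      if (!is.na(token)) {
        token <- sub("^[^A-Za-z0-9]+", "", token)  # strip opening brackets/quotes
        if (tolower(token) %in% abbreviation_stoplist) next
        if (grepl("^[A-Za-z]\\.$", token)) next  # initials, species shorthand
      }
      nxt <- sub("^\\s*", "", substr(text, e + 1L, n))
      if (grepl("^[a-z]", nxt)) next
      bounds <- c(bounds, e)
    }
  }
  bounds <- unique(c(bounds, n))

  spans <- list()
  a <- 1L
  for (b in bounds) {
    raw <- substr(text, a, b)
    lead <- nchar(sub("^(\\s*).*$", "\\1", raw))
    trail <- nchar(sub("^.*?(\\s*)$", "\\1", raw))
    s1 <- a + lead
    e1 <- b - trail
    if (s1 <= e1) spans[[length(spans) + 1L]] <- c(s1, e1)
    a <- b + 1L
  }
  if (!length(spans)) return(out)
  sp <- do.call(rbind, spans)
  tibble::tibble(
    doc_id = doc_id,
    sentence_id = seq_len(nrow(sp)) - 1L,
    start = sp[, 1] - 1L,
    end = sp[, 2],
    text = substring(text, sp[, 1], sp[, 2])
  )
}

#' Load a plain-text document and segment it into sentences
#'
#' @param path Path to a UTF-8 `.txt` file.
#' @param doc_id Document identifier; defaults to the file name without
#'   extension.
#' @return A sentence tibble (see [segment_sentences()]); zero rows for an
#'   empty file. The full document text is attached as attribute `doc_text`.
#' @export
read_document <- function(path, doc_id = NULL) {
  if (!file.exists(path)) stop("cannot read document: ", path)
  doc_id <- doc_id %||% sub("\\.[^.]*$", "", basename(path))
  text <- readr::read_file(path)
  sents <- segment_sentences(text, doc_id = doc_id)
  attr(sents, "doc_text") <- text
  sents
}

#' @rdname read_document
#' @param paths Character vector of document paths.
#' @return `read_documents()` row-binds the per-document sentence tibbles.
#' @export
read_documents <- function(paths) {
  if (!length(paths)) {
    return(segment_sentences("")[0, ])
  }
  purrr::map(paths, read_document) |> dplyr::bind_rows()
}

#' Read gold gene-mutation annotations
#'
#' Gold annotations are per-document gene-mutation pairs: a TSV with header
#' `doc_id`, `gene_symbol`, `mutation`, where `mutation` must parse under the
#' canonical one-letter grammar (e.g. `G109E`). Malformed rows are rejected
#' with their row numbers.
#'
#' @param path Path to the gold TSV.
#' @return A tibble with columns `doc_id`, `gene_symbol`, `mutation`.
#' @export
read_gold <- function(path) {
  gold <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  need <- c("doc_id", "gene_symbol", "mutation")
  if (!all(need %in% names(gold))) {
    stop("gold file must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(is.na(gold$mutation) | !grepl(canonical_regex, gold$mutation))
  if (length(bad)) {
    stop("gold rows not in canonical form (row ",
         paste(bad, collapse = ", "), "): ",
         paste(gold$mutation[bad], collapse = ", "))
  }
  tibble::as_tibble(gold[need])
}
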
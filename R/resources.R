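# Shipped resources: the amino-acid code table, the mutation pattern set,
# and the natural-language lexicon. All are plain TSV under inst/extdata so
# users can supply their own via the read_* functions.

the <- new.env(parent = emptyenv())

pkg_file <- function(...) {
  path <- system.file("extdata", ..., package = "mutminer", mustWork = TRUE)
  path
}

#' Amino-acid code table
#'
#' The standard 20 amino acids plus the stop codon, with full name,
#' three-letter code and one-letter code. Used by [normalize_mentions()] and
#' by the natural-language extraction templates.
#'
#' @return A tibble with columns `full_name`, `three_letter`, `one_letter`.
#' @export
#' @examples
#' amino_acid_table()
amino_acid_table <- function() {
  if (is.null(the$aa)) {
    the$aa <- readr::read_tsv(pkg_file("amino_acids.tsv"),
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  }
  the$aa
}

aa_one_letters <- function() {
  setdiff(amino_acid_table()$one_letter, "*")
}

# named lookup vectors (keys lowercased)
aa_maps <- function(lexicon = default_lexicon()) {
  aa <- amino_acid_table()
  syn <- dplyr::filter(lexicon, .data$role == "aa_synonym")
  stops <- dplyr::filter(lexicon, .data$role == "stop_name")
  list(
    three = stats::setNames(aa$one_letter, tolower(aa$three_letter)),
    full = c(
      stats::setNames(aa$one_letter, tolower(aa$full_name)),
      stats::setNames(syn$maps_to, tolower(syn$term)),
      stats::setNames(stops$maps_to, tolower(stops$term))
    )
  )
}

#' Read a mutation pattern set
#'
#' A pattern set is an ordered TSV with columns `pattern_id`, `mention_kind`
#' and `pattern` (PCRE with named groups `ref`, `pos`, `alt`). The
#' placeholders `{AA1}`, `{AA3}` and `{AAFULL}` expand to the one-letter
#' class, the three-letter alternation and the full-name alternation built
#' from [amino_acid_table()] plus lexicon synonyms. Pattern order is the
#' tie-break for overlapping matches of equal length.
#'
#' @param path Path to a pattern TSV.
#' @param lexicon Lexicon tibble, used for full-name synonyms.
#' @return A tibble with columns `pattern_id`, `mention_kind`, `pattern`,
#'   `priority`.
#' @export
read_patterns <- function(path, lexicon = default_lexicon()) {
  pat <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("pattern_id", "mention_kind", "pattern")
  if (!all(need %in% names(pat))) {
    stop("pattern file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(pat$pattern_id)) {
    stop("duplicate pattern_id: ",
         paste(unique(pat$pattern_id[duplicated(pat$pattern_id)]), collapse = ", "))
  }
  kinds <- c("protein_substitution", "dna_substitution", "nonsense",
             "deletion", "insertion", "indel", "natural_language_substitution",
             "other")
  bad <- setdiff(unique(pat$mention_kind), kinds)
  if (length(bad)) stop("unknown mention_kind: ", paste(bad, collapse = ", "))

  aa <- amino_acid_table()
  aa1 <- paste0("[", paste(aa_one_letters(), collapse = ""), "]")
  aa3 <- paste(setdiff(aa$three_letter, "Ter"), collapse = "|")
  full <- c(setdiff(aa$full_name, "stop"),
            dplyr::filter(lexicon, .data$role == "aa_synonym")$term)
  full <- full[order(-nchar(full), full)]
  aafull <- paste(full, collapse = "|")
  expand <- function(p) {
    p <- gsub("{AA1}", aa1, p, fixed = TRUE)
    p <- gsub("{AA3}", aa3, p, fixed = TRUE)
    gsub("{AAFULL}", aafull, p, fixed = TRUE)
  }
  pat$pattern <- vapply(pat$pattern, expand, character(1), USE.NAMES = FALSE)
  pat$priority <- seq_len(nrow(pat))
  tibble::as_tibble(pat)
}

#' Default mutation pattern set
#'
#' Structured ("basic") mention shapes: one-letter `X123Y`, three-letter
#' `Xxx123Yyy` and `Xxx-123-Yyy`, full-name hyphen forms, arrow connectors
#' (`G12->A`, `Gly12→Ala`), nucleotide `c.123A>G` and `123A>G`, nonsense
#' `Q123*` / `Q123X`, and simple `del`/`ins` tokens attached to positions.
#' One-letter codes match case-sensitively (uppercase); three-letter and
#' full-name forms match case-insensitively.
#'
#' @return A pattern tibble, see [read_patterns()].
#' @export
default_patterns <- function() {
  if (is.null(the$patterns)) {
    the$patterns <- read_patterns(pkg_file("patterns.tsv"))
  }
  the$patterns
}

#' Read a natural-language lexicon
#'
#' TSV with columns `term`, `role`, `maps_to`. Roles: `aa_synonym` (extra
#' amino-acid names such as aspartate/glutamate), `stop_name` (amber, ochre,
#' opal), `sub_noun`/`sub_verb` (substitution vocabulary), `pos_word`
#' (codon/residue/position/amino acid), `indel_del`/`indel_ins`.
#'
#' @param path Path to a lexicon TSV.
#' @return A tibble with columns `term`, `role`, `maps_to`.
#' @export
read_lexicon <- function(path) {
  lex <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("term", "role", "maps_to")
  if (!all(need %in% names(lex))) {
    stop("lexicon file must have columns: ", paste(need, collapse = ", "))
  }
  tibble::as_tibble(lex)
}

#' @rdname read_lexicon
#' @export
default_lexicon <- function() {
  if (is.null(the$lexicon)) {
    the$lexicon <- read_lexicon(pkg_file("lexicon.tsv"))
  }
  the$lexicon
}

#' Degenerate codon set of a residue
#'
#' All codons that encode `ref` under the standard genetic code (e.g. glycine
#' `G` gives GGT, GGC, GGA, GGG — "GGN"); `"*"` gives the stop codons.
#'
#' @param ref A one-letter residue code or `"*"`.
#' @return Character vector of codons.
#' @export
#' @examples
#' degenerate_codons("G")
degenerate_codons <- function(ref) {
  tab <- degenerate_codon_table()
  tab[[ref]] %||% character(0)
}

degenerate_codon_table <- function() {
  if (is.null(the$codons)) {
    gc <- Biostrings::GENETIC_CODE
    the$codons <- split(names(gc), gc)
  }
  the$codons
}
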
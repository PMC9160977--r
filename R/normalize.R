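# Normalization of mention components to canonical one-letter substitution
# form, plus the per-block discard accounting.

# Map one residue token to its one-letter code; NA when unknown.
token_to_one <- function(token, kind) {
  out <- rep(NA_character_, length(token))
  t <- trimws(token)
  maps <- aa_maps()
  one <- grepl("^[ACDEFGHIKLMNPQRSTVWY*]$", t)          # case-sensitive
  out[one] <- t[one]
  low <- tolower(t)
  three <- !one & low %in% names(maps$three)
  out[three] <- unname(maps$three[low[three]])
  full <- is.na(out) & low %in% names(maps$full)
  out[full] <- unname(maps$full[low[full]])
  stop_x <- is.na(out) & kind == "nonsense" & t == "X"   # Q123X nonsense shape
  out[stop_x] <- "*"
  out
}

#' Normalize mutation mentions to canonical one-letter form
#'
#' Substitution mentions (structured, nonsense, or natural-language) with
#' complete `ref`/`pos`/`alt` components are mapped through the standard
#' three-letter / full-name to one-letter amino-acid table into
#' `<REF><POS><ALT>` (e.g. `V600E`); amber/ochre/opal and `X`/`*` map to the
#' stop symbol `*`. Deletion, insertion, indel and other component-less
#' mentions are discarded with status `discarded_unsupported`; mentions
#' missing a component or carrying an unrecognized residue token are
#' discarded with status `discarded_incomplete` and the offending token
#' named. Nucleotide-level mentions (`c.123A>G`) are carried as
#' `discarded_unsupported`: downstream pairing and validation operate on
#' protein-level canonical forms. Normalization is idempotent on already
#' canonical input. Positions are kept exactly as written by the authors; no
#' initiator-methionine renumbering.
#'
#' @param mentions A mention tibble (see [extract_mentions()]).
#' @return The input with columns added: `canonical` (string or `NA`),
#'   `position` (integer), `status` (`normalized`, `discarded_incomplete`,
#'   `discarded_unsupported`) and `reason` (`NA` when normalized).
#' @export
#' @examples
#' s <- segment_sentences("The Arg-107-Cys change was confirmed.")
#' normalize_mentions(extract_regex(s))
normalize_mentions <- function(mentions) {
  n <- nrow(mentions)
  canonical <- rep(NA_character_, n)
  status <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  sub_kinds <- c("protein_substitution", "nonsense",
                 "natural_language_substitution")
  unsupported <- mentions$mention_kind %in%
    c("deletion", "insertion", "indel", "other", "dna_substitution")
  status[unsupported] <- "discarded_unsupported"
  reason[unsupported] <- if_else(
    mentions$mention_kind[unsupported] == "dna_substitution",
    "nucleotide-level mention; protein-level canonical form required",
    paste0(mentions$mention_kind[unsupported], " mentions are not normalized")
  )

  todo <- !unsupported & mentions$mention_kind %in% sub_kinds
  other <- !unsupported & !todo
  status[other] <- "discarded_unsupported"
  reason[other] <- "mention kind carries no substitution components"

  missing <- todo & (is.na(mentions$ref) | is.na(mentions$pos) | is.na(mentions$alt))
  status[missing] <- "discarded_incomplete"
  reason[missing] <- "missing ref/position/alt component"
  todo <- todo & !missing

  ref1 <- token_to_one(mentions$ref[todo], mentions$mention_kind[todo])
  alt1 <- token_to_one(mentions$alt[todo], mentions$mention_kind[todo])
  idx <- which(todo)
  unknown <- is.na(ref1) | is.na(alt1)
  bad_tok <- ifelse(is.na(ref1), mentions$ref[todo], mentions$alt[todo])
  status[idx[unknown]] <- "discarded_incomplete"
  reason[idx[unknown]] <- paste0("unknown amino-acid token: ", bad_tok[unknown])

  ok <- idx[!unknown]
  canonical[ok] <- paste0(ref1[!unknown], mentions$pos[ok], alt1[!unknown])
  status[ok] <- "normalized"

  out <- mentions
  out$canonical <- canonical
  out$position <- mentions$pos
  out$status <- status
  out$reason <- reason
  out
}

#' Per-block discard accounting
#'
#' Summarizes normalization outcomes the way a curation run is reported: how
#' many mentions each extraction block produced, how many normalized, how
#' many were discarded, and each block's discarded share *of the total
#' mention count* (so a natural-language block whose output is entirely
#' dropped contributes `100 * n_block / n_total` percent).
#'
#' @param normalized A normalized mention tibble (one row per mention, see
#'   [normalize_mentions()]).
#' @param mentions Optional: the original mention tibble; if supplied, a row
#'   count mismatch is an error.
#' @return A tibble with one row per source block plus a `total` row:
#'   `source_block`, `n_mentions`, `n_normalized`, `n_discarded`,
#'   `pct_discarded_of_total` (`NA` when there are no mentions).
#' @export
discard_accounting <- function(normalized, mentions = NULL) {
  if (!is.null(mentions) && nrow(mentions) != nrow(normalized)) {
    stop("normalized records (", nrow(normalized),
         ") do not match mentions (", nrow(mentions), ")")
  }
  total <- nrow(normalized)
  per <- normalized |>
    dplyr::group_by(.data$source_block) |>
    dplyr::summarise(
      n_mentions = dplyr::n(),
      n_normalized = sum(.data$status == "normalized"),
      n_discarded = sum(.data$status != "normalized"),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$source_block)
  all_row <- tibble::tibble(
    source_block = "total",
    n_mentions = total,
    n_normalized = sum(per$n_normalized),
    n_discarded = sum(per$n_discarded)
  )
  dplyr::bind_rows(per, all_row) |>
    dplyr::mutate(pct_discarded_of_total =
                    ifelse(total > 0, 100 * .data$n_discarded / total, NA_real_))
}
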
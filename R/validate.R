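# Proteome loading and the reference check at the heart of the pipeline:
# a gene-mutation pair survives only if at least one isoform of the gene
# carries the claimed reference residue (or, on the CDS, a degenerate codon
# encoding it) at the claimed position.

#' Load a validation proteome from FASTA
#'
#' Protein FASTA headers are `gene_id|isoform_id`; an optional CDS FASTA uses
#' identical headers. When a CDS is supplied it must be 3x the protein length
#' (optionally plus a trailing stop codon) and must translate to the protein
#' under the standard genetic code; violations are errors.
#'
#' @param protein_fasta Path to the protein FASTA.
#' @param cds_fasta Optional path to the matching CDS FASTA.
#' @return A tibble with columns `gene_id`, `isoform_id`, `protein` and
#'   `cds` (`NA` when absent).
#' @export
read_proteome <- function(protein_fasta, cds_fasta = NULL) {
  aa <- Biostrings::readAAStringSet(protein_fasta)
  hdr <- sub("\\s.*$", "", names(aa))
  parts <- stringr::str_split_fixed(hdr, stringr::fixed("|"), 2)
  if (any(!nzchar(parts[, 2]))) {
    stop("protein FASTA headers must be 'gene_id|isoform_id'")
  }
  prot <- tibble::tibble(
    gene_id = parts[, 1],
    isoform_id = parts[, 2],
    protein = toupper(as.character(aa)),
    cds = NA_character_
  )
  if (!is.null(cds_fasta)) {
    nt <- Biostrings::readDNAStringSet(cds_fasta)
    nhdr <- sub("\\s.*$", "", names(nt))
    nparts <- stringr::str_split_fixed(nhdr, stringr::fixed("|"), 2)
    cds_tbl <- tibble::tibble(gene_id = nparts[, 1], isoform_id = nparts[, 2],
                              cds_seq = toupper(as.character(nt)))
    prot <- dplyr::left_join(prot, cds_tbl, by = c("gene_id", "isoform_id")) |>
      dplyr::mutate(cds = .data$cds_seq, cds_seq = NULL)
    has <- !is.na(prot$cds)
    plen <- nchar(prot$protein[has])
    clen <- nchar(prot$cds[has])
    bad <- clen != 3 * plen & clen != 3 * (plen + 1)
    if (any(bad)) {
      stop("CDS length inconsistent with protein for: ",
           paste(paste0(prot$gene_id[has][bad], "|", prot$isoform_id[has][bad]),
                 collapse = ", "))
    }
    core <- substr(prot$cds[has], 1L, 3L * plen)
    trans <- as.character(Biostrings::translate(Biostrings::DNAStringSet(core)))
    mism <- trans != prot$protein[has]
    if (any(mism)) {
      stop("CDS does not translate to protein for: ",
           paste(paste0(prot$gene_id[has][mism], "|",
                        prot$isoform_id[has][mism]), collapse = ", "))
    }
  }
  prot
}

#' Check the claimed reference residue against a protein sequence
#'
#' `TRUE` iff `position` (1-based, residue 1 = first residue of the sequence
#' as supplied) lies within the protein and the residue there equals `ref`.
#' Out-of-range positions are `FALSE`, never an error. Vectorized over all
#' arguments.
#'
#' @param protein Protein sequence string(s) over the one-letter alphabet.
#' @param position 1-based residue position(s).
#' @param ref Claimed one-letter reference residue(s).
#' @return Logical vector.
#' @export
#' @examples
#' check_reference("MGGAV", 2, "G")
check_reference <- function(protein, position, ref) {
  position >= 1L & position <= nchar(protein) &
    substr(protein, position, position) == ref
}

#' Check the claimed reference residue against a CDS by degenerate codon
#'
#' `TRUE` iff the codon at nucleotides `[3(position-1)+1, 3*position]`
#' (1-based) belongs to the degenerate codon set of `ref` under the standard
#' genetic code (e.g. glycine accepts GGN). A trailing stop codon is
#' tolerated; out-of-range positions are `FALSE`. The check is codon-set
#' membership, not translation. Vectorized over all arguments.
#'
#' @param cds CDS nucleotide sequence string(s) (T or U alphabet).
#' @inheritParams check_reference
#' @return Logical vector.
#' @export
#' @examples
#' check_reference_codon("ATGGGA", 2, "G")
check_reference_codon <- function(cds, position, ref) {
  cds <- chartr("u", "T", chartr("U", "T", toupper(cds)))
  n_codons <- nchar(cds) %/% 3L
  codon <- substr(cds, 3L * (position - 1L) + 1L, 3L * position)
  sets <- degenerate_codon_table()
  member <- purrr::map2_lgl(codon, ref, function(cd, r) {
    cd %in% (sets[[r]] %||% character(0))
  })
  position >= 1L & position <= n_codons & member
}

#' Pair normalized mutations with candidate genes and validate
#'
#' Candidate pairs are the cross product, per document, of every gene entity
#' found in the document with every normalized mutation in the document. A
#' pair is kept iff at least one isoform of the gene passes
#' [check_reference()]; when a CDS is present the degenerate-codon check is
#' recorded as corroboration (`cds_corroborated`). Kept matches carry curator
#' metadata: how often the mutation was mentioned in the document, how many
#' genes in the document it validates against (the "possible in more than
#' one gene" alert), other validated mutations at the same residue of the
#' same gene, supporting strain/allele/method entities, and the verbatim
#' supporting sentences.
#'
#' @param normalized A normalized mention tibble (see [normalize_mentions()]).
#' @param entities An entity match tibble (see [match_entities()]).
#' @param proteome A proteome tibble (see [read_proteome()]).
#' @param sentences Optional sentence tibble; when given, supporting
#'   sentences are quoted verbatim in the output.
#' @param quiet Suppress the log line for genes absent from the proteome.
#' @return A tibble ordered by (`doc_id`, `gene_id`, `position`): `doc_id`,
#'   `gene_id`, `gene_symbol`, `canonical`, `position`, `ref`, `alt`,
#'   `valid_isoforms` (list), `cds_corroborated`, `mention_count`,
#'   `candidate_gene_count`, `similar_mutations` (list), `strains`,
#'   `alleles`, `methods`, `sentences` (list). Only verified pairs are
#'   materialized: `valid_isoforms` is never empty.
#' @export
pair_and_validate <- function(normalized, entities, proteome,
                              sentences = NULL, quiet = FALSE) {
  empty <- tibble::tibble(
    doc_id = character(), gene_id = character(), gene_symbol = character(),
    canonical = character(), position = integer(), ref = character(),
    alt = character(), valid_isoforms = list(), cds_corroborated = logical(),
    mention_count = integer(), candidate_gene_count = integer(),
    similar_mutations = list(), strains = character(), alleles = character(),
    methods = character(), sentences = list()
  )
  genes <- entities |>
    dplyr::filter(.data$entity_class == "gene") |>
    dplyr::group_by(.data$doc_id, .data$canonical_id) |>
    dplyr::summarise(gene_symbol = sort(unique(.data$surface_form))[1],
                     .groups = "drop") |>
    dplyr::rename(gene_id = "canonical_id")
  muts <- normalized |>
    dplyr::filter(.data$status == "normalized") |>
    dplyr::group_by(.data$doc_id, .data$canonical) |>
    dplyr::summarise(
      position = .data$position[1],
      ref = substr(.data$canonical[1], 1, 1),
      alt = substr(.data$canonical[1], nchar(.data$canonical[1]),
                   nchar(.data$canonical[1])),
      mention_count = dplyr::n(),
      sentence_ids = list(sort(unique(.data$sentence_id))),
      .groups = "drop"
    )
  if (nrow(genes) == 0L || nrow(muts) == 0L) return(empty)

  pairs <- dplyr::inner_join(genes, muts, by = "doc_id",
                             relationship = "many-to-many")
  known <- pairs$gene_id %in% proteome$gene_id
  if (any(!known) && !quiet) {
    skipped <- unique(pairs$gene_id[!known])
    message("skipping ", sum(!known), " candidate pair(s): gene(s) not in proteome: ",
            paste(skipped, collapse = ", "))
  }
  pairs <- pairs[known, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)

  iso_by_gene <- split(proteome, proteome$gene_id)
  checked <- purrr::map(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    iso <- iso_by_gene[[p$gene_id]]
    ok <- check_reference(iso$protein, p$position, p$ref)
    if (!any(ok)) return(NULL)
    has_cds <- !is.na(iso$cds)
    cds_ok <- if (any(has_cds)) {
      any(check_reference_codon(iso$cds[has_cds], p$position, p$ref))
    } else NA
    dplyr::mutate(p, valid_isoforms = list(iso$isoform_id[ok]),
                  cds_corroborated = cds_ok)
  }) |> dplyr::bind_rows()
  if (nrow(checked) == 0L) return(empty)

  checked <- checked |>
    dplyr::add_count(.data$doc_id, .data$canonical,
                     name = "candidate_gene_count") |>
    dplyr::group_by(.data$doc_id, .data$gene_id, .data$position) |>
    dplyr::mutate(similar_mutations = {
      cv <- .data$canonical
      purrr::map(cv, function(x) sort(setdiff(cv, x)))
    }) |>
    dplyr::ungroup()

  collapse_class <- function(cls) {
    entities |>
      dplyr::filter(.data$entity_class == cls) |>
      dplyr::group_by(.data$doc_id) |>
      dplyr::summarise(val = paste(sort(unique(.data$surface_form)),
                                   collapse = "; "), .groups = "drop")
  }
  for (cls in c("strain", "allele", "generation_method")) {
    nm <- c(strain = "strains", allele = "alleles",
            generation_method = "methods")[[cls]]
    tab <- collapse_class(cls)
    checked[[nm]] <- tab$val[match(checked$doc_id, tab$doc_id)]
    checked[[nm]][is.na(checked[[nm]])] <- ""
  }

  if (!is.null(sentences)) {
    key <- paste(sentences$doc_id, sentences$sentence_id)
    checked$sentences <- purrr::map2(checked$doc_id, checked$sentence_ids,
                                     function(d, ids) {
                                       sentences$text[match(paste(d, ids), key)]
                                     })
  } else {
    checked$sentences <- purrr::map(seq_len(nrow(checked)), ~ character(0))
  }

  checked |>
    dplyr::select("doc_id", "gene_id", "gene_symbol", "canonical", "position",
                  "ref", "alt", "valid_isoforms", "cds_corroborated",
                  "mention_count", "candidate_gene_count", "similar_mutations",
                  "strains", "alleles", "methods", "sentences") |>
    dplyr::arrange(.data$doc_id, .data$gene_id, .data$position)
}
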
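# Synthetic corpus generator: documents, dictionaries, proteome and gold
# annotations with known ground truth. Every planted mutation truly carries
# its reference residue in the generated proteome, so validation succeeds by
# construction; every decoy is constructed so that no gene mentioned in its
# document carries the claimed residue, so validation must reject it.

#' Specify a synthetic fixture corpus
#'
#' @param n_documents Number of documents.
#' @param n_genes Number of genes in the synthetic proteome.
#' @param protein_length_range Length range (residues) for generated
#'   proteins.
#' @param mutations_per_document Planted true mutations per document.
#' @param decoy_rate Fraction of sentences carrying mutation-shaped decoys
#'   that must not validate (wrong reference residue or out-of-range
#'   position, including cell-line-like identifiers such as "T47D").
#' @param random_seed Seed; identical seeds give byte-identical fixtures.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_documents = 20L, n_genes = 12L,
                         protein_length_range = c(120L, 300L),
                         mutations_per_document = 3L, decoy_rate = 0.2,
                         random_seed = 42L) {
  stopifnot(n_documents >= 0, n_genes >= 1,
            length(protein_length_range) == 2,
            protein_length_range[1] >= 10,
            protein_length_range[2] >= protein_length_range[1],
            mutations_per_document >= 0,
            decoy_rate >= 0, decoy_rate <= 1)
  structure(list(
    n_documents = as.integer(n_documents),
    n_genes = as.integer(n_genes),
    protein_length_range = as.integer(protein_length_range),
    mutations_per_document = as.integer(mutations_per_document),
    decoy_rate = decoy_rate,
    random_seed = as.integer(random_seed)
  ), class = "fixture_spec")
}

sample_codon <- function(residue) {
  set <- degenerate_codons(residue)
  set[sample.int(length(set), 1L)]
}

filler_pool <- c(
  "Worms were grown on NGM plates at 20 degrees.",
  "Animals were scored blind to genotype.",
  "All crosses were performed at least three times.",
  "Image acquisition used a spinning-disk confocal microscope.",
  "Statistical comparisons used a two-tailed t-test.",
  "Total RNA was extracted from synchronized L4 larvae.",
  "Transgenic lines were maintained as described previously.",
  "Behavioral assays were recorded for ten minutes per animal."
)

mutation_templates <- c(
  "The %s mutant allele carries the %s substitution and was generated by EMS mutagenesis.",
  "Sequencing of %s revealed the %s change in the affected strain.",
  "We recovered a %s allele carrying %s after ENU treatment.",
  "CRISPR-Cas9 editing of %s introduced the %s lesion."
)

decoy_templates <- c(
  "Control experiments were repeated in the %s cell background.",
  "Antibody staining followed the %s protocol described previously.",
  "The construct failed to rescue in the %s assay series."
)

surface_form_of <- function(ref, pos, alt, style) {
  three <- stats::setNames(amino_acid_table()$three_letter,
                           amino_acid_table()$one_letter)
  switch(style,
         one = paste0(ref, pos, alt),
         three_hyphen = paste0(three[[ref]], "-", pos, "-", three[[alt]]),
         three_concat = paste0(three[[ref]], pos, three[[alt]]))
}

#' Generate a synthetic fixture corpus with known ground truth
#'
#' Writes, under `dir`: `documents/doc*.txt`, dictionaries
#' (`dicts/genes.tsv`, `dicts/strains.tsv`, `dicts/methods.tsv`), a protein
#' FASTA and matching CDS FASTA (headers `gene_id|isoform_id`), the gold TSV
#' of planted gene-mutation pairs, and `decoys.tsv` listing the planted
#' non-validating decoys. Planted mentions cycle through the one-letter,
#' three-letter-hyphenated and three-letter-concatenated surface forms.
#' Generation is fully determined by the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written `paths`, plus tibbles `genes`,
#'   `planted`, `decoys` and the `spec`.
#' @export
generate_fixtures <- function(spec = fixture_spec(), dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(file.path(dir, "documents"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "dicts"), recursive = TRUE, showWarnings = FALSE)
  aa20 <- aa_one_letters()
  with_seed(spec$random_seed, {
    # --- proteome -----------------------------------------------------
    syll <- c("dpy", "unc", "mec", "lin", "egl", "che", "rol", "sma",
              "lon", "bli", "vab", "mab", "tra", "fem", "him", "srf")
    sym <- paste0(rep_len(syll, spec$n_genes), "-",
                  seq_len(spec$n_genes) + sample.int(40L, spec$n_genes, replace = TRUE))
    genes <- tibble::tibble(
      gene_symbol = sym,
      gene_id = sprintf("WBGene%08d", seq_len(spec$n_genes))
    )
    iso <- purrr::map(seq_len(spec$n_genes), function(i) {
      len <- sample(seq(spec$protein_length_range[1],
                        spec$protein_length_range[2]), 1L)
      prot_a <- paste(c("M", sample(aa20, len - 1L, replace = TRUE)),
                      collapse = "")
      rows <- tibble::tibble(gene_id = genes$gene_id[i], isoform_id = "a",
                             protein = prot_a)
      if (stats::runif(1) < 0.5) {
        chars <- strsplit(prot_a, "")[[1]]
        at <- sample(2:len, 3L)
        chars[at] <- sample(aa20, 3L, replace = TRUE)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          gene_id = genes$gene_id[i], isoform_id = "b",
          protein = paste(chars, collapse = "")))
      }
      rows
    }) |> dplyr::bind_rows()
    iso$cds <- vapply(iso$protein, function(p) {
      codons <- vapply(strsplit(p, "")[[1]], sample_codon, character(1))
      paste0(paste(codons, collapse = ""), sample_codon("*"))
    }, character(1), USE.NAMES = FALSE)

    strains <- sprintf("CB%d", 1000L + sample.int(8000L, 6L))
    methods <- c("EMS", "ENU", "CRISPR-Cas9")

    # --- documents ----------------------------------------------------
    planted <- list()
    decoys <- list()
    doc_texts <- character(spec$n_documents)
    doc_ids <- sprintf("doc%02d", seq_len(spec$n_documents))
    for (d in seq_len(spec$n_documents)) {
      gsel <- genes[sample.int(spec$n_genes, min(2L, spec$n_genes)), ]
      doc_iso <- iso[iso$gene_id %in% gsel$gene_id, ]
      max_pos <- min(nchar(doc_iso$protein))
      if (spec$mutations_per_document > max_pos - 1L) {
        stop("mutations_per_document (", spec$mutations_per_document,
             ") exceeds achievable positions (", max_pos - 1L, ")")
      }
      sents <- sprintf("We characterized mutations in %s in strain %s.",
                       paste(gsel$gene_symbol, collapse = " and "),
                       strains[sample.int(length(strains), 1L)])
      styles <- c("one", "three_hyphen", "three_concat")
      used_pos <- integer(0)
      m <- spec$mutations_per_document
      if (m > 0L) {
        for (j in seq_len(m)) {
          g <- gsel[1L + (j - 1L) %% nrow(gsel), ]
          prot <- iso$protein[iso$gene_id == g$gene_id & iso$isoform_id == "a"]
          repeat {
            pos <- sample(2:nchar(prot), 1L)
            if (!pos %in% used_pos) break
          }
          used_pos <- c(used_pos, pos)
          ref <- substr(prot, pos, pos)
          alt <- sample(setdiff(aa20, ref), 1L)
          style <- styles[1L + (j - 1L) %% 3L]
          mention <- surface_form_of(ref, pos, alt, style)
          tmpl <- mutation_templates[sample.int(length(mutation_templates), 1L)]
          sents <- c(sents, sprintf(tmpl, g$gene_symbol, mention))
          planted[[length(planted) + 1L]] <- tibble::tibble(
            doc_id = doc_ids[d], gene_symbol = g$gene_symbol,
            gene_id = g$gene_id, mutation = paste0(ref, pos, alt),
            surface_form = mention, style = style, position = pos
          )
        }
      }
      sents <- c(sents, sample(filler_pool, 2L))
      n_base <- length(sents)
      n_decoy <- round(spec$decoy_rate / (1 - min(spec$decoy_rate, 0.99)) * n_base)
      for (k in seq_len(n_decoy)) {
        # residue claimed by the decoy must be wrong in every isoform of
        # every gene mentioned in this document, at an in-range position
        pos <- sample(2:max_pos, 1L)
        present <- unique(substr(doc_iso$protein, pos, pos))
        ref <- sample(setdiff(aa20, present), 1L)
        alt <- sample(setdiff(aa20, ref), 1L)
        decoy <- paste0(ref, pos, alt)
        tmpl <- decoy_templates[sample.int(length(decoy_templates), 1L)]
        sents <- c(sents, sprintf(tmpl, decoy))
        decoys[[length(decoys) + 1L]] <- tibble::tibble(
          doc_id = doc_ids[d], mutation = decoy, position = pos)
      }
      doc_texts[d] <- paste(sents, collapse = " ")
    }

    planted <- dplyr::bind_rows(planted) %||% tibble::tibble()
    decoys <- dplyr::bind_rows(decoys) %||% tibble::tibble()
    if (nrow(planted) == 0L) {
      planted <- tibble::tibble(doc_id = character(), gene_symbol = character(),
                                gene_id = character(), mutation = character(),
                                surface_form = character(), style = character(),
                                position = integer())
    }
    if (nrow(decoys) == 0L) {
      decoys <- tibble::tibble(doc_id = character(), mutation = character(),
                               position = integer())
    }

    # --- write everything (fixed order, LF endings) -------------------
    doc_paths <- file.path(dir, "documents", paste0(doc_ids, ".txt"))
    for (d in seq_along(doc_paths)) {
      writeLines(doc_texts[d], doc_paths[d], useBytes = TRUE)
    }
    write_tsv_plain <- function(df, path) {
      lines <- c(paste(names(df), collapse = "\t"),
                 do.call(paste, c(unname(as.list(df)), sep = "\t")))
      if (nrow(df) == 0L) lines <- lines[1]
      writeLines(lines, path, useBytes = TRUE)
    }
    gene_dict <- tibble::tibble(surface_form = genes$gene_symbol,
                                canonical_id = genes$gene_id,
                                entity_class = "gene")
    strain_dict <- tibble::tibble(surface_form = strains,
                                  canonical_id = strains,
                                  entity_class = "strain")
    method_dict <- tibble::tibble(surface_form = methods,
                                  canonical_id = toupper(methods),
                                  entity_class = "generation_method")
    dict_paths <- file.path(dir, "dicts",
                            c("genes.tsv", "strains.tsv", "methods.tsv"))
    write_tsv_plain(gene_dict, dict_paths[1])
    write_tsv_plain(strain_dict, dict_paths[2])
    write_tsv_plain(method_dict, dict_paths[3])

    write_fasta <- function(headers, seqs, path, width = 60L) {
      lines <- purrr::map2(headers, seqs, function(h, s) {
        c(paste0(">", h),
          substring(s, seq(1L, nchar(s), width),
                    pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))))
      })
      writeLines(unlist(lines), path, useBytes = TRUE)
    }
    hdr <- paste0(iso$gene_id, "|", iso$isoform_id)
    protein_fasta <- file.path(dir, "proteome_protein.fasta")
    cds_fasta <- file.path(dir, "proteome_cds.fasta")
    write_fasta(hdr, iso$protein, protein_fasta)
    write_fasta(hdr, iso$cds, cds_fasta)

    gold_path <- file.path(dir, "gold.tsv")
    write_tsv_plain(planted[c("doc_id", "gene_symbol", "mutation")], gold_path)
    decoy_path <- file.path(dir, "decoys.tsv")
    write_tsv_plain(decoys, decoy_path)

    invisible(list(
      paths = list(documents = doc_paths, dicts = dict_paths,
                   protein_fasta = protein_fasta, cds_fasta = cds_fasta,
                   gold = gold_path, decoys = decoy_path),
      genes = genes, isoforms = iso, planted = planted, decoys = decoys,
      spec = spec
    ))
  })
}
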
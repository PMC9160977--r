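# A tiny hand-built proteome: mec-5-like gene with Gly at 109, a second
# gene sharing Gly at 359 so one mutation can validate in two genes.
toy_protein <- function(len, fixed = list()) {
  chars <- rep("A", len)
  chars[1] <- "M"
  for (pos in names(fixed)) chars[as.integer(pos)] <- fixed[[pos]]
  paste(chars, collapse = "")
}

toy_proteome <- function() {
  tibble::tibble(
    gene_id = c("WBGene1", "WBGene1", "WBGene2"),
    isoform_id = c("a", "b", "a"),
    protein = c(toy_protein(400, list(`109` = "G", `218` = "G", `359` = "G")),
                toy_protein(200, list(`109` = "G")),
                toy_protein(400, list(`359` = "G"))),
    cds = NA_character_
  )
}

toy_dict_path <- function() {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("surface_form\tcanonical_id\tentity_class",
               "mec-5\tWBGene1\tgene",
               "unc-99\tWBGene2\tgene"), path)
  path
}

validate_doc <- function(text, proteome = toy_proteome(), quiet = TRUE) {
  sentences <- segment_sentences(text, "p1")
  normalized <- normalize_mentions(extract_mentions(sentences))
  entities <- match_entities(sentences, load_dictionaries(toy_dict_path()))
  pair_and_validate(normalized, entities, proteome, sentences = sentences,
                    quiet = quiet)
}

test_that("check_reference verifies the claimed residue, out-of-range is FALSE", {
  prot <- toy_protein(200, list(`109` = "G"))
  expect_true(check_reference(prot, 109, "G"))
  expect_false(check_reference(prot, 109, "A"))
  expect_false(check_reference(prot, 109, "E"))
  expect_false(check_reference(toy_protein(50), 109, "G"))
  expect_false(check_reference(prot, 0, "M"))
  expect_true(check_reference(prot, 1, "M"))
})

test_that("check_reference_codon accepts exactly the degenerate codon set", {
  cds <- paste0("ATG", strrep("GCT", 107), "GGA", "TAA")  # codon 109 = GGA
  expect_true(check_reference_codon(cds, 109, "G"))
  expect_false(check_reference_codon(cds, 109, "A"))
  expect_false(check_reference_codon(cds, 500, "G"))
  expect_setequal(degenerate_codons("G"), c("GGT", "GGC", "GGA", "GGG"))
  expect_setequal(degenerate_codons("*"), c("TAA", "TAG", "TGA"))
  # RNA alphabet tolerated
  expect_true(check_reference_codon("AUGGGA", 2, "G"))
})

test_that("codon check agrees with a translate-then-compare oracle", {
  set.seed(101)
  aa21 <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")
  for (i in 1:300) {
    cds <- random_cds(sample(5:40, 1))
    pos <- sample(1:45, 1)
    ref <- sample(aa21, 1)
    expect_identical(unname(check_reference_codon(cds, pos, ref)),
                     oracle_codon_check(cds, pos, ref),
                     info = paste(cds, pos, ref))
  }
})

test_that("proteome FASTA loading validates headers and CDS consistency", {
  fx <- default_fixture()
  prot <- read_proteome(fx$paths$protein_fasta, fx$paths$cds_fasta)
  expect_true(all(c("gene_id", "isoform_id", "protein", "cds") %in% names(prot)))
  expect_true(all(!is.na(prot$cds)))

  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">gene_without_isoform", "MATTS"), bad)
  expect_error(read_proteome(bad), "gene_id\\|isoform_id")

  p <- tempfile(fileext = ".fasta"); c2 <- tempfile(fileext = ".fasta")
  writeLines(c(">g|a", "MG"), p)
  writeLines(c(">g|a", "ATGGGTTT"), c2)   # not 3n or 3(n+1)
  expect_error(read_proteome(p, c2), "length")
  writeLines(c(">g|a", "ATGCCT"), c2)     # translates to MP, not MG
  expect_error(read_proteome(p, c2), "translate")
})

test_that("pairing keeps only reference-verified gene-mutation pairs", {
  m <- validate_doc("The mec-5 allele carries G109E. It was outcrossed.")
  expect_equal(nrow(m), 1L)
  expect_equal(m$gene_id, "WBGene1")
  expect_setequal(m$valid_isoforms[[1]], c("a", "b"))
  expect_equal(m$mention_count, 1L)
  expect_equal(m$candidate_gene_count, 1L)
  # verbatim supporting sentence
  expect_equal(m$sentences[[1]], "The mec-5 allele carries G109E.")

  # wrong reference residue: dropped entirely
  expect_equal(nrow(validate_doc("The mec-5 allele carries E109K.")), 0L)
})

test_that("a mutation validating in two genes alerts the curator", {
  m <- validate_doc("Both mec-5 and unc-99 appear here. The G359A lesion was mapped.")
  expect_equal(nrow(m), 2L)
  expect_setequal(m$gene_id, c("WBGene1", "WBGene2"))
  expect_equal(m$candidate_gene_count, c(2L, 2L))
})

test_that("similar mutations at the same residue are cross-listed", {
  m <- validate_doc("The mec-5 mutants G218D and G218L behaved differently.")
  expect_equal(nrow(m), 2L)
  expect_equal(m$similar_mutations[[1]], "G218L")
  expect_equal(m$similar_mutations[[2]], "G218D")
})

test_that("genes missing from the proteome are skipped with a log line", {
  proteome <- toy_proteome()[3, ]  # drop WBGene1
  expect_message(
    m <- validate_doc("The mec-5 allele carries G109E.", proteome = proteome,
                      quiet = FALSE),
    "not in proteome")
  expect_equal(nrow(m), 0L)
})

test_that("adding isoforms never invalidates a match", {
  set.seed(202)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:20) {
    base <- paste(sample(aa20, 60, replace = TRUE), collapse = "")
    pos <- sample(1:60, 1)
    ref <- substr(base, pos, pos)
    prot1 <- tibble::tibble(gene_id = "g", isoform_id = "a",
                            protein = base, cds = NA_character_)
    extra <- tibble::tibble(gene_id = "g", isoform_id = "b",
                            protein = paste(sample(aa20, 40, replace = TRUE),
                                            collapse = ""),
                            cds = NA_character_)
    iso1 <- prot1$isoform_id[check_reference(prot1$protein, pos, ref)]
    both <- dplyr::bind_rows(prot1, extra)
    iso2 <- both$isoform_id[check_reference(both$protein, pos, ref)]
    expect_true(all(iso1 %in% iso2))
    expect_true(length(iso2) >= length(iso1))
  }
})

test_that("fixture decoys are rejected and planted pairs validate", {
  fx <- default_fixture()
  sentences <- read_documents(fx$paths$documents)
  normalized <- normalize_mentions(extract_mentions(sentences))
  dict <- load_dictionaries(fx$paths$dicts)
  proteome <- read_proteome(fx$paths$protein_fasta, fx$paths$cds_fasta)
  matches <- pair_and_validate(normalized, entities = match_entities(sentences, dict),
                               proteome = proteome, sentences = sentences,
                               quiet = TRUE)
  expect_true(all(lengths(matches$valid_isoforms) >= 1L))
  # soundness: every planted pair is present
  got <- paste(matches$doc_id, tolower(matches$gene_symbol), matches$canonical)
  want <- paste(fx$planted$doc_id, tolower(fx$planted$gene_symbol),
                fx$planted$mutation)
  expect_true(all(want %in% got))
  # every decoy is absent
  decoy_keys <- paste(fx$decoys$doc_id, fx$decoys$mutation)
  expect_false(any(paste(matches$doc_id, matches$canonical) %in% decoy_keys))
  # CDS corroboration agrees with the protein-level decision
  expect_true(all(matches$cds_corroborated))
})
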
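test_that("regex block captures the standard structured mention shapes", {
  cases <- list(
    list("We collected basic mutations (e.g. Q115P) from publications.",
         "protein_substitution", "Q", 115L, "P", "Q115P"),
    list("The location was given as relative location eg. Arg-107-Cys.",
         "protein_substitution", "Arg", 107L, "Cys", "Arg-107-Cys"),
    list("the same mutation G359A was studied",
         "protein_substitution", "G", 359L, "A", "G359A"),
    list("Sequencing revealed Arg107Cys in two animals.",
         "protein_substitution", "Arg", 107L, "Cys", "Arg107Cys"),
    list("A change written Gly12→Ala was reported.",
         "protein_substitution", "Gly", 12L, "Ala", "Gly12→Ala"),
    list("Also written G12->A in the text.",
         "protein_substitution", "G", 12L, "A", "G12->A"),
    list("The transcript carries c.123A>G in all clones.",
         "dna_substitution", "A", 123L, "G", "c.123A>G"),
    list("The premature stop W123* truncates the protein.",
         "nonsense", "W", 123L, "*", "W123*"),
    list("An amber allele Q123X was recovered.",
         "nonsense", "Q", 123L, "X", "Q123X")
  )
  for (cs in cases) {
    m <- extract_regex(sent(cs[[1]]))
    expect_equal(nrow(m), 1L, info = cs[[1]])
    expect_equal(m$mention_kind, cs[[2]], info = cs[[1]])
    expect_equal(m$ref, cs[[3]], info = cs[[1]])
    expect_equal(m$pos, cs[[4]], info = cs[[1]])
    expect_equal(m$alt, cs[[5]], info = cs[[1]])
    expect_equal(m$raw_text, cs[[6]], info = cs[[1]])
    expect_equal(m$source_block, "regex")
  }
})

test_that("regex block stays silent on mutation-free text and lowercase shapes", {
  expect_equal(nrow(extract_regex(sent("The worms were grown at 20 degrees."))), 0L)
  expect_equal(nrow(extract_regex(sent("the token g109e is not a mention"))), 0L)
})

test_that("deletion and insertion tokens are flagged without components", {
  m <- extract_regex(sent("The allele carries E746del in exon 19."))
  expect_equal(m$mention_kind, "deletion")
  expect_true(is.na(m$ref) && is.na(m$alt))
  m2 <- extract_regex(sent("An insertion allele 1153ins was reported."))
  expect_equal(m2$mention_kind, "insertion")
})

test_that("overlapping matches resolve longest-first with span fidelity", {
  s <- sent("The Arg-107-Cys substitution was confirmed.")
  m <- extract_regex(s)
  expect_equal(nrow(m), 1L)
  expect_equal(m$raw_text, "Arg-107-Cys")
  # span fidelity + pairwise disjoint spans on a mention-dense sentence
  s2 <- sent("We saw G359A, Arg107Cys and W12* plus c.5A>T together.")
  m2 <- extract_regex(s2)
  expect_true(nrow(m2) >= 4)
  for (i in seq_len(nrow(m2))) {
    expect_identical(substr(s2$text, m2$start[i] + 1L, m2$end[i]),
                     m2$raw_text[i])
  }
  sp <- m2[order(m2$start), ]
  expect_true(all(sp$start[-1] >= sp$end[-nrow(sp)]))
})

test_that("natural-language templates parse both argument orders", {
  m <- extract_natural_language(
    sent("We found a glycine to arginine substitution at codon 20."))
  expect_equal(nrow(m), 1L)
  expect_equal(tolower(m$ref), "glycine")
  expect_equal(m$pos, 20L)
  expect_equal(tolower(m$alt), "arginine")
  expect_equal(m$mention_kind, "natural_language_substitution")
  expect_equal(m$source_block, "natural_language")

  # passive, alt named second: ref = glutamic acid, alt = valine
  m2 <- extract_natural_language(
    sent("Here glutamic acid was substituted by valine at residue 6."))
  expect_equal(tolower(m2$ref), "glutamic acid")
  expect_equal(m2$pos, 6L)
  expect_equal(tolower(m2$alt), "valine")

  # alt-first order
  m3 <- extract_natural_language(
    sent("They engineered a valine for glutamic acid substitution at residue 6."))
  expect_equal(tolower(m3$ref), "glutamic acid")
  expect_equal(tolower(m3$alt), "valine")

  # indel phrase flagged without components
  m4 <- extract_natural_language(
    sent("We made a deletion of 10 and 8 residues from the N- and C-terminals."))
  expect_equal(nrow(m4), 1L)
  expect_equal(m4$mention_kind, "deletion")
  expect_true(is.na(m4$ref))
})

test_that("the gate sends a sentence to the NL block only when regex finds nothing", {
  both <- sents(c(
    "Both Q115P and a glycine to arginine substitution at codon 20 appear here.",
    "Only a glycine to arginine substitution at codon 20 appears here.",
    "Nothing to see here."
  ))
  m <- extract_mentions(both)
  s0 <- m[m$sentence_id == 0L, ]
  expect_equal(s0$source_block, "regex")
  expect_equal(s0$raw_text, "Q115P")
  s1 <- m[m$sentence_id == 1L, ]
  expect_equal(s1$source_block, "natural_language")
  expect_equal(nrow(m[m$sentence_id == 2L, ]), 0L)

  # gating property: no sentence contributes from both blocks
  per_sent <- split(m$source_block, m$sentence_id)
  expect_true(all(vapply(per_sent, function(x) length(unique(x)) == 1L,
                         logical(1))))

  # config contract: NL block off
  m_off <- extract_mentions(both, use_nl_block = FALSE)
  expect_true(all(m_off$source_block == "regex"))

  # empty document
  expect_equal(nrow(extract_mentions(segment_sentences(""))), 0L)
})

test_that("a plugin tagger replaces the NL block on regex-silent sentences", {
  tagger <- function(sentence) {
    hit <- regexpr("special", sentence$text, fixed = TRUE)
    if (hit < 0) return(NULL)
    tibble::tibble(
      doc_id = sentence$doc_id, sentence_id = sentence$sentence_id,
      start = as.integer(hit) - 1L,
      end = as.integer(hit) + attr(hit, "match.length") - 1L,
      raw_text = "special", source_block = "plugin",
      mention_kind = "other", pattern_id = "demo",
      ref = NA_character_, pos = NA_integer_, alt = NA_character_)
  }
  s <- sents(c("This one is special.", "This one has G359A and special."))
  m <- extract_mentions(s, plugin = tagger)
  expect_equal(m$source_block[m$sentence_id == 0L], "plugin")
  # regex hit gates the plugin out of sentence 1
  expect_equal(m$source_block[m$sentence_id == 1L], "regex")
})

test_that("all planted structured surface forms are recovered on fixtures", {
  fx <- default_fixture()
  sentences <- read_documents(fx$paths$documents)
  mentions <- extract_mentions(sentences)
  expect_setequal(unique(fx$planted$style),
                  c("one", "three_hyphen", "three_concat"))
  found <- paste(mentions$doc_id, mentions$raw_text)
  expect_true(all(paste(fx$planted$doc_id, fx$planted$surface_form) %in% found))
  # span fidelity across the whole fixture corpus
  key <- paste(sentences$doc_id, sentences$sentence_id)
  stext <- sentences$text[match(paste(mentions$doc_id, mentions$sentence_id), key)]
  expect_identical(substr(stext, mentions$start + 1L, mentions$end),
                   mentions$raw_text)
})
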
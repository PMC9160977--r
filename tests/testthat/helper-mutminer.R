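# Shared test helpers: quick sentence rows, a memoized default fixture
# corpus, and a brute-force translation oracle independent of the
# degenerate-codon validator.

sent <- function(text, doc_id = "d", sentence_id = 0L) {
  tibble::tibble(doc_id = doc_id, sentence_id = sentence_id,
                 start = 0L, end = nchar(text), text = text)
}

sents <- function(texts, doc_id = "d") {
  tibble::tibble(doc_id = doc_id, sentence_id = seq_along(texts) - 1L,
                 start = 0L, end = nchar(texts), text = texts)
}

# One fixture corpus at the package's default study conditions, generated
# once per test run and shared read-only across tests.
.fixture_cache <- new.env(parent = emptyenv())
default_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    dir <- file.path(tempdir(), "mutminer-fixture-default")
    unlink(dir, recursive = TRUE)
    .fixture_cache$fx <- generate_fixtures(fixture_spec(), dir)
    .fixture_cache$dir <- dir
  }
  .fixture_cache$fx
}

fixture_doc_paths <- function(fx) fx$paths$documents

# Independent oracle: translate a CDS with Biostrings and compare the
# residue at `position` with `ref` (never uses degenerate codon sets).
oracle_codon_check <- function(cds, position, ref) {
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1, 3 * (nchar(cds) %/% 3))),
    no.init.codon = TRUE))
  position >= 1 && position <= nchar(prot) &&
    substr(prot, position, position) == ref
}

random_cds <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
        collapse = "")
}
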
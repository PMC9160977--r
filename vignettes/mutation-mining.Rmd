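---
title: "Mining and validating protein-coding mutation mentions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating protein-coding mutation mentions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mutminer)
```

## The problem and the model

Curators of model-organism databases extract sequence variants from papers
by hand. The bottleneck is mechanical: most protein-coding variants are
written either as structured tokens (`Q115P`, `Arg-107-Cys`, `c.123A>G`)
or as a narrow family of natural-language phrases ("glycine to arginine
substitution at codon 20"). `mutminer` implements a hybrid extraction and
validation pipeline around three ideas:

1. **Two extraction blocks with a gate.** An ordered regular-expression
   block handles structured mentions; a rule-based natural-language block
   handles the phrasal forms. A sentence reaches the natural-language block
   *only if* the regex block found nothing in it. The gate is per sentence,
   so a document can mix both kinds, but no single sentence is
   double-reported by the two blocks.
2. **One canonical form.** Every substitution mention is normalized to
   `<REF><POS><ALT>` over the 20 one-letter amino-acid codes plus `*` for
   stop, or discarded with an explicit machine-readable reason. Downstream
   pairing and evaluation operate only on this form.
3. **Sequence validation as the precision filter.** Text alone cannot tell
   a mutation from a cell-line identifier such as `T47D`, and cannot tell
   which of several genes in a paper a mutation belongs to. The pipeline
   therefore pairs every gene entity in a document with every normalized
   mutation in that document and keeps a pair only if at least one isoform
   of the gene carries the claimed reference residue at the claimed
   position. Only verified pairs reach the curator.

## Extraction

The pattern set ships as an ordered TSV (`inst/extdata/patterns.tsv`) with
PCRE named groups for the `ref`/`pos`/`alt` components; `{AA1}`, `{AA3}`
and `{AAFULL}` placeholders expand from the amino-acid table. Supported
shapes: one-letter `X123Y`, three-letter concatenated and hyphenated
(`Arg107Cys`, `Arg-107-Cys`), full-name hyphen forms, arrow connectors
(`G12->A`, `Gly12→Ala`, both ASCII and Unicode arrows), nucleotide
`c.123A>G` and bare `123A>G`, nonsense `Q123*` / `Q123X`, and simple
`del`/`ins` tokens attached to positions.

Three matching policies matter in practice:

* **Case.** One-letter patterns are case-sensitive uppercase: lowercase
  `g109e`-shaped strings are overwhelmingly false positives. Three-letter
  and full-name forms match case-insensitively.
* **Overlaps.** All pattern hits in a sentence are pooled and resolved
  longest-match-first, ties by leftmost start, then by pattern order, so
  `Arg-107-Cys` yields one mention rather than fragments.
* **Ambiguity.** A token like `G359A` is valid both as a protein
  substitution and as nucleotide shorthand. It is emitted once, as a
  protein substitution: the pipeline targets protein-coding variants, and
  the sequence validation step arbitrates truth anyway.

```{r}
s <- segment_sentences(
  "The same mutation G359A was studied. Here glutamic acid was substituted by valine at residue 6.")
extract_mentions(s)[, c("sentence_id", "raw_text", "source_block", "mention_kind")]
```

The natural-language block is a deliberate, rule-based stand-in for a
learned tagger: template grammars over the lexicon
(`inst/extdata/lexicon.tsv`) cover active ("X to Y substitution at codon
N"), passive ("X was substituted by Y at residue N" — the named-first
residue is the reference), of-forms ("substitution of X by Y...") and the
alt-first "Y for X substitution" order, plus component-less
deletion/insertion phrases. A `plugin` argument on `extract_mentions()`
accepts any function from a sentence row to a mention tibble, so a trained
tagger can be slotted in without touching the rest of the pipeline; the
gate applies to it identically.

## Normalization

`normalize_mentions()` maps components through the standard three-letter /
full-name table (aspartate/glutamate synonyms included; amber, ochre and
opal map to `*`). Design points:

* Indel and nucleotide-level mentions are *carried*, not dropped: they get
  `status = "discarded_unsupported"` with a reason, so the per-block
  accounting (`discard_accounting()`) can reproduce a run report in which
  most natural-language output is ignored while nothing silently vanishes.
* Positions are kept exactly as authors wrote them — no initiator-methionine
  renumbering. The validation step absorbs numbering ambiguity by checking
  "at least one isoform".
* Selenocysteine and pyrrolysine are rejected as unknown tokens: the
  canonical universe here is the 20 standard residues plus stop.
* Normalization is idempotent: a canonical string re-extracted as a mention
  normalizes to itself.

## Validation

`check_reference()` is the authoritative test: 1-based position, residue 1
is the first residue of the isoform as supplied in the FASTA. Out-of-range
positions are `FALSE`, never errors — a claimed position past the end of
every isoform is simply an unverifiable claim. When a CDS is available,
`check_reference_codon()` tests degenerate-codon-set membership (glycine
accepts `GGN`) and is recorded as corroboration; it is implemented as set
membership, not translation, so tests can compare it against an independent
translate-then-compare oracle. The alternate residue is deliberately not
checked: only the reference state exists in the database before the edit.

Pairing scope is the whole document, not the sentence, because curation and
evaluation both work per paper: that is also what makes the multi-gene
alert meaningful ("G359A is possible in two genes *in this paper*").
Unvalidated pairs are dropped with a log line rather than shown at lower
confidence; the output contract is that `valid_isoforms` is never empty.

## Evaluation and reporting

The evaluation unit is the (document, gene, canonical mutation) triple,
case-insensitive on the gene symbol. Precision, recall and F1 are kept as
exact fractions; a metric whose denominator is zero is `NA`/`null`, never
zero. Printed percentages are *truncated* at the reported number of
decimals rather than rounded, so a displayed precision never overstates the
computed fraction (807/977 = 82.5998% displays as 82.59%).

`write_report()` emits the curator records with a fixed column order and
deterministic row order (document, gene, position); identical inputs give
byte-identical files.

## The synthetic corpus

`generate_fixtures()` emulates the one thing that matters for end-to-end
verification: documents whose ground truth is known *by construction*. For
every planted mutation the generated isoform really carries the reference
residue at the stated position (the CDS is sampled per-residue from the
degenerate codon sets, then capped with a stop codon), and every decoy is
mutation-shaped but claims a residue that is wrong in every isoform of
every gene mentioned in its document, so the validator must reject it.
Planted mentions cycle through the one-letter, three-letter-hyphenated and
three-letter-concatenated surface forms.

Defaults are the package's study conditions: 20 documents, 12 genes,
proteins of 120–300 residues, 3 planted mutations per document, decoy rate
0.2 (the fraction of sentences carrying a decoy), seed 42. These sizes keep
a full end-to-end run around a second while still exercising every surface
form, both dictionary classes of interest, and the decoy path in every
document.

What passing on fixtures does **not** show: real papers contain mutations
in tables and figures (invisible to any plain-text pipeline), natural-
language phrasings outside the template family, author errors in positions
or residues, and genome-version ambiguity. Fixture recall of 1.0 is a
statement about the pipeline's mechanics, not about recall on literature.

## Numerical and degenerate-input choices

* Offsets are 0-based half-open everywhere; sentence spans index the
  document, mention/entity spans index the sentence. One convention,
  asserted by span-fidelity tests.
* Sentence segmentation is rule-based (terminal punctuation, abbreviation
  stop-list, single-letter-initial suppression so "C. elegans" holds
  together, no split before a lowercase continuation). It is deterministic
  and offset-stable; no equivalence with any particular tokenizer is
  claimed, and genuinely ambiguous period placements (a sentence ending in
  the numeral "I.") resolve toward not splitting.
* Empty documents, empty dictionaries, empty mention sets and zero-match
  runs all produce typed empty outputs, not errors; metric denominators of
  zero produce `NA`.
* Dictionary matching is whole-token with class-specific case rules:
  genes/strains/alleles case-insensitive (reported with dictionary casing),
  all-caps method/variation acronyms (EMS, ENU) case-sensitive so "ems"
  prose does not fire. No fuzzy matching.

## Known limitations

* The natural-language block is intentionally narrow; recall on free-form
  phrasings depends on the plugin seam.
* DNA-level mentions are extracted but not normalized or validated in this
  version; they are visible in the discard accounting.
* Gene symbols are matched by dictionary lookup only — no disambiguation
  across species or families beyond what validation filters out.
* Complex indels (`deletion of 10 and 8 residues...`) are flagged, never
  parsed.
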
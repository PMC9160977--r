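# mutminer

Biocuration teams at model-organism databases read every new paper to pull
out sequence variants by hand. Most protein-coding variants appear in text
in a small number of surface forms — structured tokens like `Q115P` or
`Arg-107-Cys`, or natural-language phrases like "glycine to arginine
substitution at codon 20" — and a large fraction of the curation effort is
mechanical: find the mention, canonicalize it, work out which gene it
belongs to, and check that the claim is even possible against the reference
proteome. `mutminer` automates exactly that triage step for plain-text
papers, producing curator-ready structured output rather than database
writes: the curator stays the arbiter.

## What it does

1. **Sentence segmentation** with stable character offsets
   (rule-based, abbreviation-aware, deterministic).
2. **Hybrid mention extraction.** An ordered regular-expression block
   catches structured mentions (`X123Y`, `Xxx123Yyy`, `Xxx-123-Yyy`,
   arrow forms, `c.123A>G`, nonsense `Q123*`/`Q123X`, simple `del`/`ins`
   tokens). A sentence is handed to the rule-based natural-language block
   *only if* the regex block found nothing in it — the gate that keeps the
   two blocks from double-reporting. A plugin seam accepts an external
   tagger in place of the shipped natural-language rules.
3. **Normalization** of every mention to the canonical one-letter form
   `<REF><POS><ALT>` (e.g. `V600E`), or an explicit discard with a reason
   (indels, nucleotide-level mentions, incomplete components).
4. **Dictionary entity linking** for genes, strains, alleles, variation
   types and generation methods (whole-token, case rules per class).
5. **Sequence validation.** Candidate pairs are (every gene in the
   document) × (every normalized mutation in the document). A pair survives
   only if at least one isoform of the gene carries the claimed reference
   residue at the claimed position — for MEC-5 G109E, some transcript must
   encode glycine (a `GGN` codon) at codon 109. With a CDS supplied, the
   degenerate-codon check is recorded as corroboration.
6. **Curator metadata and evaluation**: per-match mention counts,
   multi-gene alerts (`candidate_gene_count`), similar mutations at the
   same residue (e.g. `G218D`/`G218L`), verbatim supporting sentences, and
   precision/recall/F1 against gold annotations, where a match is the
   (document, gene, canonical mutation) triple.

A deterministic synthetic-corpus generator (`generate_fixtures()`) plants
mutations whose reference residues are true by construction and decoys that
must fail validation, so the whole pipeline is testable end to end with
known ground truth.

## Worked example

```r
library(mutminer)

fx <- generate_fixtures(fixture_spec(n_documents = 3, random_seed = 5),
                        tempfile())
run <- run_pipeline(fx$paths$documents, fx$paths$protein_fasta,
                    fx$paths$dicts, cds_fasta = fx$paths$cds_fasta,
                    gold_path = fx$paths$gold)
run
#> Mutation-mining run
#>   Corpus: 3 document(s), 24 sentence(s)
#>   Mentions: 15 total (15 regex, 0 natural language)
#>   Normalized: 15; discarded: 0 (0.0% of all mentions)
#>   Validated gene-mutation matches: 10
#>   Evaluation: TP 9, FP 1, FN 0; precision 90.00%, recall 100.00%
```

All 9 planted gene-mutation pairs are recovered (recall 1.0); the decoy
mentions are rejected by the reference check; the single false positive is
a planted mutation that also happens to validate in the document's second
gene — exactly the multi-gene situation the `candidate_gene_count` column
flags for the curator. `tidy(run)` returns the curator records as a tibble,
`glance(run)` the run counts, `autoplot(run)` a mention-outcome plot, and
`write_report(run$matches, "records.tsv")` the structured output file.

Normalization of the classic surface forms:

```r
s <- segment_sentences("We found a glycine to arginine substitution at codon 20.")
normalize_mentions(extract_mentions(s))$canonical
#> [1] "G20R"
```

A thin command-line front end with `extract`, `curate`, `evaluate` and
`fixtures` subcommands is installed at `inst/cli/mutminer.R`.

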
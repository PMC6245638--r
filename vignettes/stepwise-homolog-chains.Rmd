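---
title: "Step-wise homolog chains: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step-wise homolog chains: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthopath)
library(dplyr)
```

## The problem and the model

Orthology between two proteomes is commonly assessed with reciprocal best
hits (RBH): protein A in proteome 1 and protein B in proteome 2 are called
orthologs when B is A's best hit and A is B's best hit.  RBH becomes
unreliable between taxonomically distant species because sequence similarity
decays below the detection limit.  `orthopath` implements the step-wise
alternative: an ordered *evolutionary path* of proteomes — taxa indexed
`0..T-1` from a broad origin (e.g. cellular organisms) to a terminal genus
(e.g. Homo), each proteome placed in the last taxon it shares with the
terminal node — is traversed one step at a time, and each step's ortholog
becomes the query for the next step.  Because adjacent proteomes are close,
every individual search stays in the easy regime even when the path's ends
are far apart.

The traversal (`trace_chain()`):

1. **Entry.** The query is searched against the union of all path proteomes
   (`find_entry()`); the best hit's taxon X is the entry point.  If the hit
   *is* the query (same id and sequence) the entry step is labelled
   `query`; otherwise the entry hit is the protein used to get into the
   path and is labelled `ortholog` without a reciprocal check — a query
   from outside the path has no home proteome to reciprocate against.
2. **Two sweeps.** From X the path is traversed descending (X-1, ..., 0)
   and ascending (X+1, ..., T-1).  Both sweeps start from the entry hit and
   keep their own current search query.
3. **Per step.** The search query is aligned against every record of the
   step's proteome; the best hit passing the e-value cutoff is assessed by
   the reciprocal search against the search query's *home* proteome.  A
   reciprocated hit is an `ortholog` and replaces the search query; a
   non-reciprocated hit is recorded as `homolog` but **never** used to
   search (last-ortholog fallback); no passing hit gives `none` and the
   step is skipped.  This chain discipline — homologs are kept because they
   are informative, but only orthologs seed further searches — is asserted
   programmatically on every run (`validate_chain()`).

## Search backend and statistics

The built-in backend computes exact Smith–Waterman local alignments
(via `Biostrings::pairwiseAlignment`) under BLOSUM62 with affine gap
penalties 11 (open) and 1 (per residue), the protein-BLAST defaults.  Exact
SW is the exhaustive counterpart of BLAST's heuristic, so rank-1 hits can
only improve, and the backend is fully deterministic — a property the test
suite relies on.  Raw scores are converted with Karlin–Altschul statistics
using the standard gapped constants λ = 0.267 and K = 0.041:

* bit score = (λ·S − ln K) / ln 2
* e-value = K·m·n·e^(−λ·S), with m, n the *pairwise* sequence lengths.

Using the pairwise search space rather than a database-wide one is a
deliberate simplification; it makes the e-value a property of the pair
alone.  The default cutoff of 10 is therefore permissive: in a realistic
proteome the best random decoy alignment typically scores E ≈ 1–10 and
passes.  That does not disturb orthology calls (reciprocity filters decoys)
but it does mean a taxon lacking the family usually reports a `homolog`
decoy rather than `none`.  Analyses that need a crisp "absent" signal —
including our own deletion tests — should tighten the cutoff
(`search_params(evalue_cutoff = 1e-6)`); we expose the knob rather than
hard-coding a stricter default because the permissive default matches
common BLAST practice.

Ranking is a total order: bit score descending, then subject id ascending;
entry searches additionally prefer the higher taxon index on score ties.
Total ordering makes every run byte-reproducible.

An adapter for external BLAST+ tabular reports (outfmt 6) applies the same
rank-1 selection and tie-breaks.  Tabular reports carry no aligned strings,
so chains traced through the external backend cannot feed the region
tracker; the builtin backend is the fully featured one.

## Locked regions

A region of the query (10–100 aa, 1-based inclusive coordinates, the
UniProt feature convention) can be "locked" and followed through the chain
(`propagate_region()`).  All projections reuse the alignments stored in the
chain — re-locking a different region or owner never triggers a new search,
which the tests assert by counting backend calls.

**Coverage** of a region under an alignment is the fraction of region
positions that fall inside the aligned query range and face a residue (not
a gap) on the subject side; the region maps when coverage reaches the
threshold (default 0.75).  This is the simplest definition that detects
fragments.  Mapped coordinates are the subject positions aligned to the
first and last covered region positions.

**Reference handoff.** Walking outward from the entry (each sweep restarts
from the entry state), the reference coordinates move to a step's hit only
when that hit also seeds later searches (relation `query`/`ortholog`).
Homolog steps are mapped and reported but do not advance the reference:
advancing it would desynchronise the reference from the chain's search
query and corrupt every later projection.

**Fragment rescue.** When an ortholog is a fragment lacking the region, its
step is honestly unmapped and the reference survives unchanged.  The next
step's stored alignment has the fragment on its query side, so coordinates
the fragment cannot host can never be projected *through* it; instead the
surviving reference coordinates are carried over positionally onto the next
hit (clipped to its length, flagged `rescued` in the output), after which
normal alignment projection re-synchronises.  Positional carry-over assumes
coordinate conservation between relatives; with indels the rescue can land
a few residues off, which is why the recovery tests accept ±2.  When
several consecutive steps fail, the same rule applies each time and
coverage is reported honestly rather than guessing.

**Logo.** Mapped columns are stacked by region position: each mapping
contributes, per region position, the subject residue aligned to it;
subject insertions are dropped and unmapped positions contribute nothing,
so the logo has exactly the region's width and per-column sample sizes
vary.  Information content is log₂20 − H bits per column.  The standard
small-sample correction (19/(2·ln2·n)) is available behind a flag and off
by default so the closed-form values in the tests are exact.

## GO-term prevalence

`build_presence()` reduces a set of chains (one per query, same path) to a
boolean query × taxon matrix: `TRUE` where the chain holds an ortholog or
homolog, `FALSE` at `none`, `NA` at the query's own step.  For a GO term,
`term_ratio()` reports per taxon the fraction of queries annotated with the
term that are present there.  The denominator is the number of queries
annotated with the term — this makes each curve readable as "fraction of
this term's proteins with a detectable homolog at taxon t"; an alternative
all-queries denominator is available via `denominator = "all"`.
Annotations are taken from the query proteins only, never transferred to
hits, and are used exactly as listed (no propagation to ancestor GO terms —
a known limitation for coarse-grained terms).

## The synthetic generator

Real reference proteomes are large downloads; the generator
(`generate_path()`) emits desk-scale paths with known ground truth so every
claim in the test suite is checkable against construction:

* The terminal member is a random sequence; member k derives from member
  k+1 by i.i.d. substitutions (uniform choice among the 19 other residues)
  and geometric-length indels, so divergence grows with distance from the
  terminal taxon.  This is deliberately *not* a realistic evolutionary
  model (no trees, no rate heterogeneity, no empirical substitution
  biases); it only needs controllable identity to exercise RBH behaviour.
* Motif positions are substitution- and indel-protected, and their true
  coordinates per member are recorded.
* Deletions remove the member; truncations cut the member just before the
  motif; paralogs are planted to deterministically force the homolog
  branch: the paralog is a lightly diverged copy of the adjacent taxon's
  member (it wins the forward search) concatenated with the sequence of a
  long "anchor" decoy planted in that adjacent proteome — the reciprocal
  search then ranks the anchor first, breaking reciprocity by
  construction.  (A plain half-rate copy alone, without the anchor, still
  reciprocates to the search query and stays an ortholog.)
* Queries sit outside the path: each is a half-rate diverged copy of its
  family's member at the highest taxon where the family exists.
* All randomness flows from the single spec seed; the same seed gives
  byte-identical FASTA output.

Passing tests on these fixtures show the algorithm's bookkeeping is right
under controlled divergence; they do not show that any particular e-value
cutoff or coverage threshold is optimal for real proteomes, where domain
architecture, low-complexity regions and compositional bias all matter.

## Problem sizes and numeric choices

The test suite and the acceptance script run, per scenario, paths of 15
taxa with proteomes of 10–20 proteins, family length 200 aa, decoys of
60–120 aa, and 5–20 seeded replicates; chain recovery uses substitution
rate 0.2/step, region rescue 0.1/step with a 39-aa motif, and the
step-wise-vs-direct comparison 0.25/step.  These sizes keep a full run in
a few minutes while staying in the regimes the algorithm distinguishes:
0.2/step leaves adjacent members ~80% identical (easy per-step RBH), while
0.25/step compounds to <2% end-to-end identity, far below direct RBH
detection.  Degenerate inputs are handled explicitly: empty sequences are
errors, empty search results are valid outcomes (`none` steps), ties are
always broken by the documented total order, and non-standard residues
(U/B/Z/O) are mapped to X at load time so the aligner is total over real
proteome content.

## Known limitations

* The e-value model is pairwise, not database-wide; absolute e-values are
  not comparable to BLAST's, only their ranking is.
* The region tracker requires builtin-backend chains (stored alignments).
* Re-locking from a chain member crosses only ortholog steps back to the
  entry; re-locking across homolog/none steps is refused rather than
  guessed.
* GO annotations are used as listed; no ontology-graph reasoning.
* The generator's divergence model is a control knob, not a simulation of
  evolution.
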
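---
title: "Automated SCOP-style domain classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated SCOP-style domain classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scopclass)
```

## The problem

SCOP-style databases order protein structural domains in a seven-level
hierarchy — class, fold, superfamily, family, protein, species, domain —
where the superfamily groups families inferred to share a common
evolutionary ancestor. Manual curation of new Protein Data Bank
depositions cannot keep pace with deposition rates of hundreds of
entries per month, but the large majority of new chains are close
homologs of chains already classified. `scopclass` implements a
conservative sequence-based pipeline for exactly those chains: it
transfers domain boundaries and hierarchy placements from classified
chains to new ones, and refuses to guess in every situation where the
transfer is not overwhelmingly supported. The design goal is an error
rate indistinguishable from manual curation on the chains it does
accept, at the cost of leaving many chains unclassified.

## The pipeline

For a query chain the pipeline runs six stages, all exposed as ordinary
functions and composed by `classify_chain()`:

1. **Search** (`search_hits()`). The query's SEQRES sequence — the full
   deposited sequence, not just the residues observed in the ATOM
   records — is locally aligned against the SEQRES-based sequence of
   every classified domain (affine-gap Smith–Waterman, BLOSUM62, gap
   open 11, extend 1, via `Biostrings::pairwiseAlignment`).
   Significance is scored with the Karlin–Altschul law
   $E = K m n e^{-\lambda S}$ using the standard gapped BLOSUM62
   constants ($\lambda = 0.267$, $K = 0.041$), with $m$ the query
   length and $n$ the total residue count of the domain database.
   Because one pairwise call returns a single optimal local alignment,
   the unaligned query flanks are re-searched recursively (depth
   limited to 4, minimum flank 15 residues), so a tandem duplication of
   one domain produces one hit per copy.
2. **Filter** (`filter_hits()`). A hit survives only if its E-value is
   at least as significant as `e_max` (default `1e-4`, inclusive) and
   the alignment covers most of the target domain, defined as missing
   at most `target_end_slack` (default 10) residues from each end of
   the target sequence. Near-full target coverage is what licenses
   transferring the *whole* domain annotation.
3. **Group and rank** (`group_and_rank()`). Hits are grouped by the PDB
   chain their target domains belong to, and groups are ranked by the
   number of distinct query residues their hits cover. Coverage is a
   set size — overlapping hits are not double-counted — because the
   quantity being maximized is how much of the query the donor chain
   explains. Ties break by smaller minimum E-value, then
   lexicographically by chain key, so release builds are reproducible.
4. **Boundary assignment** (`assign_domains()`), detailed below.
5. **Confidence gate** (`gate_confidence()`), detailed below.
6. **Placement** (`place_in_hierarchy()`), detailed below.

## Boundary assignment

Each hit in the top-ranked group seeds one predicted domain. Starting
from the hit's query range:

* **Extension.** If the nearest chain terminus or ATOM-record gap edge
  lies within `extension_limit` (default 10) residues beyond a
  boundary, the boundary extends to it. The intent is to classify
  every observed residue; the 10-residue cap makes it unlikely the
  extension swallows part of another domain.
* **Clipping.** The range is then intersected with the observed
  residues; domains never contain residues absent from the ATOM
  records.
* **Interior linkers.** An unassigned *observed* region of at most
  `extension_limit` residues lying strictly between two predictions is
  appended to the preceding prediction, up to one residue before the
  next. The two extension rules above only reach toward termini and
  gap edges, so without this rule a short linker between two
  back-to-back hits would always trip the unassigned-region gate. For
  a 554-residue chain with residues 2–547 observed and hits at 2–224
  and 226–544, the three rules together give predicted domains 2–225
  (residue 225 absorbed from the linker) and 226–547 (right end
  extended 3 residues to the observed terminus) — the package's
  canonical worked example, available as `worked_example_fixture()`.

Overlapping hits in one group are resolved deterministically: the
earlier-starting prediction keeps the contested residues.

## The high-confidence gate

Predictions for a chain enter the classified set only if **no** rule
fires. Each rule is a pure predicate on the same inputs and they are
evaluated independently, so the set of reason codes does not depend on
evaluation order.

| code | rule |
|---|---|
| `LOW_RESOLUTION` | resolution ≥ 3 Å (inclusive) or the entry is non-crystallographic with a worse stated resolution |
| `RIBOSOMAL_OR_SYNTHETIC` | top-group targets classified outside the seven true classes (sccs class letter beyond *g*), or entry description matching a keyword list (`"ribosom"`, `"synthetic construct"`) |
| `GENETIC_DOMAIN_HOMOLOG` | any significant hit targets a genetic (multi-chain) domain |
| `TARGET_NOT_WHOLE_CHAIN` | a single-domain prediction whose target domain does not comprise its entire chain |
| `MULTIDOMAIN_SHAPE` | multi-domain chains must have 100% SEQRES identity with the donor chain, or exactly two domains of one contiguous segment each |
| `UNASSIGNED_REGION` | an observed region longer than `unassigned_limit` (10) residues belongs to no domain |
| `DUPLICATE_TARGET_DOMAIN` | two predictions share one target domain (domain duplications can hide swaps) |
| `NO_HITS` | nothing survived the filter |

Two readings were genuinely open and are pinned here:

* The 100% identity in the multi-domain rule is computed over the full
  SEQRES of both chains (string equality), the stricter of the two
  plausible readings (the laxer one measures identity over aligned
  columns only).
* Genetic-domain homology is judged on E-value significance alone,
  not on filtered hits: the coverage filter demands near-full coverage
  of the target, which a single query chain can never achieve against
  a domain spanning two chains, so filtering first would make the
  exclusion unreachable. Genetic domains are likewise indexed
  (flagged) in the search database but excluded from the searchable
  domain FASTA and never seed predictions.

## Placement below the superfamily

The superfamily is always inherited from the target domain — it is the
correctness unit of the whole method. Deeper levels use identity
thresholds, chosen conservatively because mistakes below the
superfamily are cheap to avoid by falling back:

* species: 100% identity over the full target domain;
* protein: ≥ `protein_identity` (default 90%) with full target
  coverage;
* family: ≥ `family_identity` (default 70%).

At the first level that fails its threshold, the domain is filed under
an *automated matches* node (created once per parent and reused;
`placement_mode` records the fallback). A 55% identity hit therefore
keeps its superfamily but lands in an "automated matches" family
beneath it. These thresholds are this package's heuristic — the
underlying method family describes such rules only as heuristics — and
they are parameters of `default_params()`, not constants.

## Benchmarking

`benchmark_release_pair(old, new)` replays history: chains present
only in the newer release are classified from the older one and scored
against the newer release's curated domains. A prediction is *correct*
when it sits in the curated superfamily and every paired segment
boundary deviates by at most `benchmark_tolerance` (10) residues.
Predicted and curated domains are paired greedily by maximal residue
overlap (deterministic tie-breaks); unequal segment counts score as a
boundary mismatch with an infinite deviation sentinel. Error rates are
printed with one decimal at ≥1% and one significant figure below 1%,
matching how release notes conventionally print such rates (e.g.
62/80140 → "0.08%", 231/30660 → "0.8%").

## File formats

Releases round-trip through SCOP-compatible parseable files —
`dir.des` (node descriptions), `dir.hie` (parent/child edges),
`dir.cla` (domain classifications with region strings and full
lineages) — plus domain and chain FASTA. Output ordering is pinned (by
sunid/sid/chain key) so writing is byte-deterministic regardless of
in-memory insertion order, and `write ∘ read` is the identity on
canonical files. Region strings use sequential SEQRES indices; author
numbering with insertion codes is deliberately kept out of the core
model and would be an I/O-layer concern. Chain-level metadata the
classifier needs (observed ranges, resolution, description) travels in
the chain FASTA headers as `key=value` tokens — this is the one place
the dialect extends the classic layout, since the classic files have
no slot for it.

## The synthetic-release generator

`generate_release(fixture_spec(...))` builds releases with controlled
homology so every stage is testable without downloads: sequences are
i.i.d. over the 20-letter alphabet, family members are point-mutated
copies of a family ancestor (default 0.05 substitutions/site, domain
lengths 120–180), and options add two-domain chains, a genetic domain,
or a non-true-class release. `derive_query()` emulates a new
deposition: a point-mutated copy of a classified chain with specified
unobserved regions. i.i.d. sequences make unrelated pairs score like
random noise while mutated copies stay overwhelmingly significant at
these lengths, which is exactly the regime the classifier assumes.

What the generator does **not** emulate: real amino-acid composition
and low-complexity regions (which inflate random-hit scores in real
searches), indels (substitutions only), remote homology near the
E-value threshold, domain swaps, and the long ambiguous linkers that
make real curated boundaries fuzzy. Passing tests therefore
demonstrate the pipeline's logic — filtering, grouping, boundary
arithmetic, gating, bookkeeping — not the sequence-search sensitivity
one would measure on real releases.

## Problem sizes and numerical choices

The test suite exercises releases of 2–4 superfamilies with 1–2
domains each (domains of 100–400 residues), a 200-query boundary
recovery experiment at mutation rates up to 0.1, and oracle
comparisons of the aligner against an exhaustive Gotoh dynamic program
on sequences up to 60 residues — sizes chosen so the whole suite runs
in well under a minute on one core while still covering every rule
edge (inclusive thresholds at exactly `1e-4`, 3.0 Å, 10 residues; the
11-residue unassigned region; the boundary exactly at the extension
limit). E-values are not claimed to match any specific BLAST build
bit-for-bit; the scoring system and its constants are pinned in the
package instead, and an external search tool can be substituted by
producing the same hit table.

## Known limitations

Chains needing three or more domains, or multi-segment domains, are
never accepted by the gate (by design); structure-based verification
is out of scope; NMR model multiplicity and chemically modified
residues are assumed resolved upstream (inputs are pre-translated
SEQRES); and the sub-superfamily thresholds, while conservative, are
heuristics — they were not fit to curated data.
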
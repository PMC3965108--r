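# scopclass

Automated SCOP-style protein domain classification by sequence
similarity.

SCOP-style databases arrange protein structural domains in a
seven-level hierarchy (class → fold → superfamily → family → protein →
species → domain). New PDB depositions arrive far faster than manual
curation can classify them, but most new chains are close homologs of
chains already classified. `scopclass` is for database curators and
structural bioinformaticians who need to transfer domain boundaries and
hierarchy placements from classified chains to new ones — conservatively
enough that accepted predictions can enter a release without manual
inspection — and to benchmark that transfer against curated domains.

## Method

For a query chain with SEQRES sequence *q*:

1. **Search**: affine-gap Smith–Waterman of *q* against the SEQRES
   sequence of every classified domain (BLOSUM62, gap open 11 /
   extend 1), scored with Karlin–Altschul E-values
   *E = K·m·n·e^(−λS)* (gapped constants λ = 0.267, K = 0.041).
2. **Filter**: keep hits with *E* ≤ 10⁻⁴ that cover the target domain
   to within 10 residues of each end.
3. **Group & rank**: group hits by the donor PDB chain; rank groups by
   the number of distinct query residues covered (union, not sum).
4. **Boundary assignment**: one predicted domain per hit in the top
   group; a boundary extends to a chain terminus or ATOM-record gap
   edge within 10 residues, is clipped to observed residues, and short
   (≤10-residue) observed linkers between adjacent domains join the
   preceding domain.
5. **High-confidence gate**: reject low-resolution (≥3 Å), ribosomal or
   synthetic entries, homologs of multi-chain ("genetic") domains,
   single-domain predictions whose target is not a whole chain,
   multi-domain chains that are neither sequence-identical to the donor
   nor exactly two contiguous domains, chains with >10 unassigned
   observed residues in a row, and duplicated target domains.
6. **Placement**: the superfamily is always inherited; family, protein
   and species are inherited only above conservative identity
   thresholds (70 / 90 / 100 %), otherwise the domain is filed under a
   reusable *automated matches* fallback node.

A prediction benchmarked against a curated domain counts as **correct**
when it lands in the same superfamily and every segment boundary
deviates by at most 10 residues.

Releases are read and written as SCOP-compatible parseable files
(`dir.des`, `dir.hie`, `dir.cla`) plus domain and chain FASTA, with
byte-deterministic output and stable identifiers (sunid, sid, sccs).
A synthetic-release generator (`generate_release()`, `derive_query()`)
makes the entire pipeline testable offline.

## Worked example

The package ships its canonical worked example as a fixture: a
554-residue chain (1vj5, chain A) with residues 2–547 observed and two
filtered hits — query residues 2–224 and 226–544 — against the two
domains of the classified chain 1ek1A.

```r
library(scopclass)

fx <- worked_example_fixture()
fx$chain
#> <chain 1vj5A> 554 residues, observed 2-547

preds <- assign_domains(fx$top_group, fx$chain)
for (p in preds) print(p)
#> <prediction 1vj5A 2-225 from d1ek1a1 (E=1e-48, 42.0% id, unplaced)>
#> <prediction 1vj5A 226-547 from d1ek1a2 (E=1e-70, 45.0% id, unplaced)>

gate_confidence(preds, fx$chain, fx$top_group, fx$db)
#> <verdict 1vj5A> high confidence
```

The first domain ends at 225 (the one-residue observed linker at 225
joins the preceding domain), and the second ends at 547 (the hit end
544 extends to the observed terminus 3 residues away). Compared with
the manually curated domains 2–223 and 224–547, the largest boundary
deviation is 2 residues, within the 10-residue tolerance:

```r
compare_domains(list(pdb_id = "1vj5", chain_id = "A",
                     superfamily_sunid = 3L, ranges = preds[[1]]$ranges),
                fx$curated[[1]], fx$bundle$hierarchy)
#>   chain predicted curated superfamily_match max_boundary_dev verdict
#> 1 1vj5A     2-225   2-223              TRUE                2 correct
```

The same machinery runs on synthetic releases end to end:

```r
old <- generate_release(fixture_spec(seed = 101, n_superfamilies = 3,
                                     domains_per_family = 1))
db  <- build_domain_db(old)
db
#> <domain db> 3 domains (0 genetic), 443 residues

q <- derive_query(old$chains[["s002a"]], mutation_rate = 0.05, seed = 8)
res <- classify_chain(q, db)
res$verdict
#> <verdict q002a> high confidence
res$predictions[[1]]
#> <prediction q002a 1-166 from ds002a_ (E=1.8e-103, 95.8% id, automated_matches)>
```

At 95.8% identity the domain keeps the donor's superfamily, family and
protein but falls back to an *automated matches* species node —
species-level transfer requires 100% identity.

A thin command-line interface wraps the same functions:

```sh
inst/exec/scope-autoclass build-db  --release <dir> --out <db-dir>
inst/exec/scope-autoclass classify  --chains queries.fa --release <dir> --out predictions.tsv
inst/exec/scope-autoclass benchmark --old <dir> --new <dir> --out bench.tsv
inst/exec/scope-autoclass diff      --old <dir> --new <dir> --out history.tsv
```

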
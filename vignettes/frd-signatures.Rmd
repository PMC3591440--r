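---
title: "Signature-motif analysis of the ferric reductase domain superfamily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-motif analysis of the ferric reductase domain superfamily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frdsig)
```

## The problem

The ferric reductase domain (FRD) superfamily comprises transmembrane,
heme-containing oxidoreductases: ferric/cupric reductases (FRE), the
ROS-generating NADPH oxidases (NOX, DUOX, NOX5, RBOH), and the short bacterial
and metazoan forms (YedZ, STEAP). All share a six-transmembrane ferric
reductase domain whose two hemes are coordinated by four canonical histidines;
in the numbering of human NOX2 these sit at positions 101 and 115 (TM3) and
209 and 222 (TM5). Three further positions separate functional classes: a
third TM3 histidine at 119 and a threonine–glycine dipeptide at 178–179 (TM4)
mark probable ROS generators, while replacement of His-101 by a conserved
arginine — with a glutamine often appearing at the 209-equivalent site —
marks the YedZ/STEAP short forms.

`frdsig` turns these observations into a reusable toolkit: per-clade
conservation profiles, coordinate transfer onto the NOX2 reference frame,
a rule-based clade classifier, EF-hand and domain-architecture
categorization, discovery of discriminating positions between clade profiles,
and a seeded synthetic-family generator that makes every stage testable at
desk scale.

## Conservation profiles

For an aligned clade family, each column's residue frequencies are computed
over the 20 canonical amino acids. Gaps are excluded from the frequencies but
tracked as a per-column gap fraction (logo renderings narrow stacks in gapped
regions rather than counting gaps as letters); the ambiguity letters X/B/Z/U
are retained in sequences but treated as missing in counts, which keeps the
entropy well defined on the canonical alphabet. Column information content is
the standard logo statistic

$$R_j = \log_2 20 + \sum_a p_{aj} \log_2 p_{aj} \in [0, \log_2 20],$$

in bits. No small-sample correction is applied by default — determinism and
closed-form testability were preferred — but the usual
$e(n) = 19/(2 \ln 2\, n)$ correction is available via
`information_content(..., correction = TRUE)`. Columns with gap fraction
above 0.5 are retained but flagged low-confidence, mirroring the practice of
dropping unreliably aligned columns without re-scoring the alignment. No
redundancy weighting is implemented: the source alignments this emulates were
already identity-filtered, and weighting choices would be invisible to the
synthetic benchmark.

```{r profile-example}
fam <- generate_family(default_clade_templates()[["NOX"]],
                       generator_config(20, epsilon = 0.05, seed = 1))
prof <- profile_msa(fam$msa, clade = "NOX")
prof
summary(prof)[1:3, ]
```

## Mapping onto the NOX2 reference frame

Signature positions are defined in NOX2 numbering, so any query must first be
placed in that frame. `global_align()` computes an optimal global alignment
with affine gaps (BLOSUM62, gap open 11, gap extend 1 — the common convention;
a gap of length $L$ costs $11 + L$). Ambiguity letters score 0 against
everything, a neutral choice that avoids extending the substitution matrix.
`build_position_map()` then pairs the residue-residue columns, giving a map
that is strictly monotone in both coordinates, and `ref_to_query()` reads any
reference position off a homolog (or reports it absent when gapped out).

A 19-residue Kyte–Doolittle window scan (threshold 1.6) provides coarse
transmembrane context for reports. It replaces no dedicated predictor and is
deliberately non-load-bearing: classification uses mapped positions only,
because the motif definitions are positional while TM labels are descriptive.

### The bundled reference sequences are synthetic

The package ships two reference FASTA files,
`inst/extdata/nox2_synthetic.fasta` and `nox5_synthetic.fasta`. Both are
synthetic stand-ins constructed by `build_reference_scaffold()` and
`build_synthetic_nox5()`: deterministic scaffolds of the documented lengths
(570 and 765 residues) with hydrophobic transmembrane windows, the seven
signature residues planted at their documented positions, and — for the
NOX5-like sequence — four canonical EF-hand loops in the N-terminal region.
They are **not** the UniProtKB entries P04839/Q96PH1 and must not be used as
biological sequences; they exist so that coordinate transfer, signature
extraction and EF-hand detection are exercised against a reference whose
ground truth is exact. The scaffold builder additionally scrubs
EF-hand-pattern windows that arise by chance in random background (and guards
the 11 residues upstream of each planted loop), so EF-hand truth on synthetic
data is well defined.

## The signature table and classifier

`signature_table()` encodes the per-clade expected residues at the seven
reference positions — one shared source for both the classifier and the
generator templates:

| clade | 101 | 115 | 119 | 178 | 179 | 209 | 222 |
|---|---|---|---|---|---|---|---|
| NOX | H | H | H | T | G | H | H |
| preNOX | H | H | ¬H | T | G | H | H |
| preNOX (green-algal variant) | H | ¬H | ¬H | T | G | H | H |
| FRE | H | H | * | * | * | H | H |
| YedZ/STEAP1 | R | H | * | * | * | H | H |
| STEAP2–4 | R | H | * | * | * | Q | H |

`classify_residue_vector()` applies a fixed cascade: the arginine replacement
at 101 is tested first (it is the sharpest single diagnostic, and testing it
first prevents a NOX/FRE call on STEAP-like vectors), with the residue at 209
separating YedZ/STEAP1-like (His) from STEAP2-4-like; then a NOX call
requires His-101, an intact T178–G179 dipeptide (conserved in all probable
ROS generators) and at least 3 of {His-119, Thr-178, Gly-179, His-115} — the
one-site tolerance covers species with multiple NOX inparalogs, which under
this rule remain NOX-group; an intact dipeptide without His-119 is
preNOX-like; at least three canonical heme histidines is FRE-group; anything
else is ambiguous. The classifier is total and deterministic, and every call
reports the heme-histidine count (His at 101/115/209/222 only).

One consequence of the inparalog tolerance is deliberate: a vector matching
the *primary* preNOX profile (His at 115, non-His at 119, intact dipeptide)
satisfies the NOX rule with 3 of 4 sites and is labelled NOX-group. The
preNOX-like label is therefore reachable only by vectors that also lack the
second TM3 histidine — the green-algal variant of the profile. The default
preNOX generator template plants exactly that variant, which keeps the
classifier, the table and the benchmark mutually consistent; profiles with
His-115 intact are treated as (tolerated) NOX-group calls.

## Signature discovery

`discover_signatures()` compares two clade profiles in reference coordinates
and reports every position where clade A's consensus residue has frequency at
least `f_cons` while that residue's frequency in clade B is at most `f_bg`.
The defaults `f_cons = 0.8` and `f_bg = 0.3` are not taken from any printed
table; they were chosen once so that planted-site recovery is robust at a 5%
substitution rate, and both are exposed as function and CLI flags. The
operation errors when `f_cons <= f_bg` (non-separating thresholds). Profiles
are mapped to reference coordinates by aligning the profile consensus to the
reference (`msa_reference_map()`).

## EF-hands and domain architectures

`detect_ef_hands()` scans with a transparent positional rule derived from the
classical 12-residue Ca²⁺-binding loop consensus: position 1 = D; 3 ∈ {D,N,S};
5 ∈ {D,E,N,S,T,G}; 6 ∈ {D,N,Q,G,H,R,K}; 9 ∈ {D,E,N,Q,S,T,A,G,C};
12 ∈ {D,E}; no proline at 7. All six classes matching is a canonical hit;
five of six is a relaxed, non-canonical hit. Hits are taken greedily left to
right without overlap. A positional rule rather than a profile search keeps
every call reproducible and hand-checkable.

`classify_architecture()` categorizes a protein from its ordered N→C domain
hits into nine categories (FRD-only, core triad, STEAP2-4-like, NOX-EF,
DUOX-like, RBOH-like, FRE+DOMON, fuFRE-like, unclassified-novel). The many
drawn architecture models of the superfamily are deliberately collapsed to
this coarse set, since only the figure legend — not the text — defines the
full inventory. Rules are tested most-specific first (DUOX-like and
RBOH-like before the generic EF-before-core NOX-EF rule), accessory domains
are expected N-terminal to the core triad, and predicted transmembrane
segments lying inside the NADPH-binding domain are ignored as prediction
artifacts. Overlapping core domains in contradictory order produce
`unclassified-novel` with a warning rather than an error.

## The synthetic generator

`generate_family()` emulates a clade-structured family: every row is the
template sequence mutated i.i.d. at rate ε (to a uniformly chosen different
residue), with deletions written as gap columns at `indel_rate`. Defaults
are the benchmark conditions: five clades on one shared NOX2-like scaffold
differing only at the planted signature positions, ε = 0.05, indel rate 0.01
(a conventional low value; no printed default exists), planted sites
protected. Sharing one scaffold makes the NOX-vs-FRE discovery truth exactly
the planted set {119, 178, 179}. Sub-seeding is stable (`seed + clade
index`), so adding a clade never perturbs earlier clades.

What the generator does *not* emulate — and what passing benchmarks therefore
do not show about real data: background residues are uniform rather than
empirically distributed (maximizing entropy contrast at planted sites),
substitutions are phylogenetically uncorrelated (no tree-structured
evolution), insertions are not generated (indels are deletions only, so MSA
columns remain in scaffold coordinates), and real clades are not
single-scaffold. Accuracy on this benchmark is an upper bound on, not an
estimate of, accuracy on curated families.

```{r benchmark, eval = FALSE}
bench <- generate_benchmark(generator_config(200, epsilon = 0.05, seed = 7),
                            default_clade_templates(), "bench")
res <- classify_sequences(read_fasta(bench$pooled))
table(res$label)
```

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, matching His-101-style
  numbering.
* Consensus ties break alphabetically; the classifier cascade order is fixed;
  alignment traceback is deterministic — identical inputs and seeds give
  byte-identical outputs, which the test suite asserts at file level.
* Duplicate sequence ids are an error, never deduplicated, because
  truth-label joins require uniqueness.
* Test and verification problem sizes are chosen for desk scale: the
  alignment oracle (exhaustive enumeration of all affine-gap alignments) is
  compared on all sequence pairs up to length 3 over a three-letter alphabet
  plus a seeded sample of length-4/5 pairs; the benchmark uses 200 sequences
  per clade at ε = 0.05.
* The TM3/TM4/TM5 boundaries on the reference are computed from the
  hydropathy scan and stored in `reference_annotation()` for reporting only;
  no exact boundary set is authoritative, and nothing downstream depends on
  them.
* Where the glutamine characteristic of STEAP2-4 sits relative to the
  209-equivalent column is an interpretation; the table pins it to 209 and
  treats it as corroborating the subtype, not required for it.

## Limitations

The classifier is rule-based, not probabilistic: it reports deterministic
labels with per-position evidence, not posterior probabilities. It presumes a
reliable global alignment to the reference; highly diverged or fragmentary
sequences degrade to `ambiguous` rather than failing. Stockholm/Clustal
parsing, profile-HMM search, tree inference, and live Pfam/InterPro scanning
are out of scope; domain architectures are classified from externally
supplied hit tables plus the package's own EF-hand scan.
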
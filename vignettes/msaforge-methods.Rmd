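---
title: "msaforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msaforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msaforge)
```

# Scope

Deep multiple sequence alignments (MSAs) are the single most important input
to modern protein structure predictors. msaforge implements the
computational core of a staged MSA-construction workflow at desk scale:

* alignment I/O in the HH-suite A3M dialect with species annotation parsing,
* MSA diversity statistics built around the effective sequence number (Neff),
* orchestration of staged homology searches (the dMSA, qMSA and mMSA blocks)
  over pluggable search backends, with model-confidence ranking of the
  resulting candidate MSAs,
* species-aware construction and selection of paired MSAs for protein
  complexes, and
* MSA-derived coevolution features: mutual information (MI) and
  pseudolikelihood-maximized (PLM) Potts couplings, with contact-score
  reduction and a long-range distance-error metric.

The external search engines (HHblits, Jackhmmer, HMMsearch), the sequence
databases they search, and the neural structure predictors are *not* part of
the package. They sit behind three small contracts — a search backend, a
structure scorer, and a complex predictor — so that the pipeline's control
flow, which is what the package implements, can be exercised end to end with
deterministic mock implementations.

# The alignment model

An `msa` is a list of records over the query's match-column coordinate
system. The first record is the query: it is gapless and defines the
alignment length $L$. In the A3M dialect, uppercase letters and `-` occupy
match columns while lowercase letters are insertions that carry no column
index; insertions therefore never contribute to identities, coverage, depth,
or any coevolution feature. Coordinates are 0-based half-open internally
(e.g. the column spans recorded next to paired MSAs) and 1-based in
user-facing reports such as contact lists.

Residues map onto a fixed 22-state alphabet: states 0–19 are the canonical
amino acids in alphabetical one-letter order, state 20 is the
unknown/nonstandard state (X, B, Z, J, U, O, and anything else
unrecognized), and state 21 is the gap. A fixed, documented order is what
makes coupling and frequency indices reproducible across runs and machines.

Species keys come from UniProt-style headers. The numeric `OX=` taxon
identifier takes precedence over the `OS=` organism name because it is
unambiguous under renaming; both are exposed through a `mode` argument since
header dialects vary. Sequences without annotation (typical for
metagenome-derived hits) simply have no key and can never be linked.
Comparison is exact string match after whitespace trimming — no taxonomy
tree is consulted.

# Diversity statistics

The effective sequence number of an alignment with $N$ rows is

$$\mathrm{Neff} = \frac{1}{\sqrt{L}} \sum_{n=1}^{N}
  \frac{1}{1 + \sum_{m \neq n} I[S_{m,n} \ge 0.8]}$$

where $S_{m,n}$ is the pairwise sequence identity and $I[]$ the Iverson
bracket. Neff discounts redundant rows and normalizes by $\sqrt{L}$, so a
fully diverse alignment has $\mathrm{Neff} = N/\sqrt{L}$ and a fully
redundant one has $1/\sqrt{L}$ regardless of $N$. Inverting the diverse
limit gives the rule of thumb $N_{\min} = \mathrm{Neff}_{cut} \times
\sqrt{L}$ for how many diverse sequences a target needs; at $L = 100$ the
cutoffs $2^0$ and $2^4$ give 10 and 160 sequences.

Two choices here were genuinely open and are worth recording:

* **Identity denominator.** $S_{m,n}$ is computed over the match columns
  where *both* rows are non-gap. This is symmetric, insensitive to terminal
  gaps, and standard in alignment-filtering tools; rows with no overlap get
  identity 0.
* **The query is a row.** Neff is a property of the alignment, and the query
  is its first row, so it participates in the sum like any other row. The
  redundancy comparison is `>= 0.8` exactly as the threshold is stated, and
  the threshold is exposed as a parameter.

Coverage is the mean, over homologs, of the fraction of query columns each
aligns; per-site depth counts non-gap homologs per column. The two are
linked by `mean(depth)/(N-1) == coverage`, which the test suite checks as an
invariant.

# Monomer search orchestration

Three blocks generate candidate MSAs: dMSA (three stages), qMSA (four
stages) and mMSA (up to three, one per seed alignment). Each stage queries a
backend; stages beyond the first may follow a two-step
`search`/`build` contract in which the orchestrator truncates the raw hit
list to at most 30,000 entries (the e-value-ranked BLAST filter) before the
clustering/realignment step builds the stage's alignment. A block stops
after the first stage whose alignment has Neff **strictly greater than
128** — the boundary case Neff = 128 continues, and the test suite pins
that. mMSA is skipped when *both* dMSA and qMSA early-stopped at stage 1:
"stopped at stage 1" is read as the Neff-triggered stop (a block whose later
stages merely failed still counts as not-stopped). The mMSA probe is the
qMSA stage-3 alignment; when qMSA ended earlier, the deepest available qMSA
alignment is used instead — a pipeline design choice, since the situation is
not otherwise specified.

Up to ten candidates result (3 + 4 + 3). A pluggable structure scorer
returns five model confidences (pLDDT) per candidate; the best of the five
is the candidate's rank score, and the global argmax is the selected MSA.
Exact ties break by higher Neff, then block order (dMSA < qMSA < mMSA) and
stage — an arbitrary but fixed rule, chosen for reproducibility.

# Multimer pairing and linking

Complex composition is written as a stoichiometry string (`"A2B2C1"`: three
distinct chains with 2, 2 and 1 copies). For heteromers, the top $M$ monomer
MSAs per distinct chain are combined into $M^N$ paired MSAs, with $M$ the
largest value satisfying $M^N \le 100$ (and at most the 10 MSAs kept per
chain); at $N = 3$ this gives $M = 4$ and 64 combinations. Homomers skip
pairing entirely: each monomer MSA is self-concatenated $n$ times.

Sequence linking builds each paired MSA. Per chain, homologs are grouped by
species and ordered within the group by identity to the chain query. For
every species present in at least two chains, the rank-$r$ group members
across chains are concatenated side by side for $r$ up to the smallest group
size among the chains carrying that species; chains lacking the species
contribute a gap block. The concatenated query is row 1, every unlinked
homolog is appended below padded with gaps in all other chains' columns, and
each distinct chain's block is repeated per its copy number. Three decisions
deserve a note:

* **Linking depth.** Only "the top sequences" of a species group need to be
  linked; rank-matched linking down to the smallest group size maximizes the
  orthologous signal while staying deterministic. `link_depth = 1` restricts
  to the top pair only.
* **Padding condition.** The rule "pad a chain missing a species that
  appears in more than one other chain" is ambiguous for two-chain
  complexes; the implemented reading pads whenever the species is shared by
  at least two chains, which never triggers for $N = 2$ (unshared species
  stay unlinked there).
* **Unlinked row order** preserves the within-chain identity ranking, the
  same currency used for linking.

Paired MSAs are ranked by the M-score,

$$M\text{-score} = \mathrm{Neff} \times
  \frac{\sum_i n_i\,\mathrm{pLDDT}_i}{\sum_i n_i},$$

with Neff computed over the **full** concatenated MSA (linked plus padded
rows — the padded rows carry real signal for their own chain) and
$\mathrm{pLDDT}_i$ the rank score of the monomer MSA chosen for chain $i$.
The top 25 heteromer MSAs survive; homomers keep all (up to 10)
self-concatenations. The downstream bookkeeping generates 25 models per
selected MSA — 625 for a heteromer, 250 for a homomer — ranks them by the
predictor's TM-score estimate, and returns the top five with provenance.

# Coevolution features

Mutual information uses plug-in frequencies over all 22 states (nats,
natural log, $0 \ln 0 = 0$), unweighted across rows; a pseudocount and a
gap-state exclusion are available but off by default, keeping the estimator
exactly as defined. The summed $L \times L$ matrix is symmetric and
nonnegative, with the diagonal flagged as self-information.

The PLM feature minimizes the negative log-pseudolikelihood of a 22-state
Potts model with fields $h$ and couplings $P$ plus L2 penalties,
$\lambda_{single} \lVert h\rVert_2^2 + \lambda_{pair} \sum_{i \ne j}
\lVert P_{ij}\rVert_2^2$ with $\lambda_{single} = 1$ and $\lambda_{pair} =
0.2\,(L-1)$. The printed form of the field penalty carries a dangling
sequence index; the standard full-norm penalties are used, which preserve
the zero-model loss $N L \ln 22$. There is no sequence reweighting, matching
the plain sum over rows in the objective. The optimizer is L-BFGS-B from a
zero start (the objective is convex, so the optimum is unique up to
tolerance); the gradient is analytic and is checked against central finite
differences in the tests. Couplings are fitted asymmetrically and
symmetrized afterwards as $(P_{ij} + P_{ji}^\top)/2$, the usual practice.
Contact scores are the Frobenius norm of each coupling block over the 21
non-gap states, followed by the average product correction (APC). APC means
are taken over the full matrix including the diagonal, which makes the
correction cancel rank-one background exactly.

Distances are derived from bin probability vectors as the midpoint of the
highest-probability bin (first-argmax tie-break). No particular bin layout
is mandated: the default scheme — 36 half-Angstrom bins spanning 2–20 Å plus
an open last bin whose nominal midpoint is its lower edge plus half the
previous width — is one reasonable choice, and every function takes the
scheme as an argument. The accuracy metric is the mean absolute error over
the top $5L$ long-range ($|i-j| \ge 24$) predicted pairs, ranked by a
caller-supplied confidence; pairs with no experimental distance are dropped
and the divisor reduced.

# Synthetic data and mocks

All tests run on generated data; every generator is a pure function of its
arguments (seed included) and restores the caller's RNG state.

* `make_msa()` mutates a random query to hit requested identity levels
  within ±0.02. Homolog $r$ shifts its mutated residues by $((r-1) \bmod 19)
  + 1$ alphabet places, so for up to 19 homologs any two rows disagree
  wherever either mutated; with levels below ~0.79 every pairwise identity
  is then provably < 0.8 and Neff equals $N/\sqrt{L}$ *exactly*, which is
  what the closed-form checks rely on. Species labels are assigned
  round-robin to the annotated fraction.
* `make_diverse_msa()` draws uniform random rows; at the lengths used the
  probability of any pair reaching 0.8 identity is negligible, and the
  seeded fixtures used in tests are verified. It emulates deep, diverse
  search results at a prescribed Neff (`n = round(target * sqrt(L))` rows),
  which is how the mock backends hit their per-stage Neff targets.
* `make_potts_msa()` samples a planted-coupling Potts alignment (zero
  fields, same-state couplings of strength 3 on disjoint site pairs — a
  strong, clearly recoverable signal) by Gibbs sweeps run in parallel over N
  independent chains: 100 burn-in sweeps plus 10 further sweeps before the
  single recorded state per chain. Uncoupled sites have a uniform
  conditional and are resampled directly. The recovery fixture used by the
  acceptance checks is L = 20, N = 1500 with three planted pairs at
  separation 17 — the largest separation three disjoint pairs admit at that
  length, standing in for the |i−j| ≥ 24 long-range convention that L = 20
  cannot accommodate.
* `make_complex_fixture()` builds chain sets whose species sharing — and
  hence the number of linked rows — is hand-enumerable; homolog $r$ carries
  $r+1$ mutations so identity ranks are unambiguous.
* `mock_scorer()` and `mock_predictor()` return confidences that saturate in
  Neff ($p = \mathrm{Neff}/(\mathrm{Neff}+8)$), making ranking tests
  closed-form and monotonicity checkable.

What the generators do *not* emulate: phylogenetic correlation between
homologs, realistic substitution processes, gap structure from true
insertions/deletions, and the heavy-tailed species distributions of real
UniProt searches. Passing tests therefore demonstrate the correctness of
the statistics, control flow and estimators on alignments with known ground
truth — not retrieval performance on biological databases, which requires
the real search tools and predictors behind the contracts.

# Numerical choices and problem sizes

Identity and Neff computations are exact (no sampling). The PLM fit uses
`pgtol = 1e-4` and `maxit = 100` by default; on the L = 20, N = 1500
recovery fixture it converges in ~30 iterations in a few seconds. MI and
frequency tensors grow as $L^2 Q^2$, so the per-pair tensor is retained only
for $L \le 50$ by default (the summed matrix is always available). The test
suite and the reproduction script run in well under a minute on one CPU at
the sizes above; those sizes were chosen because every claimed property is
already decisively visible there.

# Known limitations

* Species linking is exact-string based; strain-level annotations that
  differ textually are treated as different species.
* The Neff pairwise loop is $O(N^2 L)$; it is fine at the scale the package
  targets (thousands of rows) but is not engineered for million-row MSAs.
* The PLM fit materializes the full coupling block matrix
  ($L^2 Q^2$ parameters), practical to roughly $L \approx 100$ in memory;
  larger proteins need a factored implementation that is out of scope here.
* `parse_stoichiometry` accepts at most 52 distinct chains (single letters).
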
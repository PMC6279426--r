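---
title: "Error-controlled spectral library assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error-controlled spectral library assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speclib)
```

# Scope

`speclib` turns per-search peptide-spectrum matches (PSMs) plus their
peak lists into an error-controlled spectral library: one representative
spectrum per precursor (modified peptide sequence + charge), with decoy
entries carried through, full provenance, and an incremental update rule
whose result is independent of the order in which data arrive. This
vignette explains the underlying models, every tunable parameter, the
synthetic-data generator the test suite runs on, and the design
decisions taken where the procedure leaves genuine freedom.

Searching itself (assigning peptides to spectra and computing spectral
probabilities) is out of scope: spectral probabilities arrive in the PSM
table from the upstream search engine. Raw-file conversion, centroiding
and spectral-library *searching* are likewise out of scope; inputs are
centroided peak lists (MGF).

# The scoring model

## Database p-values

Each PSM carries a spectral probability $p = P(S \mid T)$: the
probability that a random peptide matches spectrum $S$ with a score
better than the observed threshold $T$. Significance against a database
of $N$ candidate peptides is

$$\mathrm{dbp}(p, N) \;=\; 1 - (1 - p)^N,$$

the probability of at least one random candidate matching as well.
`databasePValue()` evaluates this as `-expm1(N * log1p(-p))`, which
keeps full relative precision down to $p = 10^{-300}$ (a direct
`(1-p)^N` underflows to 1 long before that). The function is strictly
increasing in both arguments, is the identity at $N = 1$, and tends to 1
as $N \to \infty$.

## Dynamic search-space adjustment

In limited-complexity samples (affinity purifications) far fewer
proteins are present than in the full proteome database, so the same
match can be re-assessed against a reduced $N$. `adjustSearchSpace()`
marks a protein eligible when, at the peptide-level FDR (default 1%,
peptide score = best PSM p-value per distinct sequence), **two or more
distinct peptide sequences pool onto the target protein or its reversed
decoy**. Pooling the decoy side is what lets the target-decoy machinery
model true/false and false/false peptide pairs symmetrically. PSMs to
eligible proteins get their database p-value recomputed at the reduced
$N$; single-peptide proteins keep their original values; the adjusted
set is re-filtered at the PSM-level FDR. Whether eligibility should be
counted before or after pooling the target/decoy pair is not fully
determined by the procedure's description; the pooled reading ("a total
of two or more") is implemented, and the non-pooled behavior can be
recovered by supplying a mapping in which decoy peptides point to their
own accessions.

The reduced $N$ itself is supplied by the caller (`reducedDatabaseSize`)
rather than recomputed internally, because $N$ must mean the same thing
in both search passes and only the caller knows the digestion convention
of the original search. The fixture generator uses a fully tryptic
digest for this purpose.

## Synthetic-pool empirical FDR

Synthetic peptide pools are searched against a tiny known database, far
too small for ordinary decoy statistics. `syntheticPoolFilter()`
therefore treats as a *decoy PSM*: (a) any main-pool spectrum matched to
the decoy database, and (b) any background-run spectrum matched to
either database — except background peptides that also occur in the
target pool, which are genuinely present and excluded from decoy
counting. Within each peptide length, PSMs are ranked by database
p-value and the threshold is placed strictly below the best decoy, so
the accepted set contains zero decoy PSMs by construction (an
"empirical 0% FDR"). The filter refuses to run without background runs,
since the error rate would be undefined.

# Library-level error control

## Why per-search FDR is not enough

Each search is filtered to 1% PSM-level FDR by standard target-decoy
counting (`psmFdrFilter()`; decoys inside the accepted prefix are kept,
flagged, precisely so that library-level error can still be estimated).
But a union of thousands of such sets accumulates false precursors: the
package reports this as the *naive aggregate FDR* — the decoy/target
ratio over the full unfiltered precursor ledger — alongside every build.

## Local precursor FDR

`localPrecursorFdr()` bins precursor records by peptide length (score
distributions are strongly length-dependent), ranks each bin by best
p-value, and computes at each record the decoy/target ratio in a window
of 500 records. The per-bin threshold is the highest p-value whose
window ratio is strictly below 1%; accepted records are a score prefix
of their bin.

Two window semantics are defensible — a window *around* the record
versus the 500 records at *better* ranks — and the procedure's
descriptions support both. The default (`window_mode = "trailing"`)
takes the 500 records at better ranks, inclusive of the record itself,
following the more specific phrasing; `window_mode = "centered"`
implements the other reading so the ambiguity is exposed rather than
hidden. The record counts itself as a target in its own window; bins
smaller than the window shrink the window to the bin size (a
conservative, deterministic fallback).

## Site-localization collapse and protein FDR

Precursors differing only in the placement of the same modification
multiset are collapsed to the best-scoring variant
(`collapseSiteVariants()`; charge is part of the precursor, so different
charges survive). Remaining precursors are mapped onto the protein
database by exact substring search (`mapPrecursorsToProteins()`;
isoleucine/leucine are distinct by default, `equate_il = TRUE` merges
them). Proteins are scored by the sum of $-\log_{10}$ of the database
p-values of uniquely mapping precursors — equivalently one minus the
product of those p-values — and filtered by *picked* protein FDR
(`pickedProteinFdr()`): each target competes only against its own
reversed decoy, the higher scorer survives into a ranking, and the
largest prefix with decoy/target ratio at or below 1% is accepted.
Precursors are retained iff they map to at least one accepted protein;
decoy precursors whose decoy protein is accepted become flagged decoy
library entries, never silently dropped.

# Spectra

Peaks are stored sorted by m/z; peaks whose m/z coincide after rounding
to 4 decimals are merged by summing intensity so that one-to-one peak
matching is well defined. Intensities are rescaled to unit Euclidean
norm (`normalizeSpectrum()`, idempotent). Fragment annotation
(`annotatePeaks()`) enumerates b/y ions (plain, first isotope, H2O and
NH3 losses) and plain a ions at fragment charges up to the precursor
charge, with a 0.1 Da match tolerance; loss and isotope variants are not
combined, matching the standard label set. Monoisotopic residue masses
and the proton mass come from a fixed internal table (documented to five
decimals, emitted next to every exported library by
`writeConstantsFile()`), so libraries are reproducible independently of
any external mass table.

Two quality gates guard library admission: at least 40% of total
fragment intensity must be explained by annotated peaks (each peak
counted once however many annotations it carries — the gate measures
explained *intensity*, not annotation multiplicity), and the observed
precursor mass must lie within 50 ppm of the theoretical neutral mass,
allowing one ^13^C isotope error (1.00335 Da). All ppm arithmetic is on
neutral masses ($m/z \cdot z - z \cdot m_\mathrm{proton}$), which makes
mass accuracy charge-independent.

## Cosine similarities

`cosineSimilarity()` matches peaks one-to-one within the fragment
tolerance and sums intensity products. The default matching is greedy by
descending intensity product — deterministic, symmetric, and the
community norm; an exact maximum-weight assignment mode
(`method = "optimal"`) exists and is used by the test suite as a
verification target on small spectra. The same 0.1 Da tolerance used for
annotation is used for cosine between library candidates (a single
fragment tolerance keeps the pipeline internally consistent;
configurable). Raw normalized intensities are compared — no square-root
transform is applied; this is an assumption, flagged here, since the
representative-selection procedure does not specify one.

`alignedCosine()` generalizes this for isotopically labelled pairs: each
light peak may match a heavy peak at shift 0 or at
$\Delta/z$ for any fragment charge $z$ up to the precursor charge, where
$\Delta$ is the neutral precursor mass difference; the alignment
maximizing the score is kept. A zero shift is always admissible, so the
aligned cosine is never below the plain cosine.

# Assembly and order invariance

All sorting uses one lexicographic total order: (database p-value,
targets before decoys, run id, scan). For every precursor ever observed
— including decoys and sub-threshold precursors — the state keeps a
ledger row (best PSM) and a candidate set: the best 100 PSMs, at most 20
per dataset. The per-dataset cap is applied first, then the global cap;
both are prefix operations under the total order, so merging PSM batches
is associative, commutative and idempotent (duplicate PSMs collapse).
This is the whole order-invariance argument: the state after any batch
partition and permutation equals the state of an all-at-once build, and
every later stage is a deterministic function of the state. Canonical
serialization (entries sorted by peptide then charge, fixed-precision
floats) makes exported libraries byte-identical, which the tests verify
directly.

The representative of each accepted precursor is the candidate spectrum
with the highest mean cosine to all other candidates (single candidate:
itself; ties broken by the total order). Pairwise cosines are recomputed
at each build rather than cached across builds — correctness first;
a content-hash cache would be a compatible optimization.

The ambiguity filter (`filterAmbiguous()`) consumes a re-search
annotation table (up to 20 alternative peptide explanations per
representative spectrum) supplied as an input: the re-search engine
itself is deliberately externalized. Alternatives passing the PSM
threshold of the entry's original search are counted after collapsing
site-localization variants; two or more surviving distinct annotations
remove the entry. Using the *original search's* threshold is the stated
rule; how it interacts with synthetic-pool 0% thresholds (where the
threshold excludes all decoys rather than targeting 1%) is not
documented anywhere and is inherited as-is. Entries missing from the
annotation table are retained and logged.

# Downstream analyses

**Proteotypic selection** (`selectProteotypic()`) is greedy set cover
over the searches in which a protein was called (by unique peptides
passing the library's per-length score cutoff): repeatedly add the
precursor covering the most not-yet-covered searches until 90% coverage
or 20 precursors. Ties go to the precursor with the better best
p-value, then the total order. Greedy guarantees coverage at least
$(1 - 1/e)$ of the optimum at equal size, which the tests check against
exhaustive optimization on small instances.

**Co-observation detectability** (`detectInteractions()`): two proteins
accepted in the same pulldown are co-observed; the pair is detectable by
proteotypic precursors iff each protein has at least one proteotypic
precursor among that search's accepted precursors. Protein calls use
unique peptides only; shared-peptide inference is deliberately not
modeled.

**Novel-protein calling** (`callNovelProteins()`): peptides of length at
least 9 are mapped to proteins lacking prior protein-level evidence
(protein-existence levels PE2–PE5); peptides that are an exact substring
of — or a single-amino-acid variant of, i.e. Hamming distance at most 1
from an equal-length window of — any PE1 protein are excluded
(`isSaavOfPe1()`, I/L per the global mode, modification deltas ignored:
the variant rule is a sequence-level rule); a protein is called iff two
of its remaining peptides occupy disjoint residue intervals.
"Non-overlapping" is read as disjoint coordinate spans — the only
reading compatible with the word — and missing PE annotations default
conservatively to PE1 (with a log message).

**SILAC gold standard** (`buildSilacGold()`): light/heavy pairs of the
same peptide (labels +8.0142 Da on K, +10.0083 Da on R) are paired
within the same run (co-elution implies the same LC run) and accepted as
concordant when all four gates hold — identical sequence modulo the
label, aligned cosine above 0.6, explained intensity above 0.5 in both
spectra, retention times within one minute. The light member is
eligible; the lowest-p-value spectrum per precursor becomes its
representative. Charge-mismatched pairings are skipped with a log.

# The synthetic-data generator

Everything is testable offline because the `fixtures` module generates
all inputs deterministically from a seed (per-entity sub-seeds from a
stable string hash, so regenerated fixtures are byte-identical and
independent of batch partitioning):

- **Universe**: random tryptic-friendly proteins (segments of 7–14
  non-K/R residues terminated by K/R) with whole-protein reversed
  decoys; planted PE2 "novel" proteins; planted SAAV traps (a
  distance-1 copy of a novel peptide inserted into a PE1 protein).
- **Scores**: true-match spectral probabilities log-uniform on
  $[10^{-15}, 10^{-9}]$, random-match on $[10^{-8}, 10^{-2}]$ —
  separable but overlapping, so the FDR machinery is exercised
  nontrivially. The default effective database size is $N = 1000$,
  chosen so null database p-values spread over $(0,1)$ instead of
  saturating at 1 (at proteome-scale $N$ every null PSM would print
  as exactly 1.0 in double precision and ranks would be tie-dominated).
- **Spectra**: singly-charged plain b/y ladders with reproducible
  pseudo-random intensities; noise controls for peak dropout, spurious
  unannotatable peaks, and multiplicative intensity jitter.
- **SILAC pairs**: heavy spectra are the light spectra with y ions
  shifted by the label delta; retention-time jitter and y-peak
  scrambling plant known-discordant pairs.

What the generator does **not** emulate: real instrument noise
structure, chimeric spectra, co-eluting interferences, intensity
saturation, retention-time drift between runs, or realistic protein
abundance distributions. Passing tests therefore demonstrate the
correctness of the *procedures* (error control at the stated levels on
the stated score model, exact threshold behavior, order invariance),
not the sensitivity that would be achieved on real instrument data.

# Problem sizes and numerical choices

The test suite measures error control at sizes chosen to make binomial
noise small relative to the 1% levels being verified: 10 simulations of
20,000 precursors for the local-FDR filter and 10 simulations of 500
target/decoy protein pairs for the picked protein filter (realized rates
are compared to the nominal level plus three binomial standard errors of
the estimate); order invariance is verified byte-for-byte on a
5,000-precursor stream under six batch permutations; each staged
procedure is additionally checked against an exhaustive brute-force
oracle on 200 random small instances.

Numerical conventions worth knowing:

- Modification deltas are canonicalized to four decimals (SILAC deltas
  are conventionally printed to four); precursor equality is string
  equality of the canonical form.
- All TDA prefix rules use "largest prefix with ratio $\le \alpha$";
  the local-FDR window rule uses strictly "$< \alpha$" as stated for
  it. Degenerate windows with zero targets count as FDR 0 when they
  also have zero decoys, infinite otherwise.
- Threshold boundary sweeps in the acceptance material construct ppm
  deviations $10^{-6}$ ppm inside each integer value so that the
  m/z-to-neutral-mass float round-trip cannot cross the boundary being
  measured.
- `-expm1/log1p` for all p-value arithmetic; no p-value is ever
  computed via `(1-p)^N` directly.

# Known limitations

- mzML reading is not implemented; MGF is the peak-list interface
  (the reader contract would admit an mzML backend).
- The ambiguity re-search is consumed as a table, not executed.
- No q-value monotonization beyond the stated window procedure; no
  Bayesian local-FDR model.
- Protein inference is by unique peptides only; no isoform-level
  inference, no quantification.
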
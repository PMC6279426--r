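# speclib

Error-controlled assembly of peptide spectral libraries from
peptide-spectrum matches (PSMs) and peak lists, with order-invariant
incremental updates.

## The problem

Shotgun proteomics experiments identify peptides by matching tandem mass
spectra against a sequence database. Pooling identifications from many
independent searches into one reference spectral library is attractive —
every new dataset adds coverage — but naive aggregation is statistically
unsafe: each search is filtered to a small false discovery rate (FDR) on
its own, yet the *union* of many such filtered sets accumulates false
precursors far beyond any per-search level. A usable community-scale
library therefore needs error control at the library level, a
deterministic rule for choosing one reference spectrum per precursor,
and an update procedure whose output does not depend on the order in
which datasets happen to arrive.

`speclib` implements that pipeline for R users: search-space-aware PSM
scoring, spectrum quality gates, a length-binned sliding-window local
precursor FDR, picked protein-level FDR, representative spectrum
selection by average cosine similarity, ambiguity filtering, and an
associative/commutative candidate-merging scheme that makes incremental
builds exactly equal to an all-at-once build. Downstream tools select
proteotypic precursors by greedy set cover, assess co-observation
detectability, call novel proteins under single-amino-acid-variant
(SAAV) exclusion, and build SILAC light/heavy gold-standard libraries.

## The statistics in brief

- **Database p-value.** A PSM's spectral probability *p* = P(S|T) — the
  probability that a random peptide matches spectrum S better than the
  observed score T — is converted to the probability that at least one
  of the *N* candidate peptides in the searched database does so:
  `1 − (1 − p)^N`. Smaller search spaces (affinity purifications,
  synthetic pools) therefore yield smaller (better) p-values for the
  same match quality; eligibility for a reduced search space requires
  two distinct peptides on the target protein or its reversed decoy
  (pooled counting).
- **Local precursor FDR.** Precursors (peptide + charge) are binned by
  peptide length and ranked by best p-value; the decoy/target ratio in a
  sliding window of 500 records sets the per-length acceptance
  threshold at 1%.
- **Picked protein FDR.** Each protein is scored by the sum of
  −log10(p) over uniquely mapped precursors; each target competes only
  against its own reversed decoy and the winners are ranked for a 1%
  protein-level cut.
- **Representative selection.** Among up to 100 candidate spectra per
  precursor (at most 20 per dataset), the representative is the
  spectrum with the highest mean cosine similarity to all others.
- **Order invariance.** The candidate caps are prefix operations under
  a single total PSM order, so merging batches is associative and
  commutative and the exported library is byte-identical for any batch
  permutation.

## Worked example

```r
library(speclib)

cfg    <- fixtureConfig(seed = 7, nProteins = 12, nTruePeptides = 40,
                        nDecoyPeptides = 15)
uni    <- generateUniverse(cfg)
stream <- generatePsmStream(cfg, uni)

conf  <- buildConfig()                      # all pipeline defaults
psms  <- spectrumQualityFilter(stream$psms, stream$store, conf)
state <- updateCandidates(newLibraryState(conf), psms,
                          store = stream$store)
state
#> LibraryState: 55 precursors in ledger ( 15 decoy ); 55 candidate sets

lib <- buildLibrary(state, uni$targets, stream$store)
lib
#> SpectralLibrary: 40 entries ( 0 decoy )
#>   naive aggregate precursor FDR: 0.375

mean(stream$trueKeys %in% libraryEntries(lib)$key)
#> [1] 1
```

The ledger holds every precursor ever seen (planted decoy fraction
15/40 = 0.375 shows up as the naive aggregate FDR — the error rate a
merge without library-level controls would carry), while the built
library retains all 40 planted true precursors and rejects the decoys.
`exportLibrary(lib, "library.mgf", "mgf")` (or `"sptxt"`) writes a
canonical, annotated library file.

A command-line wrapper over the same functions is installed at
`inst/scripts/speclib` (`build`, `augment`, `export`, `proteotypic`,
`novel`, `silac-gold`, `fixtures`, `report`).

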
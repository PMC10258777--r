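---
title: "Methods: sequon-aware glycopeptide search, group-specific FDR, and HLA-II deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures implemented, the parameters that matter, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

# The identification problem

MHC class II-associated peptides are produced by nonspecific proteolysis,
so the candidate space is every protein substring within a length window
(7–25 residues by default). N-glycans survive class II antigen processing
and remain attached at the sequon **N-X-S/T (X ≠ P)**; in non-enriched
immunopeptidome data glycosylated spectra are rare (< 5%). Two structural
consequences drive the design:

* the glyco candidate space (sequon peptides × glycan compositions) is far
  larger per spectrum than the non-glyco space, so false glyco matches
  score higher than false non-glyco matches;
* a pooled target-decoy filter sets its threshold on the dominant
  non-glyco population and under-filters the glyco fraction.

# Search model

**Database and decoys.** Proteins are reversed wholesale (`rev_` prefix).
Target sequons are `N[^P][ST]`; decoy "sequons" are the mirrored pattern
`[ST][^P]N`. Since reversal is a bijection on substrings, the number of
distinct sequon-bearing target peptides equals the number of distinct
reversed-sequon decoy peptides *exactly* — the property that makes the
glyco-group decoy competition fair. This is asserted as an invariant over
random proteomes in the test suite. The unknown residue `X` never counts
toward a sequon.

**Index.** Nonspecific peptides are deduplicated by (sequence, decoy
status) with merged protein provenance, expanded over variable
modifications (Met oxidation +15.994915, protein-N-terminal acetylation
+42.010565 — protein N-terminus only, cysteinylation +119.004099; at most
2 per peptide, deterministically localized to the first eligible
residues), and mass-sorted. Lookup allows monoisotopic-peak errors of
0/+1/+2 × 1.00335 Da and a 20 ppm precursor window; the glyco branch adds
every glycan mass in the composition database and is restricted to
sequon-bearing candidates.

**Oxonium gate.** A spectrum enters the glyco branch only if the summed
intensity of peaks matching the oxonium panel (HexNAc series 126.055,
138.055, 168.0655, 186.0761, 204.0867; Hex 163.0601; HexNAc+Hex 366.1395;
NeuAc 274.0921/292.1027) reaches 10% of the base peak. Each panel ion
contributes at most its single most intense match within tolerance — a
conservative choice that prevents near-isobaric noise from being counted
twice.

**Scoring.** `hyperscore = ln(Nb!) + ln(Ny!) + ln(max(1, ΣI_b)) +
ln(max(1, ΣI_y))` over matched b/y ions (for glyco candidates, the Y-ion
ladder Y0/Y1/Y2/Yc counts toward the y series). The glycan is treated as a
mass offset: fragments are glycan-agnostic except the Y ladder, so
candidates differing only in composition tie and the composition decision
is deferred to the assignment stage. Ties between candidates break by the
residual against the matched mass hypothesis (|delta − glycan − isotope
correction|), then fewest assumed isotope errors, then lexicographic
peptide, unmodified first. The residual tie-break matters: breaking ties
on raw |delta mass| alone silently prefers the largest isotope error for
glyco candidates and corrupts the reported delta mass by 1–2 Da.

# Layered FDR

**Group split.** PSMs with delta mass ≥ 145 Da (the smallest glycan
considered) form the glyco group; each group is filtered separately to 1%
FDR.

**Estimator.** `tdc_qvalues()` implements FDR(t) = #decoys ≥ t /
max(1, #targets ≥ t) with decoys counted before targets at ties and
q-values as running minima over thresholds. The PSM-level filters add the
standard +1 finite-sample correction to the decoy count: without it, the
plain estimator is anti-conservative exactly in the regime this package
cares about (a small glyco group with a few hundred true PSMs), which we
measured as a ~2× inflation of the true false-discovery proportion at the
nominal 1% level in repeated simulations. The peptide- and protein-level
filters and the glycan competition keep the plain estimator, whose
contract (a lone target with no decoys has q = 0) is part of the module
interface. A consequence worth knowing: with the +1 correction, no 1% FDR
discovery set can contain fewer than 100 PSMs — small runs legitimately
accept nothing at strict levels, and the pipeline handles the empty case.

**Posterior model.** For protein scoring, target hyperscores are modeled
as a two-component mixture: the negative density is a kernel estimate
anchored on decoy scores (Silverman bandwidth — no bootstrap, so no RNG),
the positive component is a Gaussian fitted by EM together with the mixing
proportion, and the posterior is clipped monotone in the score. The score
being modeled is the hyperscore (this simplified search has no expectation
value; FDR calibration is score-scale-free).

**Protein inference.** Parsimony over accepted peptides: proteins with
identical peptide sets are grouped; the minimum cover is found *exactly*
for ≤ 15 candidate groups per decoy class (subset enumeration by
increasing size) and greedily beyond. Exactness at small scale is a
deliberate deviation from a pure greedy rule: greedy set cover is not
guaranteed minimal even on 10-protein instances, and the package's own
oracle tests compare against exhaustive enumeration. Protein score is
Σ −ln(1 − posterior) over assigned peptides, capped at posterior
1 − 10⁻⁶; protein q-values come from decoy proteins. A sequential filter
then removes PSMs whose every protein failed. Peptide- and protein-level
filters are applied pooled (not per group), matching the stated ordering
of the procedure; the group split exists to fix the PSM-level threshold,
which is where the asymmetry bites.

# Glycan assignment

Candidates are all compositions within 20 ppm of the (isotope-corrected)
delta mass. Each is scored on its *composition-dependent* expected ion
set: HexNAc oxonium ions and Hex always; NeuAc oxonium ions only if the
composition is sialylated; Y0/Y1 always, Y2 if HexNAc ≥ 2, the core Yc if
the composition contains HexNAc₂Hex₃, and the fucose diagnostic Y1+Fuc if
fucosylated. Score = +1 per matched ion, −0.5 per expected-but-absent ion,
−0.02 × |ppm error| (all three weights configurable). The fucose
diagnostic is load-bearing: the composition family 2×Fuc vs. NeuAc differs
by 1.0163 Da ≈ one isotope spacing, so with isotope errors allowed the two
are co-candidates and only the Fuc/NeuAc diagnostic ions separate them.

Each candidate also gets one decoy glycan — the same composition with its
Y ions displaced by a seed-controlled shift of ±(0.5–2.5) Da. The best
target competes with the best decoy per PSM; q-values are target-decoy
q-values over competition winners; decoy-winning PSMs get q = 1 and
assignments are retained at q ≤ 0.05. PSMs failing the threshold are
dropped from the glyco set, never re-labeled non-glyco.

# HLA class II deconvolution

**Rank-based assignment.** With an external predictor's percentile-rank
table, a peptide goes to its lowest-rank allele if that rank ≤ 20
(boundary inclusive), else to TRASH; ties resolve to the lexicographically
first allele. Binding-core offsets come from the rank table when supplied,
else from the deconvolved motif.

**PWM mixture EM.** K motif classes (9 × 20 PWMs) plus one always-present
flat background class, over latent (class, core offset). E-step weight:
class weight × offset weight × Π PWM/background. M-step: pseudocount
(α = 0.1) regularized updates; one offset-weight vector per class shared
across peptide lengths (renormalized over each peptide's feasible
offsets) — a simplification of a full per-length offset prior. Defaults
follow the deconvolution stage they replace: K ≤ 10, 20 restarts, minimum
peptide length 12. K is selected by BIC, **including K = 0** (background
only): without the K = 0 option, a fitted near-uniform PWM and the flat
background split responsibility for pure-noise peptide sets arbitrarily,
and no model-free criterion can push all mass to the background class.

**Positional characterization.** Relative position p = site − core offset;
upstream (p < 0), core (0 ≤ p ≤ 8), downstream (p ≥ 9). Coordinates are
0-based internally; TSV outputs carry 1-based companions (`_1b`). Motif
conservation per allele is a two-sided Fisher's exact test (exact
hypergeometric enumeration; tables at most as probable as the observed one
with 10⁻⁷ relative tolerance) on (binder vs. trash) × (glyco vs.
non-glyco), among peptides whose best-ranked allele it is; degenerate
margins give p = 1 with a warning. Gene groups parse from allele-name
prefixes (DPA/DPB → DP, DQA/DQB → DQ, DRA/DRB → DR).

# Synthetic world

The generators state the simulated conditions once; tests and acceptance
checks run at those defaults.

* **Proteome** — i.i.d. residues, uniform frequencies by default (simpler
  nulls than Swiss-Prot frequencies; switchable), sequons planted at the
  requested density ≥ 3 residues apart, entrapment proteins tagged in
  headers.
* **Spectra** — b/y ions with log-normal intensities (meanlog ln 1000,
  sdlog 1), uniform-m/z noise peaks, precursor = peptide (+ glycan) mass
  with isotope-error injection. Glycopeptide spectra carry the
  composition-dependent diagnostic-ion set with oxonium intensity summing
  to 25% of the base peak — above the 10% gate by construction.
* **PSM population** — correct scores N(10, 1); incorrect and decoy scores
  N(5, 1); glyco fraction 3% (the glycosylated share of identified spectra
  in unenriched data is < 5%); non-glyco spectra are correct with
  probability 0.7 (typical of curated immunopeptidome runs); glyco
  incorrect-match *odds* are 30× the non-glyco odds (the search-space
  asymmetry), leaving ~7% of glyco spectra correct, i.e. ~200 true glyco
  PSMs per 100,000 spectra — above the 1/level = 100 floor below which no
  1% FDR procedure can return discoveries at all. Incorrect spectra land
  on a target or decoy with equal probability (the exchangeability
  assumption under which target-decoy competition is valid — and which
  reversed-sequon decoys are designed to deliver in the real search).
* **Rank tables** — planted binders get 20 × Beta(1.2, 8) ranks (strongly
  near 0) with a 2% miss probability; everything else gets
  20 + 80 × Beta(2, 2).

What a green test does **not** establish: real spectra have correlated
noise, co-eluting chimeras, intensity structure along the backbone, and
calibration drift; real score distributions are not Gaussian; real decoys
are only approximately exchangeable with false targets. The simulations
certify the *statistical machinery* (parity, calibration, competition,
recovery), not instrument-level robustness.

# Numerical choices and limitations

* Monoisotopic residue masses fixed at 6-decimal values in a versioned
  constants table; mass book-keeping is consistent to 10⁻⁴ Da.
* Glycan type classes are count-based (structures are out of scope):
  high-mannose iff HexNAc = 2, Hex ≥ 4, no Fuc/sialic acid; truncated iff
  HexNAc ≤ 2, Hex ≤ 3, no sialic acid; complex/hybrid otherwise. All
  thresholds overridable.
* The default composition database is generated combinatorially (HexNAc ≤
  6, Hex ≤ 10, Fuc ≤ 3, NeuAc ≤ 4, NeuGc = 0, 145–4000 Da, HexNAc ≥ 1 as
  the attachment residue; 1307 compositions). Users with a curated glycan
  list should load it as a TSV.
* MGF is the required spectrum format; the mzML reader is minimal
  (centroided MS2, 32/64-bit little-endian arrays, optional zlib).
* EM fits (score mixture, PWM mixture) assert non-decreasing
  log-likelihood traces in the tests; PWM restarts and decoy-glycan shifts
  are seed-controlled, so identical inputs and seeds give byte-identical
  outputs.
* I and L are distinct symbols throughout; deduplication is by exact
  string.
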
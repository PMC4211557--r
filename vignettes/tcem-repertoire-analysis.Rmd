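---
title: "Motif registers, frequency classes, and presentation models in tcemrep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif registers, frequency classes, and presentation models in tcemrep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcemrep)
```

## The model

An MHC-bound peptide exposes only a few side chains to the T-cell
receptor. `tcemrep` fixes the standard register conventions: class II
peptides are scored as 15-mers whose central 9-mer core occupies window
positions 4–12; on core numbering, TCEM IIa is core 2,3,5,7,8 (window
5,6,8,10,11) and TCEM IIb is core −1,3,5,7,8, where "−1" is the residue
immediately N-terminal of the core (window 3,6,8,10,11 — there is no
position 0 in this convention). Class I peptides are 9-mers with TCEM I at
positions 4–8. Each register's complement is its GEM; TCEM and GEM
positions always partition the window, so a point mutation moves a residue
between T-cell-facing and groove-facing roles depending on the reading
frame. All mask positions carry equal weight; no TCR-contact weighting is
attempted.

Presentation of a 15-mer additionally requires excision: endosomal
cathepsins read an octamer spanning four residues either side of the
scissile bond (P4..P1 | P1′..P4′). The full "influence span" of one class
II binding peptide is therefore 4 + 15 + 4 = 23 residues (17 for class I),
and an interior residue participates in 23 overlapping spans — its own
window's span plus 22 more. `frame_span_count()` counts **complete** spans
by default: a window whose excision octamers would run past a terminus
cannot be fully processed, which is the only reading under which a
sequence's first residue sits in exactly one span while interior residues
sit in 23.

When class I and class II motifs of the *same* 15-mer are compared (as in
`shared_tcem_registers()`), TCEM I is taken from the central core;
repertoire-wide class I tables use all 9-mer windows independently.

## Frequency classes

Motif re-use is summarized on a reciprocal base-2 scale: a motif present in
a fraction *f* of repertoire **molecules** gets

FC = ⌈−log2 *f*⌉,

computed in integer arithmetic (the smallest k with
`molecule_count * 2^k >= total_molecules`), so exact powers of two keep
their exponent — 1/4 → FC2, 1/32 → FC5, 1/1024 → FC10 — presence in every
molecule is FC0, and a singleton among 39,982 molecules is FC16
(−log2 = 15.29, rounded up). The ceiling rule is a package choice: the
rounding convention is not fixed by the FC definition itself, but only the
ceiling reproduces the FC16-singleton identity while preserving the exact
power-of-two anchors. FC is molecule-based by default because the classes
are read as "1 in 2^k clonal products"; instance-based classification is
available (`assign_frequency_class(instance_count =, total_instances =)`,
`fc_mode = "instance"` in the pipeline) for sensitivity analysis.

`fc_histogram()` reports per class the unique-motif count and the
frequency-weighted (instance) count; the cumulative weighted fraction
defines the spectrum midpoint as the smallest FC reaching 0.5, ties
resolving to the lower class.

Two further conventions, where the underlying definitions are genuinely
open:

- **Co-location** (`colocalization_fraction()`): "unique" means found in
  exactly one molecule. The default counts, over unique IIa motifs, the
  fraction with at least one window whose IIb partner is also unique;
  `count_by = "window"` counts over window occurrences instead, and
  swapping `from`/`to` gives the symmetric variant. Both are exposed
  because the statistic can be normalized either way.
- **Origin ratios**: origin attribution is a set lookup — a motif is
  germline-origin iff its letters occur in any germline reference sequence
  for the same register — so both per-unique-motif and per-instance
  germline:SHM ratios can be formed from the table; the package computes
  both and fixes neither as canonical.

## The synthetic generator

`make_germline_library()` emulates a family-structured germline set: each
family has an independent random ancestor, members diverge from it at 4% of
positions by default, so intra-family identity (~96%) far exceeds
inter-family identity (~5%, the random-alphabet baseline). Usage weights
come from a flat Dirichlet. Sequences are fixed-length (130 residues, the
standard truncation coordinate).

`simulate_clonotype()` mutates at the amino-acid level: position *i* of a
length-*L* germline substitutes with probability

`base_rate * exp(-(L - i)/decay_length) * hotspot_multiplier`,

to a uniformly random different residue; no indels, so positional alignment
and ground truth are exact. The biology being emulated — AID-driven
hypermutation decaying with distance from the transcription start — is a
nucleotide-level mechanism; what this protein-level profile reproduces is
its *observable*: germline-motif retention falls, and SHM-motif diversity
rises, toward the C-terminal (CDR3-containing) end. Defaults: `base_rate`
0.07, `decay_length` 50 residues, hotspot windows 26–35 (×4), 50–58 (×4),
95–110 (×6) — rough CDR spans on the 130-residue coordinate, configurable.
No quantitative SHM rate is fixed by the biology at protein level; 0.07 was
chosen once so the expected substitution count per 130-residue clonotype
(the analytic sum of the per-position rates, ≈7) sits in the middle of the
5–10 band typical of mutated IGHV, and it is not tuned thereafter.

All randomness flows from one seed through a 32-bit FNV-1a splitting hash
(`(seed, "clone", i)` → sub-seed), so per-clonotype generation is
order-independent, and every stochastic component is bit-reproducible.

What a green simulation test establishes: the counting, classification,
attribution, and profile machinery is exact on data whose truth is known,
and the qualitative germline-vs-SHM spectral structure (common low-FC
germline motifs, rare high-FC SHM motifs, opposite positional trends)
emerges from the stated mutation model. What it does not establish:
repertoire-scale constants (unique-motif totals, co-location percentages,
proteome overlaps) that depend on real curated corpora, V(D)J junctional
diversity, selection, or class-switch structure — none of which are
modeled.

## Presentation scoring

Trained per-allele predictors are deliberately not reproduced: their
training data is external. The module fixes the *contract* — an
`affinity_predictor` is an allele id plus ≥1 member functions mapping a
window to ln IC50 (natural-log nanomolar) — and ships a deterministic
surrogate: each member scores a window as a fixed linear function of five
residue physicochemical indices (Kyte–Doolittle hydropathy, van der Waals
volume, Grantham polarity, charge, flexibility) with allele-specific
weights and small member-specific perturbations, centered near ln(500 nM).
Ensembles aggregate as mean and sample (n−1) SD. Everything downstream —
standardization, threshold profiles, motif-conditioned distributions — is
exercised against this surrogate; per-allele accuracies of real models are
out of scope.

**Johnson Sb standardization.** Within one protein, each allele's ln IC50
values are mapped through
`z = gamma + delta * ln((x - xi)/(xi + lambda - x))`. The bounds start at
the sample range inflated by 1% per side; each side's pad is then fitted by
Nelder–Mead to minimize the squared deviation of the transformed sample's
skewness and excess kurtosis from Gaussian targets, after which the
least-squares `(gamma, delta)` pin the sample mean and SD to exactly
(0, 1). Fitting the bounds (rather than freezing them at 1%) matters: with
frozen bounds a standard-normal sample is visibly distorted
(cor(input, output) ≈ 0.97), whereas the fitted bounds recede and the
transform approaches linearity (cor > 0.99) while still symmetrizing
skewed inputs. The transform is strictly monotone, so within-allele
peptide ranking — and hence any rank-based threshold statistic — is
preserved exactly. Degenerate inputs: constant samples error; samples with
fewer than 20 values fall back to plain z-scoring with a warning.

**Binding fractions.** "Binding" means standardized ln IC50 more than
`threshold_sd` (default 1) below the allele's within-protein mean — lower
IC50 is stronger affinity, so −1 σ is unusually strong binding. The
threshold is applied on the standardized scale; because standardization is
monotone, raw-scale and standardized thresholds select the same rank
boundary per allele. Repertoire profiles aggregate per aligned window
center as mean and 10th/90th percentiles. The default allele panel is the
64 identifiers shipped in `hla_allele_roster()` (20 HLA-A, 16 HLA-B, 16 DR,
6 DP, 6 DQ); class II alleles score full 15-mers throughout.

**Cleavage.** A `cleavage_predictor` maps each P1P1′ dipeptide to a scoring
function on the octamer, squashed to a probability in [0, 1]; the surrogate
draws dipeptide-specific weights deterministically from
`(enzyme, seed, dipeptide)`. Profiles score interior bonds 4..L−4 only —
bonds nearer a terminus have no complete octamer and are reported absent.

## Numerical and interface choices

- Coordinates are 1-based inclusive everywhere.
- Windows containing `X` are enumerated but flagged `skip`: they yield no
  motifs and no counts (ambiguity cannot define a motif); they are skipped,
  never an error.
- Curation truncates to the first 130 residues by default and deduplicates
  by id (first occurrence wins); full-sequence dedup is a flag. Signal
  peptides are not predicted or removed — callers supply mature sequences.
- Gapped motif display prints one `~` per run of skipped positions between
  selected positions (`AI~W~RQ`, `N~I~W~RQ`), so the IIb "−1 gap" collapses
  to a single tilde.
- The pipeline config is JSON (jsonlite) rather than YAML — no YAML parser
  is a package dependency — with identical key structure; every default
  used is echoed into the run manifest, which also records the seed and an
  md5 digest of each output, making runs reproducible from the manifest
  alone.
- `theoretical_motif_space()` returns exact doubles (20^10 exceeds 32-bit
  integers but is exact below 2^53) and warns beyond 2^53.

## Known limitations

- The worked-example class I motif of a 15-mer is defined via the central
  core; a class I motif arising from an arbitrary unaligned 9-mer register
  of the same peptide region is not recoverable from a 15-mer alone, and no
  attempt is made to infer binding registers.
- Origin attribution is presence-based: an SHM event that regenerates a
  motif present elsewhere in the germline reference is labeled germline —
  with known ground truth this coincidence rate is measurable, but it is
  not corrected for.
- The surrogate predictors share only the *interface* and aggregation
  statistics with trained models; absolute affinities, per-allele AROC, and
  ensemble-SD magnitudes are properties of real training data and are not
  emulated.
- Population-scale statistics in the literature of this problem (unique
  motif totals of ~2.75 × 10^5 in 40,000-sequence sets, ~85% overlap with a
  proteome reference, and the like) require those corpora and are
  represented here only as property tests on synthetic data.
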
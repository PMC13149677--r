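---
title: "Screening food metabolomics features against chemical knowledge bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening food metabolomics features against chemical knowledge bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtrace)
```

## The problem

Untargeted LC-MS profiling of foods yields tens of thousands of molecular
features, of which only a small fraction can be identified against authentic
standards. The remainder carry at best a molecular-formula annotation.
`chemtrace` implements a two-branch triage of such a feature table against
chemical knowledge bases:

1. **Structure branch.** Features identified at the structure level (with an
   InChIKey) are matched by exact InChIKey equality to curated references of
   pharmaceuticals, food-contact chemicals and agrochemicals, and annotated
   with therapeutic categories where available.
2. **Formula branch.** Features annotated only at the formula level are
   screened by set membership of their canonical molecular formula in the
   union of formulas from natural-product occurrence databases. A formula
   absent from that union is called a *putative xenobiotic* — a candidate
   anthropogenic signal.

Two follow-up analyses build on these branches: a fluorine prioritization of
the xenobiotic pool (fluorinated natural products are exceptionally rare, so
F-containing non-natural formulas are strong anthropogenic candidates, PFAS
among them) and a taxonomy-aware *novel producer* screen that flags
(compound, genus) pairs where a pharmaceutically relevant compound is
detected in a food whose organism genus is not recorded as a producer in any
natural-product database.

The two branches are disjoint by design: a structure-annotated compound is
never re-screened as a xenobiotic even when its formula is absent from the
natural-product union.

## Formula arithmetic

Formulas are flat neutral elemental compositions. The parser accepts
underscore and Unicode-subscript count markers (`"C_8F_17KO_3S"`) because
published tables often typeset subscripts that way, and rejects charges,
isotopes, parentheses and hydrates — those notations do not occur in
formula-level feature annotations, and silently mis-parsing them would be
worse than failing loudly. The canonical rendering is Hill order (C, then H,
then other elements alphabetically; fully alphabetical without carbon), which
serves as the portable membership key for all set operations.

The degree of unsaturation is computed as

$$\mathrm{DBE} = C - \frac{H + X}{2} + \frac{N}{2} + 1,$$

with $X$ the total halogen count (F, Cl, Br, I); O, S and P contribute
nothing. The implementation computes $2\,\mathrm{DBE}$ in integer arithmetic
and divides by two, so every attainable value (integers and half-integers)
is exact; half-integer values indicate radical or adduct species and are
reported as-is rather than rounded, since rounding would distort the
distribution's peak at zero that characterizes perfluoroalkyl chemistry.
Formulas containing any element outside {C, H, N, O, S, P, F, Cl, Br, I}
(e.g. K in the PFOS potassium salt `C8F17KO3S`) have no defined DBE: the
equation carries no valence term for them, so they are reported as
*excluded*, a value rather than an error, and tallied separately wherever
DBE distributions are built.

Van Krevelen coordinates are the elemental ratios H/C and O/C; they are
undefined for carbon-free formulas, which are dropped from the diagram and
counted. Heteroatom profiles track S, P, F, Cl, Br, I. The reported
per-element numbers are *features-containing* counts (a feature with 17 F
atoms counts once), matching how such tables are reported. Because the
halogen flag covers all four halogens while published per-element tables
sometimes enumerate only the observed ones, both the per-element counts and
the any-halogen count are reported, so either tallying convention can be
reproduced.

## Reference indexing

Six source kinds are recognized: three drug-like structure references
(`drugbank`, `fccdb`, `agrochem`; matched by InChIKey, schema
`inchikey, name, categories`) and three natural-product occurrence
references (`lotus`, `coconut`, `supernatural`; schema
`inchikey, formula, genus`). Loading validates InChIKeys against the
27-character pattern, canonicalizes formulas to Hill strings, drops and
counts invalid rows, and merges duplicate keys within a source (genera and
categories unioned). The index holds per-source InChIKey sets, the union of
natural-product formulas, a genus-occurrence map keyed by both InChIKey and
canonical formula, and a therapeutic-category map; genus comparisons are
case-insensitive over capitalized keys because organism-name capitalization
is inconsistent across sources. Reference fixtures are plain TSV — the
screens only ever need (inchikey, formula, genus, category) tuples, never
full database dumps.

Therapeutic-category exports mix pharmacological classes with
non-therapeutic descriptors; `select_therapeutic_categories()` intersects
each compound's terms with a user-supplied whitelist (the analysis this
package supports keeps 20 broad categories) and drops compounds left with
none, without affecting their InChIKey matchability.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `match_mode` | `"full"` | Full 27-character InChIKey equality. `"block1"` matches the 14-character skeleton only, conflating stereoisomers; opt-in because relaxed matching inflates match counts. |
| `detect_min` | `0` | Detection floor on normalized intensity (dimensionless); a cell is a detection when strictly greater. The matrices this package targets are dense and internal-standard normalized, so zero is the natural floor. |
| `prevalence_threshold` | `0.10` | Compounds detected in more than this fraction of the denominator population are excluded from the novel-producer screen (strictly greater), retaining specialized rather than ubiquitous metabolites. |
| `prevalence_population` | `"plant"` | Denominator for prevalence: plant samples or all samples. Both conventions appear in practice, so both are first-class. |
| `aggregation` | explicit | `"mean"` (dense block mean, zeros included) or `"sum"`. Both are meaningful summaries and published figures use both, so the choice is never implicit. `detected_only = TRUE` switches means to detections only. |
| `transform` | `"log10p1"` in heatmaps | log10(x + 1), applied after aggregation; chosen because intensities include zeros. |
| `bin_width` | `0.5` | DBE histogram bin width — one bin per attainable half-integer value. |

## The novel-producer screen

The sample's genus is the first whitespace-delimited token of its organism
binomial, capitalized; bare non-binomial strings (`"unknown"`) yield no
genus and are skipped with the feature's detection. The screen restricts to
structure-annotated compounds matched to the pharmaceutical reference (the
`"all-structure"` scope widens this), applies the prevalence filter, then
emits one pair per (compound, genus) whose genus is absent from the
compound's known producers, deduplicated keeping the maximum-intensity
detection (ties broken by sample id). Genus occurrence is looked up by
InChIKey first, falling back to the canonical formula when the
natural-product record lacks a key. `rank_producers()` merges novel and
known detections of each screened compound into a single intensity ranking
so a novel source can be compared against the best known producers.

## The synthetic study generator

`generate_study()` emulates the structure of a large food-metabolomics
release at desk scale, with every downstream answer planted and recorded as
machine-readable ground truth. Defaults: 2,000 features (100
structure-annotated, 1,900 formula-only) over 100 samples split 70 plant /
15 animal / 8 algal / 7 fungus — the 70%-plant, 15%-animal composition of
the release it emulates, at a size where the full test suite runs in
seconds. Planted truth:

* **Xenobiotics** (96 features, the 4.8% rate of the full-scale release):
  absence from the natural-product union is enforced *constructively* —
  the natural-product grammar only emits CHNO(S,P) formulas, so any
  halogenated or metal-containing plant is absent by construction, and
  plain-CHNO plants are rejection-sampled against the realized union.
  Sensitivity and specificity of the screen are therefore exactly 1 by
  design, and the tests assert that.
* **Fluorinated candidates** (30): biased toward DBE 0 (the perfluoroalkyl
  signature), and including verbatim the three recurring hard-cheese
  formulas (`C33H35FN2O5`, `C21H23ClFNO2`, `C23H27FN4O2`) and the PFOS
  potassium salt `C8F17KO3S`, which also exercises the DBE exclusion path.
* **Source matches** (12 drug, 5 food-contact, 2 agrochemical): disjoint
  subsets of the structure stratum whose InChIKeys are planted in the
  corresponding reference fixture alongside decoy compounds, including
  drug decoys carrying only non-therapeutic categories.
* **Novel pairs** (7) and **decoys** (3): drug-matched compounds whose
  detections are fully controlled. A novel compound is detected in one
  plant sample of an unrecorded genus (at the highest intensity, so it
  tops its producer ranking) plus two samples of genera registered as
  known producers; its prevalence stays below the threshold under both
  denominator conventions. Decoys are detected in >10% of plant samples
  and must be screened out.
* **Group effect**: drug-matched intensities are amplified 10-fold in
  plant samples, so the plant row of the aggregation matrix must strictly
  dominate.
* **Intensity model**: log-normal (meanlog 7, sdlog 1.5) with a 0.6 zero
  fraction — heavy-tailed, sparse, scale-free, the shape of normalized
  untargeted intensities. The tests check the realized zero fraction to
  within two percentage points over the non-planted cells.

Randomness is re-seeded per table (metadata, references, features,
intensities) from fixed offsets of the study seed, so resizing one table
does not perturb the others, and a fixed seed reproduces the study — and
its serialized file tree — byte-identically.

What the generator does *not* emulate: m/z values, retention behavior,
adducts and isotopes, correlated feature blocks from shared biosynthesis,
real database coverage biases, or annotation errors. Passing the
planted-truth suite therefore demonstrates that the screening logic is
exact given its inputs; it says nothing about upstream formula-assignment
quality or the coverage of real reference databases, which on real data
dominate the error budget.

## Numerical and degenerate-input choices

* Percentages are rounded half away from zero at report time only
  (`round_half_up()`); internal values stay exact.
* The xenobiotic share is reported relative to **all** features, not
  formula-only features — the convention consistent with the printed
  headline rates this workflow reproduces.
* Unparseable formulas route to an `unclassifiable` side table and are
  never silently dropped; the partition identities
  (structure + formula-only = total; NP-match + xenobiotic +
  unclassifiable = formula-only) are asserted on every run.
* Hierarchical clustering uses average linkage on Euclidean distances of
  the log-transformed matrix; rows and columns are pre-sorted by label
  before clustering so leaf orders are reproducible across runs.
* Ties in rankings break lexicographically (sample id, food name) —
  deterministic output over equal intensities.
* Empty feature subsets aggregate to structurally present zero rows with a
  warning rather than disappearing.

## Known limitations

Formula-level calls are putative by nature: structural isomers share a
formula, so no chemical-class assignment is attempted for xenobiotics.
"Novel producer" means *absent from the supplied occurrence records*, which
reflects database coverage as much as biology. InChIKey validation is
pattern-only; the package cannot verify that keys derive from standard
InChIs. The percent-style reports follow half-up rounding of the printed
conventions they mirror, which can differ from banker's rounding in the
last digit.
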
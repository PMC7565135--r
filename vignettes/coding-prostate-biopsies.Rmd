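---
title: "Coding prostate biopsies from SNOMED CT extracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding prostate biopsies from SNOMED CT extracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biopsycoder)
```

## The procedure and its assumptions

Pathologists code each prostate biopsy in the laboratory information
system (LIS) with SNOMED CT morphology (M) and topography (T) axis codes,
captured as chained comma-separated strings, alongside the narrative
report. `biopsycoder` converts warehouse extracts of those strings into
registry-style coded variables through reusable lookup tables:

1. chained strings are parsed and normalised (case, spacing and exact
   duplicates are treated as presentation; the printed form `M-81 403`
   and the key form `M-81403` are the same code);
2. the *unique* code combinations are extracted and classified once each,
   producing an M lookup table (diagnosis, diagnosis ICD-O-3,
   sub-diagnosis, sub-diagnosis ICD-O-3, sub-result) and a T lookup table
   (organ, organ ICD-O-3);
3. the lookup tables are joined back onto the episode-level extracts with
   left-outer-join semantics, so every episode is retained and
   missingness is measured rather than silently dropped.

The central modelling assumptions are:

* **Combination order carries no diagnostic information.** Lookup keys
  are sorted and de-duplicated, so `M-81 403, M-80 003` and
  `M-80 003, M-81 403` classify identically. The original order-sensitive
  strings are retained separately because completeness reporting counts
  them as captured. This is a deliberate departure from spreadsheet-era
  practice, where each captured ordering occupied its own hand-coded row;
  a consequence is that the table of unique combinations is smaller than
  an order-sensitive count, and `build_stats()` reports both counts.
* **A malignant code anywhere in the chain makes the episode
  malignant.** The full class precedence is malignant > uncertain
  (8000/1) > atypia/dysplasia > benign (8000/0) > unclassifiable. Only
  the malignant-over-benign step is directly attested by worked examples
  (normal tissue + adenocarcinoma ⇒ malignant); ordering uncertain and
  atypia between malignant and benign is a clinical-severity choice, kept
  configurable through the rule set rather than hard-coded.
* **Benign findings compose.** Benign sub-diagnoses are built from six
  components reported in a fixed clinical order — inflammation,
  hypertrophy, hyperplasia, edema, atrophy, adenosis — joined as
  "Inflammation and hypertrophy" (two) or "Inflammation, hypertrophy and
  hyperplasia" (three or more). Combinations containing only neutral
  codes (normal tissue, morphologic description only) become "No
  pathologic diagnosis". When an inflammation code's description carries
  a type qualifier (acute, chronic, granulomatous) it populates the
  sub-result.
* **Topography is binary.** A combination containing a
  prostatic-structure code (`T-92000`, `T-28000`) is Prostate (ICD-O-3
  C61.9); everything else is Other. Mixed chains such as
  `T-92 000, T-74 000` are prostatic.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_age` | 30 years | cohort lower age bound, inclusive |
| `date_range` | 2006-01-01..2016-12-31 | review-date window, inclusive endpoints |
| `keyword` | `"prostate"` | case-insensitive narrative filter |
| `top_n` | 10 | frequency rows before the "Other" roll-up |
| report precision | 0 / 1 / 2 decimals | capture table / combination table / frequency tables |

Percentages are computed with half-up rounding, the convention of the
registry tables this package reproduces (`base::round()`'s half-to-even
would print 7.545% as 7.54). Capture-table percentages use the grand
total, not row totals; combination percentages use the M-captured count;
sub-diagnosis percentages use their diagnosis count.

## ICD-O-3 conventions

Behaviour codes follow the registry scheme: 8000/0 benign, 8000/1
uncertain, 8000/3 malignant; adenocarcinoma 8140/3, carcinoma 8010/3,
high grade intraepithelial lesion 8148/2. Two deliberate fidelity
choices: the atypia/dysplasia diagnosis class carries 8000/0 (the
published convention, although /2 would be the in-situ behaviour), and
adenocarcinoma is always 8140/3 (the behaviour digit consistent with its
malignant diagnosis; an isolated printed variant 8140/2 exists in the
source material's worked example and was not adopted).

## The rule set and dictionary are data

`default_rules()` names explicit codes only where the published coding
scheme names them (the three malignant codes, the
inflammation/hypertrophy/hyperplasia benign codes, the two neutral
codes, the two prostate codes). Everything else — edema, atrophy,
adenosis, inflammation qualifiers — activates by case-insensitive keyword
match on the code's dictionary description, so registry teams extend the
classifier by extending the dictionary file, not the code. The shipped
dictionary (`inst/extdata/snomed_dictionary_synthetic.tsv`) is a
synthetic stand-in for a real LIS code table: it contains the codes the
published scheme names plus package-default codes for the classes whose
LIS codes are not public (atypia M-69700, dysplasia M-74000, HGPIN
M-74008, uncertain M-80001, edema M-36300, atrophy M-58000, adenosis
M-72400, acute/chronic/granulomatous inflammation M-41000/M-43000/
M-44000, and T-74000 as a non-prostatic example site). Unknown codes
never abort a run: they render as `<code>:UNKNOWN`, classify as
Unclassifiable when nothing else is present, and are counted in
`build_stats()`. Expert curation is modelled by `apply_overrides()`
(override > rule) and survives the lookup table's text round trip.

## What the synthetic generator emulates

`generate_extracts()` produces the two extract files the pipeline
consumes. Its defaults are the study conditions of a provincial
2006–2016 national-laboratory extract: 25 010 episodes; capture-cell
rates 88.0% both codes, 0.7% M-only, 10.1% T-only, 1.1% neither;
a chained-M-combination distribution proportional to the ten most common
published combinations (inflammation-only 15.5% of M-captured episodes,
adenocarcinoma combinations next) with the remaining ~30% spread over a
tail of benign, atypia/dysplasia/HGPIN and uncertain combinations chosen
once as a realistic completion (the published top-10 covers only ~70% of
M-captured volume and the remainder's composition is not public; the tail
includes the rarer classes so all four diagnosis branches are exercised);
topography ~93.4% prostatic among both-captured; ages truncated-normal
(mean 65, sd 11, support 18–95, so the ≥30 filter bites); review dates
uniform over the window; narrative templates that always contain the
word "prostate" and a Gleason mention for malignant findings (which the
pipeline deliberately does not parse). Chained strings are emitted in
the spaced display form and order-scrambled with probability 0.25 to
emulate capture-order variation; classification is provably invariant to
this. All randomness flows from one seed (default 20060101).

What it does **not** emulate: real narrative prose (templated sentences
only), PSA values and Gleason grade distributions, temporal incidence
trends, facility-level case-mix differences, patient-level repeat-biopsy
correlation (episodes are independent draws; patient identifiers repeat
only incidentally), and M/T capture correlation beyond the four cell
rates. Passing tests therefore demonstrate the coding pipeline's
correctness on structurally realistic extracts, not the clinical
representativeness of any simulated cohort.

`fixture_from_counts()` is the deterministic inverse of the reporting
layer: given exact category counts it builds a record-level dataset whose
reports reproduce those counts exactly. A benign "Other" roll-up count is
split across unnamed benign labels each kept strictly below the smallest
named top-10 count, and unnamed combination volume is filled with
distinct tail combinations the same way, so top-N + Other reports
round-trip. Inconsistent nested counts are rejected with the violated sum
named.

## Numerical and degenerate-input choices

* Ties in frequency tables break lexicographically on the rendered label,
  making golden-file comparisons stable.
* Empty report inputs warn and render zero tables rather than erroring.
* Records lacking an age or review date are excluded by the cohort filter
  and counted in `filter_stats`.
* A chained string of only commas/whitespace counts as not captured.
* Duplicate episodes in the biopsy extract are an error (the episode is
  the unit of analysis); duplicate SNOMED rows for one episode union
  their codes per axis before classification.
* The episode-count question of filter-before-report versus
  report-before-filter is left to the caller: `filter_cohort()` is a
  separate step that logs both input and output counts, and every
  reporting surface works on whatever record set it is given. The
  synthetic extracts are generated as already cohort-screened (every
  narrative contains the keyword), mirroring a warehouse query that
  filtered at extraction time.

## Problem sizes used in the test suite

The suite exercises the exact-count fixtures at the full 25 010-episode
scale, end-to-end synthetic runs at 400–10 000 episodes (10 000 for
binomial parameter recovery, which bounds deviations by three binomial
standard errors), and exhaustive rule-engine verification over all code
subsets of size ≤ 3 from the shipped dictionary against an independent
nested-conditional oracle.

## Known limitations

* The classifier is combination-based: it cannot assign findings to
  individual cores within one episode, and it inherits any miscoding in
  the LIS.
* Gleason scores live in the narrative and are out of scope here.
* Episodes are the unit of analysis; no patient-level deduplication or
  probabilistic matching is attempted.
* The ~11–12% of episodes lacking an M or T code are measured but cannot
  be classified; making the code fields mandatory in the LIS, or text
  mining the narrative, is the only remedy.
* The precedence of atypia and uncertain classes in mixed combinations is
  a documented design choice, configurable via the rule file.
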
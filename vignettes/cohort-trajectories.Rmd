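---
title: "Mining comorbidity trajectories from longitudinal EMR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining comorbidity trajectories from longitudinal EMR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cohortflow)
```

## The analysis model

cohortflow studies how a cohort of patients sharing one *index diagnosis*
(chronic kidney disease in the shipped configuration) accumulates other
diseases and procedures over time. The pipeline is a fixed sequence of
transformations, each of which is a plain function you can also call on its
own:

1. **Factor mapping.** Raw diagnosis/procedure codes are mapped to a small
   vocabulary of binary *factors* `F = {f_1, ..., f_M}` via pattern rules
   (prefixes, numeric and decimal ICD-9 ranges, exact procedure codes).
2. **Alignment.** Each patient becomes a trajectory of records
   `(F_k, t_k)`, with `t_k` the signed day offset from the *first*
   index-factor occurrence. Using the first occurrence makes day 0 the
   incident diagnosis; patients never carrying the index factor are not
   part of an index-disease cohort and are excluded (and counted).
3. **Windowing.** User-chosen boundaries define half-open windows
   `[t_l, t_{l+1})`; a patient's records inside a window merge into one
   factor set (the union). The set observed in a window is that patient's
   *comorbidity*; its sorted, `|`-joined label is the canonical key of the
   "unique combination".
4. **Clustering.** Within each window patients are grouped into cohorts,
   either by frequency (small exact-comorbidity groups merge into
   "others") or by agglomerative clustering of the unique comorbidities
   under the Ochiai similarity
   `|s1 ∩ s2| / sqrt(|s1| |s2|)`.
5. **Network.** Cohorts become nodes; consecutive-window cohorts with
   overlapping membership are joined by edges carrying the overlap
   cardinality and the conditional probability
   `pb(c_{l+1,j} | c_{l,i}) = |c_{l,i} ∩ c_{l+1,j}| / |c_{l,i}|`.
   Each source cohort gets an *outcome entropy* over its outgoing
   probabilities, and edges can be filtered by an entropy threshold.
6. **Layout and export.** Node orders are optimized to reduce weighted
   ribbon crossings, and the result is exported as a Sankey JSON document
   plus a static standalone HTML view.

## Design choices worth knowing about

### The outcome-entropy formula

The dispersion measure attached to each cohort is, by default, the Shannon
entropy with natural logarithm, `-sum(p_k * log(p_k))`. This is the form
consistent with the intended semantics of the filter: it is 0 exactly when
all of a cohort's members flow to one target, and maximal (`log K`) when
the `K` outcomes are uniform, so a threshold of 0 keeps only the fully
confident ("fully overlapped") associations. An alternative mode,
`as-printed`, computes `-sum(p_k * p_k)` — a negated Simpson-type
concentration index that some implementations rank by. It orders cohorts
the same way but lives on `[-1, -1/K]` (a deterministic outcome scores -1,
not 0), so threshold values are not interchangeable between the modes.
Both are exposed via `outcome_entropy()` and the `entropy$mode` run-config
key; Shannon is the default because every textual property claimed of the
filter (zero at determinism, maximum at uniformity, a meaningful 0
threshold) holds for it.

Entropy is a property of the *source* cohort — every outgoing edge of a
node shares it — so filtering removes a node's out-edges all or none.
Nodes are never removed by filtering, only edges.

### Probabilities under attrition

The conditional probability divides by the full source cohort size
`|c_{l,i}|`, even if some members have no presence in the next window.
Because patients with no in-window records are kept in an explicit
`"(none)"` cohort, attrition can only occur at the ends of the observation
span; where it does, a node's outgoing probabilities sum to less than 1
and the per-node sum is reported (`prob_sum`) rather than silently
renormalized.

### Clustering over unique comorbidities

Hierarchical clustering operates on the window's *unique* factor sets, not
on patients: the similarity is defined between two unique comorbidities,
and the cost then scales with the number of distinct combinations rather
than the cohort size. Patients inherit the cluster of their key.

Average linkage is used (a robust default for similarity-derived
distances; the `weighted` option switches to patient-count-weighted
averages for users who want populous combinations to dominate). Equal-distance merges
are resolved by always merging the pair whose representative keys are
lexicographically smallest, which makes the dendrogram — and therefore any
cut — deterministic, and makes the `k`-cluster solution an exact
refinement of the `(k-1)`-cluster one.

The Ochiai coefficient is undefined on empty sets (division by zero). The
conventions used are: both sets empty, similarity 1 (they are identical);
exactly one empty, similarity 0. The `"(none)"` combination therefore
clusters with itself and merges with others only when `k` forces it.

### Labels

A cohort's label lists the factors shared by *all* its members, with `*`
appended when some member carries more. Two corner cases meet here: a
mixed group sharing nothing is labelled exactly `"*"`, while a group whose
members all have empty window sets is labelled `"(none)"` — the explicit
no-factor group is a real analysis object (e.g. patients with no watched
post-index factor), not an uncertainty marker. Custom labels override.
The merged small groups are labelled `"others"` and, by default, split
into others-with-index and others-without-index, with reserved light
orange / light green tints in the export.

### Layout

Node ordering uses barycenter sweeps with simulated annealing: per sweep,
each window's nodes are reordered by the cardinality-weighted mean of
their neighbours' band centers, restacked with a configurable gap (which
resolves overlaps while preserving order), and the move is accepted if it
does not worsen the objective — weighted crossings first, total weighted
ribbon length as tie-break — or with probability `exp(-delta/T)` under a
geometric cooling schedule (default 32 sweeps, cooling 0.98, initial
temperature one mean node height). The best state ever visited is
returned, so the final weighted crossing count never exceeds the initial
one; exact minimization is NP-hard and not attempted. All randomness is
drawn from a seed local to the call; the global RNG stream is untouched.
Ribbons draw large-first (`z_order()`), keeping minority flows visible.

## The synthetic-data generator

Real claims extracts of this kind (the shipped factor vocabulary targets
Taiwan national-insurance-era claims coding) are access-restricted, so the
package includes a seeded generator, `synth_generate()`, producing
long-format CSVs in the same shape a claims extract would take. What it
emulates:

- an index diagnosis for every patient at a randomized calendar date
  (1998–2011 era, so ISO date parsing is exercised), day 0 by construction;
- pre-index comorbidity accrual as independent per-factor Poisson
  processes over an 8-year lookback, with prevalence-ordered annual rates
  (hypertension 0.12/yr down to lupus 0.005/yr);
- a first post-index year in which hemodialysis occurs with probability
  0.0954 — the population proportion reported for the CKD setting this
  vocabulary comes from;
- one terminal-phase event in the 5-year follow-up, with outcome splits
  conditioned on first-year hemodialysis: given HD, none 0.702 /
  death 0.149 / peritoneal dialysis 0.099 / transplant 0.05 (anchored on
  the reported 70.2 % HD-only persistence); without HD, none 0.62 /
  death 0.05 / PD 0.28 / transplant 0.05 (most non-HD patients show no
  watched follow-up factor, and their mortality is lower);
- a configurable *deterministic subcohort* (default 10 %) whose members
  follow a fixed chain — polycystic kidney disease before the index, then
  hemodialysis, then peritoneal dialysis — so the cohort network contains
  zero-entropy transitions and the strict confidence filter has something
  to keep. Mortality is emitted as a sentinel `DEATH` code bound to a
  `Death` factor in `synth_factor_map()`, since real extracts encode death
  outside the diagnosis stream.

Codes are sampled from the shipped pattern lists themselves (range
patterns yield random in-range codes), so the code-matching layer is
exercised end-to-end, and the generator also emits a truth table of every
patient's per-window factor sets; the mapping and windowing stages must
reproduce it exactly, which the test suite asserts.

What the generator deliberately does *not* model: clinically realistic
CKD natural history (stage progression, correlated comorbidities, age and
sex effects), coding noise and miscoding, repeated procedure billing, or
calibration to any real database's joint distributions. Passing tests on
synthetic cohorts therefore demonstrate the *mechanics* — alignment,
merging, clustering, probabilities, filtering, layout, export — not
epidemiological validity on real claims data.

## Numerical and degenerate-input conventions

- Codes are normalized (dots and whitespace stripped, uppercased) before
  matching; diagnosis category codes act as prefixes (250 covers 250.xx),
  decimal ranges are closed intervals within one 3-digit category, and
  alphanumeric procedure codes match exactly.
- Windows are half-open `[t_l, t_{l+1})`; a record on a boundary belongs
  to the window opening there. Out-of-range records are dropped, not
  clipped.
- Chronic-condition persistence is *off* by default (a factor appears only
  in windows where a code occurs); `carry_forward = TRUE` propagates
  earlier diagnosis factors (never procedures) into later windows.
- Probability sums are compared to 1 at `1e-12`; layout objective ties at
  `1e-12`-level differences are treated as equal and broken
  lexicographically.
- JSON exports are byte-stable: fixed key order, floats at 6 significant
  digits, label colors assigned by a stable string hash.

## Problem sizes

The shipped tests and the acceptance script run cohorts of 100–2,000
synthetic patients over three windows — enough for every frequency path,
both clustering operators, entropy filtering and layout to be exercised
with stable statistics, while a full suite run stays comfortably in the
tens of seconds. The implementation itself scales with the number of
unique combinations per window (clustering) and edges (layout), matching
how the underlying method is meant to be used interactively.

## Known limitations

- The interactive web application around this model — brushing, live
  re-clustering, metadata query panels — is out of scope; the library
  computes the same quantities (`highlight_selection()`,
  `summarize_selection()`) and the HTML export is a static rendering.
- The default factor vocabulary ships the 15 published association-rule
  rows; accompanying prose mentions 17 criteria, but only 15 rows with
  code patterns exist to ship, and the package will not invent the
  missing two. Users can extend the map freely via `parse_factor_map()`.
- No statistical significance testing of associations; the entropy filter
  ranks confidence, not significance.
- ICD-9-CM only; no ICD-10/SNOMED translation and no validation against
  official code catalogues.
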
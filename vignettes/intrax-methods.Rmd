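---
title: "Methods: integrated-similarity read-across"
author: "intrax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated-similarity read-across}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`intrax` performs analogue-based read-across for a binary toxicity
endpoint (here: modulation of human aromatase, CYP19A1, in a cell-based
assay). A *target chemical* is compared against every labelled *source
chemical* under three independent similarity views, each yielding a
candidate list:

1. **Structural** — Tanimoto coefficient over 881-bit substructure-key
   fingerprints, candidates at similarity ≥ `strs_threshold`;
2. **Metabolic** — Tanimoto coefficient over ordered 5-bit CYP
   isoform-inhibition profiles (1A2, 2C9, 2C19, 2D6, 3A4), candidates at
   similarity ≥ `mts_threshold`;
3. **Mechanistic** — at least one structural alert (SMARTS fragment
   associated with the endpoint) shared with the target.

The analogue category is the intersection of the three lists: every view
carries equal weight, and no cap is placed on the category size. The
predicted label is the strict majority of the members' experimental
labels. The central assumption is the read-across premise itself:
compounds that are simultaneously similar in structure, expected
metabolism and mechanistic flags tend to share the endpoint outcome. The
intersection narrows the applicability domain deliberately — many targets
receive no prediction — in exchange for purer categories, which is the
behaviour the leave-one-out statistics quantify (high unpredicted rate,
higher sensitivity and MCC than a structure-only vote).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `strs_threshold` | 0.7 | inclusive Tanimoto cut-off on fingerprints (dimensionless, 0–1) |
| `mts_threshold` | 0.7 | inclusive Tanimoto cut-off on 5-bit CYP profiles |
| `mode` | `"IntS"` | vote over the intersection; `"StrS"` votes over the structural list alone |
| `tie_policy` | `"equivocal"` | tied votes give no call; `"worst_case_active"` implements a conservative worst case |
| `fingerprinter` | `pubchem_fingerprint` | pluggable fingerprint generator (scheme-tagged; fingerprints of different schemes are never compared) |

Both thresholds are *inclusive* (≥ 0.7): the case-study categories
contain members scored at exactly the threshold-adjacent scores 1.0 and
0.98, and inclusive comparison is the common convention. On 5-bit
vectors the inclusive 0.7 threshold admits exactly the similarity levels
{0.75, 0.8, 1.0} — a fact asserted in the tests by enumerating all 32×32
profile pairs.

A tied vote is reported as `equivocal` and grouped with `unpredicted` in
all statistics: majority voting defines no tie outcome, and declining to
call is the conservative default. The alternative worst-case policy
(ties → active) is available but not default.

## The fingerprint dictionary and its dialect

Structural similarity uses the published 881-key substructure dictionary
(hierarchic element counts; ring counts; atom pairs; atom neighbourhoods;
simple and complex SMARTS patterns). The package evaluates the dictionary
itself rather than wrapping a fingerprint routine:

* **Key table.** The table of key definitions is loaded from ChemmineR's
  copy of the published dictionary (`fingerprint_keys()` exposes it and
  can write the versioned TSV). That copy truncates every definition at
  the first `#` character; the affected entries are restored in code, and
  six hydrogen-anchored patterns whose whole definition was lost are
  best-effort reconstructions flagged `reconstructed` in the emitted
  table. Tanimoto similarity depends only on the evaluated pattern set,
  not on bit order.
* **Element semantics.** Element tokens in the published definitions
  match the element irrespective of aromaticity; they are translated to
  `[#n]` SMARTS atoms.
* **Bond semantics.** Single- and double-bond tokens are matched
  kekulé-tolerantly (`-` → `-,:`, `=` → `=,:`): aromatic bonds satisfy
  them too. This reproduces how CDK-style implementations of these keys
  behave on kekulized aromatic systems and was selected because it
  reproduces all four case-study similarity scores within ±0.02 of their
  reported values, whereas strict Daylight bond semantics drifts up to
  0.09 below on the aromatic-rich pairs. Exact bit-level parity with any
  particular implementation is not claimed — fingerprint dialects differ
  at the margin, which is why a ±0.02 band accompanies the case-study
  scores and why alternative generators can be plugged in.
* **Hydrogen patterns** become minimum-H-count constraints (`!H0` …), so
  molecules with implicit hydrogens match directly.
* **Rings.** Ring-count keys are evaluated over an ESSSR-style ring set:
  for every bond on a cycle, the smallest ring through that bond
  (breadth-first search), de-duplicated by atom set. Aromaticity comes
  from OpenBabel's perception (a ring is aromatic when all its bonds
  are); a ring is *saturated* when every ring bond is a single bond,
  *unsaturated non-aromatic* otherwise.

All substructure matching (fingerprint SMARTS sections and structural
alerts) runs through OpenBabel via ChemmineOB; canonical SMILES and InChI
come from the same toolkit, so one aromaticity model is used throughout.

## Structure standardization and curation

`standardize_smiles()` keeps the largest organic fragment (most heavy
atoms; ties by carbon count, then lexicographically smallest canonical
SMILES), preserving formal charges — a permanently cationic imidazolium
stays charged, which the alkyl-imidazolium alert (`[n+]`) requires. The
duplicate-detection key is the standard InChI of that parent: its
mobile-hydrogen layer collapses tautomers by a fixed, documented rule,
which implements the tautomer normalisation step of dataset curation
deterministically.

Curation rules: potency converts as `pAC50 = 9 − log10(AC50[nM])`;
replicate groups whose AC50 max/min ratio exceeds 3 are rejected,
otherwise merged. Two points were genuinely open and are decided here:
the *1:3 range* is read as max/min ≤ 3, and the replicate *mean* is taken
on the −log molar scale (equivalently the geometric mean of AC50),
because potencies are log-distributed and the range rule itself compares
fold-changes. Qualitative-only replicate groups are kept when their
labels agree and rejected otherwise. Agonist and antagonist calls both
binarize to *active*; the direction of modulation is not retained.

One representational limitation is documented rather than hidden: SMARTS
matching sees the charge placement as drawn, so for charge-delocalized
cations (imidazolium) the alert requires the resonance form with the
charge on the methyl-bearing nitrogen; the fixtures and the generator
write SMILES in that form.

## Validation statistics

Active counts as positive. Unpredicted targets (including equivocal
votes) enter only the unpredicted rate; sensitivity, specificity,
accuracy and MCC are computed over predicted targets. MCC uses the
standard square-root denominator — the reported value pairs
(0.77 with matrix 34/3/5/27 and 0.49 with 49/35/23/178) are only
consistent with the square root, which the tests verify. The likelihood
ratio is implemented as `((tp+tn)/(fp+fn)) · ((tp+fn)/(tn+fp))` (correct
over wrong predictions times the class balance); its typeset source is
ambiguous and no reference value exists, so the formula is isolated in
one place and documented here. Statistics with zero denominators are
reported as absent (`NA`), never as zero; a run with no wrong prediction
reports an infinite likelihood ratio. The non-unique match tally counts
every category member once per category and reports the ratio of
non-matching to matching counts, the reading that reproduces both
reference ratio values (944/2050 → 0.46, 26/211 → 0.12).

Leave-one-out removes the target row *and* every source sharing its
structure key, so salt forms of the same parent cannot vouch for each
other.

## The synthetic generator

`synthetic_azoles()` emulates the two case-study chemotypes with exact
ground truth:

* 1-alkyl-3-methylimidazolium cations, chains C2–C18; active from 8
  chain carbons on (the same chain length at which the alkyl-imidazolium
  alert fires), actives carrying the 2D6-only inhibition profile seen in
  the case study;
* 2-aminobenzothiazoles with C1–C6 alkoxy chains at position 6 (active,
  1A2+2C19 profile) or position 4 (inactive, 1A2-only profile),
  mirroring the reported 4-substitution inactivation pattern.

Label noise flips each label independently at the stated rate under a
seed; identical spec and seed give identical output. The defaults (29
compounds) were chosen once as the smallest set that exercises every
pathway: categories that vote correctly, short-chain targets with no
alert (hence unpredicted under integration), and a metabolic split that
separates the 4- from the 6-substituted subseries.

What the generator does *not* emulate: real structural diversity (only
two scaffolds), assay noise in the quantitative potencies, borderline
similarity values near the 0.7 threshold, and compounds with partial or
missing profile data. A green synthetic suite therefore shows the
machinery is correct under the stated rules, not that the thresholds are
optimal for any real dataset.

On the noiseless default series, leave-one-out integrated predictions
are perfect (sensitivity = specificity = 1) and short-chain homologues
are unpredicted, by construction. Under label noise the sensitivity
advantage of the integrated mode over the structure-only mode is a
statement about expected behaviour: single replicates of a 29-compound
set have sensitivity granularity 1/17 and can invert the ordering by
chance, so the acceptance test compares means over several seeded
replicates rather than one draw.

## Problem sizes

The test suite and acceptance checks run on the fixture sets (11 and 9
source compounds), the 29-compound synthetic series with 12 noisy
replicates, 1,000 random confusion matrices for the statistics
cross-check, and the full 32×32 profile-pair enumeration. These sizes
make every check exact or tightly converged while keeping a full run in
the order of a minute.

## Known limitations

* CYP profiles are inputs; the package deliberately does not re-train or
  re-implement an inhibition predictor. Two all-zero profiles score
  metabolic similarity 1.0 by policy (identical predicted behaviour);
  the raw Tanimoto is 0/0 and the choice is this package's decision.
* A target matching no structural alert has an empty mechanistic list
  and is always unpredicted in integrated mode; this is the rule's
  consequence, reported with the reason `empty mechanistic list`.
* The structure-only mode applies the same 0.7 threshold as the
  integrated mode's structural screen.
* Fingerprint scores carry a dialect uncertainty of about ±0.02 around
  values computed by other implementations of the same dictionary.
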
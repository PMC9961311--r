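# intrax — integrated-similarity read-across for analogue identification

`intrax` implements a read-across workflow for qualitative toxicity
prediction, developed around in vitro human aromatase (CYP19A1) modulation
by azole chemicals. Read-across estimates the endpoint of an untested
*target chemical* from tested *source chemicals* judged similar; the
package is for computational toxicologists who need a transparent,
reproducible way to pick those analogues and to audit why each one was
picked.

## The method

Candidate analogues are retrieved from a labelled source dataset by three
independent similarity views and only compounds passing **all three**
screens form the analogue category:

* **Structural similarity (StrS)** — the Tanimoto coefficient
  `T(a, b) = c / (n_a + n_b − c)` over 881-bit PubChem-style substructure
  fingerprints (`c` shared set bits, `n_a`, `n_b` set-bit counts), with an
  inclusive threshold of 0.7.
* **Mechanistic similarity (McS)** — sharing at least one structural alert
  with the target, from a shipped registry of 21 SMARTS alerts for human
  aromatase toxicity.
* **Metabolic similarity (MtS)** — the Tanimoto coefficient over 5-bit
  cytochrome P450 inhibition profiles (isoforms 1A2, 2C9, 2C19, 2D6, 3A4;
  threshold 0.7). Profiles are supplied as data or through a pluggable
  predictor; the package does not predict CYP inhibition itself.

The predicted label is the strict majority vote of the category members
(`IntS` mode); a structural-only mode (`StrS`) votes over the structural
list alone. Leave-one-out validation reports sensitivity, specificity,
accuracy, error rate, unpredicted rate, MCC and a likelihood ratio, plus
the non-unique tally of category members matching their target's activity.

Curation helpers cover the dataset-preparation rules: salt stripping with
charge retention, tautomer-collapsing structure keys (standard InChI),
AC50→pAC50 conversion (`9 − log10(AC50[nM])`), duplicate reconciliation
(reject groups whose AC50 range exceeds 1:3, otherwise average on the
−log scale), and azole classification.

## Worked example

The shipped fixtures carry the two case studies: an alkyl-imidazolium
target and 2-amino-6-ethoxybenzothiazole. For the latter:

```r
library(intrax)
fx <- case_study_fixtures("benzothiazole")
model <- rax(fx$dataset, profiles = fx$profiles)
pred <- predict(model, fx$targets[, c("id", "smiles")])
pred
#> Read-across predictions (IntS mode)
#>                              id    status  label votes_active votes_inactive n_members
#> 1 2-Amino-6-ethoxybenzothiazole predicted active            3              0         3
evidence_report(pred)
#>                               id membership activity rank  strs mts shared_alerts
#> 1 2-Amino-6-methoxybenzothiazole       StrS   active    1 0.975  NA          SA_1
#> 2                    Tioxidazole  IntS+StrS   active    2 0.942   1          SA_1
#> 3                       Riluzole  IntS+StrS   active    3 0.934   1          SA_1
#> 4 2-Amino-4-methoxybenzothiazole       StrS inactive    4 0.906  NA          SA_1
#> ...
```

Nine sources pass the structural screen, but only Methabenzthiazuron,
Riluzole and Tioxidazole also share the target's CYP profile; the
4-substituted analogues are structurally close (e.g. 0.906) yet drop out
on metabolism, and the category votes 3–0 for *active* — the correct
call. `predict(..., mode = "StrS")` shows what a structure-only vote
would have done (6 active vs 3 inactive here).

`loo(model)` (or `summary(model)`) runs the leave-one-out validation;
`synthetic_azoles()` generates homologous series with known ground truth
for end-to-end testing. A command-line interface is installed as
`exec/intrax` with subcommands `predict`, `loo`, `curate`, `fingerprint`,
`alerts` and `synth`.

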
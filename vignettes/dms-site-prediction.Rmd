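---
title: "Predicting active-site and buried residues from deep mutational scanning data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting active-site and buried residues from deep mutational scanning data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmsites)
```

## The problem

A deep mutational scan (DMS) measures the phenotypic effect of nearly every
single amino-acid substitution in a protein. Positions that are sensitive to
mutation fall into two structurally distinct groups: buried residues, where
substitutions destabilize the fold, and exposed *active-site* residues —
catalytic, ligand-binding or interface positions — where substitutions break
function directly. Without a structure, sensitivity alone cannot separate
the two. This package implements a procedure that adds one extra, cheap
signal: per-residue relative side-chain solvent accessibility predicted from
sequence (PROF, NetSurfP, SPIDER3, or any tool exporting a
`position, rel_acc` table). Sensitive **and** predicted-exposed residues are
called active-site; sensitive **and** predicted-buried residues are called
buried; everything else is exposed non-active-site.

## The model

1. **Rescaling.** Raw effect scores $M$ (log-ratio-like, wild type near 0)
   are mapped to $[-1, 0]$ by
   $M_{\mathrm{rescaled}} = (b-a)\,\frac{M - \min(M)}{\max(M)-\min(M)} + a$
   with $a = -1$, $b = 0$, where $\min(M)$ is the 5th percentile of the
   score distribution and $\max(M)$ is the wild-type peak — the mode of the
   histogram, populated by near-neutral mutations. Fully deleterious scores
   sit near $-1$, neutral ones near $0$.
2. **Aggregation.** Rescaled scores are averaged per position; positions
   with fewer than 10 observed mutants are dropped. Per-position
   *sensitivity* is defined as minus the mean rescaled score, so it lies in
   $[0, 1]$ with 1 = fully sensitive.
3. **Combination.** Over positions that also have a sequence-predicted
   accessibility value, both sensitivity and accessibility are converted to
   Z-scores (mean 0, population SD 1). The combined scores are
   $Z_{\mathrm{active}} = Z_{\mathrm{sens}} + Z_{\mathrm{acc}}$ and
   $Z_{\mathrm{buried}} = Z_{\mathrm{sens}} - Z_{\mathrm{acc}}$.
4. **Calling.** Each combined score is thresholded one standard deviation
   above its own mean ($k = 1$). Residues above neither cutoff are exposed
   non-active-site, giving a full three-class partition.
5. **Evaluation.** Each class is scored one-vs-rest: sensitivity,
   specificity, accuracy, and the Matthews correlation coefficient, with
   cross-dataset summaries as unweighted means over datasets.

### The sign convention

"Add for active-site, subtract for buried" is only meaningful once the
orientation of the sensitivity score is fixed. We define sensitivity as
*positive* (1 = fully sensitive). Then both rules are consistent: a
sensitive exposed residue has both terms of $Z_{\mathrm{active}}$ positive,
a sensitive buried residue has both terms of $Z_{\mathrm{buried}}$ positive,
and both classes use the single one-sided rule
$\text{score} > \text{mean} + k\cdot\text{SD}$. With the raw (negative =
sensitive) orientation, addition would cancel sensitive-exposed residues to
zero, which cannot produce the observed classification behaviour. This is
our documented reading, not a claim about the original authors' code;
`k_sd` is exposed for sensitivity analysis.

### Other conventions and numerical choices

- **Percentile:** linear interpolation between order statistics (R quantile
  type 7). The choice barely matters at DMS sample sizes (thousands of
  mutants) but is fixed and tested against a hand-rolled oracle.
- **Wild-type peak:** median of the scores in the most populated of
  `n_bins = 100` equal-width bins across the score range; ties between bins
  break toward the larger bin midpoint (wild-type-like scores sit at the
  high end). `n_bins` is configurable; manual anchors can be pinned per
  dataset via `min_M`/`max_M` when a distribution is pathological.
- **Clamping:** scores outside the anchor interval are clipped to
  $[-1, 0]$ by default (off switch available). This keeps sensitivity in
  $[0, 1]$, which downstream standardization assumes; the tail below the
  5th percentile carries no extra information about class.
- **Population SD** everywhere (no stated ddof; keeps `standardize()` exact
  on small vectors).
- **Dual calls:** a residue above both cutoffs keeps the class whose
  combined score lies more SDs above its mean and is flagged
  `ambiguous_dual_call`.
- **Exclusion lists** (e.g. buried-but-catalytic metal-coordinating
  cysteines labelled active-site) are removed from the buried call and from
  buried-class evaluation only.
- **MCC zero-denominator** convention: 0.
- **Residue numbering:** all tables are 1-based in the DMS dataset's
  coordinate system; `numbering_offset` shifts accessibility-table numbering
  onto it. How published datasets reconciled DMS and structure numbering is
  generally unstated, so the offset is our generalization.

## The synthetic generator

`synthetic_config()` / `simulate_dataset()` state a world resembling a
mid-sized single-domain protein under a well-behaved phenotypic screen:

| parameter | default | meaning |
|---|---|---|
| `n_positions` | 200 | mutagenized positions |
| `class_fractions` | 0.10 / 0.25 / 0.65 | active-site / buried / exposed |
| `deleterious_mean`, `deleterious_sd` | −4, 1 | raw-scale deleterious effect |
| `wt_score_sd` | 0.3 | neutral noise around 0 |
| `aliphatic_tolerance` | 0.7 | P(aliphatic substitution neutral at buried position) |
| `target_r` | 0.9 | Pearson r between true and predicted accessibility |
| `missing_rate` | 0.1 | unobserved mutants |

The class rules encode the substitution-preference structure seen in real
scans: active-site residues are sensitive to every substitution category,
buried residues tolerate aliphatic substitutions (never when the wild type
is Ala or Gly, which leave no room to repack) but not polar, charged or
aromatic ones, and exposed non-active-site residues are neutral. Buried
wild types are biased 4:1 toward hydrophobic identities. The published
description names the categories but not their memberships; we fix
aliphatic {A,V,L,I,M,G}, aromatic {F,W,Y,H}, polar {S,T,N,Q,C}, charged
{D,E,K,R}, and treat proline — which belongs to none — as non-aliphatic
(deleterious at buried positions). Predicted accessibility is the
standardized truth plus Gaussian noise of variance $1/r^2 - 1$, mapped back
to the percent scale and floored at 0, so its expected correlation with the
truth is `target_r`.

Where no published value existed (effect-size distributions, tolerance
probability, missing rate), defaults were chosen once as a realistic regime
for a screen in which roughly a third of substitutions yield measurable
phenotypes, and are calibration targets of this package, not published
values.

**What a green synthetic test establishes — and does not.** The generator
produces clean two-component score distributions, class-conditionally
independent noise, no epistasis, no position-to-position correlation, no
systematic predictor bias (its accessibility error is unbiased Gaussian),
and truth labels that follow the 5% burial rule exactly. Passing recovery
tests therefore shows the pipeline implements its own model faithfully and
degrades sensibly with predictor quality; it does not certify performance
on real scans, whose score distributions are messier and whose
active-site labels are curation-dependent.

## Worked example

```{r example, eval = FALSE}
library(dmsites)
sim <- run_simulate(list(n_positions = 200, seed = 7), "sim")
pred <- run_predict(file.path("sim", "scores.tsv"),
                    file.path("sim", "accessibility_predicted.tsv"),
                    out_dir = "run")
report <- run_evaluate(file.path("run", "predictions.tsv"),
                       file.path("sim", "truth.tsv"), dataset_id = "sim7")
report[, c("class", "sensitivity", "specificity", "accuracy", "mcc")]
```

At seed 7 and defaults this prints active-site sensitivity 0.85 /
specificity 0.96 and buried sensitivity 0.94 / specificity 0.98 — the
qualitative regime of the better published datasets (the tests recompute
these numbers; nothing here is asserted that the suite does not itself
compute).

## Known limitations

- Residue depth is not used anywhere (it never enters the prediction
  formulas), and accessibility is always consumed as a table — no
  coordinate-level calculation.
- The one-sided 1-SD rule and the sign convention are our documented
  reading of an ambiguous description; `k_sd` and the convention's effects
  are testable but the original authors' exact choices are not recoverable.
- Whether positions failing the ≥10-mutant filter belong in published
  evaluation denominators is unstated; here they are excluded from both
  prediction and evaluation (intersection semantics, logged).
- Stop codons, indels and multi-mutant variants are rejected, not modelled.
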
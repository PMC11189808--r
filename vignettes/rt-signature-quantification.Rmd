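---
title: "Quantifying m1A from reverse-transcription signatures: model and methods"
author: "rtsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying m1A from reverse-transcription signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtsig)
```

## The assay and its model

N1-methyladenosine sits on the Watson–Crick face of adenosine. A reverse
transcriptase copying an mRNA template through an m1A therefore produces a
mixture of outcomes at that one position, and the mixture is informative
about the fraction of molecules carrying the mark. `rtsig` models one
modified site per amplicon — by default the m1A at ND5 transcript position
1374 (mtDNA 13710, wobble position of codon GCA) — with a per-molecule
generative model:

* with probability θ (the **stoichiometry**) the template molecule is
  methylated; otherwise the RT copies it faithfully;
* conditional on methylation, the RT outcome is multinomial:
  **read-through** (correct incorporation of T, probability
  `pReadthrough`), **misincorporation** of cDNA base b ∈ {A, C, G}
  (`pMis[b]`), a **jump** that skips the template base (`pJump`, a 1-nt
  deletion in the cDNA), or **arrest** (`pArrest`, truncation);
* every emitted base is then subject to uniform sequencing error at rate
  `seqError` (substitution to one of the three alternatives, chosen
  uniformly; no indel errors, so jumps remain RT-derived by construction).

Because the cDNA is the reverse complement of the mRNA and all reporting is
on the **sense strand**, incorporation of A or C opposite the site appears
as a T or G mismatch. The observed mismatch composition T > G > C is
therefore the mirror of an A > C > G incorporation preference — the
diagnostic skew of m1A under a high-read-through RT. The involution
`incorporationToSenseMismatch()` encodes exactly this logic.

Reverse transcription proceeds 3'→5' along the mRNA. An arrested molecule
consequently yields a cDNA covering only the region 3' of the site: in the
pileup it appears as a read *starting* just after the site, never as a
base call at the site. Arrests are counted (`termCount`) but no arrest-rate
statistic is produced; misincorporation and jumps are the two readouts, and
they deliberately use different denominators:

* `mismatch_rate = (Σ base calls − reference calls) / Σ base calls`
* `jump_rate = deletions / (base calls + deletions)`

A deleted site produces no base call, so mixing the two denominators would
bias both estimators.

## Coordinates and the SNP exclusion rule

Coordinates are 1-based and inclusive throughout; BED input is converted at
the boundary. The packaged ND5 annotation starts at mtDNA 12337, which is
what makes transcript position 1374 equate genome position 13710. The
G13708A variant sits two bases upstream of the site on the sense strand
(inside the same GCA codon) and abolishes methylation; carrier samples show
no m1A signature at all. Genotyping is fraction-based rather than binary
because mtDNA is heteroplasmic: a sample is a carrier when the alternative
allele fraction at the SNP pileup is ≥ 0.8, a non-carrier when ≤ 0.2, and
indeterminate otherwise (indeterminate samples are excluded and logged,
never silently kept).

Whether mismatches should be reported on the read strand or the sense
strand is a genuine convention choice; `rtsig` fixes the sense strand
everywhere (reference stored mRNA-sense, pileup bases sense-frame), which
removes per-read strand bookkeeping from the statistics layer. Similarly,
the jump window is exactly the site coordinate — not a ±k window — which is
unambiguous here because the simulator builds amplicons without
homopolymers of length ≥ 3, and the aligner left-aligns deletions.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| θ (`theta`) | 0.05 control / 0.15 case | fraction of methylated molecules |
| `pReadthrough` | 0.80 | correct incorporation given m1A |
| `pMis` | A 0.10, C 0.06, G 0.01 | misincorporated cDNA base given m1A |
| `pJump` | 0.02 | site skipped (1-nt deletion) |
| `pArrest` | 0.01 | truncation at the site |
| `seqError` | 0.001 | per-base uniform substitution error |
| `minDepth` | 100 | minimum spanning reads per site |
| `vafThreshold` | 0.8 | SNP carrier allele-fraction cutoff |
| amplicon length | 200 nt | site centred, ≥ 20 nt flanks |
| depth | 10,000 molecules/sample | cohort simulations |
| cohort | 12 controls / 13 cases, 2 carrier cases | default structure |

The RT event probabilities are free parameters of the synthetic model —
chosen as plausible values for a high-read-through RT on m1A, with the
A > C > G incorporation skew — not measurements. The first-order expected
readouts are `mismatch_rate ≈ θ·Σ pMis` and `jump_rate ≈ θ·pJump` (exact
expressions in `expectedSignature()`, which accounts for sequencing error
and the denominator corrections). `minDepth = 100` reflects that
sub-percent signatures drown in binomial noise below that coverage.

## Alignment

Amplicon reads span the reference by construction, so the aligner is a
strict Needleman–Wunsch with linear gap penalty (match +1, mismatch −1,
gap −2; affine gaps are unnecessary when the only expected indel is a
single-base RT jump). The pipeline uses the end-gap-free ("overlap")
variant in which leading/trailing *reference* bases are free, so
arrest-truncated reads are placed by mapping position instead of being
penalized as giant deletions. Tie-breaking in the traceback is fixed — M
over D over I — which provably left-aligns deletions, matching standard
variant-normalization conventions and making the jump coordinate
deterministic. An equal-length read whose best gapped score cannot beat its
all-match score is shortcut past the DP; the shortcut condition is derived
from the scoring bounds, so it is exact, and the aligner is verified
against a brute-force DP oracle in the test suite. A minimal SAM
writer/reader lets the pileup layer consume externally aligned data.

## Cohort statistics

Group comparison applies, in a fixed and logged order: (1) SNP-carrier
(and indeterminate-genotype) exclusion, (2) optional Braak stratification
(cases at stages 5–6 versus controls at 0–3; records with missing stage are
dropped with a warning), (3) Grubbs outlier exclusion within each group,
(4) a two-sided unpaired t-test. The order is a design choice — outliers
are judged only among the samples actually being compared.

"Unpaired t-test" is implemented as the pooled-variance Student test by
default (the classical reading, and the default of the common GUI
statistics packages), with Welch available behind `variant = "welch"`.
Grubbs uses the two-sided critical value
`((n−1)/√n)·√(t²/(n−2+t²))`, `t` the upper α/(2n) Student quantile with
n−2 df, applied **per group** with at most one removal per group per
metric — a conservative cap consistent with removing only extreme points.
Robust-regression outlier screening (ROUT-style) is intentionally not
implemented: it targets regression residuals and its tuning parameter has
no counterpart here; Grubbs alone is the supported exclusion. No
multiple-testing correction is applied across metrics, which are reported
as separate per-metric tests.

## What the simulator does and does not emulate

Emulated: per-molecule RT outcomes with the stated probabilities, uniform
substitution sequencing error, constant Phred quality (Q40, carried but
unused), single-end full-amplicon reads, SNP-carrier samples (alt allele in
every molecule, θ forced to 0), Braak-staged two-group cohorts (controls
drawn from stages 0–3 centred near 2.5, cases from 4–6 centred near 4.8),
and deterministic per-sample seeds derived from one master seed.

Not emulated: PCR duplicates and jackpotting, position- or quality-
dependent error profiles, indel sequencing errors, heteroplasmy gradients
beyond the binary carrier flag, primer/adapter artefacts, and multi-exon
genes (mitochondrial genes are single-exon). Passing tests therefore
demonstrate estimator correctness under the stated generative model — not
robustness to library-preparation artefacts real data may contain.

For statistical calibration experiments that need hundreds of cohorts,
`simulateSignatureCohort()` draws each sample's site column directly from
the exact multinomial outcome distribution (`siteOutcomeProbs()`). The site
counts are sufficient statistics for every signature, so this reproduces
the sampling distribution of the read-level pipeline at negligible cost;
the read-level path itself is exercised by the convergence, SNP-carrier and
determinism tests.

## Numerical choices and degenerate inputs

* Grubbs requires n ≥ 3 and non-zero variance; groups failing either are
  left untouched. Ties in the extreme deviation go to the first index.
* `unpairedT()` refuses degenerate (zero-variance-everywhere) inputs
  rather than returning NaN.
* A pileup whose spanning depth is below `minDepth` raises a typed
  `lowCoverageError` carrying the observed depth.
* If a site pileup contains deletions only (possible in degenerate
  simulations with `pJump = 1`), the mismatch rate is reported as 0 — no
  base calls means no evidence of misincorporation — while the jump rate
  is 1.
* `compareGroups()` sorts records by sample id before any step, so results
  are invariant to input row order.
* Probability vectors are validated to sum to 1 within 1e-12;
  `mismatchRate` equals the sum of its per-base decomposition within the
  same tolerance.

## Problem sizes used by the test suite

The suite simulates at depth 10,000 molecules per sample where estimator
convergence is asserted (tolerances are 4 binomial standard errors), uses
2,000 null cohorts at the site-count level for the type-I calibration of
the full exclusion-plus-t-test pipeline (Monte Carlo SE ≈ 0.005 around the
nominal α = 0.05), 250 random 15-nt pairs for aligner/oracle equivalence,
and small read-level cohorts for end-to-end byte-reproducibility. These
sizes were chosen so each property is tested at a precision matching its
tolerance.

## Known limitations

* One configured site (plus its SNP site) per amplicon; this is a targeted
  assay, not transcriptome-wide m1A discovery.
* Absolute stoichiometry recovery requires the RT event probabilities to
  be known or calibrated; across-group *comparisons* only require them to
  be shared, which is the package's primary use.
* The arrest rate is observable (`termCount`) but no statistic is built on
  it, since truncation yields depend strongly on reaction conditions.
* The aligner is a transparent stand-in for whatever read processing a
  production sequencing facility would use; the SAM layer exists precisely
  so external alignments can be substituted.
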
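---
title: "Modelling DNA damage tolerance pathway choice at a single chromosomal lesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DNA damage tolerance pathway choice at a single chromosomal lesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddtsim)
```

## The assay and the question

When a replication fork meets an unrepaired blocking lesion — a UV
photoproduct such as TT(6-4) or TT-CPD, or a bulky adduct such as G-AAF —
the cell can finish replication without removing the damage. Three fates
compete for the single-stranded daughter-strand gap left opposite the
lesion:

* **HDGR** (homology-directed gap repair): the missing information is
  retrieved from the intact sister chromatid;
* **TLS** (translesion synthesis): a specialized polymerase copies straight
  across the lesion, potentially mutagenically;
* **damaged chromatid loss**: the gap is never filled, the daughter cell
  inheriting the damaged chromatid dies, and the colony is founded solely
  by the sister that replicated the undamaged strand.

The assay this package models integrates a heteroduplex vector carrying
exactly one lesion into the *E. coli* chromosome, with strand-specific
genetic markers in *lacZ* (A and B on the undamaged strand, C and D on the
damaged strand) so that each fate leaves a distinct colour and marker
signature: sectored blue/white colonies carry C+B (HDGR), pale blue C+D
(TLS), and pure white colonies carry only A+B (chromatid loss). Colony
counts, normalised to a lesion-free control and to an internal
transformation standard, become tolerance percentages.

## The stochastic model

One integration is one Bernoulli/Poisson experiment
(`simulate_integration()`, vectorised in `simulate_colonies()`):

* the introduced gap resolves by HDGR with per-gap probability $h$, by TLS
  with probability $t$, otherwise stays unresolved and the damaged-chromatid
  daughter dies;
* the sister daughter carries $n \sim \mathrm{Poisson}(\lambda)$ gaps from
  lesions on the opposite strand, $\lambda = \lambda_{opp} + \lambda_{uv}$
  (endogenous burden plus, in clustered-UV mode, the introduced load); each
  resolves independently with probability $r = h + t$, and the daughter
  survives only if all do;
* a colony forms if either daughter survives.

Writing it out gives the closed form used throughout
(`survival_closed_form()`):

$$S = r + (1-r)\,e^{-\lambda(1-r)},\qquad
\mathrm{HDGR} = h,\quad \mathrm{TLS} = t,\quad
\mathrm{loss} = (1-r)\,e^{-\lambda(1-r)},$$

all as fractions of integrations, the lesion-free control being 1. The
control arm survives with probability one by construction: normalisation to
the lesion-free control cancels any attrition shared by both arms, so only
differential death belongs in the model. Endogenous lesions are placed only
on the strand opposite the introduced lesion for the same reason.

```{r closed-form}
str(survival_closed_form(default_params("recA", "TT64")))
```

## Parameters and calibration

`default_params()` holds the per-strain calibration. The driving
observations are: parental strains tolerate a single lesion essentially
without viability loss, >80% of events being HDGR, with ~10% chromatid loss
and rare TLS (below 0.3% for UV lesions, below 3% for G-AAF); recA-null
strains survive at ~50% with ~85% of survivors white and 7–13% sectored
(a residual RecA-independent exchange activity); recF strains halve HDGR
with little viability cost and a four-fold G-AAF TLS rise; recB trims HDGR
by roughly 20%; sulA behaves parentally.

```{r params}
default_params()
```

The shared $\lambda_{opp} = 0.8$ makes the recA survival come out at
$0.06 + 0.94\,e^{-0.8 \times 0.94} \approx 0.50$, and is itself recoverable
from data by inverting the survival model
(`estimate_opposite_burden()`, exact to $10^{-9}$ against the closed form).
At $\lambda_{opp} = 0.8$ about 55% of integrations carry at least one
opposite-strand lesion — the model's reading of why only half of
HR-deficient cells survive a single introduced lesion.
`calibrate_params()` reproduces such tables from target percentages by a
deterministic minimax grid search ($h, t$ on a 0.005 grid,
$\lambda_{opp}$ on 0.05; ties broken by L2, then grid order), treating
published values as band targets rather than point data.

Clustered-UV mode adds $\lambda_{uv} = 2.56$ lesions on the opposite
strand, chosen so the lesion-free zero class of the Poisson load is
$e^{-2.56} = 7.73\%$ — within the two-to-three lesions per strand the
protocol aims for — matching the zero-class correction below.

## The molecular readout

Constructs are synthetic but geometrically faithful
(`build_reference_construct()`): primer sites for VP56/VP215 (506 bp
amplicon), VP210/VP215 (1100 bp) and VP56/GM1 (2283 bp) are embedded so the
published product lengths fall out of `pcr_amplify()`; lesion context
oligonucleotides are the published 13-mer (HincII site, UV lesions) and
15-mer (NarI site, G-AAF). Marker alleles are engineered so each locus
toggles one diagnostic restriction site (SspI/PvuII for pLL1/2c,
EcoRI/PvuII for pLL1/7, SspI/NheI for pLL4/5, BglII/SspI for pLL9/2c) — the
published data constrain only decodability and lengths, not which allele
carries which site, so that assignment is the package's own. The backbone is
drawn from a fixed deterministic stream and then scrubbed so no diagnostic
motif or primer site occurs where it should not, for any of the up-to-64
allele combinations.

`digest()` treats enzymes as blunt cutters at a fixed offset (overhang
chemistry does not move gel bands) and scans both motif orientations; gel
resolution is treated as perfect. `decode_genotype()` forward-simulates all
allele combinations once per layout, verifies the pattern-to-genotype map is
injective, and inverts it; the exhaustive round-trip is part of the test
suite. Marker D is a 2-nt insertion allele and B a 4-nt insertion opposite
it, so the B/D frame bookkeeping (+6 vs +2 relative to the common frame)
matches the blue/pale-blue/white colour logic; translation itself is not
modelled. One consequence: the TLS daughter's amplicon is 504 bp rather
than 506 — below gel resolution in the real assay, and the printed 506 bp
is asserted on the undamaged daughter.

```{r readout}
con <- build_reference_construct("pLL1_2c")
amp <- pcr_amplify(daughter_sequence(con, event_genotype(con, "hdgr")),
                   con$primers[["fwd"]], con$primers[["rev"]])
digest(amp, con$enzymes)
```

## Quantification and corrections

`tolerance_partition()` computes class percentages as
$100\,(x_i/\text{std}_\text{lesion})\,/\,(n_\text{ctrl}/\text{std}_\text{free})$
with Wilson score intervals on the lesion-arm multinomial, scaled by the
normalisation ratio (the score formula is evaluated directly because
corrected counts are non-integer).

**Marker conversion.** About 5% of B/D heteroduplex regions are converted
before replication even without mismatch repair. The package models
conversion as a single joint flip of the B/D unit per daughter: an HDGR
daughter then reads C+D and a TLS daughter C+B, which is exactly the 2×2
confusion matrix $[[1-c, c],[c, 1-c]]$ that
`marker_conversion_correct()` inverts. Independent per-locus flips were
considered and rejected: they would relabel HDGR as TLS only with
probability $c^2$ and create a marker pattern (C alone) that the assay's
readout has no class for, leaving the published single ~5% correction with
nothing to correct. `estimate_conversion_rate()` recovers $c$ from
lesion-free control colonies as the fraction of decoded daughters whose B/D
information contradicts their A/C strand of origin.

**Zero-class correction.** With clustered UV lesions, a fraction
$f_0 = e^{-\lambda}$ of molecules escaped irradiation unlesioned; observed
survival is the mixture $S_{obs} = f_0 S_{single} + (1-f_0) S_{clustered}$,
which `clustered_survival_correct()` inverts (clipping to $[0,1]$ with a
warning when sampling noise pushes the inversion outside).

## Synthetic data: what it does and does not emulate

The generator reproduces the study conditions: per-integration outcome
sampling under the calibrated parameter table, Poisson opposite-strand
burden, optional clustered load, 5% marker conversion, a lesion-free
control arm, and internal standards drawn as Poisson(10 000) counts in both
arms (adding the ~1–2% normalisation noise a transformation standard
contributes). It does not emulate sector-size variation within colonies,
partial digestion or gel artefacts, SOS induction dynamics, replicate-level
batch effects, or any position dependence of gap repair — so green tests
show the pipeline's arithmetic and the model's internal consistency, not
that real colonies obey the model.

Default problem sizes are 20 000 integrations per simulated experiment
(matching the desk-scale the percentages stabilise at; binomial SE ≈ 0.35
points at 50%) and 10 000 control colonies for conversion estimation.

## Numerical and degenerate-input choices

* All probabilities are validated on entry; $h + t \le 1$ is enforced.
* `estimate_opposite_burden()` returns 0 at $S_{rel}=1$, `Inf` at
  $S_{rel}=r$ and errors below $r$ (no admissible burden).
* Corrected class counts that turn negative (possible when the true TLS
  rate is near zero) are clipped to zero with a warning rather than
  propagated.
* Decoding errors distinguish "no genotype matches" (corrupt pattern) from
  "layout not decodable" (a construct design failure).
* Pure-blue colonies — only the HDGR daughter survived — have no published
  class; they are counted as HDGR and reported as their own column for
  transparency.
* All simulation entry points take explicit seeds; `run_pipeline()` seeds
  each experiment as config seed + experiment index and logs it.

## Known limitations

* In clustered mode the residual recA-null resolution probability predicts
  a few percent survival, whereas the wet-lab observation is essentially
  none; whether RecA-independent exchange fails on multi-gap chromatids is
  unknown, so no claim is made about clustered survival.
* The published "7–13% of tolerance events" for sectored recA colonies is
  ambiguous between denominating survivors or integrations; both readings
  are computable (`estimate_event_fractions()` vs `tolerance_partition()`).
* Construct sequences are synthetic; only lengths, primer/context sequences
  and decodability are anchored to the published assay.
* The endogenous burden estimate and the classical ~1.3-lethal-lesions
  figure from UV survival curves imply slightly different burdens; the
  package reports its estimate with a CI and does not arbitrate.
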
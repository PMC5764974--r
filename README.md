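# hecmscreen

Chemometric screening of **hepatotoxic equivalent combinatorial markers
(HECMs)** from herbal-medicine LC-MS fingerprints, with *Dioscorea
bulbifera* tuber (DBT) as the motivating system. The package is for
analysts who have (or simulate) a batch-by-peak fingerprint table and
per-animal serum enzyme endpoints (ALT/AST, U/L) and want to know which
peaks carry the toxicity — and whether the selected compound combination
is toxicologically equivalent to the whole extract.

## What it does

1. **Adduct annotation** — theoretical negative-mode ion m/z from
   molecular formulas: `[M−H]⁻`, `[M+Cl]⁻`, `[M+COOH]⁻` (formate), all
   including the electron mass; ppm errors; library matching within a ppm
   tolerance. A 40-compound DBT library is packaged.
2. **Fingerprinting** — common-peak matching by retention time, a median
   reference fingerprint, and cosine (congruence) similarity
   `u·v / (‖u‖‖v‖)` between batches.
3. **Marker screening** — two-block NIPALS PLS of `Y = (ALT, AST)` on the
   peak-area matrix with variable importance for the projection,

   VIPⱼ = √( p · Σₐ SSYₐ wₐⱼ² / Σₐ SSYₐ ),   screening rule VIP > 1.0;

   a 3-knot back-propagation neural network (logistic hidden layer,
   linear output, 5000 full-batch epochs) with mean impact values,

   MIVⱼ = IVⱼ / n,  IVⱼ = Σ ( ŷ(X·(1+δ)ⱼ) − ŷ(X·(1−δ)ⱼ) ),  δ = 0.10;

   and hierarchical clustering of z-scored peaks together with ALT/AST.
4. **Equivalence testing** — TOST 90% CI of the candidate/extract
   toxicity ratio on the log scale,

   exp[ (Ȳ_B − Ȳ_H) ∓ t₀.₉₅,ₙ₁₊ₙ₂₋₂ · σ̂_W · √(½(1/n₁ + 1/n₂)) ] ⊂ (0.70, 1.43),

   with strict containment required for an "equivalent" verdict.
5. **Synthetic study design** — a generator reproducing the statistical
   regime of the motivating study (21 batches × 10 common peaks, planted
   toxic peaks 9 and 10, similarities > 0.9, toxic ALT/AST ranges), so
   the whole pipeline is testable without instrument data.

## Worked example

```r
library(hecmscreen)

# theoretical m/z of the two diterpenoid marker ions
round(adduct_mz("C19H20O6", "[M+COOH]-"), 4)   # diosbulbin B  -> 389.1242
round(adduct_mz("C21H24O7", "[M+Cl]-"), 4)     # EEA           -> 423.1216

# a synthetic 21-batch study with planted toxic peaks 9 and 10
cfg <- scenario_config(seed = 14)
peaks <- generate_fingerprints(cfg)
tox   <- generate_toxicity(peaks, cfg)
report <- hecm_pipeline(peaks, tox)
report
```

```
== HECM screening report ==
Fingerprints: 21 samples x 10 common peaks; similarity vs reference 0.992-0.999
PLS: 2 component(s), R^2 = 0.951
VIP > 1: 10, 9
MIV top-2: 10, 9
Selected markers: 10, 9
```

Reading this: all batches look near-identical by fingerprint similarity
(0.99+), yet their toxicity varies several-fold; the PLS model
explains 95% of the enzyme variance, and both screening routes put peaks
9 and 10 — the planted markers — on top, so the selected marker set is
exactly the planted truth. An equivalence stage can be added by passing
per-animal `candidate`/`original` enzyme values:

```r
g <- generate_equivalence_groups(geo_mean_ratio = 1.05, cv = 0.3, n = 10, seed = 1)
equivalence_test(g$candidate, g$original)
```

```
Hepatotoxic equivalence (two one-sided t tests)
  geometric-mean ratio: 1.015
  90% CI: 87.3-118.0%  [limits 70-143%]
  sigma_w = 0.2748 (log scale, df = 18), t = 1.7341
  decision: EQUIVALENT
```

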
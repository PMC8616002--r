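# pHdisorder

Predicts whether a protein is folded or intrinsically disordered **as a
function of solution pH**, from sequence alone, for single sequences or
whole FASTA batches — and reports the pH values at which a protein is
predicted to switch between order and disorder (conditional folding /
unfolding).

## Who this is for

Researchers studying intrinsically disordered proteins (IDPs) whose
conformational state depends on environment rather than sequence alone:
pH-conditioned disorder is relevant to organellar and extracellular biology
(lysosomes, secretory pathway, gut), to biotechnology (purification, storage
and formulation buffers far from neutrality) and to pH-modulated
liquid–liquid phase separation.

## The model

Disordered and folded proteins separate across a line in the
charge–hydrophobicity plane. This package recomputes both coordinates at
every pH:

* **Net charge per residue (NCPR).** Each ionizable group (D, E, C, Y, H,
  K, R; optionally the chain termini) titrates by the Henderson–Hasselbalch
  equation: acids carry `-1/(1 + 10^(pKa - pH))`, bases
  `+1/(1 + 10^(pH - pKa))`. NCPR is the length-normalized sum. Default pKa
  values are the EMBOSS set, overridable via CSV.
* **Mean hydrophobicity ⟨H⟩.** Every residue has a neutral-species and (if
  ionizable) a charged-species lipophilicity in [0, 1]; at a given pH the
  residue value is the protonation-weighted mix
  `f·h_neutral + (1 - f)·h_charged`, with `f` the Henderson–Hasselbalch
  neutral fraction. Local values are averaged over a sliding window
  (default 51 residues, truncated at the chain ends), then averaged again
  into ⟨H⟩. The bundled scale is a documented **stand-in** (min–max
  normalized Kyte–Doolittle for the neutral species, charged species at the
  scale minimum); supply your own scale via CSV to replace it.
* **DispH score.** The two are combined through the linear boundary

  `DispH = c1·⟨H⟩ - |NCPR| - c2`,  defaults `c1 = 2.785`, `c2 = 1.151`.

  Positive scores predict a folded state, negative scores disorder.
* **Transitions.** Scanning a pH grid (default 0–14, step 0.5: 29 values)
  yields a score-vs-pH curve. A transition is reported only when the curve's
  maximum exceeds `+0.02` and its minimum falls below `-0.02` (the
  confidence band); sign flips outside the band are counted (in-band
  wiggles are debounced), each crossing pH is linearly interpolated and
  classified as acid (< 6), neutral (6–8) or basic (> 8). A negative→positive
  flip with increasing pH is *conditional folding*, the reverse
  *conditional unfolding*; two or more flips make a *multitransition*.

## Worked example

```r
library(pHdisorder)
fa <- system.file("extdata", "example.fasta", package = "pHdisorder")
sc <- disph_scan(fa)          # defaults: pH 0-14, step 0.5, window 51
sc
```

```
pH-dependent disorder scan: 7 sequence(s), pH 0-14 step 0.5, window 51
polyG: folded  [max 0.1177 @ pH 0; min 0.1177 @ pH 0]
polyK: unfolded  [max -0.9661 @ pH 14; min -2.1510 @ pH 0]
polyE: unfolded  [max -0.8417 @ pH 0; min -2.1510 @ pH 14]
VK25: transition  [max 0.2875 @ pH 14; min -0.3049 @ pH 0]
  conditional folding at pH 10.82 (basic)
VE25: transition  [max 0.3498 @ pH 0; min -0.3049 @ pH 14]
  conditional unfolding at pH 4.17 (acid)
VH25: transition  [max 0.3962 @ pH 14; min -0.3049 @ pH 0]
  conditional folding at pH 6.37 (neutral)
rand100: multitransition  [max 0.0831 @ pH 8; min -0.1137 @ pH 14]
  conditional folding at pH 5.66 (acid)
  conditional unfolding at pH 9.94 (basic)
```

Reading it: poly-G has no titratable groups, so its score is flat and
(mildly) positive — folded at every pH. Poly-K is so charged *or* so
hydrophilic that it stays disordered everywhere. The alternating
valine–lysine copolymer VK25 is disordered at low pH (lysines fully
protonated: high |NCPR|, low ⟨H⟩) and crosses to folded at pH 10.82 —
right at lysine's pKa of 10.8, where the charge titrates away. VE25 is the
mirror case (glutamate, conditional unfolding at pH 4.17 ≈ pKa 4.1), and
VH25 crosses in the physiological window because histidine titrates near
neutrality. `summary(sc)` aggregates verdicts, directions and crossing
classes over the dataset; `plot(sc)` draws the score-vs-pH curves;
`write_results(sc, "out/")` writes `summary.csv`, per-sequence profile
CSVs and a `results.json` with the full run configuration in its header.

The same pipeline runs from the shell:

```sh
inst/cli/disphscan scan --fasta in.fasta --out res/          # grid mode
inst/cli/disphscan single --ph 7.0 --fasta in.fasta --out res/
```

## Acceptance script

`scripts/acceptance.R` regenerates a deterministic 200-record synthetic
mini-proteome (titration-designed fixtures plus random sequences), scans it
end to end over the default grid, verifies the companion truth table,
writes the result bundle, and emits a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Limitations

The per-residue lipophilicity values are a stand-in scale, so absolute
verdicts on real proteomes will differ from predictors built on
solvation-derived scales; the charge model ignores local electrostatic
context (no pKa shifts from neighbours or structure); and no smoothing is
applied beyond the ±0.02 confidence band. See the methods vignette
(`vignettes/ph-dependent-disorder.Rmd`) for the full modelling account.
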
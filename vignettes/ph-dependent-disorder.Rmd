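---
title: "Predicting pH-dependent protein disorder: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting pH-dependent protein disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pHdisorder)
```

## The problem

Intrinsically disordered proteins (IDPs) expose their side chains to the
solvent, which makes their conformational state sensitive to solution
conditions. pH is a particularly direct lever: it sets the protonation
state of every ionizable group, and with it both the protein's net charge
and — because charged species are less lipophilic than their neutral
forms — its effective hydrophobicity. A protein that sits near the
order/disorder boundary can therefore be pushed across it by a pH change
alone. This package predicts where on the pH axis that happens, for
arbitrary numbers of sequences.

## The model

### Charge

Each ionizable group titrates independently by the Henderson–Hasselbalch
equation. With pKa values $pK_a$ and solution pH:

$$q_\text{acid}(\mathrm{pH}) = \frac{-1}{1 + 10^{\,pK_a - \mathrm{pH}}},
\qquad
q_\text{base}(\mathrm{pH}) = \frac{+1}{1 + 10^{\,\mathrm{pH} - pK_a}}.$$

Both are non-increasing in pH, so the net charge per residue (NCPR, the
length-normalized sum) is non-increasing too — a property the test suite
checks on a thousand random sequences. Non-ionizable residues contribute
zero. Terminal amino/carboxyl groups are **excluded by default**: at
typical lengths their $\pm 1/L$ contribution is negligible, and excluding
them keeps homopolymer controls exactly neutral; `include_termini = TRUE`
adds them.

The default pKa values are the EMBOSS set (D 3.9, E 4.1, C 8.5, Y 10.1,
H 6.5, K 10.8, R 12.5, N-terminus 8.6, C-terminus 3.6) — a widely used,
citable choice. Any set can be substituted through a three-column CSV
(`residue,pka,polarity`); `inst/extdata/emboss_pka.csv` shows the format.

### Hydrophobicity

Each residue has a neutral-species lipophilicity $h_n \in [0,1]$ and, if
ionizable, a charged-species value $h_c \le h_n$ (ionization never makes a
side chain more lipophilic). At a given pH the residue's effective value is
the protonation-weighted mix

$$h(\mathrm{pH}) = f\,h_n + (1-f)\,h_c,$$

where $f$ is the Henderson–Hasselbalch fraction of the *neutral* species.
Local values are averaged over a sliding window (default 51 residues, odd
by construction), and the mean of that windowed profile is the sequence's
mean hydrophobicity $\langle H\rangle$.

**The bundled scale is a stand-in.** The solvation-calculation-derived
pH-dependent scale this method was originally built on is not publicly
tabulated. The package ships min–max-normalized Kyte–Doolittle hydropathy
for the neutral species with all charged species at the scale minimum
(0.0), clearly labelled as synthetic
(`inst/extdata/standin_scale_synthetic.csv`), and accepts a replacement via
`read_scale_csv()`. This preserves the method's *structure* —
protonation-weighted mixing of two species values — while making the
numeric values an explicit, replaceable input. Consequences: absolute
verdicts on real proteins will differ from the original predictor, but all
qualitative behaviour (titration-driven crossings at the relevant pKa,
direction of transitions) is scale-robust, and the fixture tests re-derive
expected behaviour from whatever scale is configured.

### The boundary and the DispH score

Folded and disordered proteins separate linearly in the
charge–hydrophobicity plane. The signed score

$$\mathrm{DispH} = c_1 \langle H\rangle - |\mathrm{NCPR}| - c_2$$

uses the classic boundary coefficients $c_1 = 2.785$, $c_2 = 1.151$ as
defaults. The recalibrated coefficients of the pH-aware single-sequence
predictor this tool generalizes are not published numerically, so they are
not guessed; both coefficients are plain config fields, logged in every
output header, so a recalibrated pair drops in without code changes.
A score of exactly zero is labelled **unfolded** — a deliberate,
documented tie rule that errs toward disorder.

### Transition detection

Scanning a pH grid gives a score series $s_1,\dots,s_n$. The rules, in
order:

1. **Gate.** A transition can exist only if $\max s > +c$ and
   $\min s < -c$ with the confidence half-width $c = 0.02$. Inside that
   band the linear boundary is not trusted to discriminate.
2. **Debouncing.** Scores map to $+1$ ($> c$), $-1$ ($< -c$) or $0$;
   in-band runs inherit the previous definite sign (leading zeros inherit
   the first definite sign). This is this package's documented resolution
   of an underspecified corner: without it, band-sized noise between two
   definite signs would inflate multitransition counts.
3. **Counting.** Each sign flip of the collapsed series is one transition;
   two or more make a multitransition. Flip parity therefore matches the
   endpoint band signs, which a 10,000-series fuzzer asserts.
4. **Crossing pH.** Within the span from the last definite old-sign point
   to the first definite new-sign point, the first adjacent pair of raw
   scores straddling zero is linearly interpolated. This refines "the
   bracketing grid points" to the case where in-band points lie between
   the definite signs, and is stable under step refinement (halving the
   step moves fixture crossings by less than one coarse step — tested).
5. **Direction and class.** Negative→positive with increasing pH is
   *conditional folding*, the reverse *conditional unfolding*. Crossing
   pHs are classed acid ($<6$), neutral (closed $[6, 8]$) or basic
   ($>8$); the closed neutral interval is a deliberate inclusivity choice
   at both ends.
6. **No-transition label.** Profiles failing the gate are labelled by the
   score sign at the median grid point (lower-middle point for even-length
   grids — a deterministic tie-break), with a low-confidence warning when
   even that score sits inside the band.

### Aggregation

Dataset summaries report the no-transition/transition split of the whole
input, the single/multi and folding/unfolding splits *among transitioning
sequences* (a multitransition protein contributes its first transition's
direction — one direction per protein, as proteome-style tables require),
and the acid/neutral/basic split over *all* crossings (so a
multitransition protein contributes each of its crossings).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `ph_min`, `ph_max` | 0, 14 | pH | full titration range |
| `step` | 0.5 | pH | 29 grid points; resolves every side-chain titration at a few points per transition |
| `window` | 51 | residues | smooths local composition; global verdicts are largely window-insensitive, profiles are not |
| `ci` | 0.02 | score | half-width of the no-trust band around the boundary |
| `c1`, `c2` | 2.785, 1.151 | — | classic charge–hydrophobicity boundary |
| `include_termini` | FALSE | — | terminal charges are $O(1/L)$ |

Windows must be odd (a centered window needs a center; even input is
rejected rather than silently adjusted) and are truncated at the chain
ends, so sequences shorter than the window collapse to whole-sequence
averaging.

## What the synthetic fixtures emulate — and what they don't

`fixture_catalog()` and `make_mini_proteome()` generate sequences whose
titration behaviour is known *by construction*: homopolymers of inert
(poly-G) or single-titrating (poly-K, poly-E) residues, and alternating
valine/X copolymers whose whole-sequence score has the closed form

$$s(\mathrm{pH}) = c_1\frac{h_V + h_X(\mathrm{pH})}{2}
  - \frac{|q_X(\mathrm{pH})|}{2} - c_2,$$

so the expected crossing is computable by bisection independently of the
scanning code — that is exactly how the tests derive it. VK25 folds
conditionally near lysine's pKa, VE25 unfolds near glutamate's, VH25
crosses in the physiological window. The mini-proteome's truth table is
computed at generation time from the *configured* scale/pKa/boundary, so
swapping in a real solvation-derived scale regenerates a consistent truth
table instead of breaking the end-to-end tests.

These fixtures deliberately do **not** mimic real proteome length or
composition distributions. A green fixture test establishes that the
pipeline's machinery (titration math, windowing, boundary, detection
rules, serialization) is correct and deterministic; it does not establish
that the published proteome-wide transition fractions are reproduced —
that would additionally require the original lipophilicity scale, the
recalibrated boundary and a specific proteome release, and is documented
as an optional large run, not asserted by the suite.

## Numerical choices

* Grid counts use `floor((ph_max - ph_min)/step + 1e-9) + 1`; the relative
  slack keeps 14/0.5 from flooring to 27 under floating point, and the
  same slack is used by the brute-force enumeration oracle in tests.
* Output floats are fixed at six decimals and field order is fixed, so
  re-runs with timestamps disabled are byte-identical (asserted on a
  200-record scan).
* Ambiguity codes X/B/Z/U/O are tolerated: zero charge, scale-mean
  lipophilicity, one warning per sequence. Any other letter rejects the
  record — batch runs skip and log it (`skipped.tsv`) rather than abort.
* Sub-band perturbations cannot flip a definite sign
  ($|s| > c$ and $|\delta| < c$ imply $\mathrm{sign}(s+\delta) =
  \mathrm{sign}(s)$), so verdicts on profiles whose scores stay outside
  the band are robust to score noise smaller than the band — the property
  tests assert this in that defensible form (a score *between* $c$ and
  $2c$ can legitimately enter the band under such a perturbation, so the
  stronger "gate never changes" claim is not made).

## Known limitations

Independent-site titration (no coupled or structure-shifted pKa values);
a stand-in lipophilicity scale; a single linear boundary for all pH values
(no per-pH recalibration); no uncertainty on interpolated crossing pHs
beyond the confidence band; no structure-based or machine-learned disorder
signal. These are scope decisions, not oversights: the package is the
charge–hydrophobicity method made pH-aware and batch-capable, with every
unpublished numeric input isolated behind a config surface.
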
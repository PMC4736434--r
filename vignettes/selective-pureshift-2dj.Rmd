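---
title: "Selective pure shift 2D J spectroscopy: model, processing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective pure shift 2D J spectroscopy: model, processing and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psychedelicr)
```

## The experiment in brief

A conventional 2D J-resolved spectrum separates chemical shift (F2)
from multiplet structure (F1), but two problems make it a poor tool for
measuring individual couplings: all couplings are active at once, so F1
traces are full multiplets; and the phase-modulated t1 evolution gives
phasetwist lineshapes. The experiment simulated here fixes both. A pair
of ideal frequency-selective 180° pulses restricts the J evolution in
t1 to couplings involving a chosen spin (or band of spins), a PSYCHE
low-flip-angle double-chirp element refocuses every other coupling
broadband, and acquiring normal (N) and reversed (R) t1-evolution
datasets allows echo/antiecho recombination into double-absorption
lineshapes. A second, interferogram-style evolution period (t2) plus
chunked direct acquisition (t3) makes F2 a pure shift dimension. After
a 45° shear, couplings to the selected spin appear as clean F1 doublets
at the shifts of the coupling partners — one J per trace.

## Spin model

A spin system is a set of n ≤ 8 protons with chemical shifts (ppm), a
symmetric scalar-coupling matrix J (Hz), a Larmor frequency used for
the ppm-to-Hz conversion, and per-spin transverse relaxation times.
The rotating-frame Hamiltonian is, in angular units,

$$H = 2\pi\Big(\sum_i \nu_i I_{iz} + \sum_{i<j} J_{ij}\,
  \mathbf{I}_i\cdot\mathbf{I}_j\Big)$$

with the isotropic (`strong`) coupling term by default; the `weak`
model truncates it to $J_{ij} I_{iz} I_{jz}$. States are density
matrices in the Zeeman product basis; propagation uses the
eigendecomposition of H (computed once per system, so delays of any
length are one matrix sandwich). Detection is
$s = \mathrm{Tr}(\rho \sum_i I_i^+)$, normalised so a unit in-phase
transverse term detects as 1; with this convention the detected
coherence order is −1 and positive offsets give positive frequencies.
Relaxation is applied as a per-spin exponential envelope
$e^{-t/T_2}$ on each spin's detected contribution over the total
evolution time (t1 + t2 + t3) rather than by Lindblad propagation:
linewidths come out Lorentzian with FWHM $1/(\pi T_2)$, which is all
the realism the experiment's resolution claims need, at a small
fraction of the cost.

## Sequence implementation and the evolution contract

The element order used is

```
90°(Φ1) — SEL — BIP(Φ2) — t2/2 — PSYCHE(Φ3) — BIP(Φ4) — SEL — t2/2 — acquire
```

with the two t1/2 halves inserted **after** each selective pulse for
the N-type experiment and **before** each selective pulse for the
R-type (the two acquisitions differ in nothing else). BIP denotes the
broadband inversion pulses, modelled as ideal hard 180° rotations; SEL
is an ideal spin-selective 180°. Product-operator bookkeeping for this
ordering gives, for a detected spin k with selected partners S:

* during t1, only $\pm\pi J_{kS} t_1$ phases evolve (shift and
  unselected couplings refocused), with the opposite sign in the R-type
  sequence;
* during t2, shift plus selected couplings evolve;
* during t3, the full Hamiltonian is active, continuously with the end
  of t2 — the property chunk assembly relies on.

These statements are enforced by tests against an independently coded
closed-form signal model (`analytic_signal()`); with the first-order
Hamiltonian the two agree to numerical precision (~1e−14 RMS), which
pins down every pulse phase, pathway and delay convention at once.
With the isotropic Hamiltonian the residual difference is genuine
second-order physics and scales like J/Δν (about 8% RMS at Δν/J = 20,
1% at Δν/J ≈ 100); the strong→weak convergence is tested separately.

Coherence selection: gradients are represented by an exact projection
onto the coherence-transfer pathway. All ideal elements map coherence
order deterministically, so the only place a genuine branch choice
occurs is the PSYCHE element; there the order-reversing branch
(p → −p) is kept, the software equivalent of the matched gradient pair
flanking the element. The printed 32-step phase cycle
(Φ1 = 0₄2₄ on the 90°, Φ2 = 0₈2₈ and Φ4 = 0₁₆2₁₆ on the two hard
180°s, Φ3 = 0123 on the chirps, receiver −Φ1 + 2Φ3) is implemented as
an alternative mode and agrees with the projection shortcut to 1e−15
— consistent with the receiver rule Δp = +1 at the excitation pulse
and |Δp| = 2 at the PSYCHE element.

### The selected spin's own signal

The selected spins' magnetization passes through both selective pulses
and therefore follows a different effective evolution: its shift is
refocused in t2 (and runs in t1). In the assembled pure shift
dimension its intensity consequently appears not at its own shift but
redistributed over the chunking sideband comb (multiples of SW2
weighted by how far its shift sits from the nearest multiple), with a
broad, folded t1 structure. This is reported as simulated; extraction
flags peaks at the selected spins' F2 shifts and does not J-analyse
them, and the fixtures keep carrier and shifts clear of each other so
the ghost does not sit on a real peak.

### PSYCHE: ideal and explicit modes

The ideal mode implements the element's net effect: for each spin k in
turn, keep the part of the state in which k is the only transverse
spin and all other spins' longitudinal states are untouched, rotate k
by 180° (about the cycled phase Φ3), discard all cross-transfer terms,
with uniform amplitude across spins. This is the standard active/
passive-spin picture of the element, and it is exact for the pathway
the experiment keeps.

The explicit mode builds piecewise-constant propagators for two
simultaneous counter-sweeping chirps (a saltire) over a grid of
z-slices whose gradient-encoded offsets span `gradient_encoding_Hz`,
averages the slice results, and applies the same order-reversing branch
selection. The RF amplitude is calibrated by root-finding on a
single-spin simulation so that one chirp alone gives an on-resonance
net flip of β (seeded by the Landau–Zener estimate). Defaults: β = 15°,
30 ms duration, 10 kHz sweep, 1000 time slices, 50 z-slices — common
practice for this element; no values are prescribed by the experiment
itself.

One quantitative observation from the brute-force average is worth
recording: the retained transverse fraction after pathway selection is
proportional to sin²β but with prefactor ≈ 0.5, not 1. The reversal
proceeds through two partial rotations (one per chirp crossing), and
the interference of the possible orderings bounds the per-slice
amplitude at 0.75·sin²β with an ensemble mean near half. The package's
tests assert the sin²β proportionality and the measured prefactor; the
often-quoted "sensitivity ∝ sin²β" rule is a proportionality, and the
cross-validation that matters — identical extracted J from explicit and
ideal modes (±0.001 Hz on the two-spin fixture) — holds.

## Processing conventions

* **Chunk assembly.** A chunk of duration 1/SW2 is acquired per t2
  increment. By default (`half_first`) the first increment contributes
  only its first half chunk and later increments are centred on the t2
  grid (their t2 delays are (j − ½)/SW2), the standard interferogram
  convention that minimises chunking sidebands; a plain `aligned` mode
  is available. Unselected couplings evolve only within chunks, which
  is what creates the sidebands at multiples of SW2 (below 10% of the
  parent line for the fixtures tested).
* **Recombination.** cos = (S_N + S_R)/2, sin = (S_N − S_R)/(2i),
  then States-style transforms; the real/real quadrant is the
  spectrum, and all four quadrants are kept for lineshape diagnostics.
  The phasetwist metric resamples the 2D neighbourhood of the tallest
  peak symmetrically about its sub-bin centre and reports odd-odd to
  even-even power; double absorption gives ~1e−5, N-only processing
  ~0.9.
* **Apodization and zero-filling.** t2′: exponential line broadening
  matched to the mean T2 (1/(πT2) Hz) by default; t1: decaying
  cosine; both dimensions zero-filled ×2; first points halved. Zero-
  order phasing only — the simulator's conventions are chosen so
  simulated data are absorptive at zero phase, and no first-order
  correction is ever needed for ideal pulses of zero duration.
* **Tilt.** The shear (f1, f2) → (f1, f2 − f1) is applied per F1 row
  as a Fourier-domain phase ramp, i.e. sub-bin accurate and circular;
  the doublet rows of the two-spin fixture align to better than 0.1 of
  an F2 point. The direction sign is fixed by requiring that shear to
  move partner doublets onto the true shift; a tilt flag prevents
  double application.

## Coupling extraction

F2 peaks are local maxima of the F1-integrated positive skyline above
a relative threshold, refined by three-point parabolic interpolation.
Each peak's F1 trace (linearly interpolated between columns) is reduced
to line positions by parabolic interpolation on log intensity — exact
around a Lorentzian apex, which buys sub-bin J precision without full
lineshape fitting. Patterns are matched with symmetric-pair
enforcement: one line near zero is a singlet; two lines symmetric
about zero a doublet (J = separation); four symmetric lines a doublet
of doublets with J1 = a + b, J2 = a − b from the outer/inner half-
splittings (larger J reported first); three lines with a central
component the degenerate J1 = J2 case. Anything else is labelled
`complex` and no J is reported — deliberately conservative, so noise
or strong-coupling distortions produce refusals rather than wrong
numbers. The reported uncertainty is half the F1 digital resolution.

## The fixtures and what passing tests show

All test inputs are generated in code: canned systems (AX with
J = 7 Hz; a strongly coupled AB pair with Δν = J = 10 Hz; a
peptide-residue-like four-spin system with J(Hα,·) = 8/5/11 Hz; a
six-spin crowded ring fragment; a two-residue "alpha family" whose two
Hα shifts share one selection band and couple 9.5/4.0 Hz to a common
partner — the doublet-of-doublets case) and seeded random systems
(shifts uniform over a 2 kHz window with a 60 Hz minimum separation so
peaks stay resolvable at the digital resolutions used, sparse J in
2–15 Hz, and a guaranteed Δν/J ≥ 20 floor for every coupled pair in
weak-only mode; T2 uniform in 0.5–2 s, a realistic small-molecule
range — the experiment itself prescribes no relaxation values).

These fixtures emulate shift/coupling topologies, relaxation and
additive complex Gaussian noise. They do not emulate RF field
inhomogeneity, finite selective-pulse bandwidth (a selective pulse
near-degenerate with a partner shift would fail in reality but not
here), pulse miscalibration, temperature drift or exchange — so
passing tests demonstrate the correctness of the sequence logic,
processing and extraction, not robustness to hardware imperfections.

Problem sizes used in the automated checks: t1 grids of 64–128 points
over SW1 = 40–50 Hz with ×2 zero-filling (F1 resolution ≤ 0.2 Hz per
point, supporting the 0.1 Hz recovery bound), 12–16 chunks of 40–120
points, and batches of 10 (oracle) and 50 (recovery) seeded random
systems; these keep the full suite within a few minutes on one CPU
while leaving the measured errors (≈ 0.01 Hz) an order of magnitude
inside the bounds.

## Numerical choices and edge cases

* Propagators by eigendecomposition of the Hermitian Hamiltonian,
  cached per delay length; pulse unitaries built as Kronecker products
  of exact 2×2 rotations.
* Detection is vectorised: one transition-frequency/amplitude table
  per system serves every increment.
* Chunk duration is validated against 1/SW2 exactly (mismatch is an
  error, not a warning); `half_first` requires an even chunk length.
* Degenerate inputs: an empty selection band warns and yields a pure
  shift spectrum with a frozen t1 dimension; equivalent spins are
  allowed and co-resonate in F2; SW1 smaller than a selected coupling
  warns about F1 folding; a double tilt and extraction from an
  untilted spectrum are errors.
* Noise is complex Gaussian per point, generated from the dataset's
  integer seed, so every pipeline output is reproducible byte for
  byte.

## Known limitations

Ideal-pulse selectivity is binary (a spin is either inverted or
untouched); the n ≤ 8 limit reflects dense 2ⁿ matrices; the explicit
PSYCHE mode costs minutes, not hours, only because its propagators are
state-independent and reused across increments; and the strong-coupling
regime is simulated faithfully but the extractor intentionally refuses
to assign J values to second-order patterns.
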
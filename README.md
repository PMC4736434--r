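# psychedelicr

Measuring individual ¹H-¹H coupling constants in crowded spectra is one
of the classic bottlenecks of small-molecule and peptide NMR: multiplets
overlap, and every additional coupling multiplies the number of lines.
Selective pure shift 2D J-resolved spectroscopy solves this by combining
three ingredients in one experiment: a PSYCHE (low-flip-angle
double-chirp) element that refocuses all unselected homonuclear
couplings broadband, a pair of selective 180° pulses that let only the
couplings to a chosen spin (or family of spins) evolve, and
echo/antiecho (Pell–Keeler) recombination of normal (N) and reversed (R)
t₁ evolution that delivers double-absorption lineshapes. After a 45°
shear, the result is a spectrum with one line per chemical shift in F2
and, at the shift of every coupling partner of the selected spin, a
simple doublet in F1 split by exactly J — couplings read off one at a
time, at pure-shift resolution.

`psychedelicr` is a complete desk-scale implementation of that
experiment for R:

* a **density-matrix simulator** of the pulse sequence (N- and R-type,
  ideal or explicitly time-sliced PSYCHE element with spatial averaging,
  the published 32-step phase cycle or an exact coherence-transfer-
  pathway projection, chunked pseudo-3D acquisition, per-spin T₂),
  for arbitrary scalar-coupled spin systems with either the isotropic
  (strong) or first-order (weak) J Hamiltonian
  `H/2π = Σᵢ νᵢ Iᵢz + Σᵢ<ⱼ Jᵢⱼ (Iᵢ·Iⱼ  or  Iᵢz Iⱼz)`;
* an independent **analytic weak-coupling signal model** used as an
  oracle for the simulator;
* the full **processing pipeline**: interferogram chunk assembly,
  echo/antiecho recombination, apodization, States-style 2D FT, and the
  sub-bin-accurate 45° shear;
* automated **coupling extraction**: F2 peak picking, F1 multiplet
  classification (singlet / doublet / doublet of doublets), and a tidy
  coupling table;
* JSON spin-system I/O, NMRPipe-format spectrum output, and a
  command-line interface.

## A worked example

Two spins A and X (offsets 100 and 300 Hz at 500 MHz, J = 7 Hz) plus an
uncoupled bystander U; the selective pulses are placed on A:

```r
library(psychedelicr)

sys <- spin_system(shift_ppm = c(4.2, 4.6, 5.0),
                   J_Hz = matrix(c(0,7,0, 7,0,0, 0,0,0), 3),
                   spectrometer_MHz = 500, carrier_ppm = 4.5,
                   T2_s = 1.5, labels = c("A", "X", "U"))

par <- sequence_params(selected_band = c(4.2, 0.1),   # centre, width (ppm)
                       n1 = 128, SW1_Hz = 50,         # t1: J dimension
                       n2 = 16,  SW2_Hz = 50,         # t2: pure shift steps
                       points_per_chunk = 40, SW_acq_Hz = 2000)

spec <- psychedelic_spectrum(sys, par)   # simulate + process + tilt
extract_couplings(spec)
```

```
<coupling_table> 2 F2 peaks
 f2_ppm  f2_hz label multiplicity J1_hz J2_hz uncertainty_hz selected
    4.6  50.03     X            d 6.994    NA         0.1953    FALSE
    5.0 250.00     U            s    NA    NA         0.1953    FALSE
```

X appears at its chemical shift (50 Hz from the carrier) as an F1
doublet whose splitting recovers J(A,X) = 7 Hz to 0.006 Hz; the
uncoupled spin U is a singlet at F1 = 0. The `uncertainty_hz` column is
half the F1 digital resolution. The selected spin itself is flagged
(`selected`) and not J-analysed.

The same pipeline is available step by step
(`run_psychedelic() |> assemble_chunks() |> pk_recombine() |> ft2d() |>
tilt45() |> extract_couplings()`), and from the shell:

```sh
inst/scripts/psychedelic simulate --system sys.json --params par.json --out raw.rds
inst/scripts/psychedelic process  --raw raw.rds --out spec.ft2
inst/scripts/psychedelic extract  --spec spec.ft2 --out couplings.csv
inst/scripts/psychedelic demo     --outdir demo_out
```

## Scope

The simulator treats hard and selective pulses as ideal rotations (the
broadband inversion pulses of the real experiment are modelled as exact
180° rotations) and applies relaxation as per-spin exponential
envelopes. Chemical exchange, heteronuclei, RF inhomogeneity and
alignment-media theory for residual dipolar couplings are out of scope.
See the methods vignette (`vignettes/selective-pureshift-2dj.Rmd`) for
the model, the processing conventions and the known limitations.
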
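---
title: "An integrated cross-talk model of the epithelial innate immune response to dsRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An integrated cross-talk model of the epithelial innate immune response to dsRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(iircross)
```

## The biological system and the model

When double-stranded RNA (dsRNA) — the molecular signature of replicating
RNA viruses — appears inside an airway epithelial cell, two pattern
recognition receptors fire in parallel: cytoplasmic RIG-I and endosomal
TLR3. In this model the two arms are deliberately separated, reflecting
knockdown evidence that RIG-I couples to the antiviral IRF3 program while
TLR3 drives the inflammatory NF-κB program:

* **RIG-I arm.** dsRNA-bound RIG-I recruits the mitochondrial adapter MAVS
  and TRAF3; the assembled complex activates the IKK1 kinase complex
  (IKKγ–TBK1–IKKε), which phosphorylates IRF3. Phospho-IRF3 dimerizes and
  enters the nucleus (IRF3an), where it activates ISG56, contributes to the
  IFNβ enhanceosome, and represses the RelA gene.
* **TLR3 arm.** Endosomal dsRNA-bound TLR3 recruits TRIF and TRAF6; the
  complex activates the IKK2 kinase complex (IKKα–IKKβ–IKKγ), which
  phosphorylates IκBα in the NF-κB:IκBα complex, freeing NF-κB/RelA to
  translocate (RelAn). The same receptor complex activates a
  TLR3-dependent, IRF3-independent transcription factor (TLR3dTF) that
  drives MAVS, IRF3, IKK1 and IKK2 expression.
* **Negative feedback.** The NF-κB targets IκBα and TNFAIP3/A20 close two
  loops: newly made IκBα recaptures nuclear NF-κB and exports it; A20 binds
  and inactivates both active kinase complexes.
* **Cross-inhibition.** Nuclear IRF3 represses the RelA gene and nuclear
  NF-κB represses the IRF3 gene, so silencing either arm de-represses the
  other.
* **IRF7 → RIG-I.** RIG-I transcription is driven by IRF7 (itself an NF-κB
  target expressed in active form), not by IRF3 — so RIG-I induction
  survives an IRF3 knockdown but is abolished when IRF3 and IRF7 are both
  removed.
* **IFNβ enhanceosome.** The IFNβ gene transcribes only when both nuclear
  NF-κB and active nuclear IRF3 are bound; the assembled complex
  dissociates with the slow complex-dissociation rate (half-life of order
  ten days), making IFNβ induction effectively irreversible on the
  experiment's time scale.
* **IRF3 maturation buffer.** Newly translated IRF3 enters an inert pool
  (IRF3ii) that matures only slowly into the activatable form (IRF3i),
  which shuttles between cytoplasm and nucleus. Phosphorylation of IRF3i
  is itself slow relative to the pre-stimulus pool, so the first hours of
  the response are kinase-limited — a RIG-I knockdown, which weakens
  signaling from the start, visibly blunts IRF3-dependent ISG56
  expression — while the late phase is supply-limited by the buffer, so
  the extra kinase activity a TNFAIP3 knockdown releases does not
  translate into more nuclear IRF3. This temporal separation is how the
  model reconciles the two knockdown observations.

Everything is mass action with reactions of order at most two; molecule
counts (not concentrations) are the state variables. Each of the eleven
regulated genes (RelA, IRF3, RIG-I, MAVS, IKK1, IKK2, IκBα, TNFAIP3, IFNβ,
ISG56, IRF7) carries a gene module: two gene copies that bind activating
(or repressing) transcription factors, activated transcription at
`mRNA_transc_r`, basal transcription at `mRNA_basal_transc_r` (zero for
IFNβ and ISG56, whose pre-stimulus levels are zero), mRNA decay,
translation, protein decay. The model comprises 83 chemical species and
150 reactions (`validate_model(model, conformance = TRUE)` checks exactly
this). Species beyond the published simplified schematic — the adapter
complexes, phospho-IκBα forms, the IRF3 dimer, the constitutive TLR3 and
TLR3dTF mRNAs, the endosomal dsRNA pool, secreted IFNβ — are
reconstruction intermediates needed to realize the couplings with
bimolecular steps, and each is documented in the serialized model file.

## Rates: base constants and calibrated coefficients

Every reaction's rate constant is the product of a *base constant rate*
(BCR) shared by its reaction class — e.g. `prot_transl_r` = 5×10⁻² 1/s,
`prot_bind_r` = 10⁻⁷ 1/(molecule·s), `gene_act_r` = 10⁻⁷ 1/(molecule·s) —
and a dimensionless per-reaction coefficient. `rate_assignment()` dumps the
(BCR, coefficient) factorization of all 150 reactions.

The coefficient values shipped in `iir_calibrated_coefficients()` are this
package's own calibration of the reconstructed network: they were obtained
by staged numerical refinement (coordinate and simplex search in
log-coefficient space) against the behaviour the model must reproduce —
physiological basal abundances near 10⁵ molecules for constitutive
proteins, the stimulated 6-hour working point of both arms (active IKK1
and IKK2 near 2×10⁴ molecules, nuclear RelA near 6×10⁴, active nuclear
IRF3 near 10⁴, TNFAIP3 mRNA near 700), the TNFAIP3-knockdown contrasts,
rapid NF-κB-arm induction with delayed IFNβ, the RIG-I dip-then-resynthesis
profile, and 1–3 h single-cell oscillations. They are not the original
study's coefficient set, which is not available in the main text.

Second-order units: the BCR table prints bimolecular constants in
1/(molecule·s) and the model uses them directly as per-molecule propensity
constants (convention A). The alternative reading — dividing each
second-order BCR by the average protein count — is implemented behind the
`divide_second_order_by_prot_avg` switch accepted by every simulation
entry point, so both conventions remain available; the default follows the
printed units, which are self-consistent.

## The simulation protocol

`schedule()` encodes the experiment: the system starts from zero molecules
(two free copies of each gene excepted) at −500 h, equilibrates to its
pre-stimulus steady state, receives an instantaneous bolus of dsRNA at
t = 0 (2×10⁴ molecules for the reference 4 µg dose), and is followed on
the measurement grid 0, 0.5, 1, 2, 4, 6 h (18 h for dose–response, 6-min
cadence for imaging).

Three engines share this protocol:

* `run_ode()` — deterministic mass-action ODEs (deSolve's `lsoda` with the
  analytic Jacobian, rtol 10⁻⁸ / atol 10⁻⁶ for the response phase). The
  pre-stimulus state is computed by `steady_state()`: the −500 h
  integration followed by a Newton polish onto the fixed point. The
  Newton system carries one explicit copy-sum equation per gene module,
  which removes the conservation null space from the Jacobian and keeps
  iterates on the gene-copy manifold; stationarity is accepted when
  max |dx/dt| / max(x, 1) < 10⁻⁹ 1/s. Perturbed models (knockdowns,
  knockouts) are always equilibrated from scratch — the network is
  multistable under strong perturbations, and warm starts can land on the
  wrong branch.
* `run_ssa()` — exact Gillespie direct-method sampling of the chemical
  master equation (compiled), with a fixed-step tau-leaping variant for
  regimes where event-by-event simulation is infeasible: at the network's
  physiological copy numbers an exact 6-h trajectory is of order 10⁹
  events. The leap draws all channel counts from propensities evaluated
  at the leap start and caps each channel's firings by reactant
  availability, so over-drawn channels cannot create mass. Because the
  nuclear NF-κB capture cycle is stiff (per-molecule rates of a few per
  second), the leap bias grows roughly linearly in τ; the mean-field
  consistency checks run at τ = 0.1 s, where the measured bias on the
  main readouts is about half the 10% comparison band. The stochastic
  equilibration segment is replaced by the deterministic steady state with
  counts rounded to integers, which is what the −500 h segment exists to
  deliver.
* `run_hybrid()` — the intrinsic-noise model: gene states (0, 1 or 2
  active copies per gene) evolve as an exact jump process whose integrated
  hazard is accumulated alongside the deterministic flow of all other
  species; a unit-exponential threshold crossing locates each switching
  event, and one channel fires with probability proportional to its
  propensity. The flow between events is stiff (the nuclear
  NF-κB–IκBα capture cycle relaxes in sub-seconds while expression evolves
  over hours), so the compiled engine integrates it with a fixed-step
  backward-Euler method (L-stable, analytic Jacobian, LAPACK solves,
  default step 5 s); a reference R implementation on `lsodar`'s root
  finder cross-validates the compiled path in the test suite. With all
  gene-activation rates zero the hybrid result coincides with the ODE.

All stochastic runs are reproducible bit-for-bit given a seed.

## Perturbation experiments

A knockdown multiplies the target's mRNA-degradation coefficient
(`siRNA_incr_degr_r` = 10 is the default factor); it acts from the start
of equilibration, since experimentally the siRNA precedes stimulation by
66 h — several mRNA lifetimes — so the pre-stimulus state is already
knocked down. A knockout zeroes the gene's copies.
`calibrate_knockdown()` finds the multiplier that reproduces a measured
residual mRNA fraction at 6 h after stimulation (root-finding on the
log-multiplier to 10⁻³ relative tolerance), on the deterministic model,
because the calibration data are population-level measurements. A
consequence of this mechanism, recorded as model output rather than
assumed: basal (pre-stimulus) mRNA is knocked down by roughly the same
factor as the stimulated value.

Cell-population experiments draw each cell's dose from a lognormal
distribution with mean 2×10⁴ molecules and CV 3 (mean and CV of the dose
itself: σ² = ln(1+CV²), µ = ln(mean) − σ²/2) — the extrinsic noise — and
simulate each cell in ODE mode (extrinsic only) or hybrid mode (extrinsic
plus intrinsic); the population summary is the ensemble mean with
±1.96 SE bands from 100 cells (20 for the hybrid panels in the shipped
scripts, a run-time choice documented there). Dose–response sweeps convert
"X µg" doses through the dosimetry anchor (4 µg ↦ 2×10⁴ molecules) and
read the ensemble means at 18 h.

## Single-cell analysis

`nc_ratio()` forms the nuclear/cytoplasmic ratio of (free plus complexed)
RelA, the quantity live-cell imaging reports; `detrend_poly3()` removes a
least-squares cubic trend; `periodogram()` is the raw (unsmoothed,
untapered) discrete Fourier periodogram at the Fourier frequencies,
normalized so the one-sided power sums to the detrended series' sum of
squares (Parseval — the test suite checks this and cross-validates against
`stats::spec.pgram`). The dominant period is the maximum-power period
inside a 0.5–5 h search band; exact power ties resolve to the lowest
frequency. Imaging-style two-column CSVs can be analyzed identically via
`read_ratio_series()`.

At a low dose (5 µg scale) the hybrid model's cells show repeated
translocation excursions whose dominant detrended periods cluster at 1–3
h; at a high dose (50 µg scale) the typical profile is a single sustained
translocation with faint residual periodicity. The oscillation is
noise-excited: the IκBα gene's two copies switch on a tens-of-minutes
timescale (its activation and inactivation coefficients were chosen ~50×
slower than the generic gene at the same duty cycle), so transcription
arrives in bursts, and the IκBα feedback loop — deliberately fast in this
calibration (mRNA half-life ~10 min, prompt complex phosphorylation,
export and re-import) — converts those bursts into translocation cycles
with 1–3 h periods. The imaging generator emits n = T/Δt frames spanning
exactly the imaging duration, the standard periodogram convention, so
Fourier periods fall at T/k.

A related design point: `scale_copy_numbers()` defines the family of
models used for stochastic-versus-deterministic consistency checks. By
default it also speeds gene switching up by the scale factor at fixed
duty cycle, so gene noise — like copy-number noise — vanishes in the
large-factor limit and stochastic ensemble means converge to the mean
field; with that switch off, the deterministic solution of the scaled
model is exactly the factor times the base solution, which is the form
the exact-scaling property test uses.

## Measurement model, scoring and the synthetic-data generator

Only relative values within a measurement series are trusted (assay units
are arbitrary), so scoring rescales each empirical series onto the
simulation with the factor minimizing Σ|a·e − s|/s — an exactly solvable
weighted-median problem (`scale_series()`; a brute-force grid search is
the test oracle). The fit score (`fit_score()`) averages the scaled
relative absolute difference over all series and times; replicates enter
as their mean; the denominator is the simulated value floored at one
molecule, with `scaled_empirical` and `mean` denominators available as
configuration since the original formula's denominator is not printed in
an extractable form. The score is zero exactly when every series matches
up to units, and is invariant to per-series rescaling of the data.

`refine_coefficients()` implements staged calibration: per stage, each
named reaction coefficient is moved across a multiplicative grid and kept
at its best value, so the score trace is non-increasing and the procedure
is deterministic given the plan.

The synthetic-data generator replaces the study's Q-RT-PCR/SRM tables:
it simulates the generator model, applies random per-series reporting
scales (log-uniform over 10⁻³–10³, forcing the scale-estimation machinery
to work) and multiplicative lognormal noise with CV 10% per replicate
(triplicates). Multiplicative noise is the realistic choice because
expression values span orders of magnitude. With this design the expected
score of the generator against its own data is ≈ 0.8·0.10/√3 ≈ 0.046
(replicates are averaged before scoring), which the tests assert; the same
machinery applied to single draws sits at ≈ 0.08, the expected absolute
deviation of 10% lognormal noise. What passing these tests shows is that
the pipeline is unbiased and correctly scaled under its own noise
assumptions; it does not certify the noise model against real assay data,
where error structure can be heavier-tailed and time-correlated.

Welch's unequal-variance t-test (`welch_test()`) makes the knockdown
significance calls on replicate fold-change tables, reporting the
direction of change as a sign alongside the two-sided p-value.

## Numerical choices and degenerate inputs

* Steady state: −500 h integration at moderate tolerance plus
  constraint-augmented Newton; failure to reach 10⁻⁹ 1/s stationarity is
  an error, not a warning.
* ODE response phase: rtol 10⁻⁸, atol 10⁻⁶, analytic Jacobian.
* Hybrid flow: backward Euler at 5 s; halving on Newton failure; event
  location to 10⁻⁶ s.
* Tau-leaping: fixed τ, Poisson channel counts, states clamped at zero
  (appropriate only at large copy numbers; the exact method guards its
  event budget and errors rather than silently approximating).
* 2A → products propensity: k·x(x−1)/2, matched by k·x²/2 in the ODE, so
  the deterministic model is the exact large-copy limit.
* Fold-change denominators below 10⁻⁶ molecules give NA (IFNβ and ISG56
  have zero baselines by construction).
* An all-zero empirical series has no defined scale and errors.
* Cubic detrending requires ≥ 5 points; the periodogram requires a
  uniform grid and errors otherwise, directing to resampling.

## Scales used by the shipped analyses

The numbered scripts under `analysis/` run the study end to end at sizes
chosen to keep a full desktop run in minutes: 100-cell ODE ensembles,
20-cell hybrid ensembles and imaging sets, 30-cell dose–response
ensembles, 12 h imaging at 6-min cadence. Each script takes the ensemble
size as a command-line argument, so the full 100-cell hybrid panels are
one flag away.

## Known limitations

* The reaction list is a reconstruction: its structural counts and
  couplings match the described network, but individual intermediates and
  coefficients are this package's calibration, so molecule-count
  predictions inherit that uncertainty (the headline knockdown contrasts
  are reproduced within a few percent, but that is a fit, not a
  measurement).
* The TLR3dTF is abstract — a transcription-factor placeholder with
  constitutive supply, not a sequence-identified protein.
* No spatial structure, no delay reactions, no viral replication or
  antagonism; dsRNA enters as a single bolus and decays.
* The hybrid engine treats all non-gene species deterministically, so
  low-copy noise in mRNAs (beyond what gene switching induces) is not
  represented; the fully stochastic path covers it but is only practical
  at reduced copy scales.
* Identifiability is deliberately out of scope: the calibration is one
  coefficient set consistent with the targets, in a parameter space known
  to be sloppy.
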
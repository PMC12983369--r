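---
title: "Dynamic Monte Carlo track structure for liquid-water radiolysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Monte Carlo track structure for liquid-water radiolysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquadmc)
```

## The problem

When an energetic electron (20 eV to 30 keV here) enters liquid water it
ionises and electronically excites water molecules along its track. Within a
picosecond each liberated secondary electron either escapes its parent
cation's attraction and hydrates — becoming a hydrated electron, e_aq^- —
or remains bound near the parent, in which case the event effectively acts
as an electronic excitation. The ratio of these two outcomes, expressed as
the initial hydrated-electron yield G_hyd(1 ps) in species per 100 eV of
deposited energy, seeds all subsequent radiation chemistry. In the vapour
phase the ionisation/excitation split is fixed by the collision channel; in
the liquid it is not, because slow secondaries can be pulled back
(relocalised) by the parent's Coulomb field, and highly excited electrons
can wander off and hydrate anyway. `aquadmc` resolves the split
*dynamically*: it follows every secondary electron through femtosecond
Newtonian motion in the time-dependent, dielectrically screened field of
its own parent cation, down to thermalisation, and then classifies the
final electron-cation separation against a charge-separation radius.

## Model components

### Collision channels and cross sections

Transport is driven by a channel-resolved cross-section table
(`aq_xsec`): elastic scattering, quasi-elastic phonon scattering,
two vibrational modes (0.198 and 0.453 eV quanta), three discrete
electronic excitation bands (8.4, 10.1, 11.5 eV), a collective
(plasmon-like) excitation, one valence ionisation shell (10.9 eV binding),
and a dissociative-attachment channel that is parsed but carries zero cross
section — DEA is taken to be strongly suppressed in the liquid phase, and
enabling it requires both a non-zero column and an explicit configuration
flag. Cross sections are interpolated log-log (they span decades), with a
linear fallback where a bracketing node is zero, and never extrapolated
above the grid.

The packaged default table (`default_xsec_table()`) is a smooth synthetic
parametrisation, not a digitised data set: Bethe-shaped electronic
channels (threshold rise, ln(E)/E tail) and empirical low-energy forms.
Its magnitudes were calibrated once against liquid-water observables —
keV-scale inelastic mean free paths, subexcitation thermalisation
distances of about 1 to 8.5 nm for 0.1 to 4 eV electrons, penetration
ranges, and the picosecond hydrated-electron yield — and are fixed. The
collective excitation carries the largest single inelastic cross section,
as liquid-phase energy-loss functions require; its 21.4 eV transfer exceeds
its 12.4 eV effective binding, so each collective excitation liberates a
~9 eV tracked electron. This is the model's expression of the fact that
broad-spectrum excitations in the liquid often end, after electron
delocalisation, as ionisation. All unit tests run on small synthetic
fixture tables so correctness never depends on the default's exact values.

The ionisation differential (secondary-energy) model is a one-parameter
truncated Lorentzian tail, dσ/dW ∝ 1/(W² + a²) on [0, (E−B)/2]
(indistinguishability cap), sampled by inverse CDF; `a` defaults to 8 eV
per channel. The true liquid-phase differential law is not settled; this
form is integrable, exactly sampleable, and gives delta-ray spectra with
the familiar soft peak and hard tail.

### Time-dependent screening

Each electron-cation pair carries its own clock t_i. The pair interaction
is the Coulomb attraction screened by a permittivity that develops in
stages as the medium polarises:

eps_r(t) = eps_e + A_p (1 − e^(−t/tau_p)) + A_o (1 − e^(−t/tau_o))

with the instantaneous electronic response eps_e = 1.78 (optical n²), a
phonon component (A_p = 2.755, tau_p = 9.9 fs) and an orientational
component (A_o = 75.465, tau_o = 8.67 ps) whose amplitudes sum to the
static limit of 80. The two amplitudes and rise times were fitted once so
the screened pair potential at 0.75 nm passes through the literature
anchor values 0.27, 0.22 and 0.15 eV at 300, 500 and 1000 fs while the
response saturates near 80 after a few tens of picoseconds; the fit
reproduces all three anchors within ±0.004 eV. The fitted phonon rise time
(9.9 fs) sits at the fast edge of the tens-of-femtoseconds phonon regime;
it is what the anchors force with a two-exponential form.

### The propagation engine

One unified propagator (C++, velocity-Verlet) serves every electron:

* The primary starts at the origin along +z and, like every electron above
  the electronic thresholds, alternates exponential free flights with
  sampled collisions; it is retired below `tracking_cutoff` (8.4 eV) and
  its remainder handed to the secondary propagator.
* Every channel-born electron is propagated under the screened force of
  its own parent cation only (electron-electron and cross-pair forces are
  neglected; cations are immobile), interleaved with collisions sampled by
  optical-depth accumulation along the numerical trajectory. Secondaries
  that are still energetic keep ionising and exciting, so the full
  delta-ray cascade is generated; every event spawns exactly one tracked
  electron, which makes N_total(t_0) equal to the electron count.
* Force-free electrons (the primary, or injection experiments) advance by
  exact analytic flights.

Numerical choices: adaptive time step bounded by `dt_max` (0.5 fs), a
per-step displacement cap (0.05 nm near the parent, 0.5 nm beyond 2 nm),
and a fraction of the local orbital period 0.2/ω; Plummer softening of the
force inside 0.05 nm (sub-ångström structure has no classical meaning
here); screened-Rutherford elastic deflections with screening parameter
η = η₀/E (η₀ = 0.5 eV), which is automatically isotropic at sub-eV
energies. Per-(seed, history, electron) counter-based RNG substreams make
histories order-independent and runs bit-reproducible.

### Where a freed electron enters classical transport

The channel threshold (binding or transition energy) is, by definition,
the energy needed to remove the electron from the molecular region. Placing
a secondary at r = 0 inside the macroscopic screened well would therefore
double-count the binding: at eps_e = 1.78 the softened well is many eV deep
and essentially nothing would escape. Electrons instead enter classical
transport displaced radially from the event position by a sampled birth
radius r_birth + Exp(tail), defaults 0.30 + 0.25 nm: the molecular cavity
scale plus an exponential tail representing the spatial extent of the
vacated or excited orbitals, which ranges up to diffuse, Rydberg-like
nanometre states. Discrete excitations free their electron with zero
kinetic energy; such electrons are bound states in all but name and are
frozen at their entry point rather than integrated (their classical
sub-ångström jitter resolves nothing at the classification scale).

### Thermalisation

Sub-excitation electrons lose energy through vibrational quanta and
phonon scattering. Below ten k_B T the bath's thermal motion matters:
sub-thermal elastic collisions apply a Langevin-type partial velocity
thermalisation, v ← sqrt(1−λ) v + sqrt(λ) w with w drawn from the bath
Maxwellian — a kernel that satisfies detailed balance and whose stationary
velocity distribution is exactly Maxwellian at the bath temperature.
(Literal binary-collision kinematics with an 18 u partner would exchange
only ~2 m/M ≈ 6×10⁻⁵ of the energy per collision; the physical exchange is
phonon-mediated, which this kernel represents.) Phonon collisions below
their quantum remain open as quasi-elastic momentum relaxation; closing
them would bias the stopping statistics, because the thermalisation dwell
counter advances faster in states with more open channels.

An electron is declared thermalised when its kinetic energy stays within
[0, 5 k_B T] for 30 consecutive collisions; it then stops at an
exponentially sampled settling time (about one mean flight later) rather
than at a collision epoch, so the recorded kinetic energy is
time-weighted — the stationary Maxwellian — instead of collision-rate
biased. The coupling λ = 0.25 and the 30-collision dwell were chosen so
the stopped-electron energy distribution passes a Kolmogorov-Smirnov test
against Maxwellian(300 K) at distance < 0.05. Thermalised electrons never
move again: they hydrate in place, which is also why late-time spectra and
spatial distributions are stationary between 500 fs and 1 ps.

### Classification and yields

At the 1 ps horizon every channel-born electron is classified by its final
distance to its own parent cation against the charge-separation radius
r_sep = 0.75 nm — the hydrated-electron/hydronium reaction radius, and
essentially the Onsager radius of water (0.716 nm at 298.15 K, eps 78.3):
**delocalised** at or beyond r_sep (ionisation; a nascent e_aq^-),
**localised** within r_sep for excitation-born electrons, and
**relocalised** within r_sep for ionisation-born electrons recaptured by
the parent field. Ties at exactly r_sep count as delocalised (a
measure-zero convention fixed for determinism). Then

* G_total(t0) = ⟨N_total(t0)⟩ / E0 × 100 per 100 eV,
* P_ion = n_delocalised / N_e, P_exc = 1 − P_ion,
* G_hyd(1 ps) = G_total(1 ps) × P_ion, W = 100 / G_hyd.

The primary's sub-cutoff remnant is propagated (anchored at its most
recent event's cation) but excluded from classification: it is not
channel-born, and including it would break the one-electron-per-event
identity behind N_e. Relocalised electrons count toward P_exc — the final
judgement is spatial — while retaining their channel origin for the
three-way decomposition.

## What a default run produces

At E0 = 1 keV with the packaged table (a few hundred histories suffice;
the Monte Carlo standard error of G_hyd is then a few times 0.01), the
simulation yields G_total(1 ps) ≈ 6.2 per 100 eV, P_ion ≈ 0.68,
G_hyd(1 ps) ≈ 4.2-4.3 per 100 eV (W ≈ 23-24 eV), an
ionisation/excitation ratio ≈ 2, and a delocalised/localised/relocalised
split of roughly 8 : 3 : 1. Tightening r_sep from 1.00 to 0.75 nm raises
G_hyd by about +0.2 per 100 eV on the same ensemble — classification is a
pure post-process, so this costs no re-simulation. The yield falls with
primary energy (≈ 3.8 at 100 eV, ≈ 2 at 20 eV) because slow primaries
drive proportionally more low-energy secondaries and direct excitations
that localise. Penetration ranges at 1 ps are ~10 nm at 100 eV, several
tens of nm at 1 keV and ~10 µm at 30 keV. These numbers are all computed
by the test suite and the worked example in the README; none are inputs.

## What the generator does and does not emulate

The synthetic table and the engine together emulate: channel competition
with realistic thresholds, delta-ray cascades, geminate
attraction with time-dependent screening, subexcitation thermalisation
with the right distance scale, and the resulting picosecond yield
partition. They do **not** emulate: the exact liquid-water energy-loss
function (channel magnitudes are a calibrated parametrisation, so
agreement on G_hyd does not validate any specific cross-section set),
molecular dissociation following excitation or relocalisation, explicit
hydration dynamics after thermalisation (quantum mechanical), DEA
resonances, relativistic kinematics (at 30 keV the ~3 % speed error only
shifts event timestamps), or multi-cation collective fields. Passing tests
therefore demonstrate internal consistency and agreement with the
headline liquid-water observables, not a first-principles prediction of
them.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `r_sep` | 0.75 | nm | charge-separation radius read at 1 ps |
| `t_horizon` | 1000 | fs | global classification time |
| `t_cut_secondary` | 500 | fs | per-electron propagation cutoff |
| `r_birth`, `r_birth_tail` | 0.30, 0.25 | nm | classical-transport entry radius |
| `tracking_cutoff` | 8.4 | eV | primary retirement energy |
| `lambda_th`, `therm_dwell` | 0.25, 30 | — | bath coupling, stopping dwell |
| `eta0` | 0.5 | eV | elastic screening parameter scale |
| `dt_max`, `disp_cap` | 0.5, 0.05 | fs, nm | integrator caps |
| `lorentz_a` | 8 | eV | ionisation differential width |

Problem sizes used by the shipped checks: the headline ensemble is 500
histories at 1 keV (statistical uncertainty on G_hyd ≈ 0.03-0.05 per
100 eV); thermalisation experiments inject 1000-3000 electrons; ordering
and trend checks use tens of histories per energy. These sizes keep every
result's Monte Carlo error well inside the tolerances being checked while
a full suite run stays within a coffee break on one core.

## Known limitations

* The localised component's sub-ångström structure is not resolved
  (softened classical dynamics); only its population is meaningful.
* The vapour-phase comparison (W values against gas-phase measurements)
  requires a vapour cross-section table, which is not packaged.
* Excitation-born electrons with zero kinetic energy are frozen at birth;
  their later fate (dissociation, fluorescence, relocalisation of the
  excited state itself) is outside the physical stage treated here.
* `epsilon_r(t)` is a bulk, wavevector-independent response; spatial
  dispersion and temperature dependence are ignored.
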
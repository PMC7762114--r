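---
title: "Models and methods behind memdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind memdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdyn)
```

memdyn analyses all-atom trajectories of protein–bilayer systems. This
vignette explains the models it implements, the parameters that matter,
the design decisions taken where several conventions exist, and what the
synthetic ground-truth systems do and do not establish about real data.

## Trajectory preparation

Coordinates are Cartesian (Å), times in ns, boxes orthorhombic. Two
repairs precede any analysis:

* **Jump leveling.** Simulation software occasionally translates a whole
  molecule by one box length between saved frames. `levelJumps()`
  detects, per molecule and axis, center displacements between
  *consecutive* frames exceeding `L/2` and shifts the trailing
  trajectory by the integer multiple of `L` minimizing the displacement.
  Consecutive-frame detection (rather than deviation from the first
  frame alone) handles repeated jumps and keeps false positives low;
  shifts apply to whole molecules so they stay internally rigid. The
  operation is idempotent provided genuine inter-frame motion stays
  below half a box length — amply true at typical save intervals. Tests
  verify round-trip identity against injected artefacts at 1e-9 Å and
  MSD restoration at 1e-6 Å².
* **Leaflet assignment.** Lipids split by the z of their first-frame
  geometric center relative to the bilayer midplane; the leaflet whose
  mean phosphorus plane is nearer the protein center is `contact`.
  Assignment is frozen at frame 1 — lipid flip-flop is far slower than
  the tens-of-ns trajectories this targets. A lipid exactly at the
  midplane goes to the noncontact side (an arbitrary but fixed tie
  rule).

Atom typing is table-driven (`inst/extdata/atom_typing.json`, editable):
donors are N/O atoms with a covalently bonded hydrogen (hydrogens are
associated to the nearest heavy atom of their residue within 1.35 Å);
acceptors are oxygens plus explicitly listed nitrogens; hydrophobic atoms
are the listed carbons (acyl-tail and apolar side-chain carbons — carbons
with no covalent bond to N/O/P); formal charge classes come from residue
templates with one representative atom per charged group. The lipid's
−1 is carried by the phosphate P atom and the +1 by the head-group
nitrogen: this keeps the zwitterion neutral and makes cation attachment
to the phosphate group appear as P–Na⁺/P–K⁺ pairs, the form in which
such contacts are conventionally reported.

## Interaction detection

**Hydrogen bonds** use an energy criterion rather than a pure
geometric one. For a donor–H···acceptor triple,

$$E = E_\mathrm{opt}\;
  \mathrm{clamp}\!\left(\frac{d_0 - \max(d_{HA}, d_p)}{d_0 - d_p},0,1\right)\;
  \mathrm{clamp}\!\left(\frac{\theta_{DHA} - 100^\circ}{80^\circ},0,1\right)$$

with optimum $E_\mathrm{opt} = 25$ kJ/mol, distance plateau
$d_p = 2.1$ Å, distance zero $d_0 = 2.6$ Å (hydrogen–acceptor,
minimum-image), and the donor angle ramping from 100° to 180°. A bond is
counted when $E$ strictly exceeds 25% of the optimum, 6.25 kJ/mol; a
triple at exactly the threshold is not counted. The product form is the
simplest continuous, monotone shape consistent with the published
optimum/threshold semantics; the exact functional form used by the
original simulation engine is not public, so the ramps are exposed as
parameters (`interactionParams()`). A donor may bond several acceptors
simultaneously — totals are counted, not exclusive pairings.

**Hydrophobic contacts** are pairs of hydrophobic atoms from different
residues within 5.0 Å, a conventional hydrophobic-contact radius (no
published cutoff exists for the reference analysis; it is a parameter).
**Ionic contacts** are oppositely charged atom pairs from different
residues within 5.0 Å; a residue's own zwitterion pair (P⁻–N⁺ of one
lipid head) is excluded, since it is a covalent-skeleton feature, not an
interaction. Records flag solvent-ion participation. **Water bridges**
are waters simultaneously H-bonded (as donor or acceptor) to atoms of
two distinct non-water molecules, one record per water and partner-atom
pair; two bonds into the same molecule do not form a bridge.

Detection uses cell lists on the wrapped box (falling back to a blocked
dense scan when fewer than three cells fit per axis) purely for speed:
tests enforce exact agreement with exhaustive $O(n^2)$/$O(n^3)$
enumeration on systems up to 500 atoms, and invariance under rigid
motions. Counts aggregate into maps (protein residue × lipid atom name,
or atom × atom with alphabetical pair ordering so symmetric interactions
land in single cells); map totals always equal record counts.

## Anomalous diffusion

The per-leaflet MSD is origin-based,

$$\mathrm{MSD}(t) = \frac{1}{N}\sum_{i=1}^{N} |\vec r_i(t) - \vec r_i(0)|^2,$$

over unweighted geometric centers (hydrogens included), with no
time-origin averaging — this is the literal ensemble definition; a
sliding-window variant (`time_origin_average = TRUE`) exists for variance
reduction but is not the default, because the two differ for aging or
non-stationary processes. The fit of $\mathrm{MSD}(t) = 6 D_\alpha
t^\alpha$ is ordinary least squares on $\ln \mathrm{MSD}$ vs $\ln t$ over
the full positive-lag range excluding the first saved frame (fit range
configurable); standard deviations come from the linear-fit covariance,
$D$ by the delta method. Note the quoted errors are conditional on the
realized trajectory; the molecule-ensemble scatter of $\hat\alpha$ is
larger because origin-based MSD errors are strongly correlated across
lags. $D$ converts to cm²/s^α via $10^{-16}/(10^{-9})^\alpha$ (round-trip
tested at 1e-12). The MSD is 3D with the $6D$ prefactor; a lateral
(x,y, $4D$) mode is available but off by default, matching the
convention of the motivating analysis.

## Microrheology

The generalized Stokes–Einstein estimate treats each lipid as a sphere
of radius $R_g$ (the mean mass-weighted radius of gyration over lipids):

$$|G^*|(\omega) = \frac{k_B T}{\pi R_g\, \mathrm{MSD}(1/\omega)\,
\Gamma[1 + \alpha(\omega)]},\qquad
G' = |G^*|\cos\frac{\pi\alpha}{2},\quad
G'' = |G^*|\sin\frac{\pi\alpha}{2},$$

with $\alpha(\omega) = \mathrm{d}\ln\mathrm{MSD}/\mathrm{d}\ln t$ at
$t = 1/\omega$. The default pipeline evaluates the fitted power law
(constant $\alpha$), the route appropriate when moduli are derived from
fitted MSD functions; a tabulated-MSD route (log–log interpolation,
central finite differences) exists for curves that are not power laws,
and the two agree to 1e-4 on power-law inputs. No numerical Fourier
transform of the raw MSD is attempted — the $\Gamma$-function local
approximation *is* the implemented estimator. Units: inputs in Å, ns, K;
moduli in kPa (the natural order of magnitude at molecular probe radii);
the conversion is tested against an independent SI evaluation at 1e-9
relative. Closed-form anchors: $\alpha = 1$ gives $G' = 0$ and
$G'' = k_B T \omega / (6\pi R_g D)$; $\alpha = 0.5$ gives $G' = G''$.
$\alpha(\omega)$ must lie in (0, 2); the default ω grid is 40 log-spaced
points spanning the inverse fitted time range.

## Schlitter entropy

For one lipid, each atom's x, y and z series are mean-subtracted per
coordinate and concatenated, giving $3F$ realizations from $F$ frames;
$\sigma_{ij}$ is the average product of the concatenated series of atoms
i and j ($n \times n$ for an $n$-atom lipid — 130 × 130 for the DPPC-like
template, 3000 realizations at 1000 frames). The entropy bound is

$$S = k_B \ln\det\!\left(\mathbf{1} + \frac{k_B T e^2}{\hbar^2}
\mathbf{M}^{1/2}\boldsymbol\sigma\mathbf{M}^{1/2}\right),$$

reported in $k_B$ units and kcal/(mol·K). Numerical choices:

* the mass weighting is symmetric ($M^{1/2}\sigma M^{1/2}$), which has
  the same determinant as $M\sigma$ for diagonal $M$ but keeps the
  matrix symmetric for a stable eigendecomposition;
* the log-determinant is $\sum_k \log(1+\lambda_k)$ over eigenvalues, in
  the log domain, so large systems cannot overflow;
* eigenvalues below zero beyond tolerance (1e-8, relative) trigger a
  warning and are clamped — the identity addition keeps the determinant
  nonzero even for few-frame (rank-deficient) windows;
* the formula above carries no ½ prefactor; the conventional
  Schlitter-bound ½ is available via `half = TRUE`. The default follows
  the formula as used in the motivating analysis, where the curve shape
  rather than the absolute value carries the conclusion;
* coordinates enter as-is after jump leveling — overall translation is
  *not* removed by default (it inflates the absolute entropy of mobile
  molecules, which is accepted there for the same reason);
  `remove_com = TRUE` enables removal.

`entropyTimeCurve()` evaluates cumulative-window covariances, per lipid,
averaged over the contact leaflet. On stationary synthetic Gaussians the
curve rises to the closed-form plateau of the true covariance; the tests
hold this to 5% at 1800–3000 realizations, and the scalar/diagonal closed
forms to 1e-12. `gaussianityDiagnostics()` exports the correlation
matrix and per-atom histograms of the concatenated series, because the
covariance-based bound assumes near-Gaussian fluctuations — real lipid
coordinates are only approximately so, and per-axis concatenation can
itself produce multimodal marginals.

## Membrane profiles

Electron density assigns each atom its atomic number of electrons to a
1 Å z-bin (point assignment, no Gaussian spreading; bin width
configurable), normalized by $L_x L_y \Delta z$ and averaged over a frame
window; electron conservation holds to 1e-6 relative. Thickness is the
distance between the two lipid-density head-group peaks (peak-to-peak,
the standard electron-density convention). The second peak must lie at
least 10 Å from the first so phosphate/choline sub-peaks of one leaflet
are not mistaken for the other side; optional smoothing exists for noisy
profiles but is off by default because it flattens sharp head peaks.
Penetration depth is measured from the mean z of the contact-leaflet
phosphorus atoms (the natural head-plane marker present in both studied
lipids; the reference surface behind published depth figures is not
stated, so this convention is documented rather than assumed
universal) to the deepest protein atom beyond it toward the bilayer
center, with the owning residues reported. Interior waters are water
oxygens strictly between the two per-frame phosphorus planes.

## The synthetic ground-truth generator

`generateTopology()`/`generateTrajectory()` emulate the features the
analyses are sensitive to — and only those:

* two planar leaflets (default 144 lipids each, 40 Å head-to-head, in a
  95 × 86 × 196 Å box — the composition and box of the reference
  simulations) on a jittered lateral grid;
* lipid templates with correct atom counts (DPPC-like 130, POPE-like
  125, formulas C₄₀H₈₀NO₈P and C₃₉H₇₆NO₈P) and head atoms named P, N,
  O13, O14, O22, C11, C12 with correct typing (PC nitrogen quaternary —
  no donor; PE nitrogen a charged donor). The head group is built
  electron-dense and z-compact so the density profile shows the sharp
  head peaks real bilayers have; geometry is otherwise schematic, and
  hydrogen placement guarantees each hydrogen's nearest heavy atom is
  its covalent parent so distance-based bonding inference is exact;
* lipid centers follow exact 3D fractional Brownian motion: per
  coordinate, the path covariance $K(s,t) = D(s^\alpha + t^\alpha -
  |s-t|^\alpha)$ is Cholesky-factorized and sampled exactly, so the
  ensemble MSD is $6Dt^\alpha$ at *any* frame count — recovery tests
  then probe the estimator, not the generator. The default sampling is
  1000 frames at 0.05 ns (20 frames/ns over 50 ns), matching the
  reference protocol of 2 fs steps saved every 25,000 steps;
* intramolecular fluctuations are i.i.d.-per-frame Gaussians with a
  chosen atom covariance (Å²); hydrogens reuse their parent's draw so
  covalent geometry survives the noise, hence the covariance ground
  truth is exact for hydrogen-free templates (the `minimal` template)
  and applies to heavy atoms otherwise;
* a coarse protein chain with correctly *typed* residues (Lys N⁺ donors,
  Asp carboxylate, aromatic/aliphatic hydrophobic carbons, Ser/Thr/Tyr
  hydroxyls), static waters and monovalent ions;
* `plantContacts()` moves selected atoms so contact geometries hold
  strictly inside or outside thresholds in every frame (reporting and
  skipping clashes); `injectJumps()` adds box-length artefacts.

What this does **not** emulate: force-field energetics, realistic lipid
conformational sampling, water dynamics, correlated inter-lipid motion,
or protein flexibility. Passing tests therefore establish that the
*estimators* are correct (unbiased exponent recovery, exact detection,
exact entropy bookkeeping), not that any particular biological
conclusion holds; on real trajectories the data quality, sampling and
force field dominate.

## Problem sizes and determinism

The test suite and acceptance script run at desk scale, chosen to keep
statistical bounds meaningful: exponent recovery uses 288 molecules ×
1000 frames (the full reference composition) per α ∈ {0.1, 0.3, 0.5,
1.0} across 5 seeds, with |bias| ≤ 0.05 and D within 20%; covariance
recovery uses 3000 realizations (10% Frobenius); entropy sampling 1800–
3000 realizations (5%); detector oracles ≤ 500 atoms. End-to-end
pipeline demonstrations use 6–64 lipids per leaflet and 30–400 frames.
All randomness descends from a single integer seed; equal seeds give
bit-identical systems and byte-identical pipeline outputs.

## Known limitations

* Orthorhombic boxes only; no DCD/XTC/TRR readers (multi-model PDB is
  the interchange format, via `bio3d`).
* The H-bond energy is a documented stand-in for an unpublished engine
  formula; absolute bond counts depend on its ramps, though the
  25/6.25 kJ/mol semantics are preserved and all parameters are
  exposed.
* Origin-based MSD fits carry larger ensemble variance than
  time-averaged ones; the reported least-squares errors understate it.
* The Schlitter value is an upper bound and, without center-of-mass
  removal, includes translational contributions; curves are comparable
  across conditions, absolute values are not thermodynamic entropies.
* No secondary-structure assignment, no π-stacking/cation-π detection,
  no area-per-lipid or order parameters.
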
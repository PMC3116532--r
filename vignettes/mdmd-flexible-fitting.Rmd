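---
title: "Flexible fitting with Maxwell's-demon molecular dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flexible fitting with Maxwell's-demon molecular dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

Cryo-EM reconstructions often capture a molecule in a conformation different
from any available crystal structure. Flexible fitting bridges the two: an
atomic model is deformed until a density synthesized from it matches the
experimental map. `mdmdfit` implements the selection-based variant of this
idea, Maxwell's-demon molecular dynamics (MdMD):

1. run a short, unbiased stochastic "sprint" of dynamics (50 fs to 5 ps);
2. evaluate a scalar progress variable at the sprint end — here the
   cross-correlation (CC) between the model's simulated density and the
   target map;
3. accept the sprint only if the progress variable *strictly* improved on
   the best of the last *k* archived values; otherwise restore the last
   archived state, redraw velocities, and retry.

The demon acts purely by selection. No force derived from the map is ever
added to the potential — this is what distinguishes MdMD from
gradient-driven flexible-fitting schemes, and it is why any stochastic
propagator with a reasonable equilibrium ensemble can be plugged in. Within
a sprint the progress variable is free to fluctuate downhill; only its
value at the sprint boundary is judged.

### The progress variable

The cross-correlation between two maps $\rho^{a}$, $\rho^{b}$ on a common
voxel grid is

$$\mathrm{CC} \;=\;
\frac{\sum_{ijk} \rho^{a}_{ijk}\, \rho^{b}_{ijk}}
     {\sqrt{\sum_{ijk} (\rho^{a}_{ijk})^2 \sum_{ijk} (\rho^{b}_{ijk})^2}}.$$

Note this is an unnormalized cosine similarity, **not** a Pearson
correlation: no mean is subtracted. For non-negative maps the value lies in
$[0, 1]$, equals 1 exactly when the maps are proportional, and 0 when their
supports are disjoint. A `mean_subtract` option provides the Pearson
variant but is off by default, and no thresholding is applied to either map
before comparison.

### Simulated density

The simulated map places on every atom the Gaussian kernel

$$g(\mathbf r) = \exp\!\left[-\frac{3}{2\sigma^2}\,
\lVert \mathbf r - \mathbf r_n \rVert^2\right],$$

and each voxel receives the *integral* of the kernel over the voxel volume,
not a center-point sample. Because the kernel is separable this integral is
computed exactly as a product of one-dimensional erf differences, which is
cheap and independent of grid size. Atoms contribute only to voxels whose
centers lie within `cutoff_radius` of the atom (default $2\sigma$); this
deterministic truncation makes CC values reproducible bit for bit, and
discards under 1% of the kernel mass (doubling the cutoff to $4\sigma$
recovers less than 1.2%, the 3-D Gaussian tail bound, which the test suite
verifies numerically).

**σ from resolution.** `kernel_params()` maps a nominal resolution $R$ to
$\sigma = R/2$, so the default $2\sigma$ cutoff equals the resolution. If
both `sigma` and `resolution` are given, `sigma` wins. Default synthesis
grids pad the structure's bounding box by the cutoff radius and use spacing
$R/3$.

**Grid convention.** Voxel indexing is 1-based in R; the center of voxel
$(i,j,k)$ sits at `origin + (i - 1/2, j - 1/2, k - 1/2) * spacing`. This is
declared once and used by the synthesizer, the resampler and the MRC
reader/writer alike.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_sprint`, `max_sprint` | 0.05, 5 | ps | the working range of sprint lengths |
| `grow_factor`, `shrink_factor` | 1.5, 0.5 | — | multiplicative sprint adaptation |
| `goal_cc` | 0.99 | — | termination for noise-free synthetic maps; lower it (~0.95) for experimental maps |
| `archive_depth` (k) | 3 | — | how many archived progress values the comparator consults |
| `temperature` | 300 | K | velocity-reset and thermostat temperature |
| ENM `cutoff` | 10 | Å | spring contact radius |
| ENM `spring_k` | 1 | kcal/(mol Å²) | uniform network stiffness |
| `friction` | 1 | ps⁻¹ | Langevin coupling; 0 gives NVE velocity Verlet |
| `timestep` | 0.002 | ps | 2 fs, the conventional production timestep |
| tether `k` | 5 | kcal/(mol Å²) | mid-range of the 1–10 used for anticodon tethering |

Two conventions deserve emphasis because the field is split on them:

* **Restraint energy is $k d^2$, not $\tfrac12 k d^2$.** The tether force
  constant is quoted per hydrogen-bonding atom in kcal/(mol Å²) applied to
  the squared displacement directly. The ENM springs use the same
  convention for consistency.
* **Acceptance ties reject.** "Moved toward the goal" means strict
  improvement over the best of the last *k* archived values. Accepting ties
  would let neutral drift bloat the archive without progress; with strict
  improvement the archived CC trace is strictly increasing *by
  construction*, and the tests assert it on every run.

Masses are a uniform 330 amu per site by default — the scale of one
nucleotide, appropriate for the one-bead-per-residue models the built-in
engines target. Velocities follow Maxwell–Boltzmann at the configured
temperature ($k_B = 0.8314$ amu Å² ps⁻² K⁻¹).

## Propagators

All-atom explicit-solvent MD is deliberately out of scope; the MdMD
contract only needs *some* stochastic propagator, and two are built in:

* **`enm_engine`** — an elastic network: every atom pair of the input
  structure within 10 Å is joined by a harmonic spring at its input
  distance, advanced by BAOAB Langevin dynamics. With the thermostat
  disabled it conserves energy to < 1% over 10 ps at the 2 fs timestep
  (tested), and a single spring reproduces the analytic harmonic
  trajectory to 10⁻⁴ Å.
* **`hinge_mc_engine`** — a hinge Monte-Carlo proposer that rotates the
  anticodon arm rigidly about the current hinge axis (bend) and about its
  own axis (twist), with Gaussian step sizes scaling as
  $\sqrt{\text{duration}}$ so the adaptive sprint schedule controls move
  size. This is the fast engine used by the synthetic benchmark.

External engines can be adapted by writing a `propagate` method for a new
engine class; the driver only requires determinism given the state's
`rng_state`.

After every accepted sprint the net linear momentum and the net angular
momentum about the center of mass are removed (the "flying ice-cube"
correction); the cadence is configurable. Velocities are re-thermalized
only after rejections — after an accepted sprint the system keeps its
momenta, which preserves whatever ballistic motion just proved productive.
Each rejection draws from a fresh, deterministic substream of the master
seed, so retries differ but whole runs are bit-reproducible.

## tRNA geometry analyses

* **Interarm angle** — the bend between the acceptor arm and the anticodon
  arm of the L. Each stem's axis is the dominant eigenvector of its
  phosphorus-atom covariance, with the sign oriented from the stem end
  nearest the hinge outward, making the angle a true bend angle free of
  axis-sign ambiguity. Default stem windows use canonical cloverleaf
  numbering — acceptor stem 1–7 + 66–72, anticodon stem 27–31 + 39–43,
  hinge 26/44/45 — and are configuration, not code: crystal structures with
  different numbering need a user-supplied `stem_definition`. Published
  interarm angles depend on the (usually unstated) stem windows, so exact
  reproduction of literature tables is not promised; rigid-transform and
  atom-order invariance are.
* **Per-residue RMSF** — frames are superposed twice onto a refined mean
  over the alignment selection, then each residue's P (or Cα) fluctuation
  about its mean position is reported. This is the quantitative counterpart
  of a jittergram rendering.
* **Docking and contact maps** — a trajectory is placed in a ribosome frame
  by least-squares fitting of an anchor selection (default the anticodon,
  residues 34–36). A contact is scored per frame within a 4 Å cutoff:
  protein partners via Cα-to-base distances, RNA partners via base-to-base
  distances. "Base atoms" are all heavy atoms outside the sugar-phosphate
  backbone — the paper-level definition ("base") does not list atoms, and
  the heavy-atom convention is reproducible. On the tRNA side base atoms
  are used for both modes, for symmetry with the base-to-base rule.
  Occupancy denominators count *all* frames, including frames with no
  contacts, and the boundary is inclusive: 3.9 Å is a contact, 4.1 Å is
  not.

## The synthetic benchmark

`make_pseudo_trna()` builds a coarse-grained L: one P pseudo-atom per
residue plus two base pseudo-atoms, 76 residues in canonical numbering,
two helical arms (rise 2.8 Å, radius 2.5 Å) meeting at a controllable
hinge angle. Paired stem strands are placed phase-opposed around the arm
axis, so each stem's principal axis coincides *exactly* with its arm axis
and the measured interarm angle equals the requested hinge angle; the
generator/analyzer agreement within 2° over 60–120° is tested. The D-arm
is a bulge out of the L plane near the hinge, and the variable loop sits at
the arm junction, so hinge rotations move a realistic subset of the mass.

`recovery_experiment()` is the end-to-end exercise: bend the pseudo-tRNA by
a known angle (default 25°), synthesize the target map at 8 Å resolution
(optionally with seeded Gaussian voxel noise, clipped at zero), and drive
the *unbent* structure into it with the hinge Monte-Carlo engine. Under the
default conditions the initial CC is ≈ 0.84 and runs reach CC ≥ 0.99 within
a few dozen sprints, recovering the bend angle to within 5° and the true
coordinates to well under 1 Å RMSD.

**What the generator does and does not emulate.** It reproduces the
features the pipeline actually exercises — an elongated two-arm point
cloud, canonical residue numbering, a single dominant hinge degree of
freedom, map noise. It does not model base pairing, sequence, sugar
puckers, ions, or the many soft degrees of freedom of real RNA, and its
deformation family (rigid hinge bend + twist) is exactly the family the
hinge engine proposes. Passing the recovery benchmark therefore
demonstrates that the demon loop, density synthesis, CC, and geometry
analyses are correct and consistent — not that an elastic network will fit
an arbitrary experimental map. Fitting real maps additionally depends on
map quality, the resolution-σ match, and the propagator's ability to reach
the target conformation.

## Numerical choices and problem sizes

* Synthesis grids in the tests and benchmark stay at or below 64³ voxels
  (spacing = resolution/3, 8 Å resolution), keeping a full recovery run
  under a second and the whole suite under half a minute.
* The acceptance comparator and the sprint bounds are asserted with 10⁻¹²
  slack only to absorb floating-point noise, never to relax the rule.
* Degenerate inputs fail loudly: all-zero maps make CC undefined (error),
  superposition needs ≥ 3 non-collinear pairs, single-frame trajectories
  have no RMSF, reflections are excluded from superposition (determinant
  forced +1) because nucleic-acid chirality must be preserved.
* Alternate PDB locations resolve to the highest occupancy, ties to
  altloc "A", deterministically. Waters are dropped by default.
* MRC I/O is written against the 2014 standard (mode 2), normalizes axis
  permutations on read, honors the ORIGIN words (falling back to
  NXSTART·spacing), accepts anisotropic spacing (recorded, but synthesis
  requires isotropic grids — resample first), and clips negative
  experimental densities to zero with a warning since every consumer
  assumes non-negative density.
* Sprint-length adaptation uses fixed multiplicative factors. Scaling the
  growth with the magnitude of the CC improvement is a plausible
  alternative; fixed factors were chosen because they keep the schedule
  independent of the progress variable's scale.

## Known limitations

* Single connected model per map; no multi-chain simultaneous fitting.
* No Fourier-space synthesis, B-factor weighting, sharpening, or local
  resolution handling.
* The ENM cannot cross large energy barriers that a real force field
  could; for large conformational changes the hinge engine or an external
  propagator is the right tool.
* CC as printed (no mean subtraction) rewards overall density overlap; in
  very low-contrast maps a Pearson variant may discriminate better — it is
  available but off by default to match the method's definition.
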
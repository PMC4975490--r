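---
title: "Structure-based models of the myosin mechanochemical cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based models of the myosin mechanochemical cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorgo)
```

## The model

`motorgo` builds coarse-grained structure-based (Gō-type) models of motor
proteins: every residue is a single bead at its C-alpha position, and the
energy function is biased toward one or more reference crystal
conformations. For a myosin head bound to actin the Hamiltonian is a sum of
six switchable terms,

$$H = H^{preMH} + H^{preConv} + H^{postConv} + H^{preConv-MH}
      + H^{postConv-MH} + H^{MH-Actin},$$

where *MH* is the catalytic motor-head domain, *Conv* the converter domain,
and the *pre*/*post* labels mark which reference conformation
(pre-powerstroke or post-powerstroke) supplied the native geometry. The
domain terms carry:

* harmonic bonds between consecutive beads,
  $\tfrac{K_r}{2}(r_{i,i+1}-r^0_{i,i+1})^2$ with
  $K_r = 20$ kcal/(mol·Å²);
* harmonic angles, $\tfrac{K_\theta}{2}(\theta_i-\theta^0_i)^2$ with
  $K_\theta = 20$ kcal/(mol·rad²);
* backbone dihedrals,
  $\sum_{n=1,3} K^{(n)}_\phi\left[1-\cos n(\phi_i - \phi^0_i)\right]$ with
  $K^{(1)}_\phi = 1.0$, $K^{(3)}_\phi = 0.5$ kcal/mol;
* a 10–12 attraction for every native contact,
  $\varepsilon_h\left[5(r^0_{ij}/r_{ij})^{12} -
  6(r^0_{ij}/r_{ij})^{10}\right]$, minimised at exactly $r^0_{ij}$ with
  depth $-\varepsilon_h$;
* and an excluded-volume repulsion
  $\varepsilon_l(\sigma/r_{ij})^{12}$ for every non-native pair, with
  $\sigma = 4$ Å and $\varepsilon_h = \varepsilon_l = 1$ kcal/mol.

A *native contact* is a residue pair closer than 8 Å in the reference
conformation with sequence separation strictly greater than 3; interface
terms (converter–head, head–actin) run over the full cross-product of the
two groups with no separation filter. Contact distances are measured
between the C-alpha beads — the model's only particles — and the cutoff is
exposed in configuration.

Energies are handled in reduced units of $\varepsilon_h$; with the default
$\varepsilon_h = 1$ kcal/mol, reduced and physical values coincide.
Lengths are nm throughout (PDB Ångström are converted on read).

### Scenario wiring

The cycle's states are simulated by switching terms of $H$ on or off:

| scenario | active terms | initial coordinates |
|---|---|---|
| leading (pre-powerstroke head) | preMH, preConv, preConv–MH, MH–Actin | pre conformation |
| trailing (post-powerstroke head) | preMH, postConv, postConv–MH, MH–Actin | composite: pre head + post converter |
| powerstroke (with P$_i$) | all six | pre conformation |
| powerstroke (P$_i$ released) | all six, phosphate-mediated subset removed from preMH | pre conformation |
| strain scan | trailing terms + constant force on the converter | composite |

The *phosphate-mediated* subset is found by geometry: residues whose bead
lies within `lig_cutoff` (default 0.8 nm) of any phosphate ligand atom form
the coordinating set, and native head contacts with **both** endpoints in
that set are bridged by the ligand. Whether one or both endpoints should
coordinate is not a settled convention; both rules are implemented
(`pi_mode = "both"` or `"any"`), with the bridged (both-endpoint) reading
as the default because it is the most literal meaning of a contact
*mediated by* the ligand. Removed pairs become ordinary repulsive pairs.

### Dual-basin bookkeeping

When both converter basins are active the Hamiltonian is the literal sum:
the converter carries two bonded term sets (two sets of angle and dihedral
minima) and two native-contact sets, and a contact listed by both basins
contributes one term per basin. A `dedup_basins` switch collapses shared
pairs to a single term for users who prefer that reading; the literal sum
is the default. Bonded terms that span the head–converter junction are
assigned per converter basin with native values from that basin's
structure, so each basin encodes a definite hinge orientation; the junction
bond itself is common to both conformations and is taken once. The
repulsive list excludes every pair that is native in *any* active term and
all intra-chain pairs with $|i-j|\le 3$, and a pair repels at most once no
matter how many basins list it.

## Dynamics

Sampling uses Langevin dynamics,
$m\ddot{\vec r}_i = -\zeta\dot{\vec r}_i - \partial_{\vec r} H + \vec\Gamma_i(t)$,
with the random force satisfying
$\langle\vec\Gamma_i(t)\cdot\vec\Gamma_j(t')\rangle = (6\zeta k_BT/h)\,\delta_{ij}(t-t')$
(i.e. variance $2\zeta k_BT/h$ per Cartesian component over a step of
length $h$). The integrator is the BBK discretization of velocity Verlet —
second order, and the standard choice in the low-friction regime used here
for efficient conformational sampling ($\zeta = 0.05\,\tau_L^{-1}$,
$h = 0.0025\,\tau_L$, $T = 300$ K, with
$\tau_L = \sqrt{m\sigma^2/\varepsilon_h}$ and unit bead mass). Velocities
are initialised from the Maxwell distribution at the run temperature, and
the whole trajectory is a deterministic function of (model, initial
coordinates, configuration, seed). Filament beads are frozen: they feel no
integration update and carry only head–filament attractions and repulsion
against mobile beads (no filament-internal terms). A configurable energy
guard aborts a run with a diagnostic if the potential energy diverges.

Strain is modelled as a constant force on the converter group, parallel to
the filament axis (the oriented principal axis of the filament beads).
Magnitudes are accepted in kJ mol⁻¹ nm⁻¹ and converted to the kcal-based
reduced units internally (1 kJ = 1/4.184 kcal). The stated magnitude is the
*total* over the group, shared equally per bead — the physically
interpretable reading of a single force acting on a domain; a `per_bead`
switch covers the other convention. A strain scan runs all magnitudes with
the *same* seed (common random numbers), so the small systematic response
is not swamped by independent thermal noise between runs.

Validation of the thermostat and of constant-force handling uses closed
forms on a tethered bead: positional variance $k_BT/k$, mean kinetic energy
$\tfrac32 N k_BT$, and mean displacement $F/k$ with unchanged variance.
These checks use moderate friction ($\zeta = 1\,\tau_L^{-1}$) and several
million steps so that the statistical resolution (well under 3%) tests the
thermostat rather than the sampling noise.

## Analysis

All distributional observables follow the same pattern: a per-frame scalar,
a histogram (default bin widths 0.01 nm for RMSD-type observables and
0.05 nm for inter-subunit distances, chosen to resolve peak separations of
a few hundredths to a few tenths of a nm), and kernel-density mode
estimates. Superpositions use the Kabsch algorithm (SVD with reflection
correction, proper rotations only); the fitted-subset RMSD superposes a
frame on the reference over the *fit group* only (e.g. the big subunit) and
measures the deviation over the *measure group* (e.g. the small subunit or
the converter). Distances between groups are centre-of-geometry distances
over unweighted C-alpha means; the alternative residue-pair conventions are
not implemented because nothing downstream depends on the distinction at
the toy scale. Mode estimation uses a Gaussian kernel with Silverman's
bandwidth and keeps local maxima whose topographic prominence exceeds 5% of
the global density maximum; for bimodal observables the two most prominent
peaks are reported in ascending order, and basin populations are the sample
fractions on either side of a threshold placed midway between the native
pose and the alternative pose measured on the reference structures (a
deterministic, structure-based choice rather than a fitted one).

## The synthetic toy motor

Everything above is testable without downloading crystal structures because
the package generates a deterministic miniature analogue of the system:

* a **core** ("big subunit"): three helices packed as a triangular bundle.
  The bundle geometry was chosen for contact density — about two native
  contacts per bead — because thinner topologies (a single helix, a
  two-helix hairpin) melt at 300 K under this Hamiltonian. Near-straight
  strands are avoided on numerical grounds: bond angles near $\pi$ make the
  angle gradient and the dihedral normals singular, which injects energy at
  low friction.
* a **pocket flap** ("small subunit"): a compact 5-bead helix folded
  against the outer face of one strand. Every flap–core contact is bridged
  by a single pseudo-phosphate atom placed at the pocket centroid, so
  removing the phosphate-mediated subset frees the flap completely.
* a **converter**: a linker bead plus a compact helix, docked against the
  flap in the pre pose and — after a rigid rotation about the hinge bead —
  against the core in the post pose. The pre pose has more exclusive
  converter–head contacts than the post pose (about 17 vs 14 with the
  default geometry).
* a **filament**: beads at exact spacing on a straight line under the core,
  frozen during dynamics, oriented along the direction in which the flap
  unclamps.

The toy reproduces the structural logic the pipeline assumes: shared
head-internal contacts between conformations, disjoint non-empty exclusive
converter–head sets, and a removable ligand-bridged clamp. Its key designed
behaviour is the allosteric coupling of the powerstroke: with the clamp in
place, switching to the post pose forfeits the converter–flap contacts
(the flap cannot follow — it is pinned), so the pre basin dominates; with
the clamp removed the flap travels with the converter, the post pose
retains both contact sets, and the post basin dominates. This mirrors the
cracking-mediated mechanism of phosphate-coupled powerstroke at miniature
scale.

Default sizes (`n_body = 40`, `n_conv = 12`) keep a full scenario run in
tens of seconds. Generation is a pure function of the spec: no randomness
is used, and equal hinge angles are allowed as a degenerate control in
which the two conformations coincide.

### What the toy does and does not show

Passing the behavioural suite demonstrates that the *machinery* — contact
classification, toggle wiring, phosphate removal, frozen-filament
dynamics, fitted-RMSD analysis — implements the intended mechanism, and
that the mechanism itself (clamp-coupled basin switching) is reproduced
when the geometry supports it. It does not show that any particular real
myosin reproduces the published peak positions: those depend on the actual
crystal structures, on domain-boundary choices that the original analyses
do not print (the shipped myosin VI partition file is explicitly an
interpretation), and on much longer sampling. Real structures can be fed
through the identical pipeline by loading them with `read_calpha()` and a
partition YAML.

The toy's strain response also differs quantitatively from a real motor:
a 52-bead model is far stiffer per contact than a ~790-residue head, so
at 0–5 kJ mol⁻¹ nm⁻¹ the inter-domain extension grows by only ~0.001 nm
per force step (resolved through common random numbers), and the
small–big subunit distance mode is unchanged at the 0.05-nm resolution of
its histogram. The scan therefore verifies non-decrease of the response,
not the large published shifts, which require the real system's softness.

## Worked example

```{r demo, eval = FALSE}
lv <- langevin_config(n_relax = 5e4, n_sample = 4e5, save_every = 200,
                      seed = 5)
res <- run_scenario(scenario_config("toy_demo", langevin = lv))
res$summaries$mode_leading    # converter RMSD mode, pre basin  (~0.25 nm)
res$summaries$mode_trailing   # converter RMSD mode, post basin (~1.78 nm)
```

Problem sizes used by the shipped tests and the acceptance script: the
thermostat checks integrate a single tethered bead for 4–6 million steps;
scenario runs use the default 52-bead toy plus a 10-bead filament for
0.4–2 million steps each. These lengths were chosen by convergence
diagnostics (mode stability across seed triplicates during development),
not by matching any target value.

## Numerical choices and limitations

* Angle forces clamp $\sin\theta$ away from zero and dihedral terms with
  degenerate normals are skipped; well-formed native geometries never
  approach these guards (the generator keeps all angles below ~2.7 rad).
* The Boltzmann constant is 0.0019872 kcal/(mol·K), so 300 K corresponds
  to a reduced temperature of 0.596.
* The divergence guard defaults to $|E| > 10^8$; runs that trip it abort
  with the offending energy rather than writing corrupt frames.
* Actin–myosin non-native pairs are repulsive by default (configurable),
  and frozen–frozen pairs are dropped from the repulsion list since they
  contribute only an additive constant.
* No neighbour lists are used: energies are exact sums. At the intended
  system sizes (tens to a few thousand beads) the compiled engine is fast
  enough without them.
* Hamiltonian-mixing schemes (exponential/eigenvalue basin coupling) are
  out of scope; the additive multi-basin form is the model.
* The command-line surface is deliberately thin: scenarios are driven from
  R via `scenario_config()`/`run_scenario()`, which keeps the full toggle
  matrix declarative and scriptable without a separate config dialect.
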
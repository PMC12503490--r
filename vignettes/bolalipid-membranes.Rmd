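---
title: "Modelling bolalipid membranes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bolalipid membranes: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`bolasim` simulates implicit-solvent, coarse-grained lipid membranes in the
bead-spring tradition: a **bilayer lipid** is a chain of one head bead and
two tail beads; a **bolalipid** is two such lipids joined tail-to-tail by a
bond, giving a six-bead, double-headed molecule that can either span the
membrane (straight) or fold both heads into the same leaflet (U-shaped).
All quantities are in reduced units: lengths in the bead diameter
$\sigma \approx 1\,$nm, energies in the tail attraction depth
$\epsilon_p$, times in $\tau$. The thermostat temperature in these units is
the effective temperature $T_\mathrm{eff} = k_BT/\epsilon_p$, the control
parameter for membrane fluidity.

Interactions:

* **Volume exclusion**: WCA repulsion with core diameters $b = 0.95\sigma$
  for any pair involving a head and $1\sigma$ for tail pairs.
* **Hydrophobicity**: tail beads attract with a flat-bottomed well of depth
  $\epsilon_p$ that tapers to zero as $-\epsilon_p\cos^2[\pi(r-r_c)/2\omega]$
  over the range $\omega$ (default $1.5\sigma$). This one attraction stands
  in for the solvent.
* **Bonds**: FENE springs ($k=30\,\epsilon/\sigma^2$,
  $r_\mathrm{max}=1.5\sigma$) plus the WCA core. The tail-tail junction
  inside a bolalipid uses the same parameters as every other bond.
* **Angles**: $k(1+\cos\theta)$, minimal and flat at $\theta=\pi$. Each
  three-bead half is straightened with strength `k0` (default
  $10\,k_BT$); the two hinge angles across the bolalipid junction (beads
  2-3-4 and 3-4-5 of the chain) carry the tunable molecular stiffness
  `k_bola`. `k_bola = 0` is a fully flexible bolalipid, larger values model
  the stiffening attributed to cyclopentane rings in archaeal lipids.
* **Cargo adhesion**: an optional large sphere of radius `r_cargo`
  interacts through the same WCA/taper forms evaluated at the shifted
  distance $r - (r_\mathrm{cargo} - b/2)$, so its surface behaves like a
  bead surface; only head beads feel the adhesive well of depth `eps_mc`.

**Non-bonded exclusions.** Chain neighbours up to `excl_bonds` bonds apart
do not interact non-bondedly. The default (`excl_bonds = 1`) is the FENE
bead-spring convention: only directly bonded pairs are excluded, so second
and third chain neighbours keep their tail-tail attraction. This matters
for the science: the intramolecular tail contacts formed when a bolalipid
folds are what make the U shape marginally favourable for flexible
molecules ($c_0 < 0$ in the two-state picture below). With the fully
excluded alternative (`excl_bonds = 3`) the U state loses this
stabilisation and the equilibrium U fraction collapses to about 10%,
incompatible with the behaviour the model is meant to capture. The switch
is kept because the fully excluded variant makes the hinge angle an exactly
independent chain coordinate, which the test suite uses to validate the
thermostat against a closed-form Boltzmann marginal.

# Integration

Langevin dynamics with the Gronbech-Jensen/Farago discretisation
(`dt = 0.01 tau`, `gamma = 1/tau` by default): it reproduces free-particle
diffusion $D = k_BT/\gamma m$ exactly at finite time step and reduces to
velocity Verlet when `gamma = 0`, which the energy-conservation tests use.
Thermal noise comes from a counter-based hash RNG keyed on (seed, absolute
step, bead), so trajectories are bitwise reproducible, restartable from
checkpoints, and independent of chunking.

Flat membranes run at **zero lateral tension**: a Berendsen-style barostat
rescales $L_x, L_y$ (and all x-y coordinates) toward zero lateral pressure
every 10 steps, with the relative rescale capped at $5\times10^{-4}$.
Only the zero-tension contract matters for the observables; the coupling
constants are configurable. Cylinders, patches and gas runs use a fixed
box.

Forces use split Verlet pair lists (tail-tail pairs with the long
attraction cutoff $r_c+\omega$, head-involving pairs with the short WCA
cutoff), rebuilt from a counting-sort cell binning when any bead has moved
half the skin. The smooth attraction taper is tabulated on a 4096-point
grid in $r^2$ for the dynamics; analysis entry points
(`system_energy()`) evaluate it analytically so that forces and energies
are consistent to machine precision in the finite-difference tests.

# Conformation statistics and their equilibration

The head-to-head angle $\theta$ of a bolalipid is the angle between its two
half-lipid end-to-end vectors (head bead minus the junction-side tail bead
of that half), computed on periodic-image-corrected coordinates: collinear
molecules give $\theta = \pi$, ideal hairpins $\theta = 0$. A molecule is
**U-shaped** iff $\theta < \pi/2$ (the threshold itself counts as
straight); `u_fraction()` is the U count over all bolalipids.

Two facts shape the equilibration strategy:

1. Spontaneous U/straight flips require a head bead to cross the
   hydrophobic core. At liquid conditions we observe of order one flip per
   thousand $\tau$ per hundred lipids - orders of magnitude slower than
   any other relaxation here.
2. Single-lipid Monte-Carlo flips (reflecting half a molecule through the
   plane of its junction bead, a bond-preserving isometry, accepted by
   Metropolis; `mc_flip()`), even with orientational-bias multi-try
   selection, have essentially zero acceptance in a membrane: a U-shaped
   molecule needs two lattice sites in one leaflet where a straight one
   occupies a single transmembrane column, so the insertion always lands
   in occupied space. The move is retained - it is validated against the
   isolated-molecule equilibrium, where acceptance is about 0.8 - but it
   cannot equilibrate a dense membrane.

Conformations therefore equilibrate the way the membranes of interest
actually form: by **self-assembly**. `build_gas(..., slab = c(zlo, zhi))`
scatters molecules with isotropic orientations but centres confined to a
slab, so the aggregate assembles into a membrane spanning the periodic box
within a few hundred $\tau$; conformations partition naturally as lipids
join the growing aggregate. The assembled membrane is then relaxed under
the zero-tension barostat. For fully flexible bolalipids at
$T_\mathrm{eff} = 1.2$ this yields a stationary U fraction slightly above
one half, consistent with the two-state fit below. Pre-built flat
membranes (`build_flat()`, which places all bolalipids straight, initial
$u_f = 0$) are used wherever conformations are not the observable - for
stiff bolalipids, whose equilibrium is overwhelmingly straight, and for
bilayer systems.

The **two-state model** treats a bolalipid as straight (energy 0) or
U-shaped (energy $E_u = c_0 + c_1 k_\mathrm{bola}$), giving
$u_f = 1/(1+e^{\beta(c_0+c_1 k_\mathrm{bola})})$. `two_state_fit()`
estimates $c_0, c_1$ by nonlinear least squares; $c_0<0$ means the U shape
is favoured for flexible molecules.

# Phase classification

Fluidity is measured from the in-plane mean-squared displacement of lipid
centres of mass (`msd_diffusion()`), with the barostat's affine box motion
removed by working in scaled coordinates, a default lag window of
10-100 tau and the first quarter of frames discarded. A state point is
**gas** when the largest connected lipid cluster (tail beads within
$1.5\sigma$) holds less than half the lipids, otherwise **liquid** when
$D > D^* = 10^{-3}\sigma^2/\tau$, otherwise **gel**. $D^*$ sits inside the
observed discontinuity of $D$ across the melting transition; it is
configurable because the exact threshold is a convention.

Study temperatures used by the scaled-down suite: flexible bolalipids and
bilayers are liquid around $T_\mathrm{eff} \approx 1.1-1.25$ at
$\omega = 1.5\sigma$ (we use 1.2); stiff bolalipids ($k_\mathrm{bola} =
5\,k_BT$) remain membranes to distinctly higher temperatures (we use
1.45); liquid mixtures use $T_\mathrm{eff} = 1.3$ with $k_\mathrm{bola} =
2\,k_BT$. The gel-fluidisation experiment (a small bilayer fraction
melting a stiff-bolalipid gel) runs at this model's own gel point for
$k_\mathrm{bola} = 2$, $T_\mathrm{eff} = 1.15$ at the 144-lipid desk
scale: phase boundaries sit where the implementation puts them, not where
a larger system would. Measuring $D$ in the gel also needs lag windows of
several hundred $\tau$, long enough to look past the cage plateau that
shorter windows would misread as diffusion.

# Rigidity estimators

**Fluctuation spectra.** Head beads are binned onto an $n\times n$ grid
(cell about $1.5\sigma$; empty cells filled by periodic neighbour
averaging; frames with more than 10% empty cells are flagged as ruptured
and excluded). The tilt-corrected spectrum
$$\langle|h_q|^2\rangle = \frac{k_BT}{L^2}\left(\frac{1}{\kappa q^4} +
\frac{1}{\kappa_\theta q^2}\right)$$
is fitted in log space for $\kappa$ and the tilt persistence length
$l_\theta = \sqrt{\kappa/\kappa_\theta}$, over modes with
$q < 2\pi/(12\sigma)$ - wavelengths at least twice the membrane thickness.
A pure-Helfrich ($1/\kappa q^4$) fit is always reported alongside; when
$l_\theta > 2\sigma$ the neglected tilt power is absorbed into the
amplitude and the Helfrich $\kappa$ comes out substantially *smaller* than
the true one, which is why the tilt term is indispensable for stiff
bolalipid membranes. At the small box sizes of the test suite few modes
fall under the standard cutoff, so relative comparisons there extend the
fit range (stated per test); this raises the absolute $\kappa$ somewhat
but preserves ordering.

**Membrane tubes.** A cylinder periodic along its axis pulls the box ends
together with force $f = 2\pi\kappa/R$; `cylinder_rigidity()` measures $f$
from the time-averaged axial virial and $R$ from the mean radial distance
of tail beads, flagging ruptured tubes via cluster analysis. Paired with
conformation tables this yields $\kappa(H)$ and $u_f(H)$ against the mean
curvature $H = 1/(2R)$.

**Gaussian modulus.** Free membrane discs either flatten (edge energy
$2\pi r\lambda$) or close into vesicles (bending plus Gaussian energy
$8\pi\kappa + 4\pi\bar\kappa$). Equating the two at the critical disc
radius $r^*$ gives $\bar\kappa = \lambda r^*/2 - 2\kappa$.
`patch_closure_scan()` runs an ensemble across patch sizes, closure is
detected by flood-filling the occupancy grid (a closed surface encloses
free volume unreachable from outside), $r^*$ comes from a logistic fit of
closure against disc radius, the edge tension $\lambda$ from the
contractile force of a ribbon with two free edges, and the uncertainty
from a bootstrap over the ensemble. At the desk scale of the test suite
(discs up to a few hundred lipids, a few thousand $\tau$) no patch ever
closes, so the ratio $-\bar\kappa/\kappa$ is not measurable there: the
ensemble runs and reports itself inconclusive. The estimator chain is
instead validated against synthetic closure ensembles and closed/open
shell fixtures.

# Cargo wrapping and pores

A cargo sphere adheres to head beads; above the onset adhesion energy
$\epsilon^*_{mc}$ the membrane wraps it completely and the bud pinches
off. `wrapping_fraction()` counts adhered heads against a fully wrapped
geometric reference shell; `detect_budding()` declares
`fully_wrapped_budded` when the cargo-bearing cluster is disconnected from
the mother membrane *and* closed (the outside flood-fill component cannot
approach the cargo surface). `onset_energy()` bisects $\epsilon_{mc}$
between failure and success with majority voting over replicates
(default resolution $0.1\,\epsilon$, 3 replicates).

**Pores** are membrane openings a probe sphere of diameter $1\sigma$ can
cross. Space is discretised at $0.5\sigma$; cells within (core radius +
probe radius) of any bead are blocked; a pore exists when one free
component connects the two offset surfaces at $\pm$(half thickness +
$1\sigma$) from the midsurface (flat slab or bud sphere; for buds the
search is restricted above the mother membrane plane so the neck is not
counted). The pore diameter is the largest crossing probe, located by
bisection between $1\sigma$ and $10\sigma$ at $0.25\sigma$ tolerance.
Straight bolalipids lying flat with both heads in the bud's outer layer
line the pore rims; the conformation tables label them `pore_rim` and
exclude them from $u_f$ by default.

# Numerical choices and degenerate inputs

* $\theta = \pi/2$ classifies as straight (tie-break).
* Bond lengths at or beyond $r_\mathrm{max}$ abort with a broken-bond
  diagnostic, as does any bead moving more than $0.5\sigma$ in one step.
* Beads at identical positions signal an overlap instead of returning
  infinities.
* Empty region selections and all-0/all-1 two-state data are flagged
  rather than silently fitted.
* The two-state fit seeds its nonlinear step from a logit-linear
  regression; the spectrum fit seeds from the closed-form Helfrich
  estimate and reports it alongside.

# What the generator emulates - and what it does not

The builders produce the idealised initial states of the study conditions:
dispersed gases (self-assembly), pre-formed flat lattices, tubes, free
discs and adhesive-cargo setups, with uniformly random mixture
interleaving and balanced leaflets. Passing the suite therefore shows that
the *model* reproduces the claimed physics at desk scale; it does not
probe chemical specificity (head-group chemistry, asymmetric bolalipid
heads, electrostatics, explicit solvent), nor finite-size effects beyond
the stated boxes (a few hundred lipids; fluctuation spectra then carry few
long-wavelength modes), nor quantitative rate constants for conformational
flips, which are deliberately bypassed by the assembly protocol.

Problem sizes in the tests and the acceptance script (about 200-260
lipids, runs of order $10^5$ steps) are the package's chosen desk-scale
study conditions; cluster-scale reproduction of full phase diagrams and
onset-energy curves is out of scope.
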
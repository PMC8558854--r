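---
title: "Catalytic fields, DTSS and MULTISCAN: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic fields, DTSS and MULTISCAN: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catfield)
```

## The model

`catfield` treats the influence of an enzyme's environment on a
reaction barrier as purely electrostatic and strictly additive. Both
assumptions have a physical basis for *charged* residues at medium
range: exchange and charge-transfer terms decay exponentially and
largely cancel between the substrate (RS) and transition state (TS),
leaving electrostatics as the dominant differential term, and
electrostatics is the only interaction component that partitions
exactly over residues. The package therefore never computes a total
binding energy; every number it produces is a *difference* between the
TS and RS interactions, which is the quantity the barrier cares about.

### Multipole electrostatics

Molecular charge distributions enter as cumulative atomic multipole
moments (CAMMs): per atom, traced Cartesian moments of ranks 0–4
(monopole, dipole, quadrupole, octopole, hexadecapole) in atomic units
about the atomic center. The interaction energy between two expansions
is

$$E_{\mathrm{el}} = \sum_{a \in A}\sum_{b \in B}
  \sum_{k_a + k_b \le 4} \frac{(-1)^{k_a}}{k_a!\,k_b!}\,
  M_a^{(k_a)} \cdot T^{(k_a+k_b)}(\mathbf R_{ab}) \cdot M_b^{(k_b)},$$

where $T^{(n)} = \nabla^{n}(1/R)$ is the totally symmetric, traceless
Cartesian interaction tensor and the contraction runs over all tensor
indices. Three conventions deserve note:

- **Truncation.** A term is kept iff $k_a + k_b \le 4$, i.e. the series
  stops at the $R^{-5}$ distance dependence. This is the working
  accuracy of the CAMM literature (around 5% at equilibrium contact,
  rapidly better at range). `max_order` can be lowered but not raised:
  moments above rank 4 are not carried.
- **Traced moments.** Moments are stored traced, exactly as
  quantum-chemistry codes emit them. Because every $T^{(n)}$ with
  $n \ge 2$ is traceless, trace parts are silent in every energy; no
  detracing step exists or is needed.
- **Prefactors.** The $(-1)^{k_a}/(k_a!k_b!)$ convention is locked by
  closed forms: charge–charge $q_aq_b/R$, charge–dipole
  $-q\,\mu\!\cdot\!\hat R/R^2$, dipole–dipole
  $(\mu_a\!\cdot\!\mu_b - 3(\mu_a\!\cdot\!\hat R)(\mu_b\!\cdot\!\hat R))/R^3$,
  and by the requirement that energies of exact point-charge moments
  converge to the direct Coulomb sum. The test suite enforces all of
  these.

Interaction tensors are evaluated from the explicit pairing expansion
of $\nabla^n(1/R)$ (terms $\propto (2n-2m-1)!!\,R^{-(2n-2m+1)}$ with
$m$ Kronecker deltas); unique symmetric components only, with
multinomial multiplicities in contractions. Orders up to 8 are exposed
through `interaction_tensor()`, although energies use at most order 4.

### DTSS and the static catalytic field

The differential transition-state stabilization of an environment
fragment C is `dtss()`:
$\Delta E = E_{\mathrm{el}}(\mathrm{TS}, C) - E_{\mathrm{el}}(\mathrm{RS}, C)$,
reported in kcal/mol (1 hartree = 627.5095 kcal/mol), negative when C
lowers the barrier. `dtss_point_charge()` is the extreme approximation:
$\sum_i q_i\,(V^{TS}(\mathbf r_i) - V^{RS}(\mathbf r_i))$, exactly equal
to `dtss()` with a monopole-only environment.

The static catalytic field (`static_field()`) is defined here as

$$\Delta_S(\mathbf r) = -\bigl(V^{TS}(\mathbf r) - V^{RS}(\mathbf r)\bigr)
  \quad [\mathrm{kcal/(mol\cdot e)}],$$

so that a +1 e probe at $\mathbf r$ changes the barrier by
$-\Delta_S(\mathbf r)$: **positive $\Delta_S$ marks positions where a
positive charge is catalytic**, and the sign contract
`dtss(+1e at r) + Δ_S(r) = 0` holds identically. The sign convention
was a genuinely open choice (the defining texts in the literature can
be read either way); we fixed the one that keeps the field consistent
with the DTSS definition above and state it in every relevant help
page. Field units are kcal/(mol·e) — no published convention exists, so
the package defines one and writes it into cube/TSV headers.

### Barrier estimates

`barrier_estimate()` combines a bare barrier $B_0 = E_{TS} - E_{RS}$ of
the isolated reacting model with additive per-residue DTSS values into
$B_0 + \sum \mathrm{DTSS}$. Because only conserved charged residues are
scored, this is a *ranking* device, not an absolute barrier prediction.
The shipped HisRS reference table (`hisrs_reference_dtss()`) carries
the published per-residue values; note that two published pathway
footers (TS0, TS2) disagree with the sum of their own per-residue
entries by 1.00 and 1.28 kcal/mol, and the TS1 footer by one unit in
the last printed digit — the package always recomputes sums rather than
trusting footers, and the reference help page documents the
discrepancy.

## MULTISCAN

The rotamer search minimizes, over one rotamer choice $a_i$ per site,

$$J(a) = \sum_i \mathrm{DTSS}(\text{site } i, a_i)
       + \sum_{i<j} E_{\mathrm{el}}(\text{rot } a_i, \text{rot } a_j).$$

How the inter-residue term enters was an open design point: the
narrative definition only requires that interactions between charged
side chains be "taken into account". We add the plain pairwise
electrostatic energy in the docked frame — it is state-independent, so
it steers conformer selection without altering any single-residue DTSS,
and it reduces to independent per-site optimization when sites are far
apart. Reported results always split $J$ into its DTSS and pair parts.

- **Exhaustive mode** enumerates all assignments (capped, default
  $10^6$) and breaks ties lexicographically by (site order, rotamer
  id); the result is deterministic and independent of any RNG.
- **Iterative mode** is cyclic single-site best response from the
  crystal rotamers (or each site's first rotamer), visiting sites in
  input order, until a full pass changes nothing. Every accepted move
  strictly lowers $J$, so termination is guaranteed; the endpoint can
  be a local minimum. On coupled synthetic instances it reaches the
  global optimum roughly nine times in ten (the acceptance script
  measures the rate on 100 instances per run) — the remainder are
  genuine local minima with gaps of a few tenths to a couple of
  kcal/mol, the expected behavior of best response on frustrated
  assignments such as salt-bridged pairs.
- **Placement** (`place_rotamer()`) superposes the library's anchor
  atoms onto the site (Kabsch, proper rotations only) and transforms
  both coordinates and every moment tensor; the anchor RMSD is attached
  to the placed fragment so degraded anchors are visible.
- **Clash filter** (off by default): optionally reject rotamers with
  any heavy atom within 2.0 Å of the reacting system or another placed
  rotamer. It is off by default because the scoring model is purely
  electrostatic; turning it on marks assignments infeasible rather than
  silently skewing $J$.
- Library values are looked up per rotamer (nearest-conformer
  semantics); continuous interpolation over χ angles is out of scope.
- `crystal_vs_scan_report()` scores crystal conformations *alone*
  (without inter-residue interactions), the convention used when such
  values are quoted in parentheses next to scan results.

## Structure preparation

`superpose()` is a plain Kabsch solver (SVD with reflection guard,
error on fewer than three or collinear pairs); it is cross-checked
against `bio3d::fit.xyz()` in the tests. `conserved_charged_columns()`
classifies alignment columns by charge class — negative {D,E}, positive
{R,K}, histidine configurable and uncharged by default (it is only
partially protonated at physiological pH); gaps and unknowns always
break conservation, and an exact-identity mode is available. The
class-based test is the default because charge, not identity, is what
the long-range electrostatics sees. `flexibility_stats()` compares
ensemble RMSDs of Cα against the side-chain terminal carbon Ct; the Ct
atom per type had to be fixed by us (Arg CZ, Lys CE, Asp CG, Glu CD —
the carbon nearest the charged group).

## File formats and determinism

Multipole sets and rotamer libraries travel in documented JSON formats
(coordinates in Å, moments in e·bohr^k, symmetric-unique components in
lexicographic index order xx, xy, xz, yy, yz, zz, …). A mandatory units
declaration guards against silent unit mix-ups, and component counts
per rank (1, 3, 6, 10, 15) are validated with the offending atom named.
Numbers are written with 17 significant digits, so write→read
round-trips are bit-exact on moments. Grids export as Gaussian cube
(header in bohr, z index fastest, `%16.8E` values) and flat TSV; all
writers are deterministic — identical inputs give byte-identical files.
Converters from quantum-chemistry punch formats are deliberately out of
scope; the JSON format is the interchange point. PDB input goes through
`bio3d`, with alternate locations resolved to the highest-occupancy
copy.

## Internal units and numerical choices

Files and user-facing coordinates are in Å; everything internal is in
atomic units (bohr, hartree, e·bohr^k), converted once at the boundary
(1 Å = 1.8897259886 bohr). Energies are reported in kcal/mol.

- Centers closer than $10^{-6}$ bohr are treated as coincident and
  raise an error naming both atoms — never a silent singular tensor.
- Grid nodes within 0.5 Å of any expansion center are masked (`NA`):
  the expansion is meaningless in the near field, and fabricated values
  would contaminate downstream extrema searches. Cube export writes
  masked nodes as 0.0 (the format has no missing value); TSV export
  preserves `NA`.
- Default grid: 0.5 Å spacing with 4 Å padding around the RS∪TS
  bounding box — fine enough to resolve side-chain-scale features,
  coarse enough to keep a typical small-model grid in the tens of
  thousands of nodes. Grid values are pure functions of node
  coordinates, so refining the spacing leaves shared nodes
  bit-identical.
- Rotations must be proper orthonormal to $10^{-8}$; moment tensors are
  rotated index-by-index on the full symmetric array.

## What the synthetic fixtures emulate — and what they do not

All tests run on synthetic data; no download or quantum-chemistry run
is involved. The generators are pure functions of an integer seed (one
seed, independent substreams per generator; the caller's RNG state is
restored).

- `make_cluster()` builds point-charge "molecules" whose atomic moments
  (via `atomic_moments_from_point_charges()`) are *exact*, so the
  brute-force Coulomb double sum (`coulomb_oracle()`) is an exact
  ground truth. Oracle comparisons use atom-centered expansions (every
  center within 0.25 bohr of its charge), the regime real CAMMs live
  in; the net-charge residual is spread across charges so no outlier
  charge inflates high-rank moments.
- `make_reaction_pair()` plants a known charge displacement: the TS is
  the RS geometry with a chosen charge moved along a chosen axis, so
  the far field has an analytic dipolar $\cos\theta/r^2$ signature and
  probe DTSS values have closed-form Coulomb references.
- `make_rotamer_library()` plants a provable optimum: sites sit
  maximally spread on a 10 Å shell, and the reaction's charge shift —
  in which every per-site DTSS is exactly linear, while inter-rotamer
  couplings do not depend on it — is scaled until each site's
  best-versus-runner-up gap exceeds the 0.5 kcal/mol margin plus that
  site's total coupling spread. Any deviating assignment then costs at
  least the margin, so the recorded truth is the global optimum by
  construction, not by enumeration. `make_scan_instance()` instead
  places sites on an 8–15 Å shell where couplings genuinely shape the
  optimum, as optimizer stress tests.
- Alignment and ensemble toys plant, respectively, conserved charged
  columns among otherwise never-fully-charged noise, and side-chain
  tips jittered three times more than their Cα atoms.

What passing these tests shows: the tensor algebra, energy expansion,
sign conventions, additivity, placement geometry and optimizers are
correct. What they cannot show: anything about the *physical* adequacy
of rank-4 CAMMs for real wavefunction-derived charge distributions,
penetration effects at contact distances, or the realism of any rotamer
library — the fixtures are point charges, not molecules.

## Problem sizes

The shipped suites use small, fixed sizes chosen to exercise every code
path with comfortable margins: 5–10-charge clusters, 20–40 seeded
oracle dimers, grids of a few hundred nodes, and 100 scan instances of
3 sites × 4 rotamers (64 assignments each) per mode. The acceptance
script (`scripts/acceptance.R`) re-runs all of these from one
command-line seed.

## Known limitations

- Electrostatics only: no exchange, induction, dispersion, or solvent
  screening; results rank residues rather than predict barriers.
- Additivity is exact only for the electrostatic term; cooperative
  polarization is invisible.
- Moments stop at rank 4; `max_order > 4` is rejected rather than
  silently extrapolated.
- The iterative optimizer is a local search; use exhaustive mode when
  the assignment count allows it.
- Dynamic (derivative) catalytic fields for proton relays and
  free-energy follow-ups are out of scope.
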
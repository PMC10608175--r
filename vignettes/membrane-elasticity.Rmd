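---
title: "Methods: 1D membrane elasticity with Lo/Ld domains and adsorbed peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D membrane elasticity with Lo/Ld domains and adsorbed peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`memelastic` computes membrane-mediated interactions in a lipid bilayer in
which a liquid-ordered (Lo) phase coexists with a liquid-disordered (Ld)
phase and rigid amphipathic peptides adsorb on the upper monolayer. The
geometry is effectively one-dimensional: all boundaries are straight and
parallel, fields depend on a single lateral coordinate $x$ (nm), and every
energy is reported per unit boundary length in units of
$k_\mathrm{B}T/\mathrm{nm}$ ($k_\mathrm{B}T = 4.141\times10^{-21}$ J at
300 K).

## Elastic energy functional

Each monolayer is described by a director tilt field $n(x)$ (the deviation
of the mean lipid orientation from the monolayer normal) and by the shape
of its surfaces. The package parameterizes a configuration by five scalar
fields: the upper and lower monolayer directors $n_u, n_l$, the positions
of the two monolayer-interface surfaces $H_u, H_l$, and the bilayer
mid-surface $M$. Per unit length of boundary, each monolayer of a phase
with tilt modulus $k_t$, splay modulus $k_m$ (per monolayer), stretching
modulus $k_A$, equilibrium thickness $h$ and spontaneous curvature $J_0$
contributes a quadratic functional of the deviation from its flat
reference state, containing:

* splay, $\tfrac{k_m}{2}(n' + \text{surface curvature terms} - J_0)^2$;
* tilt, $\tfrac{k_t}{2}\,t^2$ with $t$ the local tilt deviation;
* thickness stretching, $\tfrac{k_A}{2}\,\alpha^2$ relative to $h$;
* higher-order moduli derived from the same microscopic model:
  tilt-curvature cross term $k_c = -k_t h^2/6$, splay-gradient modulus
  $k_{gr} = k_t h^4/20$ (entering as $\tfrac{k_{gr}}{2} (n'')^2$,
  see *Conventions*), and the cross couplings $B = -k_t h/2$,
  $C = k_t h^3/8$;
* lateral tension $\sigma$ acting on the excess area of the monolayer
  surfaces, with the spontaneous stretching offset
  $\alpha_0 = \sigma/(2 k_A)$.

The bilayer energy is the sum over the two monolayers plus, where the
thicker Lo phase of one monolayer faces the Ld phase of the other
(*misregistration*), a constant area-density penalty (default
0.016 $k_\mathrm{B}T/\mathrm{nm}^2$) times the misregistered width.

All parameters are collected in a `parameter_set`
(see `default_parameter_set()`); defaults are
$h_o = 1.8$, $h_d = 1.3$ nm, $k_m^o = 20$, $k_m^d = 10$ $k_\mathrm{B}T$,
$k_t = 12$ $k_\mathrm{B}T/\mathrm{nm}^2$, $k_A = 30$
$k_\mathrm{B}T/\mathrm{nm}^2$, $\sigma = 0.1$ mN/m.

## Configurations

A `membrane_configuration` is a set of Lo intervals per monolayer plus a
set of peptide strips on the upper monolayer. Convenience constructors:

* `single_boundary(L)` — one Lo/Ld boundary whose monolayer edges are
  shifted by $L$ (upper edge at $x = L$... `L > 0` means the upper
  monolayer's ordered region protrudes);
* `domain_pair(D, L_left, L_right)` — two semi-infinite Lo domains whose
  *facing, protruding* monolayer edges are a distance $D$ apart (see
  *Distance convention*);
* `peptide_in_phase(phase)` — a single peptide in a uniform phase.

A peptide is a rigid strip of width $\Delta L = 1.3$ nm on the upper
monolayer. Under the strip the upper director is not free: the strip
imposes a fixed director difference $\Delta n$ across its edges,
$\Delta n(h) = \Delta L/\sqrt{(\Delta L/2)^2 + (h/2)^2}$, interpolated
linearly in the fraction $\delta$ of the strip overlapping the
upper-monolayer Ld phase, and a rigid-rotation tie between the surface
heights at its two edges. The solver removes the strip interior from the
variational problem and couples the flanking regions through these two
constraints.

## Solution method

Within each region of constant phase composition the Euler–Lagrange
equations of the quadratic functional are linear ODEs with constant
coefficients; their solutions are sums of (complex) exponentials
$e^{\mu x}$ plus polynomial zero modes. `solve_equilibrium()`:

1. computes the characteristic roots $\mu$ per phase combination
   (`characteristic_roots()`), discarding growing modes in the two
   unbounded outer regions;
2. assembles interface conditions at every breakpoint (see
   *Conventions*), the peptide jump/rotation constraints, and far-field
   decay;
3. minimizes the exactly integrated quadratic energy over the remaining
   basis coefficients subject to those linear constraints (a KKT system).

This is exact up to floating point: no spatial discretization is
involved. An independent check, `solve_equilibrium_fd()`, discretizes the
*functional* (not the ODEs) on a uniform grid with finite differences and
minimizes the resulting sparse quadratic form subject to the same
constraints. The two routes share no code beyond the parameter structures
and agree to better than 1% on all configuration classes; the test suite
enforces this.

### Conventions

Two discrete conventions are fixed by requiring the single-boundary line
tension scan to reproduce the known behaviour of this model class
(minima at $|L| \approx 2.3$ nm with elastic line tension
$\approx 0.28\,k_\mathrm{B}T/\mathrm{nm}$):

* the splay-gradient term enters with the factor $k_{gr}/2$;
* at phase boundaries the director $n$ and surface height $H$ of each
  continuous monolayer are continuous, while $n'$ and the mid-plane $M$
  are free (natural boundary conditions). This is adjustable via
  `options(memelastic.continuity = )`.

### The tension mode

With $\sigma > 0$ the characteristic-root spectrum contains a slow
capillary mode, $\mu \approx \pm 0.05\ \mathrm{nm}^{-1}$ at the default
parameters, i.e. a $\sim$20 nm decay length, alongside the
$\sim$0.4–1.3 nm tilt-splay lengths. Deformation *amplitudes* in this
mode are small, but interaction energies inherit its range: profiles
decay like $e^{-2\mu D}$ and reach their far-field plateau only beyond
$D \approx 30$–40 nm. Default distance grids therefore extend to 40 nm,
and finite-difference cross-checks of peptide configurations use wide
boxes (half-width 60 nm).

## Scans

* `line_tension_vs_shift()` — elastic line tension vs $L$, locating the
  two symmetric minima.
* `peptide_domain_profile(L0)` — energy vs the peptide right-edge
  coordinate $X$ at fixed boundary shift, referenced to the isolated
  boundary plus a peptide far in the Ld phase; reports the boundary well
  depth and the barrier for crossing into the Lo domain.
* `joint_minimum_peptide_shift()` — free joint minimization over $(L, X)$
  on one sign branch of $L$.
* `interaction_profile(topology)` — domain-domain interaction energy
  $E(D) - E(\infty)$, minimized at each $D$ over both monolayer shift
  magnitudes and the peptide positions; `fusion_barrier()` extracts the
  barrier. Topologies (which monolayer protrudes on each side, 0–2
  peptides) are enumerated by `boundary_topologies()`.

### Distance convention and topology equivalence

$D$ is measured between the *facing, protruding* monolayer edges — the
gap that actually closes when the domains merge — while the other
monolayer's edge recedes by the shift magnitude. With this convention an
exact symmetry argument applies: reflecting the bilayer in its mid-plane
maps a configuration whose near boundaries protrude in the upper
monolayer onto one protruding in the lower monolayer while preserving the
gap, so such topology pairs have identical energy to machine precision,
and the remaining topology classes differ only through the weak coupling
across the gap (measured: $\lesssim 3\times10^{-4}$
$k_\mathrm{B}T/\mathrm{nm}$). Fusion barriers are therefore effectively
topology-independent at fixed peptide count.

### Basin tracking and the peptide basin

The per-$D$ optimization is deliberately *adiabatic*: the scan proceeds
from large to small $D$, warm-starting each point from the previous
optimum, and every coordinate update is a basin-restricted downhill line
search (`.local_line_min`) that stops at the first intervening energy
rise. A global per-$D$ optimizer would hop between distant basins (e.g.
discontinuously re-absorbing a peptide) and produce unphysical kinks in
$E(D)$.

A peptide at an isolated boundary has two competing positions: a well on
the Ld side of the edge, reachable by diffusion through the Ld phase, and
a deeper absorbed state just inside the Lo domain, separated from the Ld
side by a crossing barrier. For merging kinetics the relevant pathway
keeps the peptides in the Ld gap between the approaching domains —
`interaction_profile(peptide_side = "disordered")`, the default —
so the closing gap must squeeze the peptides and the scan truncates where
the strips no longer fit; the barrier is the profile maximum over
feasible $D$. `peptide_side = "free"` instead finds the global optimum at
every $D$, letting peptides be absorbed into the domains.

## From per-length to absolute energies

For circular domains of radius $R$, facing arcs interact over an
effective length $2\sqrt{2\lambda R}$ ($\lambda \approx 1$ nm is the
deformation decay length); `absolute_fusion_barrier()`,
`absolute_well_depth()` and `peptide_concentration_full_boundary()`
convert per-length results into absolute barriers ($k_\mathrm{B}T$), well
depths and the peptide/lipid ratio that saturates all domain boundaries.

## Worked example

```{r example, eval = FALSE}
library(memelastic)
p <- default_parameter_set()

# line tension vs shift: two symmetric minima
lt <- line_tension_vs_shift(seq(-5, 5, by = 0.1), p)
lt$extrema

# peptide profile at the optimal shift
pp <- peptide_domain_profile(2.3, params = p)
pp$details$well_depth

# fusion barrier without peptides
pr <- interaction_profile(boundary_topologies(0)[1, ], p)
fusion_barrier(pr)
```

## Limitations

* The geometry is 1D: curvature of the domain boundary, peptide
  orientation in the membrane plane, and entropic contributions are
  outside the model; absolute-energy conversions are order-of-magnitude
  estimates.
* The functional is quadratic; large deformations (e.g. at contact,
  $D \to 0$) are outside its range of validity.
* The location and depth of the *absorbed* peptide state inside the Lo
  domain are sensitive to the discrete interface conventions listed
  above; the package fixes one calibrated convention and exposes it via
  options rather than claiming it is unique. Quantities dominated by the
  Ld-side physics (line tension minima, boundary well depth, fusion
  barriers along the disordered-side pathway) are robust to this choice.
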
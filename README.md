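# memelastic

One-dimensional continuum elasticity of lipid bilayers with coexisting
liquid-ordered (Lo) and liquid-disordered (Ld) phases and rigid adsorbed
amphipathic peptides.

## What it computes

Biological membranes phase-separate into thicker, stiffer Lo domains
("rafts") and a thinner Ld surround. The hydrophobic-thickness mismatch at a
domain boundary forces elastic deformations — lipid tilt, splay and
monolayer stretching — whose overlap produces measurable, membrane-mediated
forces. `memelastic` minimizes a quadratic tilt–splay–stretch energy
functional over five fields (two monolayer directors, two monolayer
surfaces, the bilayer mid-surface) in a 1D geometry where every boundary is
a straight line, and reports energies per unit boundary length in
kBT/nm. It answers four questions:

1. **Boundary structure.** How far are the Lo edges of the two monolayers
   shifted against each other, and what is the elastic contribution to the
   boundary line tension? (`line_tension_vs_shift`)
2. **Peptide–boundary interaction.** An amphipathic peptide adsorbed on the
   upper monolayer deforms it; near a domain boundary this produces an
   energy landscape with a well that localizes peptides at the boundary.
   (`peptide_domain_profile`, `joint_minimum_peptide_shift`)
3. **Domain–domain interaction.** The energy of two Lo domains as a
   function of the gap D between them, minimized over the boundary shifts
   and peptide positions at every D, giving the fusion (merger) energy
   barrier at 0, 1 or 2 peptides on the facing boundaries.
   (`interaction_profile`, `fusion_barrier`, `boundary_topologies`)
4. **Absolute scales.** Conversions from per-unit-length energies to
   absolute energies for circular domains of radius R, and the peptide
   concentration that saturates all domain boundaries. (`estimates`
   functions)

The production solver uses the analytic (exponential) solution basis of the
Euler–Lagrange equations per membrane region and is exact up to floating
point; an independent finite-difference discretization of the same
functional (`solve_equilibrium_fd`) is shipped as a cross-check and agrees
to better than 1% (enforced by the test suite). See the vignette
(`vignettes/membrane-elasticity.Rmd`) for the functional, the interface
conventions, the distance convention and the optimizer design.

## Worked example

```r
library(memelastic)
p <- default_parameter_set()   # Lo: h=1.8 nm, km=20 kBT; Ld: h=1.3, km=10;
                               # kt=12, kA=30 kBT/nm^2, sigma=0.1 mN/m

# 1. Boundary structure: scanning the monolayer shift L finds two symmetric
#    minima at |L| = 2.30 nm with an elastic line tension of 0.28 kBT/nm.
lt <- line_tension_vs_shift(seq(-5, 5, by = 0.1), p)
lt$extrema
#>   type position     value
#> 1  min  -2.3009 0.2796...
#> 2  min   2.3009 0.2796...

# 2. A peptide near the boundary (shift held at its optimum) sits in a well
#    0.86 kBT/nm deep relative to the peptide far in the Ld phase.
pp <- peptide_domain_profile(2.3, params = p)
pp$details$well_depth        # 0.857
pp$details$crossing_barrier  # 0.40  (barrier for crossing into the domain)

# 3. Fusion barrier of two domains, no peptides: 0.054 kBT/nm at D = 1.75.
pr0 <- interaction_profile(boundary_topologies(0)[1, ], p)
fusion_barrier(pr0)          # $barrier 0.054, $D_barrier 1.75

# With one peptide per facing boundary the long-range peptide-peptide
# repulsion raises the barrier by an order of magnitude:
pr2 <- interaction_profile(boundary_topologies(2)[1, ], p)  # both-upper
fusion_barrier(pr2)$barrier  # 0.69

# 4. Absolute barrier for R = 50 nm domains:
absolute_fusion_barrier(fusion_barrier(pr2)$barrier, lambda_decay = 1, R = 50)
#> 13.8 kBT  -- merger is effectively blocked
peptide_concentration_full_boundary(R = 50)  # ~1/500 peptide per lipid
```

Parameters can be loaded from flat YAML files with explicit unit suffixes
(`load_config`), and every scan can be written to TSV with a JSON summary
sidecar (`write_profile`). A command-line front end with the same
functionality is installed at `inst/cli/memelastic.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "memelastic.R", package = "memelastic"))')" \
    fusion-barrier --peptides 2 --out profile.tsv
```

## Tests

```r
testthat::test_dir("tests/testthat", package = "memelastic",
                   load_package = "installed")
```

The suite covers unit conversions and derived moduli, solver symmetries and
boundary conditions, configuration bookkeeping, the finite-difference
cross-check, scan drivers and IO round trips, plus an acceptance file
pinning the headline reference values.
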
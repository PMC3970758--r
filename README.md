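# ringgeom

Geometric analysis of ring-shaped protein assemblies and the
single-stranded DNA (ssDNA) they enclose, motivated by hexameric MCM
helicase N-terminal domain structures in which ssDNA circles the channel
interior roughly perpendicular to the ring axis. The package turns the
quantitative claims such structures support into reusable, tidy R
functions:

- **Deviation from C<sub>n</sub> symmetry.** The subdomain Cα coordinates
  of all n chains, concatenated in ring order, are superposed in one
  global least-squares fit onto the one-step cyclic permutation of the
  chain labels (ABCDEF onto BCDEFA). The fitted RMSD is 0 iff the ring is
  exactly C<sub>n</sub> symmetric; the fitted rotation's invariant line is
  the channel axis. (`permutation_rmsd()`, `fit_axis()`)
- **Channel radius profile.** Minimum distance from the channel axis per
  axial bin — equivalently, the profile of a full 360° cylindrical merge,
  computed directly since radial distance is rotation-invariant about the
  axis. (`radial_profile()`, `narrowest_point()`, `clearance_vs_reference()`)
- **Interface engagement.** The distance between a probe Cα on one subunit
  and a partner Cα on its counterclockwise neighbor (for PfMCM: residues
  201 and 127), classified engaged (< 7.5 Å), intermediate, or disengaged
  (> 8.4 Å), and cross-tabulated against observed DNA occupancy.
  (`probe_spec()`, `classify_ring_interfaces()`, `engagement_vs_dna()`)
- **ssDNA path geometry.** 5′→3′ angular polarity (clockwise vs
  counterclockwise under an explicit viewing convention), tilt of the
  best-fit DNA plane relative to the axis, contiguous-stretch
  segmentation, and contact-based per-subunit nucleotide assignment.
  (`polarity()`, `planarity()`, `segment_stretches()`, `assign_nucleotides()`)
- **EMSA Hill fits.** The paired band-fraction isotherm
  I<sub>free</sub>/I<sub>0</sub> = K<sup>h</sup>/(K<sup>h</sup> + c<sup>h</sup>),
  I<sub>bound</sub>/I<sub>0</sub> = c<sup>h</sup>/(K<sup>h</sup> + c<sup>h</sup>),
  fitted jointly over both bands for K<sub>half</sub> and h, with
  fold-change reporting as K<sub>half</sub> ratios. (`hill_model()`,
  `fit_titration()`, `fold_change()`)
- **Synthetic ground truth.** Deterministic generators for near-C<sub>n</sub>
  rings (with controlled per-subunit perturbations), circular/helical DNA
  paths of known handedness, and simulated titrations, so every stage is
  testable without crystallographic input. (`make_ring()`, `make_dna()`,
  `simulate_titration()`)

Coordinate files are read from PDB and mmCIF (`read_assembly()`, via
bio3d); assemblies are tibbles of atoms, results are tibbles, fits have
broom-style `tidy()`/`glance()` and `autoplot()` methods, and
`inst/scripts/ringgeom.R` exposes the analyses as shell subcommands.

## Worked example

A hexamer with one subunit pushed 1.5 Å radially outward, holding a
planar, clockwise, gapped 12-mer DNA ring:

```r
library(ringgeom)

ring <- make_ring(synthetic_ring_spec(
  perturbation = list(radial_shift = c(1.5, 0, 0, 0, 0, 0))))
dna  <- make_dna(synthetic_dna_spec(radius = 15, angular_step = -30, gaps = 5))
asm  <- merge_assemblies(ring, attr(dna, "assembly"))

report <- run_full_analysis(run_config(
  structure = asm,
  rings = list(list(chains = LETTERS[1:6], subdomain = c(1, 30),
                    label = "hexamer 1", dna_chains = "M")),
  probe = list(residue_a = 1, residue_b = 15)
))
report
#> == hexamer 1: permutation RMSD 0.829 Å, rotation 60.01°, narrowest 15.961 Å at z -0.5
#>    interfaces: engaged=0 intermediate=0 disengaged=6
#>    DNA: clockwise (sweep -329.5°), plane tilt 0.00°, stretches [7, 4]
```

The permutation RMSD of 0.829 Å quantifies the asymmetry injected by the
single displaced subunit (an unperturbed ring scores 0); the rotation is
the fitted 60° symmetry operation; the DNA reads clockwise viewed from the
declared C-terminal face, lies exactly in the perpendicular plane (tilt
0°), and its single gap splits 11 modeled nucleotides into stretches of 7
and 4. The per-subunit residuals localize the distortion to the displaced
subunit and its permutation partner:

```r
tidy(report[["hexamer 1"]]$symmetry)
#> # A tibble: 6 × 5
#>   chain  rmsd permutation_rmsd rotation_angle label
#>   <chr> <dbl>            <dbl>          <dbl> <chr>
#> 1 A     1.39             0.829           60.0 hexamer 1
#> 2 B     0.250            0.829           60.0 hexamer 1
#> ...
```

A noisy simulated titration at the nine-point wild-type concentration
ladder, refit:

```r
fit <- fit_titration(simulate_titration(wt_conc_ladder(), k_half = 6.8, h = 2,
                                        noise_sd = 0.02, seed = 7))
glance(fit)
#> # A tibble: 1 × 5
#>   k_half     h     rss converged     n
#>    <dbl> <dbl>   <dbl> <lgl>     <int>
#> 1   6.34  1.95 0.00768 TRUE          9
```

With 2% band noise the recovered K_half (6.34 µM) sits within a few percent
of the true 6.8 µM; `autoplot(fit)` draws the data and fitted curves.

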
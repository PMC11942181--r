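# condstat

Structural analysis of microphase-separated biomolecular condensates in R.

Diblock elastin-like polypeptides (ELPs) with sequence
(V-P-G-V-G)<sub>n</sub>-(V-P-G-X-G)<sub>n</sub> phase-separate into a
protein-dense slab that spans the x–y plane of a periodic box and coexists
with a dilute solvent phase along z. Within that slab the two blocks can
microphase-separate into lamellar-, gyroid- or micelle-like domains whose
organisation controls the solvation microenvironment of each residue.
`condstat` implements the standard analysis pipeline for such slab
configurations, for computational biophysicists who want the observables
without re-deriving the bookkeeping:

- **Topology**: diblock chain builder at CA, 4-heavy-atom coarse, and
  atomistic-lite (heavy atoms + polar hydrogens) resolutions, with block
  labels and guest flags.
- **Alignment**: chain centre-of-mass contact graph (4 nm cutoff),
  depth-first-search largest cluster, per-frame re-centering of the slab so
  z = 0 labels the condensate centre.
- **Structure**: per-species density profiles, central-block enrichment,
  inter-chain residue contact maps (0.6 nm), block-resolved radial
  distribution functions g(r) on [10⁻⁵, 2] nm with intra-chain exclusion,
  guest-environment RDFs, radii of gyration with the ideal-chain reference
  R<sub>g</sub> = sqrt(2 l<sub>p</sub> b / ((2ν+1)(2ν+2))) · N<sup>ν</sup>
  (b = 0.38 nm, l<sub>p</sub> = 0.40 nm).
- **Hydration**: hydrogen-bond detection (donor–acceptor ≤ 3.30 Å,
  D–H–A angle ≥ 135°, both inclusive), PP/PW/WW classification, nearby-water
  counts (≤ 4.0 Å), the water hydrogen-bond density statistic, Shrake–Rupley
  SASA (0.14 nm probe) and relative solvent accessibility.
- **Thermodynamics**: surface tension from pressure-tensor anisotropy,
  τ = L<sub>z</sub>/(2N) · (P<sub>zz</sub> − (P<sub>xx</sub>+P<sub>yy</sub>)/2),
  with windowed error bars; hydrophobicity-scale normalisation and Pearson
  correlation against transition temperatures.
- **Synthetic data**: generators with known ground truth — morphology-
  controlled condensate slabs (uniform / lamellar / gyroid / micelle /
  two-phase), planted hydrogen-bond fixtures, freely jointed chain
  ensembles, and pressure series with a prescribed τ — used to validate
  every analysis stage.

I/O covers GRO (nm, multi-frame), PDB (CRYST1/MODEL dialect, Å converted at
the boundary), XVG-style pressure tables, and CSV scale/annotation files.

## Worked example

Generate a gyroid-morphology condensate of 48 V₅F₅ chains, align it, and ask
whether the blocks microphase-separate:

```r
library(condstat)

spec <- morphology_spec("GYROID", box = c(12, 12, 24), slab_width = 10,
                        phi_p = 1, guest = "F", n_chains = 48, n_repeats = 5,
                        seed = 1, n_frames = 8)
traj <- recenter_trajectory(generate_condensate(spec))

suite <- block_rdf_suite(traj, n_bins = 100)
sapply(suite, rdf_first_shell)
#>        VV        XX        VX
#> 5.5734802 6.2387040 0.5973917

central_block_enrichment(traj, central_width = 10/3)
#>   V_block   X_block
#> 0.9495937 1.0464556
```

The first-shell g(r) of the self-block pairs (V–V 5.57, X–X 6.24) towers
over the cross-block pair (V–X 0.60): the two blocks occupy the two
interpenetrating networks of the gyroid, touching mainly at the interface.
The central enrichment stays near 1 for both blocks — unlike a lamellar
morphology, the gyroid does not segregate blocks along z.

Surface tension from a pressure series with a planted τ = 10 bar·nm:

```r
ps <- generate_pressure_series(tau_target = 10, Lz = 24, n_droplets = 1,
                               n_rows = 5000, noise_sd = 3, seed = 1)
surface_tension(ps, n_windows = 5)
#> surface tension: 9.441 bar nm (0.9441 mN/m), SD 1 over 5 windows

ideal_chain_rg(50)   # ideal-chain reference for a 50-residue peptide
#> [1] 1.591645
```

The recovered τ sits within one window-SD of the planted value; the
ideal-chain R<sub>g</sub> for N = 50 is 1.59 nm.

The same stages run from a config file via `run_pipeline("run.yaml")` or
the thin CLI at `inst/cli/condstat.R`.

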
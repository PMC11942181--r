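---
title: "Methods: slab analysis of diblock ELP condensates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slab analysis of diblock ELP condensates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condstat)
```

## The system and its geometry

`condstat` analyses slab-geometry configurations of diblock elastin-like
polypeptides (ELPs): chains of sequence (V-P-G-V-G)~n~-(V-P-G-X-G)~n~, where
the guest residue X may be any standard amino acid except proline. The first
half of each chain is labelled `V_BLOCK`, the second `X_BLOCK`, and the X
position of every second-half pentamer carries a guest flag; the two glycines
flanking each guest (pentamer positions 3 and 5) form the "guest-adjacent
glycine" selection used by the hydration statistics.

All analyses assume an orthorhombic, fully periodic box with the condensate
forming a dense slab that spans the x–y plane and coexists with a dilute
phase along z. Coordinates are nm throughout; Ångström values appearing in
file formats (PDB) or literature cutoffs are converted at the boundary, so
the hydrogen-bond thresholds are stored as 0.330 nm and 0.400 nm.

## Alignment: clustering and re-centering

The condensate diffuses along z, so each frame is aligned independently.
Chains become nodes of a contact graph with an edge whenever two chain
centres of mass are within 4 nm under minimum image; a depth-first search
finds the largest connected component, and the frame is translated along z
so that component's centre of mass sits at the box midpoint. Profile
functions report z relative to that midpoint, so z = 0 labels the condensate
centre — a labelling convention, not a storage one, chosen to avoid negative
wrapped coordinates.

Centres of mass under periodic boundaries use circular-mean unwrapping: each
coordinate axis is mapped to a circle, the mass-weighted mean angle fixes a
reference, every bead is shifted to the image nearest that reference, and
the ordinary mass-weighted mean is taken and wrapped back. This makes the
COM of a chain (or cluster) split across the boundary well defined, and it
makes re-centering idempotent to floating-point precision. How the original
analyses treated COMs under periodicity is not something the coordinate
files record, so this choice is the package's own.

Size ties in the largest-cluster search are broken toward the component
containing the smallest chain id. An independent connected-components
implementation (igraph) serves as the test oracle for this search.

## Density profiles and central-block enrichment

Density profiles are time-averaged mass densities per z-bin (default bin
width 0.25 nm, a choice of this package) for protein, V block, X block,
water and ions; binned mass is conserved by construction, and mass fraction
per bin is reported alongside g/cm³.

Central-block enrichment compares each block's density in a central window
|z| < w~c~/2 with its mean over the slab. The slab extent is detected from
the protein profile: a 5-bin running mean is thresholded at 30% of its
maximum, the contiguous above-threshold run around the centre is taken, and
three bins are eroded from each end. The smoothing keeps the detection
robust to interior microphase structure (a lamellar morphology has a genuine
density dip between the inner V band and the outer X bands); the erosion
keeps the interfacial roll-off from diluting the slab mean, which would
otherwise bias the enrichment of a homogeneous slab a few percent above 1.
Both numbers were fixed by construction-level reasoning on the generators
(the dip depth and the roll-off width), not fitted to any particular run.

## Contact maps and radial distribution functions

Two residues on *different* chains are in contact when any pair of their
beads is within 0.6 nm under minimum image. The map aggregates over ordered
chain pairs and is then symmetrised — the aggregation convention is not
derivable from the published material, so it is declared here and tested
against brute-force enumeration. The diagonal is meaningful: same sequence
position on different chains.

RDFs are standard shell-normalised pair distributions over [10⁻⁵, 2] nm
(200 bins by default; only the range is prescribed, the bin count is this
package's choice): counts per bin divided by N~pairs~ · V~shell~/V~box~,
where N~pairs~ counts candidate pairs *after* exclusions. Self-pairs are
always excluded; block-resolved RDFs also exclude intra-chain pairs, so the
V–V, X–X and V–X curves isolate inter-chain organisation, while the
guest-environment RDFs (guest → native V, P, G) include intra-chain pairs to
capture the sequence-imposed first shell. Because the normalisation uses the
full periodic box volume, the dense-phase g(r) of a two-phase slab plateaus
above 1; this matches the convention of the trajectory-analysis libraries
the field uses and is deliberate.

## Radii of gyration

R~g~ is the mass-weighted second moment about the entity's COM, per chain or
per block, with chains unwrapped bead-by-bead along minimum-image bonds
before the moment is taken. A nominal bond longer than a quarter of the
smallest box edge cannot be disambiguated under minimum image and raises a
geometry error. The ideal-chain reference is
R~g~ = sqrt(2 l~p~ b / ((2ν+1)(2ν+2))) · N^ν^ with b = 0.38 nm and
l~p~ = 0.40 nm, the values commonly used for disordered proteins; ν defaults
to 1/2 (the ideal chain) and is exposed because IDP-specific exponents are
sometimes preferred.

## Hydration statistics

A hydrogen bond is a (donor heavy atom, hydrogen, acceptor heavy atom)
triple with D–A ≤ 0.330 nm and D–H–A angle ≥ 135.0°, both thresholds
inclusive (a 10⁻⁹ numerical slack keeps geometries planted exactly at a
boundary inclusive in floating point). Covalently bonded donor–acceptor
pairs are excluded — standard practice in the analysis libraries this
mirrors; in the peptide chemistry modelled here no donor is actually bonded
to an acceptor, so the rule is a guard rather than an active filter. Bonds
are classified PP/PW/WW by the species of the donor and acceptor parents.
These analyses require the ATOMISTIC_LITE resolution, which places polar
hydrogens at ideal geometry (0.10 nm O–H/N–H bonds); coarse resolutions are
rejected with a capability error.

Per-residue averages credit each PP bond to both participating residues and
each PW bond to its protein residue; whether published per-residue averages
double-credit PP bonds is not stated anywhere we could check, so the
convention is declared here. The water hydrogen-bond density of a residue
selection is, per frame, the number of PW bonds whose protein residue is in
the selection divided by the number of distinct water molecules whose oxygen
lies within 0.40 nm of the selection's heavy atoms; frames with no nearby
water are skipped with a warning. Error bars for hydration statistics are
SDs over 4 contiguous time windows; surface tension uses 5 windows.

## SASA and RSA

SASA uses the Shrake–Rupley construction: each atom's sphere is inflated by
the 0.14 nm probe, covered with a deterministic Fibonacci lattice (960
points by default, about 1% quadrature error on an isolated sphere — the
tested contract), and the exposed fraction scales the inflated-sphere area.
Radii are the Bondi van der Waals set, overridable. RSA divides the mean
SASA of each guest residue type by its maximum possible exposure; both an
empirical and a theoretical maximum table ship under `inst/extdata` because
published RSA normalisations do not always state which variant they use.
RSA is reported unclamped (a warning fires above 1.2) since highly exposed
conformations legitimately exceed the tabulated maxima.

## Surface tension and correlation

For N droplets in a box of height L~z~,
τ = L~z~/(2N) · (P~zz~ − (P~xx~+P~yy~)/2), computed per row and averaged;
for constant L~z~ this equals τ of the mean anisotropy, and the per-row form
stays correct when L~z~ varies. Units are bar·nm internally with mN/m
(= 0.1 bar·nm) reported alongside. Windows are contiguous equal-length
blocks; the SD over window means is the error bar.

Hydrophobicity scales are affinely mapped onto [0, 1] with 1 at the
hydrophobic end according to each scale's declared orientation — transfer
free energies, where lower means more hydrophobic, must declare
`LOWER_IS_HYDROPHOBIC` before normalisation is defined. Correlations against
transition temperatures use Pearson's ρ over the inner join of amino-acid
keys (at least 3); T~t~ itself is never transformed, since Pearson is
invariant under affine maps and normalising it would change nothing.

## The synthetic-data generators

The published trajectories behind this kind of analysis are rarely
deposited, so every statistic here is validated against generators with
planted ground truth:

* **Condensate slabs** (`generate_condensate`): diblock chains at CA
  resolution grown as connected random walks (bond 0.38 nm) inside
  morphology-assigned regions — uniform slab, lamellar (V inside |z| < w/4),
  gyroid (the nodal approximant sin x cos y + sin y cos z + sin z cos x
  thresholded at ±t, defaults t = 0.2, period 7.5 nm — the morphology class,
  not any specific realisation), micellar cores on a grid, and a two-phase
  variant with a dilute chain fraction. Each V half starts uniform in its
  region and *bridges* to a nearby interface point: a step marches straight
  toward the target only when the remaining bonds barely cover the distance,
  so the walk ends at the block junction without piling V mass against the
  boundary, and the X half grows onward from there (a drift rule lets it
  cross the thin interface). Water and ions fill the remaining slab volume
  so the protein mass fraction inside the slab equals φ~p~, and the dilute
  phase gets the same solvent density. Defaults are the study-scale
  conditions: 15×15×30 nm box, 15 nm slab, 64 chains of n = 5 repeats,
  φ~p~ = 0.5.
* **Hydrogen-bond fixtures** (`generate_hb_fixture`): donor–H–acceptor
  motifs planted on a 2 nm grid with ≥ 0.02 nm / ≥ 10° margins on the
  criteria, plus near-but-unbonded and far waters; detection counts are
  exact by construction.
* **Ideal chains** (`generate_ideal_chain_ensemble`): freely jointed Kuhn
  segments of length 2 l~p~ with beads every b nm of arc length; the
  ensemble sqrt(mean R~g~²) matches the closed form at ν = 1/2 up to a
  finite-chain discretisation of about 3% for 50-residue chains.
* **Pressure series** (`generate_pressure_series`): Gaussian noise around a
  planted anisotropy 2Nτ/L~z~.

Every generator is a pure function of its spec, seed included.

What these fixtures do *not* emulate: excluded volume and packing
correlations, realistic water structure, chain-length and concentration
dependence of the morphology, interfacial width physics, or any
thermodynamically consistent sampling. Passing tests therefore demonstrate
that the estimators recover known structure from configurations with that
structure — not that the generators reproduce real condensate ensembles.

## Problem sizes and statistical design

The validation suite runs at desk scale: condensate fixtures of 48 chains
(2,400 protein beads) in a 12×12×24 nm box with a 10 nm slab, 8–64
independent frames per statistic, 2,000-chain ideal-chain ensembles and
10⁴-row pressure series. Frame counts were sized from the observed
frame-to-frame variance of each statistic (chain placement is the dominant
noise source: roughly 20% per frame for central enrichment, averaging down
as 1/√frames) so that each tolerance sits at ≥ 3 standard errors, and the
whole suite stays in the minutes range on one CPU.

## Known limitations

* The chain-COM contact graph can split a lamellar slab into X-up/X-down
  components when the slab is wide enough that the two groups' COMs are more
  than 4 nm apart; the validation fixtures use a 10 nm slab in a 24 nm box,
  where the graph stays connected. Real condensates do not have this
  failure mode (chains interdigitate).
* `generate_condensate` produces CA-resolution systems; hydrogen-bond and
  SASA analyses operate on ATOMISTIC_LITE topologies, whose coordinates come
  from the planted fixtures (or from the user's own files), not from the
  slab generator.
* GRO/PDB cannot express block labels; they are reconstructed by matching
  the residue sequence against the diblock template, with a sidecar
  annotation CSV as the authoritative override. Files whose molecules are
  not grouped chains-then-solvent fall back to a generic topology with a
  warning.
* Whether "protein density near the condensate centre" is a mass or volume
  fraction is ambiguous in the literature this mirrors; this package reports
  mass fraction and labels it as such.
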
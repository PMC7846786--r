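---
title: "Dual-paratope Fv engineering: models, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-paratope Fv engineering: models, rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualfv)
library(dplyr)
```

This vignette is the package's own account of the science it implements: the
paratope partition of an antibody Fv, the scaffold rules that keep a
VH3–Vk1 dual-paratope Fab stable and modular, the merging and library
models built on top of that partition, and the structural measures used to
quantify paratope footprints and co-binding feasibility. It also records the
numerical choices and the design decisions taken where the design was
genuinely open.

## The two-paratope model of the Fv

An Fv pairs a heavy (VH) and a kappa light (Vk) variable domain, each
contributing three CDR loops. Projected onto the antigen-binding surface,
the six loops form two contiguous, spatially separated patches:

* **H-side** — HCDR1, HCDR3 and LCDR2, towards the VH N-terminus;
* **L-side** — LCDR1, LCDR3 and HCDR2, towards the Vk N-terminus.

Each patch can act as an independent paratope. The package represents a
side as a `paratope_scheme()`: three core CDRs plus optional *enhancing*
framework ranges — positions that do not normally contact antigen but can
modulate the conformation of the adjacent CDR1 loop. The shipped enhancing
extents are the VH N-terminus (H1–H7) and VH outer loop (H71–H78) for the
H-side, and the Vk N-terminus (L1–L7) and Vk outer loop (L66–L71) for the
L-side. These four ranges are design choices, not published constants: the
N-terminal spans were chosen to cover the light-chain positions L3/L5/L7
engineered in the co-operativity motif discussed below, and the outer-loop
spans are the framework stretches packing against HCDR1/LCDR1. All four are
overridable via `inst/extdata/paratope_extents.yaml`.

The load-bearing contract is **disjointness**: under every supported CDR
definition (Kabat, Chothia, Contact, and their per-CDR union), the resolved
H-side and L-side position sets never share a position, with or without
enhancing ranges. The test suite property-checks this; it is what makes the
merge below well-defined.

```{r}
tmpl <- fv_templates()
nfv  <- number_fv(tibble::tibble(id = "t", heavy = tmpl$heavy, light = tmpl$light))
h <- resolve_paratope_positions(nfv, paratope_scheme("H-side", "union"), TRUE)
l <- resolve_paratope_positions(nfv, paratope_scheme("L-side", "union"), TRUE)
length(intersect(paste(h$chain, h$label), paste(l$chain, l$label)))
```

The default CDR definition for paratope resolution is `"union"` — every
position called CDR by any of the three published schemes — because a
paratope transfer must move *all* potentially antigen-contacting residues.

## Numbering: template alignment with insertion anchors

All position symbols live in a Kabat-style frame. Numbering is
template-alignment based: each chain is globally aligned
(BLOSUM62, affine gap open 11 / extend 1, via Biostrings) to an embedded
VH3 or Vk1 consensus template whose residues carry pre-assigned labels
H1–H113 / L1–L107. A general-purpose profile-HMM numberer is deliberately
out of scope: the platform restricts itself to VH3–Vk1-like domains, and a
query whose framework identity to the template falls below 55 % is rejected
rather than numbered badly.

Length differences are absorbed only at canonical insertion anchors
(H35, H52, H82, H100; L27, L95, L106). Extra residues become
insertion-coded labels (`100A`, `100B`, …) immediately after the anchor;
deletions consume labels backwards from the anchor (an HCDR3 one residue
short lacks label 100 while 101 — the invariant Asp — remains). A length
change in a region without an anchor is an error, not a guess. Alignment
ties cannot reorder labels because labelling is segment-based: the
alignment fixes which residues belong to each region, and labels within a
region are assigned by the deterministic anchor rule, not by gap placement.

The embedded templates are synthetic germline-consensus sequences laid out
so the canonical labels tile the chains with no insertion codes. Two points
are worth knowing:

* consensus identities at the four invariant interface positions
  (H35 = Ser, H50 = Ala, L34 = Asn, L91 = Tyr) are defaults; projects with
  exact scaffold sequences supply them via the rule-set config;
* light-chain FR4 carries Leu at L104 (the clone context of the
  co-operativity worked example) rather than the germline Val. Both
  templates are replaceable via `fv_templates(heavy=, light=)`.

## Scaffold stability and HCDR3-conformation rules

Dual-paratope modularity requires that the structural core of the Fv be
invariant across binders. The shipped `ScaffoldRuleSet`
(`inst/extdata/scaffold_rules.yaml`) encodes:

* invariant VH/VL interface residues VH35, VH50, VK34, VK91 — the positions
  whose identity dominates Fab thermostability;
* the kinked-HCDR3 signature: a basic residue (Arg/Lys) at VH94 paired with
  an invariant Asp at VH101, which locks the loop in the kinked
  conformation class and keeps the H-side pocket-shaped;
* Tyr/Phe restriction at VH99 and at VK49 (the position directly ahead of
  LCDR2), allowing the aromatic pair that stabilises the HCDR3
  conformation.

`check_scaffold_compliance()` audits any numbered Fv; rules referencing
labels absent from the frame (e.g. an insertion-coded label on a short
loop) are reported `inapplicable` and fail the audit unless `lenient =
TRUE` — the strict default favours surfacing frame mismatches over silently
passing them.

## Merging monospecific binders into a bispecific Fv

`merge_paratopes(scaffold, h_binder, l_binder)` substitutes every resolved
H-side position from the H-binder and every L-side position from the
L-binder into the scaffold. Semantics worth stating precisely:

* **Ownership dictates loop length.** The H-binder's HCDR3 length and the
  L-binder's LCDR1/LCDR3 lengths carry into the product; libraries fix one
  HCDR3 length per library precisely so that H-side length variation cannot
  perturb the L-side. Length changes can therefore occur only inside
  side-owned CDRs.
* **Provenance** is recorded per position: `H-binder` / `L-binder` where
  the owner's residue differs from the scaffold, `scaffold` elsewhere, and
  `mutation` for labelled point edits applied afterwards.
* **Strictness.** A binder deviating from the scaffold at a framework
  position owned by *neither* side is an off-paratope deviation: an error
  by default, a warning (scaffold wins) in lenient mode. Deviations at the
  *opposite* side's positions are not errors — that side's owner supplies
  those positions anyway. This choice is forced by the fixed-point
  requirement `merge(scaffold, M, M) = M` for any merge output `M`, which
  the suite property-checks: a bispecific output necessarily deviates from
  the scaffold on both sides.
* Whether enhancing positions transfer is an explicit flag
  (`include_enhancing`, default `TRUE`), since one can argue for copying
  them unconditionally or only when the binder was actually selected with
  diversified enhancing residues.

Labelled point mutations use the grammar `"chain:wt+label+new"`
(`"L:Q3Y"`; insertion codes inside the label, `"H:G100AY"`). The
co-operativity motif worked example — Q3Y, T5H, S7E, Q100H, L104V on the
light chain, the contact set between two Fabs bound to the same homodimeric
antigen — is the canonical use.

## Library design and diversity accounting

A `LibrarySpec` fixes per-position amino-acid alphabets over one side's
resolved positions. Validation enforces the rule set (VH101 only Asp, VH94
within Arg/Lys, VH99 and VK49 within Tyr/Phe, invariant positions
untouched) and rejects positions outside the side. Diversity is counted in
**amino-acid combinations**, not codons — degenerate-codon/trinucleotide
chemistry design is out of scope — and is carried as an exact decimal big
integer (a realistic 18-position × 12-letter design exceeds 2^53, so
doubles would silently round; no arbitrary-precision dependency is used, a
short in-package decimal multiply suffices and is cross-checked against
exhaustive enumeration and log-sums in the tests). Sampling is uniform per
position — no positional priors are published — with an explicit integer
seed recorded in member identifiers; identical seeds give byte-identical
FASTA.

Affinity maturation is re-diversification of one paratope while the other
is held invariant (`maturation_spec()`), mirroring how matured clones are
produced in the bispecific context. With `revert_framework = TRUE`,
framework mutations *outside* the enhancing ranges are reset to the
template identity, while outer loops and N-termini may keep their selected
deviations — the same asymmetry used when maturation libraries are
constructed.

## Structural measures

**SASA.** `sasa()` implements Shrake–Rupley: for each atom, the fraction of
`m` quasi-uniform points on the sphere of radius `r_i + w` lying inside no
neighbouring sphere, times `4*pi*(r_i + w)^2`. Points are a deterministic
Fibonacci lattice, so results are exactly reproducible at a given `m`.
Defaults: probe `w = 1.4` Å, `m = 960`, published protein heavy-atom radii
(C 1.70, N 1.55, O 1.52, S 1.80 Å; table overridable), hydrogens ignored
(crystal structures generally lack them). The suite checks the
isolated-atom closed form exactly, the two-sphere analytic cap formula and
a dense-point oracle to 1 %, and 960-vs-10000-point convergence to 2 %.

**Paratope footprints.** `interface_footprint()` computes buried area as
`SASA(group alone) − SASA(group in complex)` per side, decomposed per
residue, with optional attribution to CDR/framework regions through a
`footprint_region_map()` — this assumes the structure's antibody chains are
numbered in the annotation's frame, the convention for deposited Fab
coordinates. This ΔSASA is the paratope-size metric for antibody–antigen
complexes (deposited dual-paratope structures give ≈430 Å² against the
VEGFA dimer on the L-side and ≈292 Å² against PDGF-BB on the H-side, in
the same range as benchmark therapeutic Fabs). A ±15 % band is the right
expectation when reproducing published footprints: the radii table, probe
radius, point density and choice of asymmetric-unit copy are rarely stated,
and each shifts totals by a few percent. Footprints are differences of
large areas, so their relative lattice noise exceeds that of raw SASA
totals; quantitative comparisons in the package use `m = 10000`.

**Superposition and co-binding.** `kabsch_superpose()` is the standard
SVD-based least-squares rotation with reflection correction.
`build_ternary_model()` maps shared Fab Cα atoms between two binary
complexes (≥50 by default), superposes the second complex onto the first
via its Fab, transplants the second antigen, and scans for severe
inter-antigen van der Waals overlaps (distance < `r_i + r_j − 0.4` Å — the
0.4 Å tolerance is a common steric allowance). An empty clash table means
the Fv can, geometrically, engage both antigens at once.

**Crystal bookkeeping.** `matthews()` computes `V_M = V/(z·n·MW)` and the
solvent fraction `S = 1 − 1.66054·v̄/V_M` (clamped to [0, 1], default
v̄ = 0.74 cm³/g). With the published coefficients 2.18 and 2.63 Å³/Da
this gives 43.6 % and 53.3 % — matching the printed 43.5 %/53.2 % within
the rounding of the coefficients themselves.

## Assay models

`fit_4pl()` fits `y = bottom + (top − bottom)/(1 + (x/IC50)^nH)` by
Levenberg–Marquardt least squares in a log-dose parameterisation (the
logistic becomes `1/(1 + exp(nH·(log x − log IC50)))`, which conditions the
problem and keeps IC50 positive). Initialisation: top/bottom from the
response extrema, IC50 from the dose nearest the half-maximal signal,
`nH = 1`, with both slope signs tried. The model is invariant under
swapping top/bottom while negating `nH`; fits are reported in the canonical
orientation `top ≥ bottom`, so a rising curve has negative `nH`.
Non-convergence returns initial estimates with a warning and
`converged = FALSE` rather than an error. `viscosity_from_dls()` is the
DLS-bead conversion `eta = eta0·(r_h/r_h0)`: tracer beads appear larger in
a viscous sample in proportion to the viscosity ratio.

## What the synthetic fixtures emulate — and what they do not

The generator family exists so every operation is testable without
downloads, with ground truth known by construction:

* `make_scaffold()` / `make_binder()` perturb the consensus templates only
  at diversifiable positions, so compliance and clean numbering are
  guaranteed and the deviation set is returned as machine-checkable truth.
  Real selection campaigns, by contrast, produce binders with correlated
  mutations and occasional framework drift; the merge's strict/lenient
  modes exist for exactly that reason.
* `make_toy_complex()` builds random pseudo-atom blobs with controlled
  geometry: `separated` guarantees a zero footprint, `contacting` carries a
  dense-point (`m = 1e5`) oracle value, `clashing` embeds an exact number
  of isolated severe overlaps. These validate surface and clash arithmetic;
  they are not protein folds.
* `make_antibody_complex()` arranges one Cα pseudo-atom per Kabat position
  with the chosen side's paratope ring in contact range of an antigen blob
  — enough to exercise footprint attribution and Fab-anchored ternary
  modelling end-to-end, not a model of antibody geometry.

Passing tests on these fixtures demonstrates correctness of the numerical
machinery and the combinatorial contracts. They say nothing about binding
energetics, developability, or whether a particular merged clone retains
affinity — those remain experimental questions.

## Problem sizes and determinism

The shipped suite uses sizes chosen to exercise the asymptotics without
waste: 60-Fv round-trip perturbation loops, 120-mutant rule-audit sweeps
against a brute-force oracle, 1,000 random binder pairs for merge
provenance (with 20 fixed-point spot checks), 100 sampled library members
re-audited for compliance, 100 noisy dose-response refits, 10,000-point
SASA for quantitative comparisons and 100,000-point dense oracles on ≤80
atom complexes, and 10,000 random rotations as the Kabsch brute-force
baseline. Every stochastic step runs under an explicit seed (`withr`
scoping, so the ambient RNG state is never disturbed), and
`scripts/acceptance.R` threads a single `--seed` through all of it.

## Known limitations

* Numbering supports VH3/Vk1-like domains only: no lambda chains, no
  VHH/nanobodies, no IMGT/Aho/Martin schemes.
* The paratope extents beyond the three published CDR tables (enhancing
  ranges) and the invariant-position identities are configurable defaults,
  not published constants.
* SASA is heavy-atom and rigid; no conformational sampling, no energetic
  scoring of interfaces.
* Diversity counts are theoretical amino-acid combinatorics, not
  transformant counts or codon-level designs.
* The mmCIF reader (via bio3d) targets the standard RCSB `atom_site`
  layout; exotic mmCIF dialects may need conversion to PDB first.
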
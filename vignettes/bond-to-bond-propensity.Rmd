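---
title: "Bond-to-bond propensity: model, numerics and design choices"
author: "bondprop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bond-to-bond propensity: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bondprop)
```

This vignette documents the model implemented by `bondprop`, the
parameter values it uses, why the synthetic generators look the way they
do, and the numerical choices behind the implementation. The worked
end-to-end example lives in the README; here the focus is on *why* each
piece is the way it is.

## 1. The graph model

A structure is converted to an undirected graph whose nodes are atoms and
whose edges are energy-weighted interactions:

* **Covalent bonds** from residue templates for the standard amino acids,
  peptide `C–N` links (≤ 2.5 Å), hydrogen attachment to the nearest heavy
  atom (≤ 1.6 Å), and a covalent-radius fallback (sum of radii × 1.3) for
  non-template atoms. Energies are tabulated per element pair (kJ/mol).
* **Hydrogen bonds**: for each donor–H…acceptor triple with
  donor–acceptor distance ≤ 3.6 Å and angle ≥ 90°, the DREIDING-form
  potential `E = D0 (6 x^10 − 5 x^12) cos⁴θ` with `D0 = 39.7` and
  `x = R0 / R`, `R0 = 2.75 Å`; only attractive (`E > 0`) contacts are
  kept, the strongest per donor–acceptor pair.
* **Salt bridges** between charged side-chain groups within 4 Å:
  a Coulomb energy with relative permittivity 4.
* **Hydrophobic tethers** between apolar carbons/sulfurs of different
  residues at 3.8–8.0 Å, weighted by a tabulated potential of mean force.
  Carbons covalently bonded to N or O are not apolar.
* **Coordination / conjugate records** (`LINK`): Coulomb energy at the
  recorded distance. These typically connect ligands to the protein.

Duplicate atom pairs resolve by precedence
(covalent > electrostatic > salt bridge > hydrogen bond > hydrophobic),
and 1–2/1–3 covalent neighbours are excluded from weak-bond detection.
All weak interactions carry the flag `weak = TRUE`; this flag decides
which bonds act as perturbation sources and which are scored.

A coarse-grained alternative, `buildRRIN()`, uses one node per residue
(at its C-alpha) and unit-weight contact edges; it supports the same
propensity machinery at much lower resolution.

## 2. Propensity

Let `B` (m × n) be the signed incidence matrix, `G = diag(energies)`,
and `L = Bᵀ G B` the weighted Laplacian. The edge-to-edge transfer
matrix is

\[
M \;=\; G\,B\,L^{\dagger}\,B^{\mathsf T}.
\]

`M[b, b′]` is the signed flux carried by bond `b` when a unit source is
applied across bond `b′`. The raw propensity of bond `b` with respect to
an active site is

\[
\tilde\Pi_b \;=\; \sum_{b' \in \text{site}} |M_{b,b'}|,
\qquad
\Pi_b = \tilde\Pi_b \Big/ \sum_{c} \tilde\Pi_c ,
\]

where the sources `b′` are the *weak* ligand–protein bonds of the active
site and the normalising sum runs over all scored bonds (optionally only
the weak ones, `normalizeOver = "weak"`). Residue propensity sums the
scored weak bonds incident to a residue, each bond counted once per
residue it touches.

Two exact properties are worth knowing:

* On a single edge the transfer is exactly 1; on a uniform triangle the
  source edge carries 2/3 and each other edge 1/3.
* A dangling tree branch carries **zero** flux: propensity only
  propagates around cycles. This has a design consequence for the test
  fixture (section 5).

```{r triangle}
tri <- makeToyGraph("triangle")
abs(as.numeric(transferColumns(tri, 1L)))
```

### Numerics

`L` is singular (constant vectors span its null space, one per connected
component). `bondprop` never forms a pseudo-inverse. For each source
bond `b′` it solves `L z = Bᵀ e_{b'}` on the component containing the
source, using a sparse Cholesky factorisation of the grounded system
with mean-centring and a step of iterative refinement to a residual of
1e−10, then reads off the column as `G B z`. The cost is one
factorisation plus one triangular solve per source bond, so scoring a
protein is linear in the number of active-site bonds. Disconnected
components are handled per component; sources in a different component
than a bond contribute zero, with a warning.

Correctness is enforced in the test suite by comparison with a dense
Moore–Penrose oracle (`MASS::ginv`) on random connected graphs at 1e−8
relative tolerance, alongside the closed-form cases above.

## 3. Distance-conditioned quantile scores

Raw propensities decay with distance from the source, so a raw value is
meaningless without its distance context. `bondprop` fits, for every
level `p` on a grid, the linear conditional quantile of `log Π` given
the bond-to-site distance `d` (minimum midpoint-to-source-midpoint
distance). The score of a bond is the grid level at which its observed
`log Π` crosses the fitted quantile curve at its own `d` — an in-sample
probability-integral transform. Scores below the lowest fitted quantile
clamp to 0, above the highest to 1, and zero propensities score 0 (they
are excluded from the fit, with a warning).

Choices, and why:

* **Grid** `defaultQuantileGrid()`: 0.01–0.99 in steps of 0.01, then
  0.991–0.999 in steps of 0.001. The fine tail matters because the
  headline statistic is `P(p_b > 0.95)`; a coarse grid there would
  quantise scores near the threshold.
* **Quantile regression is authored in-package** (`quantileRegress`).
  The solver is a Hunter–Lange smoothed majorise–minimise iteration on
  the tilted absolute loss, followed by an exact vertex polish that
  enumerates interpolating subsets among the smallest-residual
  candidates. The polish makes the solution an exact linear-programming
  vertex: tests verify equality with brute-force enumeration of all
  interpolating subsets (n ≤ 30) and the subgradient bracket
  `#(r < 0) ≤ pn ≤ #(r ≤ 0)` at larger n.
* **Monotone rearrangement**: independently fitted quantile lines can
  cross; at any given `d` the fitted values are sorted before inversion,
  which restores monotonicity without refitting and leaves the scores
  well defined.
* **Inversion** uses linear interpolation with tie-averaging, so a bond
  lying exactly on a fitted line receives the midpoint of the levels it
  touches (0.5 on noiseless data).

A residue-level model of `log Π_R` on the residue's minimum distance is
fitted with the same machinery.

## 4. The reference model

The intrinsic score answers "is this bond notable *within this
protein*?". To compare across proteins, a reference model adds `log E`
(E = the protein's weak-bond count) as a covariate:

\[
Q_{\log\Pi}(p \mid d, E) = \alpha_0(p) + \alpha_1(p)\,d + \alpha_2(p)\log E .
\]

Because propensities are normalised, doubling the number of weak bonds
roughly halves each one, so `α₂ ≈ −1`; the test suite verifies this
recovery on the declared generator, with a protein-level bootstrap CI.
Reference models can be persisted (`writeReferenceModel`) and reloaded
(`readReferenceModel`) as versioned JSON, so a reference fitted on a
corpus can score new structures without refitting.

## 5. Synthetic generators: what and why

The package must be fully testable offline, so it generates its own
inputs. The generators are fixed by design (parameters chosen at design
time from the physics, not adjusted to test outcomes).

**`makeToyGraph`** produces the minimal topologies with known closed
forms (single edge, triangle, path, cycle) plus seeded random connected
graphs (spanning tree + extra edges) used against the dense oracle.

**`makeToyProteinPDB`** builds a three-armed synthetic protein: three
15-residue arms at 120° in a plane, with template-correct backbone
geometry, backbone hydrogen-bond donors/acceptors aligned for ideal
DREIDING geometry, and an active-site ligand at the hub covalently
recorded (`LINK`) to all three arms. Arm A is all serine; its side-chain
oxygens carry a chain of strong electrostatic `LINK` records running to
the arm tip, where a marker ligand closes a circuit back to the hub.
**The circuit closure is essential, not decorative**: flux through a
bond requires the bond to lie on a cycle between source and sink
regions, so a "strong pathway" that dead-ends would carry exactly zero
propensity. The four residues at the end of arm A (selected by distance
to the marker ligand) are the planted allosteric site; the geometrically
equivalent residues on arm B, which lie off the circuit, are a decoy
that the detector should reject. Waters and an optional multi-model
jitter (for NMR-ensemble code paths) complete the fixture.

**`simulateReferenceTriplets` / `simulateBondSample`** draw bonds from
`Π = exp(−0.3 d + ε)/E`, `ε ~ N(0, 1)`, `d ~ U(5, 40)`, `E` per protein
in 500–5000. This is exactly the model family the quantile fits assume,
which is the point: it isolates the estimator from model
mis-specification, so a non-uniform in-sample score distribution is
evidence of an implementation bug (this caught a real one during
development: a mis-specified linear term in the majorise–minimise normal
equations).

## 6. Site detection

A candidate site (a set of residue keys) is summarised by four measures:

1. mean bond score `⟨p_b⟩`,
2. mean residue score `⟨p_R⟩`,
3. the high-scoring fraction `P(p_b > 0.95)`,
4. mean reference score `⟨p_ref⟩`.

Ligand residues are excluded via `excludeResidues` so the measures
describe the protein pocket, not the ligand itself. Measures 1–2 are
compared with surrogate sites: connected residue clusters grown from a
random seed residue by nearest-centroid accretion, constrained to the
target's residue count and to a diameter no larger than the target's,
with waters and excluded residues never included. The surrogate means
are bootstrapped (10 000 resamples, percentile interval by default) and
the site is detected on a measure when it exceeds the upper CI bound.
Measures 3–4 have fixed thresholds: 0.05 (the expected high fraction
under uniform scores) and 0.5 (the reference median). Requiring three of
four measures is a reasonable overall call; the package reports each
measure with its margin and leaves the aggregation to the user.

Surrogate growth can fail when the target is unusually compact; the
generator retries up to `100 n` times and then stops with an error
rather than silently relaxing the constraints.

## 7. Ensembles and conformers

For multi-model (NMR) structures, `propensityEnsemble()` computes a
propensity per conformer; `ensembleStats()` reports per-residue mean and
population standard deviation across conformers, `topVariableResidues()`
ranks the most variable ones, and `conformerInfluence()` regresses one
conformer's residue propensities on another's and reports Cook's
distance per residue — residues whose communication role changes most
between conformations. `ranksumCompare()` provides a tie-corrected
rank-sum test for comparing a site's scores against the rest of the
protein.

## 8. Limitations

* The graph is built from a single static structure (or a set of static
  models); dynamics enter only through the interaction energies.
* Hydrogen placement matters: hydrogen-bond detection requires explicit
  hydrogens. Without them, `buildAtomisticGraph(..., implicitHbonds =
  TRUE)` falls back to a distance/element heuristic that is noticeably
  cruder.
* Energy functions are simple closed forms (DREIDING hydrogen bonds,
  screened Coulomb, tabulated hydrophobic PMF); they are standard but
  not force-field-accurate.
* The quantile models are linear in distance. For very large or very
  heterogeneous proteins the linearity assumption in `d` is the weakest
  link; the monotone rearrangement protects the scores' ordering but not
  the fit itself.
* Intrinsic scores are in-sample quantities; they describe a bond's
  standing within its own protein and should not be compared across
  proteins — that is what the reference model is for.
* The surrogate null controls for site size and compactness but not for
  secondary-structure composition or burial depth.
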
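---
title: "Methods: geometric residue encoding, diffusion schedules and quality-diversity triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric residue encoding, diffusion schedules and quality-diversity triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binderkit)
```

This vignette is the package's own account of the methods it implements:
the model assumptions, the tunable parameters and why their defaults are
what they are, the numerical choices, and — importantly — what the
synthetic fixtures do and do not demonstrate about real proteins.

## The all-atom structure model

Structures are stored as a flat atom table (chain, residue index and name,
atom name, element, coordinates in Å) with a chain table carrying the
polymer class and a covalent-bond list, mirroring the flat-table style of
established structural packages. Proteins and nucleic acids tokenize one
token per residue, small molecules one token per atom; tokens partition the
atom set. The PDB reader is deliberately narrow: fixed-width
ATOM/HETATM/TER/CONECT records, single-character chain ids, heavy atoms
only (hydrogens are dropped on read because every metric in the package is
defined on heavy-atom geometry), and highest-occupancy alternate locations.
mmCIF, assemblies and insertion codes are out of scope — the package's
inputs are design-pipeline artifacts, which are small and regular.

## Geometric residue encoding

A designed residue is a block of exactly 14 atom slots whose first four are
the backbone N, Cα, C, O. Identity is carried by geometry alone: a residue
type with $k$ side-chain heavy atoms has $10-k$ *virtual* atoms placed
exactly on designated backbone anchors, and decoding counts the
non-backbone slots within a threshold (default **0.5 Å**) of each anchor
and looks the composition up in a table. Two compositions are fixed by the
encoding convention — proline: 7 atoms on O; threonine: 3 on N and 4 on O —
and the remaining 18 are not published anywhere we can consult. The package
therefore completes the table with a deterministic rule: within each group
of types sharing a virtual-atom count, types are processed alphabetically
and receive the first unused composition when candidates are enumerated
anchor-priority-first (N, then O, then CA, then C). The rule is arbitrary
but injective, reproducible, and consistent with the two fixed entries;
`code_table(file)` accepts a YAML override so the table can be matched
bit-for-bit to any external convention. Injectivity is machine-checked at
construction.

Numerical choices: virtual atoms are encoded at distance exactly 0 from
their anchor (not merely within the threshold); an atom within the
threshold of two anchors is assigned to the nearer one, which can only
happen if two backbone anchors are themselves closer than 1 Å — real
backbones never are; side-chain slots encoded from sequence alone receive
an ideal-geometry stub extended from Cα, spaced so that no stub atom can
fall inside any anchor's threshold. `codec_robustness_profile()` measures
the decode margin empirically: accuracy is 1.0 at zero noise, still above
0.98 at 0.1 Å isotropic coordinate noise, and collapses beyond ~0.2 Å,
which is the expected behaviour of a 0.5 Å count-based margin when the
anchor and the virtual atom are perturbed independently.

## Diffusion engine

The forward process is variance-exploding, $X_t = X_0 + t\,\varepsilon$.
All constants live in `diffusion_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `sigma_data` | 16 | Å | coordinate scale of the data |
| `s_min`, `s_max` | 4e-4, 160 | — | relative noise bounds of the schedule |
| `rho` | 7 | — | schedule exponent |
| `n_steps` | 300 | — | denoiser evaluations per sample |
| `noise_mu`, `noise_sd` | −1.2, 1.5 | log-space | training noise distribution |

Training noise levels are log-normal,
$t = \sigma_\mathrm{data}\exp(-1.2 + 1.5\,g)$, $g \sim \mathcal N(0,1)$.
The denoiser contract is EDM-preconditioned, and the loss is
$w(t)\,(\mathcal L_\mathrm{MSE} + \mathcal L_\mathrm{bond} +
\mathcal L_\mathrm{smooth\text{-}lDDT})$ with
$w(t) = (t^2+\sigma_d^2)/(t\,\sigma_d)^2$. The MSE is computed after a
rigid alignment of the target onto the prediction, weighted per atom class
(protein 1, DNA/RNA 6, ligand 11); the alignment itself uses the same
weights. The smooth-lDDT surrogate scores pairwise-distance errors with
sigmoids at thresholds 0.5/1/2/4 Å over pairs within a 15 Å inclusion
radius (30 Å is the conventional choice for nucleic acids; both the radius
and the sigmoid temperature are arguments). Its exact constants follow the
published differentiable-lDDT formulation; they are config-exposed rather
than load-bearing, since only monotonicity and rigid invariance are relied
upon downstream.

### The dilated schedule

The sampling schedule is
$t_i = \sigma_\mathrm{data}(s_\mathrm{max}^{1/\rho} + \tau_i\,
(s_\mathrm{min}^{1/\rho}-s_\mathrm{max}^{1/\rho}))^\rho$ on a uniform
$\tau$ grid. Residue identities resolve in a short window of schedule time,
approximately $\tau \in [0.6, 0.8]$, so the dilated variant passes $\tau$
through a continuous piecewise-linear bijection $\phi$ of $[0,1]$ whose
middle branch has slope $1/\lambda$: uniform steps then land $\lambda$
times denser inside $[\tau_s,\tau_e]$. As printed, the three branch
formulas of such a map cannot all hold together with the stated constants
$r=(1-\lambda(\tau_e-\tau_s))/(1-(\tau_e-\tau_s))$, $l=r\tau_s$,
$u=l+\lambda(\tau_e-\tau_s)$ — continuity at the branch points plus
$\phi(0)=0$, $\phi(1)=1$ force the unique map implemented here:
$\phi(\tau)=\tau/r$ below $l$, $(\tau-l)/\lambda+\tau_s$ on $[l,u]$, and
$(\tau-u)/r+\tau_e$ above. With the defaults $\lambda=8/3$, $\tau_s=0.6$,
$\tau_e=0.8$: $r=7/12$, $l=0.35$, $u\approx0.883$, and 160 of 300 uniform
steps map into the window — a density boost of exactly $8/3$.

### The stochastic sampler

The sampler body is not printed in any source we can consult, so the
package implements the standard stochastic sampler this family of models
cites: per step, inject noise scaled by $\beta$ to climb from $t_i$ to an
elevated level (churn factor $\gamma$, applied at every step), evaluate the
denoiser **at the actual post-injection level**
$\sqrt{t_i^2+\beta^2((1+\gamma)^2-1)t_i^2}$, and take an Euler step toward
the prediction scaled by $\alpha$, with a second-order Heun correction by
default. $\alpha=\beta=1$ is the standard sampler; raising $\alpha$ or
lowering $\beta$ trades diversity for designability. Design choices made
here, documented as this package's own: $\alpha$ multiplies the Euler step
(not the predicted displacement); $\gamma$ defaults to 0.4; noise draws are
consumed in a fixed order (initialisation, then one injection per step) so
a seed fixes the trajectory bit-for-bit.

These choices are validated against an exact oracle: for Gaussian data the
posterior mean is closed-form (`gaussian_denoiser()`), and with
$\alpha=\beta=1$ the sampled distribution must reproduce the data mean and
variance. With the Heun corrector and the exact-level bookkeeping the
residual discretisation bias in the variance is below ~1% at $N=300$; the
test suite checks agreement within 3 Monte-Carlo standard errors at
$10^4$ samples. A plain Euler step at high churn ($\gamma=0.8$) would bias
the variance downward by ~25%, which is why the corrector is on by default.

## Design-specification language

The YAML dialect is documented in `?parse_spec` and is this package's
canonical grammar (the upstream dialect is only partially visible, so a
converter rather than parity is the goal). Validation enforces the rules
that matter semantically: a covalent bond touching a designed residue must
state that residue's identity; structure groups — atom sets whose internal
pairwise distances are supplied to the model — must be disjoint; a residue
cannot be both binding and not-binding. Conditioning featurization emits a
pairwise distance matrix masked across groups, a symmetric bond matrix with
an empty diagonal, and per-token flags; all shapes are functions of
atom/token counts only, and features round-trip through JSON.

One YAML 1.1 wrinkle is handled explicitly: bare `N` and `Y` (common atom
and anchor names) would parse as booleans, so the spec parser keeps those
two strings verbatim while still accepting ordinary booleans.

The training-task sampler draws folding / binder-design /
motif-scaffolding / unconditional tasks with configured probabilities
(defaults 0.4/0.3/0.2/0.1 — the published split is in an unavailable
supplement, so these are package defaults, config-exposed), restricted to
structures that support them (no binder design on a single protein
monomer). Conditioning channels drop out independently with probability
0.5. Binding labels derive from proximity: the published rule says only
"based on proximity", so the package fixes a target residue as binding
when within 8 Å of designed atoms and eligible for not-binding beyond
12 Å — conventional contact/non-contact radii. Crops are interface-biased
spatial crops keeping contiguous runs of at least 4 residues, with budgets
of 768 tokens (folding) and 512 (generative tasks).

## Interface analysis

All criteria are heavy-atom and geometric, with every threshold an
argument:

* **Hydrogen bonds** — N/O donor with an available proton to N/O acceptor,
  distance ≤ 3.5 Å and antecedent–donor–acceptor angle ≥ 120°; a pair
  counts once even if it qualifies in both directions. This is the standard
  hydrogen-free geometric definition.
* **Salt bridges** — carboxylate oxygens vs Lys/Arg nitrogens (His only if
  flagged protonated) within 4.0 Å, counted per residue pair.
* **SASA / buried surface area** — Shrake–Rupley with a 1.4 Å probe and a
  deterministic Fibonacci sphere lattice (default 960 points/atom; the
  pipeline uses 240 for speed, which agrees with 10× refinement within a
  few percent on the fixtures); BSA = SASA(design)+SASA(target)−SASA(complex).
* **Largest hydrophobic patch** — exposed (≥ 5 Å² per atom) nonpolar (C/S)
  atoms of hydrophobic residues {ALA, VAL, LEU, ILE, MET, PHE, TRP, PRO},
  connected within 6 Å, largest component's summed exposed area.
* **Solubility** — a deliberately simple, deterministic stand-in for an
  external predictor: `0.5·(1 − normalised GRAVY) + 0.5·|net charge|/length`,
  length-normalised, higher = more soluble. It orders poly-Lys above
  poly-Ile, which is all the ranking stage requires of it; a config hook
  replaces it with any external score column.
* **Refold RMSD** — CA RMSD after rigid superposition, over the complex or
  the binder alone.

## Ranking, selection, diversity

Quality is the worst weighted rank across metrics (ties → average rank),
which is invariant under monotone transforms of any metric column — the
reason ranks, not values, are aggregated. The published rank weights were
calibrated on a proprietary benchmark; the package defaults to unit weights
loadable from a YAML sidecar. Whether weights apply before or after the
max is not stated in the text; weighted-before-max is adopted, which lets a
weight act as a per-metric importance knob.

Greedy quality–diversity selection maximises
$-\tilde q(x) + \gamma\,\mathrm{Diversity}(x, S)$ with $\tilde q$ min–max
normalised, $\gamma$ defaulting to 0.5, ties broken on the smaller design
id, and $w_\mathrm{struct}=w_\mathrm{seq}=0.5$ (the published combination
rule and weights are not printed; the additive form is the simplest
objective whose $\gamma=0$ limit is exactly top-$k$ by quality, which the
tests pin down). The empty-set diversity is 1 by convention.

TM-score uses $d_0 = 1.24(L-15)^{1/3} - 1.8$ floored at 0.5, normalised by
the reference length, and maximises over superpositions by fragment-seeded
iterative refinement on the residue correspondence — sequential for
equal-length chains, otherwise taken from the global sequence alignment.
This is a documented simplification relative to full TM-align's
alignment search; for the ranking use case the correspondence is always
known (same design refolded), where the two coincide. Sequence similarity
is global-alignment identity count over the longer length (match 1,
mismatch 0, no gap penalty — i.e. the longest common subsequence),
computed with Biostrings. The refold filter is strictly `<` 2.5 Å. The
Vendi score is the exponential of the von Neumann entropy of the
trace-normalised kernel spectrum, clamping tiny negative eigenvalues.

## What the synthetic fixtures show — and what they do not

`make_ideal_helix()` builds mathematically ideal α-helices
(φ = −57°, ψ = −47°, Engh–Huber-style covalent geometry; measured rise
1.55 Å/residue, Cα–Cα 3.80 Å). `make_toy_complex()` poses two helices and
*plants* exactly the requested interface interactions by inserting bridging
side-chain atoms — a Lys NZ donor meeting a neutral Gln OE1 acceptor at
2.9 Å for each hydrogen bond, and a Lys NZ / Asp OD1 pair at 3.8 Å
(outside the hydrogen-bond cutoff, inside the salt-bridge cutoff) for each
bridge — and verifies the planted counts against the analysis module at
build time, so fixture and metric definitions cannot drift apart. A
seed-driven rigid motion is applied, which incidentally exercises
rigid-motion invariance.

These fixtures establish *correctness of the definitions*: that the
counting, area and selection machinery computes what it claims on
structures with known ground truth. They do not establish that the metric
thresholds are well calibrated for real interfaces (side-chain geometry in
the fixtures is schematic, there are no rotamers, no waters, no packing),
nor anything about the behaviour of a trained denoiser — the sampler
guarantees are proved only for the analytic Gaussian case.

Problem sizes used by the test suite, chosen to make Monte-Carlo
tolerances meaningful: $10^4$ samples for sampler moments (3-standard-error
bands), $10^5$ draws for the training-noise distribution, 2000 draws for
task-sampler marginals (4σ binomial bands), helices of 10–30 residues for
structural tests and 900 for cropping.

## Known limitations

* The 18 unpublished anchor compositions are package-chosen; exact parity
  with any released system requires the YAML override.
* The sampler's α/β placement and per-step churn scheduling are
  reconstructed from the cited sampler family, not from a printed
  algorithm; both are documented and config-exposed.
* TM-score correspondence comes from sequence alignment, not structural
  alignment search, and can under-estimate similarity between remote folds
  with shuffled sequences.
* The solubility proxy is a ranking stand-in, not a validated predictor.
* Interface metrics ignore hydrogens, waters and electrostatics beyond the
  charged-group rules above.
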
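---
title: "Interatomic-interaction and compositional features from protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interatomic-interaction and compositional features from protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protfeat)
```

## What the package computes

`protfeat` turns a protein 3D structure (a PDB chain, optionally paired
with a TRIPOS MOL2 file carrying covalent bonds) into a fixed-length
numeric feature vector with three blocks:

* **11 interaction / physicochemical features** computed from the
  heavy-atom geometry: hydrophobic contact count, van der Waals contact
  count, rotatable-bond count ("deformation effect"), summed
  hydrogen-bond score, repulsive (clash) count, London-dispersion
  count, contact-weighted total and internal hydrophobicity, total
  surface tension, internal tension, and total accessible surface
  area.
* **8 side-chain chemical-class frequencies** (CPAASC): aliphatic
  apolar, aromatic, polar uncharged, positive, negative,
  sulfur-containing, hydroxyl-containing, and special (Gly/Pro).
* **Overlapping k-mer composition** for k = 1, 2, 3 over a 26-symbol
  alphabet (the 20 standard residues, U for selenocysteine, O for
  pyrrolysine, J for N-methylvaline and the Leu/Ile ambiguity, plus
  B, Z, X), i.e. 26 + 676 + 17,576 columns.

The full table therefore has 18,297 feature columns per chain.
A note on the dipeptide block: 26 symbols give 26² = 676 dipeptides;
we deliberately emit the complete 676-column block rather than any
truncation of it, so the block is self-consistent with the alphabet.

Each chain is an independent analysis unit: multi-chain files are
split, and k-mers never span chains.

## The geometric model

**Radii and distance bands.** Every heavy atom receives a Bondi-style
van der Waals radius (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80, H 1.20
Å). For a pair at distance $d$ with radius sum $r_{ij}$, three
contiguous bands partition the non-bonded range:

* repulsive: $d < r_{ij}$ (electron-cloud overlap),
* van der Waals contact: $r_{ij} \le d \le r_{ij} + 0.7$ Å,
* London dispersion: $r_{ij} + 0.7 < d \le r_{ij} + 3.0$ Å.

The 0.7 Å offset is the published boundary between close contact and
the dispersion shell; the inner and outer edges are qualitative in the
literature and live in `default_config()$bands` so they can be moved.
The bands are disjoint by construction, so the vdW and dispersion
counts never double-count a pair.

**Which pairs count as non-bonded.** Pairs are annotated with the
shortest covalent path between their atoms (exact up to four bonds).
Non-bonded features count pairs **five or more bonds apart**. This is
stricter than "not covalently bound": 1-3 and 1-4 separations are
fixed by bond angles and torsions, and 1-4/1-5 backbone pairs
(N$_i$–N$_{i+1}$, C$_i$–C$_{i+1}$, O$_i$–CA$_{i+1}$) sit inside the
van der Waals envelope in *every* well-formed backbone. Counting them
would make the "repulsive" feature a proxy for chain length rather
than packing strain — an ideal α-helix would report dozens of
clashes. With the 1-5 horizon (the same convention force fields use
for their non-bonded exclusion lists) an ideal helix reports exactly
zero repulsive contacts, which is the physically meaningful answer.

**Hydrogen bonds without hydrogens.** Crystal structures usually lack
hydrogen positions, so the scoring is heavy-atom only. For a donor D
(template-assigned N/O/S bearing a polar hydrogen) the *geometric
center* of D and its covalent heavy neighbours points away from the
implicit hydrogen; the donor angle $\alpha$ between (D → center) and
(D → acceptor) is therefore 180° for a perfectly linear bond. A
candidate with $d_{DA} \le 3.5$ Å and $\alpha \ge 100°$ scores

$$ s = \underbrace{\mathrm{clamp}\!\left(\frac{3.5 - d_{DA}}{3.5 - 2.6},
   0, 1\right)}_{w_d} \cdot
   \underbrace{\frac{\alpha - 100}{80}}_{w_\alpha}, $$

so an ideal bond (2.6 Å, 180°) scores 1 and bonds at either threshold
score 0. The per-protein feature is the sum of scores. The distance
and angle thresholds are geometric criteria standard in the field; the
original scoring coefficients this adapts are not published, so the
ramp is linear and fully parameterised (`config$hbond`). Whether the
angle is taken at the donor, a pseudo-hydrogen, or the acceptor is a
genuinely open choice; the donor-center convention was picked because
it needs no hydrogen placement at all, and the ideal-helix fixture
confirms it recovers the full i → i+4 ladder. Because centers use
heavy neighbours only, adding or stripping explicit hydrogens does not
change any result (tested).

**Accessible surface area.** Shrake–Rupley integration with a probe of
1.4 Å and a deterministic golden-spiral lattice of 256 points per
atom. The lattice makes results bit-reproducible without a seed; the
price is that a rigid *rotation* changes the sampling alignment by up
to the lattice resolution (≲ 1 %), so rotation invariance holds at
that tolerance rather than machine precision, while translations are
exact. Accuracy: an isolated carbon matches the closed form
$4\pi(1.7+1.4)^2$ to machine precision, a two-sphere case agrees with
a 10⁶-point Monte-Carlo reference within 2 %, and doubling the lattice
changes totals by < 1 %. Per-residue relative ASA divides by the
residue's maximum exposure in an extended Gly-X-Gly reference;
residues with relative ASA < 0.20 are "buried".

**Hydrophobicity and tension.** A hydrophobic contact is a pair of
apolar side-chain heavy atoms (carbon not bonded to N/O, or sulfur)
from distinct residues within 4.5 Å. The weighted variants add the
mean Kyte–Doolittle hydropathy of the two residues per contact;
"internal" restricts to contacts whose residues are both buried.
Total surface tension is the atomic-solvation sum
$\sum_a \sigma(\mathrm{class}_a)\,\mathrm{ASA}_a$ with
Eisenberg–McLachlan-style parameters (apolar C +16, neutral N/O −6,
charged O −24, charged N −50 cal mol⁻¹ Å⁻²); internal tension sums
|KD| over buried residues. The deformation effect is the
rotatable-bond count (acyclic, non-amide single bonds between
non-terminal heavy atoms). These four are declared *proxies*: the
source descriptions are narrative, not formulaic, so the exact
definitions live behind the config surface where alternatives can be
swapped in.

## Bond graphs

A MOL2 file, when supplied, is authoritative: bond orders (single,
double, triple, amide, aromatic) and sp² flags from SYBYL atom types
are taken as-is, and an atom-count mismatch with the PDB is a hard
error. Without MOL2, bonds are inferred geometrically (distance ≤
covalent-radius sum + 0.45 Å), inter-residue backbone C–N bonds are
typed amide — so the rotatable-bond count can exclude peptide bonds —
and sp² flags come from residue templates. The inferred graph types
everything else single; ring bonds are excluded from rotation via ring
templates (Pro, Phe, Tyr, His, Trp).

## The synthetic fixture generator

All tests run on structures built in code, so no downloads are
needed:

* `make_ideal_helix(n)` — poly-alanine with ideal helical dihedrals
  (φ = −57°, ψ = −47°, ω = 180°) built by internal-coordinate chain
  extension. Ground truth: the backbone amide of residue i+4 donates
  to the carbonyl of residue i, so n − 4 hydrogen bonds are expected,
  with known donor/acceptor atoms.
* `make_toy_core()` — a cubic lattice of residues at 5 Å spacing.
  Interior sites are surrounded on all six faces and are buried by
  construction (measured relative ASA ≈ 0.01–0.08 versus ≈ 0.7–0.9 at
  the corners); two interior sites carry leucines whose side-chain
  tips meet at hydrophobic-contact range.
* `make_atom_cloud(n, box, seed)` — seeded uniform atoms with a 2.7 Å
  minimum separation, so no accidental covalent bonds arise and every
  pair is genuinely non-bonded; this is the substrate for the
  brute-force contact-count oracles.
* `make_random_sequence(length, alphabet, seed)` — i.i.d. uniform
  draws for the composition oracles.

Fixtures are written as PDB text and re-read through the public
parser, so tests exercise the whole path. What they do *not* emulate:
real side-chain rotamers, chain breaks, crystallographic disorder
beyond simple altloc cases, or the size and diversity of a curated
structure corpus. Passing tests therefore certify the arithmetic and
the contracts, not classification performance on real proteins.

## Downstream analyses

**Mutual information.** Features are ranked against a discrete label
with a nearest-neighbour MI estimator (k = 3): per point, the distance
to its k-th same-class neighbour defines a radius, and the estimate is
$\psi(N) - \langle\psi(N_c)\rangle + \psi(k) - \langle\psi(m_i)\rangle$
with $m_i$ the number of points of any class inside the radius.
Estimates are clipped at zero; a tiny seeded jitter breaks distance
ties, which is the only stochastic element. Calibration: a feature
identical to a balanced binary label scores ln 2 within a few
tenths of a percent at n = 2000, and independent noise scores below
0.01 at n = 5000.

**Benchmark.** `run_benchmark()` shuffles with the given seed, holds
out 20 % (re-splitting until every class appears in training, then
failing loudly), optionally MI-selects the top k features *on the
training rows only*, fits any classifier honouring the fit/predict
contract (random forest and gradient-boosted trees ship as specs), and
reports accuracy, macro precision/recall/F1, and the multiclass
Matthews correlation. Macro averaging was chosen because the class
balance of curated protein-family sets is artificial; nothing in the
metrics depends on it being the "right" choice. The leakage guard is
tested with a probe feature that is predictive only on held-out rows
and must never be selected.

**Grouped-importance enrichment.** Given a proteins × features
importance matrix (e.g. SHAP values from any explainer) and a binary
feature grouping, per-protein sums inside and outside the group form
two samples compared by a two-sided two-sample Kolmogorov–Smirnov
test per class, with Benjamini–Hochberg adjustment across classes.
The package deliberately does not compute SHAP values itself — the
explainer is pluggable; the contribution is the group-sum + KS + BH
chain, which is checked against hand-computed CDF gaps and the hand
step-up.

## Numerical choices and edge cases

* Altlocs: highest occupancy wins, ties go to label 'A'. Insertion
  codes order residues by (resseq, icode).
* Waters and non-peptide HETATMs are dropped; modified residues with a
  standard backbone (MSE, SEC, PYL, MVA) are kept and mapped to
  one-letter codes.
* Sequences shorter than k give an all-zero k-mer block with a
  warning; unknown side-chain symbols fall into a configured fallback
  class.
* MI ties are broken by jitter (seeded); top-k ties by feature name.
* Degenerate geometry (isolated atoms, zero-length vectors) raises
  errors rather than returning NaN; the exported table never contains
  NaN.
* Extraction over a directory sorts files by name and is byte-identical
  across reruns with the same configuration.

Problem sizes in the shipped tests were picked to make each check
sharp but cheap: clouds up to 500 atoms for the O(n²) oracles, a 10⁶
point Monte-Carlo reference for ASA, n = 5000 for the MI null, ten
seeds for the chance-level benchmark.

## Known limitations

* The four proxy features (deformation, both tensions, the H-bond
  score ramp) are reasonable field-standard stand-ins, not
  reconstructions of unpublished formulas.
* Donor/acceptor templates are heavy-atom based and do not model
  protonation states or His tautomers.
* ASA uses a fixed-orientation lattice (see above) and ignores
  hydrogens.
* The per-chain unit means inter-chain contacts in complexes are
  invisible by design.
* No mmCIF input; no structure repair.
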
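---
title: "Fragment combination ranges for proteins: models, choices, and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment combination ranges for proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragcr)
```

## The model

`fragcr` approximates the total energy of a polypeptide as a signed sum over
*fragment combinations*,

$$E \;=\; \sum_{\mathbf{f} \in \mathrm{FCR}} p_\mathbf{f}\, E_\mathbf{f},$$

where the fragment combination range (FCR) is a family of atom sets, each
evaluated as one capped molecule, and the integer coefficients
$p_\mathbf{f}$ restore single counting of every covered interaction. The
package's job is combinatorial and geometric: it builds the atom sets, the
coefficients, the hydrogen caps, and the embedding charges; the per-fragment
energies come from a pluggable backend — two exactly solvable mocks for
development and testing, or input decks for an external quantum-chemistry
engine.

Three layers produce the FCR:

1. **Initial disjoint fragments (groups).** A scheme-specific bond-cutting
   rule partitions all atoms: MFHC severs the two bonds joining each
   interior peptide unit to its flanking $\alpha$-carbons (terminal
   amino/carboxy groups stay with their residue; proline's ring nitrogen
   stays with the peptide unit by cutting both ring N–C bonds; a disulfide
   bridge becomes a dedicated CH$_2$–S–S–CH$_2$ group). pp-GMBE cuts every
   C$_\alpha$–C$_\mathrm{carbonyl}$ bond, keeping peptide bonds intact. MIM
   cuts all C–C bonds at C$_\alpha$ (backbone and side chain). KEM cuts
   every peptide C–N bond.
2. **Initial overlapping combinations.** MFHC merges each
   $\alpha$-carbon-bearing group with every group covalently bound to that
   carbon. pp-GMBE forms all group pairs within 2.2 Å (closest atom–atom
   distance) plus all hydrogen-bonded pairs. MIM grows, from each seed
   group, the $\eta - 1$ nearest groups (distance to the *seed*), requires
   covalent contiguity (a 1.7 Å proxy threshold), includes distance ties
   with the farthest member, then absorbs any atom bonded to two or more
   atoms of the combination (iterated to a fixed point) and removes subset
   combinations. KEM's combinations are simply its residues.
3. **Coupling.** `NeiY_d` unions up to $Y$ combinations whose mutual
   proximity graph at cutoff $d$ is connected; `HierY` is the same with no
   distance bound; `[Super]` is the single whole-system term. The final
   family is de-duplicated and subset-pruned before coefficients are
   assigned.

### Coefficients

The coefficient algorithm is a generalized inclusion–exclusion on the
intersection closure of the final atom sets: processing closure sets in
decreasing cardinality and assigning
$a_S = 1 - \sum_{T \supsetneq S} a_T$ enforces the *counting identity* —
for every nonempty atom set $S$ contained in at least one combination,
$\sum_{T \supseteq S} a_T = 1$. That identity is the defining contract: it
makes the expansion exact for any energy function that decomposes over
covered atom subsets, and it makes per-atom quantities (such as assembled
charges) coefficient-weighted averages with unit weight. The recurrence
yields integers by construction; intersections are taken at the atom level
so MIM's closure-adjusted combinations, whose atom sets can cross group
boundaries, need no special casing. Intersection sets that acquire a nonzero
coefficient enter the expansion as additional terms with content-addressed
labels, so identical intersections share a ledger entry across expansions
and distinct ones never collide.

### Capping

Every severed bond is saturated by a hydrogen on the ray from the kept atom
toward the lost atom, at a fixed length per kept element: C 1.112 Å,
N 1.060 Å, O 1.030 Å (Universal-Force-Field-derived values; an S entry at
1.341 Å is provided for completeness since no default scheme cuts at
sulfur). Combinations whose caps would clash — a cap within 0.9 Å of
another cap or of a real atom other than its anchor — absorb the group of
the offending lost atom, iterated to a fixed point. The 0.9 Å default is a
declared stand-in, roughly the H–H covalent contact; it is configurable,
and MIM's closure rule makes such merges unnecessary for MIM by
construction.

### Multilevel composites

`IF-[CS1][CS2]` with two brackets evaluates the first coupling at the high
level and corrects with a cheaper low level, in the substitution (ONIOM-like)
reading implemented here:

$$E^\mathrm{ML} = E^\mathrm{LL}(\mathrm{FCR}_2) +
  \sum_{\mathbf{f} \in \mathrm{FCR}_1} p_\mathbf{f}
  \left(E^\mathrm{HL}_\mathbf{f} - E^\mathrm{LL}_\mathbf{f}\right),$$

i.e. the low-level correction terms are the high-level combinations with
negated coefficients. Two consequences are tested rather than assumed: when
both backends coincide the composite collapses exactly to the low-level
value, and with strictly additive backends the `[Super]` composite equals
the high-level supersystem energy exactly.

### Electrostatic embedding

With `ee`, each fragment is evaluated in the field of point charges on all
atoms outside it, and the total is

$$E \approx \sum p_\mathbf{f} E^\mathrm{ee}_\mathbf{f}
  - \left(\sum p_\mathbf{f} - 1\right) E_\mathrm{Coul},$$

with $E_\mathrm{Coul}$ the mutual Coulomb energy of all charges (conversion
constant 1389.35457644 kJ mol⁻¹ Å e⁻²). The backend contract deliberately
includes, in each embedded energy, the fragment–environment interaction
*and* the environment's own Coulomb self-energy; under that convention the
single $E_\mathrm{Coul}$ subtraction is exact in the classical limit, which
the flagship test exploits (below). Decks for engines that exclude the
self-energy are compensated in the results reader via a documented flag.

Embedding charges are derived from a small, cheap FCR per scheme
(`MFHC-[1]`, `PAIR_2.2_HB-[1]`, `MIM-[η = 3]`, `KEM-[1]`): a gas-phase pass
yields charges, cap charges are folded onto the atoms the caps replace
(preserving each fragment's total charge exactly), per-atom charges are
assembled with the expansion coefficients, and the procedure is repeated
with each term now embedded in the previous iterate — two embedded
iterations by default. We read "two iterations" as two embedded
re-evaluations after the initial gas-phase pass; the count is configurable.
Whether gas-phase or first-iteration charges seed the loop is ambiguous in
the source methods; this reading is the package's documented choice.

## Mock backends and what the tests prove

Real applications obtain $E_\mathbf{f}$ (and Mulliken-type charges) from an
engine such as ORCA through `write_qc_inputs()` / `read_qc_results()`. The
mocks exist to make every combinatorial claim falsifiable:

* `backend_additive()` — one-body element energies plus a short-range pair
  function; caps count as hydrogens (optionally excluded from pair terms to
  isolate pure coverage error). Any valid expansion must reproduce the
  supersystem value whenever all interacting pairs are covered.
* `backend_classical()` — one-body terms plus point-charge Coulomb over a
  *globally consistent* charge model: per-element table values plus a single
  structure-wide offset that pins the sum to the formal charge. Caps carry
  no charge and no one-body term in this backend. Global consistency is the
  point: it makes the iterative charge derivation a fixed point, keeps every
  iterate summing to the formal charge, and renders the embedded assembly
  *exactly* equal to the supersystem energy for every scheme and coupling —
  the package's flagship identity, asserted to 10⁻⁶ kJ/mol across
  scheme × coupling × ten fixture peptides.
* `backend_linear_response()` — classical charges plus a linear response to
  the embedding potential, re-shifted to conserve each fragment's charge;
  it exercises the two-step iteration against an independently coded
  fixed-point map.

Passing these tests certifies the fragmentation, coefficient, capping, and
embedding machinery. It does **not** certify chemical accuracy on real
proteins: the mocks have no exchange, polarization beyond linear response,
or charge transfer, and real engine energies introduce basis-set and
population-analysis artifacts the classical limit cannot see.

## The synthetic fixture generator

`build_polypeptide()` produces deterministic ideal-geometry chains over five
residue types: glycine, alanine, a lysine-like long side chain (15 atoms —
deliberately above the pp-GMBE 10-atom side-chain threshold and exactly at
its 15-atom group bound), proline (backbone nitrogen in a five-ring, built
as a near-regular pentagon), and cysteine with optional disulfide bridges.
Backbone torsions: extended (−140°, 135°), α-helix (−57°, −47°), coil =
extended plus seeded jitter of up to ±25°. Proline takes polyproline-II-like
torsions (−75°, 145°) in every conformation — in ideal geometry, as in real
proteins, proline is incompatible with a regular helix. Side chains are
placed in two passes (backbone first), selecting among staggered rotamers
and ring azimuths the candidate with the largest element-aware clearance
above the bond-perception threshold; disulfide sulfurs are placed
symmetrically off the C$_\beta$–C$_\beta$ axis at S–S 2.05 Å with the same
clearance scan, and the paired thiol hydrogens are removed. The generator
emulates connectivity, sterics at the bond-perception level, and size
statistics of real peptides; it does not emulate thermal disorder, real
rotamer energetics, solvent, or charged termini (chains are built neutral,
NH₂/COOH). Conclusions from fixtures therefore cover the combinatorics and
geometry of fragmentation, not conformational energetics of real proteins.

## Numerical and design choices

* **Bond perception**: distance ≤ 1.2 × (r_cov(i) + r_cov(j)), Cordero
  radii; atoms closer than 0.4 Å are an error. CONECT records can override.
* **Backbone recognition is graph-pattern based** (N–C$_\alpha$–C(=O)
  motifs), so XYZ input without atom names fragments identically to PDB.
* **Hydrogen bonds**: 1.7 Å < d(H···X) < 2.2 Å and donor–H–acceptor
  angle > 130°, donors/acceptors N and O by default (S optional). The
  alternative van-der-Waals-based rule found in the pp-GMBE literature is
  not implemented; the explicit window is the one the method's
  implementation states.
* **All atom counts include hydrogens**; caps are never counted in size
  limits. Hydrogens also participate in every closest atom–atom distance.
  Both are flagged sensitivity choices: the source methods do not say
  whether hydrogens count, and the bounds tested here hold under the
  stricter (all-atom) reading.
* **pp-GMBE subdivision**: side chains above 10 atoms split at
  C$_\alpha$–C$_\beta$; any group still above 15 atoms (e.g. a proline
  C-terminal group) is bisected at the bridge bond giving the most balanced
  split, recursively; only a ring system with no acyclic bond may remain
  oversize, with a warning. A "side chain" is the connected component of
  C$_\beta$ after deleting C$_\alpha$; if that component touches backbone
  atoms (proline's ring, a disulfide partner), the residue is not
  side-chain-split.
* **MIM growth distance** is measured group-to-seed, while the covalent
  constraint is checked against the growing cluster; the equal-distance tie
  rule is applied unconditionally. Distance ties use a 10⁻⁹ Å tolerance.
* **`NeiY_d` connectivity** is connected-cluster (the proximity graph of
  the members must be connected), the weaker and more inclusive reading,
  which reduces to the unambiguous pairwise rule at Y = 2; `HierY` is its
  infinite-cutoff limit. Hierarchical coupling refuses to exceed a term
  budget (default 50 000) rather than explode combinatorially.
* **Determinism**: groups are ordered by smallest atom index, term
  evaluation and assembly iterate in sorted label order, and all fixture
  randomness is seed-derived, so reports are byte-reproducible.
* **Charges**: each group carries the sum of its atoms' integer formal
  charges; caps are neutral. Coefficients guarantee the assembled total
  equals the structure's formal charge.
* **Problem sizes in the shipped tests**: fixtures of 8–20 residues
  (≈100–260 atoms) for the classical-limit identity, 200 random fixtures
  for the size-bound survey, exhaustive antichain families over five
  groups plus 500 random families over eight for the counting identity.
  These sizes make the identities sharp (they hold to stated tolerances,
  not asymptotically) while keeping the default suite fast.

## Known limitations

* No electronic structure: energies beyond the mocks require an external
  engine; basis sets, dispersion, counterpoise and population analysis are
  engine-side.
* Non-protein components (ligands, cofactors, waters) are not given
  scheme-specific rules; they would each become their own group.
* The cap-clash merge criterion is a declared stand-in for the unpublished
  merge rule of the MFHC lineage; it is configurable and off the hot path
  for MIM.
* Electrostatic embedding combined with multilevel brackets is not
  supported (the benchmark design keeps them separate).
* The fixture generator refuses geometrically unclosable disulfides
  (C$_\beta$ separation outside 3–6 Å) instead of distorting the backbone.
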
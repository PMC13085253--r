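# fragcr

Energy-based molecular fragmentation of proteins with fragment combination
ranges.

## The problem

Electronic-structure calculations scale steeply with system size, so whole
proteins are out of reach for accurate quantum-chemical methods.
Energy-based fragmentation attacks this by partitioning a protein into small
fragments, evaluating each capped fragment independently (embarrassingly
parallel), and recombining the pieces. `fragcr` implements four published
fragmentation schemes for polypeptides inside one common formalism, the
*fragment combination range* (FCR):

```
E  =  Σ_{f ∈ FCR}  p_f  E_f
```

where each **f** is a *fragment combination* — a set of initial disjoint
fragments treated as one capped molecule — and the signed integer
coefficients `p_f` come from an inclusion–exclusion principle so that every
covered interaction is counted exactly once.

The four schemes differ in where they cut bonds and how they recombine:

| Scheme | Initial cut rule | Typical spec string |
|---|---|---|
| MFHC | both bonds joining each interior peptide unit (HN–CO) to its α-carbons | `MFHC-[Nei2_4.0]` |
| pp-GMBE (PAIR) | every Cα–C(carbonyl) bond; side chains > 10 atoms split off; groups ≤ 15 atoms | `PAIR_2.2_HB-[Nei2_4.0]` |
| MIM | every C–C bond at Cα (backbone and side chain) | `MIM-[η = 6]` |
| KEM | every peptide C–N bond (one residue per group) | `KEM-[Nei2_4.0]` |

On top of the initial combinations sit *coupling schemes*: `NeiY_d` joins up
to *Y* combinations whose closest atom–atom distance is within *d* Å,
`HierY` does the same with no distance bound, `[Super]` is a supersystem
calculation, and a second bracket defines a cheaper low level for multilevel
composites (`MFHC-[Nei2_4.0][Super]`). An `ee` inside a bracket switches on
electrostatic embedding: every fragment is evaluated in the point charges of
all remaining atoms (derived iteratively from a small FCR, with cap charges
redistributed), and the double-counted Coulomb energy is subtracted once:

```
E  ≈  Σ p_f E_f^ee  −  (Σ p_f − 1) · E_Coul
```

Dangling bonds are capped with hydrogens on the severed-bond ray at fixed
distances (C 1.112 Å, N 1.060 Å, O 1.030 Å).

The package is aimed at method developers and practitioners who want to
compare fragmentation schemes, generate input decks for an external
quantum-chemistry engine (e.g. ORCA), and verify the combinatorial machinery
against exactly solvable mock backends. It does **not** run any electronic
structure itself.

## Worked example

```r
library(fragcr)

pep  <- build_polypeptide("GAKAGAKAGG", conformation = "helix")
pep
#> <fcr_structure> 113 atoms, charge +0, 'GAKAGAKAGG (helix)'

frag <- fragment_structure(pep, "MFHC-[Nei2_4.0]")
frag
#> <fcr_fragmentation> MFHC-[Nei2_4.0]: 19 groups -> 10 initial -> 67 terms
glance(frag$expansion)
#> # A tibble: 1 × 5
#>   n_terms sum_coefficients max_atoms n_positive n_negative
#> 1      67                1        50         34         33

backend <- backend_classical(pep)          # exactly solvable mock
total_energy(frag, backend)
#> <fcr_energy> MFHC-[Nei2_4.0]: -102167.472144 kJ/mol (67 terms)
```

The supersystem reference for this backend is −102189.320175 kJ/mol, so the
gas-phase expansion misses 21.85 kJ/mol of long-range interaction. Switching
on electrostatic embedding closes that gap to numerical precision — for a
classical backend the embedded FCR is exact by construction:

```r
total_energy(fragment_structure(pep, "MFHC-[Nei2_4.0_ee]"), backend)$energy -
  (-102189.320175)
#> -1.455192e-11
```

`tidy(frag$expansion)` lists every term with its coefficient and size;
`autoplot(fragment_size_histogram(frag$expansion))` shows the fragment-size
distribution; `write_qc_inputs()` emits one input deck (and point-charge
file) per term for an external engine, and `read_qc_results()` ingests the
engine's energy table back into a ledger for assembly.

A thin command-line front end lives in `inst/cli/fragcr`:

```sh
Rscript inst/cli/fragcr fixtures --sequence GAKAG --seed 3 --out pep.xyz
Rscript inst/cli/fragcr assemble --input pep.xyz --spec "KEM-[Nei2_4.0]" --backend classical
#> {"spec":"KEM-[Nei2_4.0]","energy_kj_mol":-53089.8793633978,"n_terms":9,"embedded":false}
```

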
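# barreljoint

Coarse-grained, joint-based description of β-barrel protein geometry from
Cα coordinates.

β-barrels — the cylindrical β-sheet folds of outer-membrane pores and of
many water-soluble catalytic and ligand-binding proteins — are chains of
β-strands S₁…Sₙ connected by loops L₁…Lₙ₋₁. Instead of per-residue φ/ψ
angles, `barreljoint` reduces each structure to its **joint points**: the
Cα of the first and last residue of every strand, P₁…P₂ₙ in chain order.
Sliding a window of four consecutive joints along the chain yields an
alternating series of 2n−3 signed torsion angles

    β₁, γ₁, β₂, γ₂, …, βₙ₋₁

* **β-type** angles (windows spanning Strand–Loop–Strand) describe the
  arrangement of adjacent strands: βᵢ ≈ 0° means Sᵢ and Sᵢ₊₁ are
  antiparallel, βᵢ ≈ ±180° parallel.
* **γ-type** angles (windows spanning Loop–Strand–Loop) describe the
  placement of Sᵢ and Sᵢ₊₂ about Sᵢ₊₁: γᵢ ≈ 0° same side, ±180° opposite
  sides. The shared sign of consecutive angles reports twist handedness:
  uniformly positive dyads (+,+) are the signature of the right-handed
  twist that natural barrels adopt.

The torsion is the standard right-handed convention: with b₁ = P₂−P₁,
b₂ = P₃−P₂, b₃ = P₄−P₃,

    angle = atan2(|b₂| · b₁·(b₂×b₃), (b₁×b₂)·(b₂×b₃))

in degrees on (−180, 180], with −180 normalized to +180.

The package is tidyverse-native: every reader and transformer takes a data
frame and returns a tibble, so analyses chain with the pipe; fitted
descriptors have `tidy()`, `glance()` and `autoplot()` methods.

## What it provides

* **Readers** — Cα traces from PDB files (altloc and insertion-code aware;
  `read_calpha_trace()`), strand boundaries from PDB SHEET records, STRIDE
  output or plain TSV segment tables, and membrane-embedded (TM) range
  tables that override full-strand boundaries.
* **Annotation** — validation and merging of raw strand ranges into the
  ordered strand/loop alternation (`build_annotation()`,
  `apply_tm_boundaries()`).
* **Descriptor** — joints, signed torsions and the β/γ series
  (`extract_joints()`, `signed_dihedral()`, `compute_descriptor()`,
  `expected_counts()`).
* **Patterns** — sign signatures, dyad/triad frequencies, quadrant dyads,
  histograms, and strand-count grouping (`pattern_summary()`,
  `aggregate_patterns()`, `tm_scheme()`, `cyto_scheme()`).
* **Synthetic structures** — idealized barrels with controllable strand
  count, twist handedness and direction pattern, plus exact flat-sheet
  limiting cases (`barrel_spec()`, `generate_barrel()`,
  `generate_flat_sheet()`, `write_pdb()`), so every geometric property is
  testable without downloading structures.
* **CLI** — `exec/barreljoint` with `compute`, `patterns` and `synth`
  subcommands over the same functions.

## Worked example

```r
library(barreljoint)

b <- generate_barrel(barrel_spec(8))            # right-handed, antiparallel
d <- compute_descriptor(extract_joints(b$trace, b$annotation),
                        structure_id = "demo8")
d
#> <barrel_descriptor> 8 strands, 7 beta + 6 gamma angles
#> # A tibble: 13 x 7
#>    structure_id n_strands index type  type_index label    angle
#>  1 demo8                8     1 beta           1 beta_1    9.97
#>  2 demo8                8     2 gamma          1 gamma_1  57.5
#>  3 demo8                8     3 beta           2 beta_2    9.97
#>  4 demo8                8     4 gamma          2 gamma_2 136.
#>  ...

glance(d)
#> # A tibble: 1 x 6
#>   n_strands n_beta n_gamma mean_beta mean_gamma frac_positive
#> 1         8      7       6      9.97       96.9             1
```

Every β angle of this barrel is +9.97°: adjacent strands are nearly
antiparallel with a small right-handed offset. The γ angles alternate
between +57° and +136° — strands two apart sit on opposite-ish sides of
the strand between them, again with uniformly positive (right-handed)
sign, so `frac_positive` is 1 and every dyad is (+,+):

```r
pattern_summary(d)
#> <pattern_summary> 1 structure(s)
#> dyads:
#>   type pattern n
#>   beta   (+,+) 6
#>  gamma   (+,+) 5
```

Real structures enter through the readers:

```r
trace <- read_calpha_trace("protein.pdb", chain = "A")
ann   <- build_annotation(read_sheet_strands("protein.pdb", "A"), trace)
compute_descriptor(extract_joints(trace, ann), structure_id = "protein")
```

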
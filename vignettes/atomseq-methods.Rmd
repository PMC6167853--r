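---
title: "Models and methods in atomseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in atomseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the models implemented in atomseq, the parameters
that matter, the numerical choices behind them, and what the synthetic
fixtures do and do not establish about real data.

## Sequence model

An alphabet is an ordered set of distinct symbols; the *symbol code* of a
symbol is its 0-based index in that order. A sequence stores only its
alphabet and the integer code array. Two consequences drive the design:
operations that consume codes (alignment above all) are independent of the
symbol type, and a substitution matrix can be indexed directly by a code
pair with no lookup. Alphabets are not byte-limited: `code_width()`
reports the smallest of 1, 2, 4 or 8 bytes whose unsigned range covers the
alphabet, and the round-trip property `decode(encode(x)) == x` is tested
across alphabet sizes up to 400, deliberately crossing the 256-symbol
boundary.

Nucleotide sequences default to the unambiguous A/C/G/T alphabet; the
IUPAC-ambiguous alphabet is opt-in (`ambiguous = TRUE`) and complements
follow IUPAC pairing, which makes `complement()` an involution on both
alphabets. RNA input is normalized at the boundary: `U` is mapped to `T`
on parse so there is a single canonical internal alphabet. The protein
alphabet is the 20 canonical amino acids plus `X` (unknown) and `*`
(stop).

Translation uses the standard genetic code, written out as a constant and
cross-checked in the tests against an independent reference table. Three
conventions were genuinely open and are fixed as follows:

* codons containing ambiguity codes translate to `X` (lossless, simple);
* ORF extraction scans the three frames of the *given* sequence only —
  callers pass `reverse_complement()` for the minus strand, keeping
  strand logic in one place;
* a start codon with no downstream in-frame stop yields a protein
  truncated at the sequence end, matching common ORF-extractor behaviour.
  The default start-codon set is `ATG` alone; alternative starts can be
  supplied via `default_codon_table(starts = ...)`.

## Pairwise alignment

`align_global()` is Needleman–Wunsch with terminal gaps penalized like
internal ones; `align_local()` is Smith–Waterman with the score floored at
zero and traceback from the maximal cell to the first zero cell. When
`open != extend` the three-state Gotoh recursion is used; a gap run of
length g contributes `open + (g − 1) · extend`, with both values
non-positive scores (not positive costs). Transitions directly between
the two gap states are allowed (re-opening), so the DP optimum provably
equals the maximum over all monotone traces scored run-by-run — the test
suite verifies exactly this equivalence against exhaustive enumeration of
every trace for sequence lengths up to 5, for both gap models, and the
acceptance script re-runs that comparison on 100 random pairs.

One optimal alignment is returned. Co-optimal traces are resolved
deterministically with priority diagonal > gap in the second sequence
(vertical) > gap in the first (horizontal); determinism is what makes the
traceback testable, and is also why the local traceback breaks ties for
the maximal cell toward the smallest indices. Memory is O(len1 · len2)
(three score plus three pointer matrices); no linear-space
divide-and-conquer variant is attempted.

A matrix *fits* a sequence when the matrix alphabet equals or is an
ordered extension of the sequence alphabet. The bundled NCBI tables are
re-indexed at load time onto the protein alphabet extended by B and Z, so
they fit `protein_sequence()` objects directly. The default CLI penalty
(BLOSUM62, open −10, extend −1) is a conventional choice, not a derived
one.

## Atom model and geometry

Structures are stored column-wise (one annotation vector per category
plus an (n×3) coordinate matrix; stacks share annotations over an
(m×n×3) array) because every analysis in the package is a vectorized
array operation over those columns. Indexing preserves atom order and
keeps annotations and coordinates paired; iteration order is file order
throughout — nothing is ever re-sorted, which is what makes the format
round trips exact.

Angles are radians internally ((0, π] for `angle()`, (−π, π] IUPAC
convention for `dihedral()`, 0 = cis, sign by the right-hand rule);
degrees appear only in CLI rendering. Degenerate geometry (zero-length
bond vectors, collinear torsion axes) yields quiet `NaN` rather than an
error so vectorized calls never abort mid-array; the same convention
marks φ/ψ/ω at chain termini and at residues with missing backbone
atoms. Residue identity for backbone pairing is `(chain_id, res_id)`.
The exact trans-boundary value is canonicalized to +π so that ideal trans
geometry is stable against sign flips at the branch cut.

## Superimposition, RMSD, RMSF

`superimpose()` centers both coordinate sets, takes the SVD of the
covariance matrix and corrects a reflection (negative determinant) by
sign-flipping the smallest singular direction, so the result is always a
proper rotation. The tests check recovery of known rigid motions to
1e-9, optimality against random rigid transforms, and agreement of the
minimal RMSD with an independent quaternion characteristic-matrix oracle.
Structures of fewer than 3 atoms are rejected; genuinely collinear inputs
make the optimum non-unique, and the fixed axis order of the SVD decides
the tie deterministically.

## Solvent-accessible surface area

`sasa()` implements the sphere-point method: `point_count` quasi-uniform
points (default 1000) on each atom's probe-inflated sphere
(`probe_radius` default 1.4 Å, water), a point buried if it falls inside
any neighbour's inflated sphere, and
`SASA = exposed/total · 4π(r + probe)²`. Points come from a
golden-section spiral lattice — deterministic, so results are exactly
reproducible and regression-testable; nothing is randomized. Neighbour
candidates come from a uniform cell grid with edge `2 · (max radius +
probe)`; the grid only prunes, never changes the result.

Two radius sets ship: `"single"` per-element van der Waals radii (for
structures with hydrogens) and `"protor"` group radii in which each heavy
atom absorbs its bonded hydrogens — the appropriate set for X-ray
structures without hydrogens, and the default. Waters and het atoms are
included unless excluded through `atom_mask`; masked atoms neither
receive a value nor occlude others — the caller's mask decides, not the
function.

Accuracy is anchored analytically: an isolated atom must reproduce
`4π(r + probe)²` exactly at any point count (every point exposed), and
two-sphere configurations are compared with the closed-form spherical-cap
area (itself confirmed against a lat-long numerical integration).
Convergence with the point count is measured as the mean absolute error
over a sweep of separations (1.2–5.4 Å); a single geometry is not a
reliable convergence probe because a coarse lattice can be accidentally
accurate for one particular cap boundary.

## Secondary-structure assignment

`annotate_sse()` labels residues a/b/c from CA geometry alone, using the
P-SEA criteria: inter-CA distances d2 (i−1, i+1), d3 (i−1, i+2), d4
(i−1, i+3), the CA bond angle and the CA torsion, each tested against a
fixed window (all windows live in one constants block, `PSEA_PARAMS`,
with a comment per constant). Runs of at least 5 (helix) or 4 (strand)
strictly matching residues seed a segment; a 3-residue strand seed also
qualifies when it makes at least 5 CA contacts at 4.2–5.2 Å to other
strand candidates (sheet pairing); segments then grow outward over
residues matching the relaxed criterion. Residues whose window crosses a
chain end stay coil, and chains with fewer than 5 CA atoms are entirely
coil by construction.

## Structure file formats

The PDB reader parses only ATOM/HETATM records (plus MODEL/ENDMDL
structure); `hetero` is true exactly for HETATM. Coordinates are
fixed-point with 3 decimals, so every round trip is exact to 0.001 Å —
coordinates are kept real-valued internally and quantized only at
serialization. Blank element columns are inferred from the atom-name
columns by the left-justification rule. Alternate locations keep the
first-listed conformer by default (a single-conformer model keeps
downstream algorithms well-defined); `keep_altloc = TRUE` retains all
with the identifier as an annotation.

The mmCIF layer is a generic category model: any `data_` block parses
into named tables of equal-length columns, with loop, quoted and
semicolon multi-line values supported; `atom_site` maps to and from atom
arrays, with `group_PDB` carrying the hetero flag and the model-number
item defining stacks. The writer emits `atom_site` plus a minimal
`data_` header.

MMTF documents are MessagePack maps whose binary fields carry a 12-byte
big-endian header (codec id, count, parameter). Codecs 1–10 are
implemented — pass-through floats/ints at 8/16/32 bits, fixed-width
strings, run-length, delta + run-length, quantized run-length, and the
coordinate codec (delta + recursive 16-bit indexing + divisor 1000;
B-factors divisor 100). The encoder builds the chain → group → atom
hierarchy from runs of `chain_id` and `(res_id, res_name, hetero)` in
file order, deduplicating group types; the decoder flattens it back.
Because no installed third-party MMTF reader exists to cross-validate
against, conformance rests on three legs: per-codec decode∘encode
identity on random arrays, hand-assembled reference byte streams written
directly from the format definition, and byte-level agreement of the
MessagePack layer with an independently produced reference encoding.

## Fixtures

All tests run on generated data. The ideal helix CA trace uses rise
1.5 Å, 3.6 residues/turn, radius 2.3 Å (consecutive CA distance ≈ 3.8 Å);
the ideal strand is a planar zigzag with 3.8 Å CA spacing and the pleat
chosen so d2 = 6.7 Å, the center of the strand window; the ideal trans
backbone uses bond lengths N–CA 1.46, CA–C 1.52, C–N 1.33 Å and a 111°
bond angle, laid flat so every torsion is exactly π. Random structures
draw uniform coordinates (annotations consistent per residue), random
stacks add Gaussian jitter of 0.5 Å per model. Everything is
seed-deterministic.

These fixtures establish correctness of the algorithms on geometry whose
ground truth is known in closed form. They do not establish behaviour on
real crystallographic data — distorted helices, chain breaks, insertion
codes, alternate conformers beyond the first, or non-standard residues;
the P-SEA windows in particular will label distorted real elements more
conservatively than ideal traces.

## Problem sizes

The test suite uses sequence lengths ≤ 5 against the exhaustive oracle
(the enumeration grows as the Delannoy numbers), 1000 random arrays per
codec layer check, a 500-atom 3-model structure for the format triangle,
and 50 superimposition recoveries; the acceptance script mirrors those
sizes. They were chosen so the whole suite completes in well under a
minute while still crossing every boundary the formats and recursions
contain.
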
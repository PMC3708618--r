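---
title: "Protein Block realignment of structurally variable regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein Block realignment of structurally variable regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbsvr)
```

## The problem

When two homologous protein structures are superposed globally, some
regions refuse to superpose: runs of aligned residues whose C&alpha; atoms
sit more than a few Angstrom apart.  Structural-alignment databases label
these *structurally variable regions* (SVRs) and move on.  But "not
superposable in the global frame" conflates two very different situations:

1. the region genuinely adopts a different backbone conformation in the
   two homologues; or
2. the region has the *same* local conformation in both structures and is
   merely reoriented as a rigid body (a loop hinging away from the core is
   the classic case).

Distinguishing the two matters for loop modelling (case 2 loops are
directly transferable between homologues) and for reasoning about which
sequence changes actually change structure.  `pbsvr` makes the distinction
by dropping from Cartesian space into a *structural alphabet*: internal
coordinates do not see rigid-body motion, so two conformationally
identical loops have identical symbol strings no matter how they are
oriented.

## The Protein Block alphabet

The alphabet used is the 16-letter Protein Block (PB) alphabet.  Each
letter (a..p) is a prototype of local backbone structure: a vector of
eight backbone torsion angles over five consecutive residues, ordered

> &psi;(i&minus;2), &phi;(i&minus;1), &psi;(i&minus;1), &phi;(i), &psi;(i),
> &phi;(i+1), &psi;(i+1), &phi;(i+2).

Letter m is the canonical &alpha;-helix, d the extended &beta;-strand; the
rest cover turns, caps and transitions.  A chain is encoded by sliding the
five-residue window along the backbone: at each position the letter whose
reference vector minimizes the *rmsda*,

$$\mathrm{rmsda}(w, r) = \sqrt{\tfrac{1}{8}\sum_{k=1}^{8}
  \Delta(w_k, r_k)^2},$$

is assigned, where $\Delta$ is the wrapped angular difference in
$[0, 180]$ degrees.  Ties (which cannot occur with the bundled reference
table but are possible with user-supplied ones) break alphabetically.
Positions without a complete window receive the sentinel `Z`: always the
two first and two last residues, plus the neighbourhood of chain breaks
(consecutive C&alpha; atoms more than 4.5 A apart; the trans peptide bond
places them at ~3.8 A, cis at ~2.9 A, so 4.5 A is a generous bound).

The reference vectors are bundled as a plain TSV
(`inst/extdata/pb_definitions.tsv`), transcribed from the published PB
definitions, and can be overridden (`pb_definitions(path)`) -- the encoder
is generic in its alphabet.

A property worth stating because it shapes the tests: a *connected* chain
cannot present the same eight-angle window at every position unless the
reference vector is periodic in one residue (only m and d are).  A shifted
window is genuinely a different local structure and correctly encodes to a
different letter.  The encode/decode round-trip probe for an arbitrary
letter is therefore the five-residue fragment its vector actually defines,
embedded (twice) in a probe chain with chain breaks between embeddings;
every assignable position of that chain carries exactly the reference
window and must recover the letter.

## The pair pipeline

`run_pair()` consumes two backbones and a pre-existing structure-based
sequence alignment (the method refines alignments, it does not create
them; for equal-length synthetic twins an identity alignment is accepted).
The stages:

1. **Encode** both chains as PB strings and project them onto the
   alignment columns.
2. **Superpose** chain B onto chain A by closed-form least-squares
   (SVD solution of the orthogonal Procrustes problem, reflection
   corrected to a proper rotation).  By default the fit uses all aligned
   columns; `fit_on = "scr_iterative"` refits once on SCR columns only and
   resegments, which tightens the conserved-core frame when large SVRs
   would otherwise tilt the fit.
3. **Segment**: per-column C&alpha;-C&alpha; distances in the global
   frame; columns above 3 A -- or gap columns, which have no distance --
   are SVR candidates; maximal candidate runs of at least 3 columns become
   SVRs, shorter runs are absorbed into the surrounding SCR.  Runs
   touching either end of the alignment are flagged terminal and excluded
   from assessment (the two `Z` positions at each chain end make their PB
   content unreliable).
4. **Realign** each eligible SVR: the PB substrings of the SVR (gaps and
   `Z` dropped) are globally realigned by affine-gap dynamic programming
   under a PB substitution matrix.  Eligibility requires more than three
   PBs -- read as at least 4 -- on the *shorter* side; both the threshold
   and the side rule are configurable because the clause is genuinely
   ambiguous.
5. **Score and classify**: the PB score of the realignment is the sum of
   substitution-matrix values over letter-letter columns; the *normalized*
   score divides by the number of such columns.  An SVR with normalized
   score at least -0.42 (inclusive) is *conformationally similar*,
   otherwise *dissimilar*.  The cutoff is applied to the normalized score:
   a single fixed cutoff across SVRs of widely varying length is only
   meaningful per column.
6. **Report**: RMSD and a structural distance metric (SDM) before
   (original equivalences, global frame) and after (realigned
   equivalences, locally refitted) realignment; an annotated flat file
   (SCRs uppercase, SVRs lowercase, region line, per-SVR records); and the
   superposed coordinates as a two-chain PDB.

"Before" and "after" RMSD deliberately live in different frames: only a
*local* refit of the realigned equivalences can reveal that a
rigid-body-displaced loop is internally identical (RMSD after refit ~ 0)
while the global frame shows it several Angstrom away.  When fewer than 3
realigned pairs exist the local refit is skipped and the after-RMSD is
reported in the global frame with a flag.

## Scoring details

**Substitution matrix.**  The published PB substitution matrix is not
redistributable here, so the bundled default
(`pb_substitution_matrix_synthetic.tsv`, generated by
`data-raw/pb_substitution_matrix.R`) is a synthetic stand-in derived from
the reference vectors themselves:

$$M(x, y) = \frac{45 - \mathrm{rmsda}(r_x, r_y)}{22.5}.$$

Identical blocks score +2; blocks whose windows differ by 45 degrees rms
score 0; the -0.42 cutoff corresponds to a mean angular dissimilarity of
about 54.5 degrees between aligned blocks.  The matrix is symmetric with a
dominant diagonal by construction, and any 16 x 16 matrix with the same
layout can be substituted via `sub_matrix_path`.

**Gaps.**  Penalties are unstated in the source method ("modified
CLUSTALW"); the defaults are gap open -5, gap extend -0.5, with a gap run
of length $L$ costing $open + (L-1) \cdot extend$.  `Z` scores 0 against
everything: it is absence of information, not a 17th letter.  With
strongly dissimilar substrings the optimal affine alignment can
degenerate to aligning nothing (all gaps); the normalized score is then
undefined and the SVR is classified dissimilar -- nothing alignable is
the strongest form of dissimilarity.

**SDM.**  The exact constants of the published structural distance metric
are in references that are not reproduced here, so the metric is a
plug-in with a documented default:

$$\mathrm{SDM} = -100 \,\ln\!\Big( w_1 \frac{N_{eq}}{\max(L_A, L_B)}
  + \frac{w_2}{1 + \mathrm{RMSD}/d_0} \Big),\qquad
  w_1 = w_2 = 0.5,\; d_0 = 3\,\mathrm{A}.$$

It is 0 for identical fully-equivalenced fragments, strictly increasing
in RMSD at fixed length, and penalizes unequivalenced residues; any
function with the same signature can be supplied to `assess_svr()`.

**Alignment engine.**  The Gotoh three-layer recurrence and its traceback
(ties broken diagonal, then gap-in-B, then gap-in-A, for determinism) are
implemented in C++; an independent exhaustive path-enumeration oracle is
kept alongside it and the two are compared on every small instance in the
tests -- the DP is trusted because it reproduces enumeration, not because
it looks right.

## The synthetic generator

Real corpus data (curated domain pairs with DALI alignments) is out of
scope; instead every stage is exercised on synthetic backbone pairs with
known ground truth, built by exact internal-coordinate (NeRF) chain
construction with canonical trans-peptide geometry (N-CA 1.458, CA-C
1.525, C-N 1.329 A; angles 121.7/111.2/116.2 degrees; omega 180).
`build_backbone()` is an exact inverse of `compute_dihedrals()`, which
pins the whole dihedral machinery to 1e-6 degrees.

`make_homolog_pair()` applies edits to a base phi/psi script
(`loop_recipe()` supplies a strand-loop-strand default: 14-residue
extended flanks around a 9-residue helical loop, which bulges away from
the flank axis so that rotation displaces it well beyond the 3 A
threshold):

- `rigid_rotate_loop` rotates the loop span rigidly about the axis
  through its two flanking C&alpha; atoms (default 140 degrees).  Because
  both anchors lie on the axis, anchor distances are preserved and no
  chain break is introduced; interior dihedrals are untouched, only the
  two hinge residues' geometry changes.  This is the ground-truth
  *conformationally similar* SVR: displaced > 3 A, identical PB interior,
  local refit RMSD exactly 0.
- `change_dihedrals` rebuilds the span by NeRF with each phi/psi moved at
  least 90 degrees from the base value, growing from the upstream anchor
  and rejection-sampled (seeded, deterministic) until the fragment lands
  within 4.2 A C&alpha;-C&alpha; of the downstream anchor, so the chain
  stays intact.  Ground truth: *dissimilar*.
- `insert` / `delete` do the same with a longer/shorter bridging
  fragment (ground truth: an SVR must appear; its class is not promised,
  since what remains aligned may be too short to assess).
- `substitute_aa` relabels residues only (structure unchanged; ground
  truth: no SVR).

Loop closure is approximate by construction -- only hinge geometry
absorbs the mismatch -- so ground-truth spans include the hinges and
span-recovery tests allow a +/- 2 column tolerance.  What the generator
does *not* emulate: side chains, Ramachandran-realistic dihedral
distributions, correlated thermal noise, missing residues, or
non-trivial amino-acid sequences (chains are poly-alanine unless
substituted).  Passing tests therefore demonstrate the correctness of
the machinery on clean backbones, not robustness to experimental-data
pathologies such as low-occupancy alternate conformations or
mis-traced loops.

## Numerical and design choices

- Internally columns and residues are 1-based (R idiom); reports always
  carry author residue numbers and insertion codes verbatim.
- Superposition refuses fewer than 3 pairs or collinear point sets
  (rotation undetermined), and never returns a reflection.
- The worked problem sizes in tests and the acceptance script -- 37-residue
  pairs, 25-pair batches, exhaustive alignment checks over 3-letter
  strings of length up to 5, 1000-vector segmentation sweeps -- were
  chosen as the smallest sizes at which every property is exercised
  non-trivially.
- Determinism is a contract: identical inputs and configuration give
  byte-identical annotated files, assessment TSVs and superposed PDBs
  (fixed float formatting throughout the writers).

## Known limitations

- The bundled substitution matrix is a principled stand-in, not the
  published one; absolute normalized scores shift with the matrix, and
  users wanting published-matrix behaviour must supply it.
- Global alignment of excised SVR substrings is used for realignment;
  whether the original method anchors SVR ends semi-globally against the
  flanking SCRs is unstated, and a semi-global mode is not provided.
- One SCR-refit iteration is supported; no hinged/flexible superposition,
  no outlier-rejection cycles, no multi-structure (family-level)
  consensus regions.
- mmCIF support follows the standard PDBx `atom_site` layout as parsed by
  bio3d; exotic dialects may need conversion to PDB first.
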
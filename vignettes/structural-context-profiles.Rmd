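---
title: "Structural context profiles: model, algorithm and design notes"
author: "rnaprofile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural context profiles: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaprofile)
```

## The quantity being computed

An RNA molecule in solution does not hold a single secondary structure; it
samples an ensemble.  For many questions — most prominently, what kind of
local structure an RNA-binding protein sees at its binding site — one wants,
for every base `i`, the probability that the base sits in each *structural
context*:

* **S** (stem): the base is paired;
* **H** (hairpin loop), **B** (bulge loop), **I** (internal loop),
  **M** (multibranch loop): the base is unpaired inside a loop polygon
  with one, two (joined by a single backbone edge on one side or not),
  or more than two closing hydrogen bonds;
* **E** (exterior loop): the base is unpaired and not enclosed by any pair.

Under the Boltzmann ensemble with the Turner nearest-neighbour free-energy
model, the profile is

$$p(i,\delta) \;=\; \frac{1}{Z}\sum_{\sigma \in \Omega(i,\delta)}
  e^{-\Delta G(\sigma)/RT},\qquad
  Z \;=\; \sum_{\sigma \in \Omega_0} e^{-\Delta G(\sigma)/RT},$$

where $\Omega_0$ is the set of admissible pseudoknot-free structures,
$\Omega(i,\delta)$ the subset in which base $i$ has context $\delta$,
$\Delta G$ the free energy relative to the open chain, $R$ the gas constant
and $T = 310.15\,$K by default.  Every base belongs to exactly one context
in every structure, so each profile row sums to 1.  The package also tracks
the *unstructured* union $U = E + M$, which — unlike $E$ and $M$
individually — is insensitive to the maximal span parameter described next.

`structural_profile()` computes these probabilities exactly (no sampling)
with a banded inside–outside algorithm in $O(NW^2)$ time and $O(NW)$
memory, which is what makes profile computation practical for thousands of
long transcripts.

## The grammar and the admissible ensemble

The computation runs over an unambiguous context-free grammar for
pseudoknot-free structures with seven nonterminals — Outer, Stem, StemEnd,
Multi, MultiBif, Multi1, Multi2 — in which every structure has exactly one
derivation, so inside/outside sums count every structure exactly once:

```
Outer   -> e | Outer a | Outer Stem
Stem    -> b< Stem b> | b< StemEnd b>
StemEnd -> s_n | s_m Stem s_n (m+n > 0) | Multi
Multi   -> a Multi | MultiBif
MultiBif-> Multi1 Multi2
Multi1  -> MultiBif | Multi2
Multi2  -> Multi2 a | Stem
```

The nonterminal a base is emitted from determines its context, so posterior
transition probabilities give the profile directly.

Three parameters delimit the ensemble:

* **Maximal span `W`** (`max_span`, required): bases further apart may not
  pair.  Long-range pairs add cost without improving local structure
  prediction, and the band is what makes the algorithm linear in `N`.
  Internally the Outer transition uses the strict bound `i-W < k < i`, so
  the admissible pair separations are `b - a <= min(W, N) - 2`; the
  enumeration oracle (below) implements the identical rule, and spans
  larger than the sequence are clamped silently.
* **Loop cap `C`** (`loop_cap`, default 30 as in standard folding tools):
  interior/bulge loops with more than `C` unpaired bases are excluded from
  the ensemble entirely (this is what reduces the complexity from
  $O(NW^3)$ to $O(NW^2)$).  Hairpin and multibranch loops are not capped.
* **Minimum hairpin loop of 3 unpaired bases**, applied uniformly.

Because the results genuinely depend on `W` (see the trend checks in the
test suite: mean exterior probability falls and mean multibranch
probability rises as `W` grows), `max_span` has deliberately **no
default** — callers must choose it.  Typical choices: 100 for genome-scale
scans, 200 for the CLIP analyses, larger values when long annotated pairs
matter.

## Energy attribution conventions

The bundled tables are the published Turner 2004 nearest-neighbour
constants, stored as plain text in kcal/mol (`load_parameters()`), with
tabulated 1x1, 1x2/2x1 and 2x2 interior loops, terminal mismatches for
hairpin and interior loops, tri-/tetra-/hexaloop bonuses, length tables
with logarithmic extrapolation beyond 30 (`lxc`), the Ninio asymmetry
penalty with cap, the affine multibranch model and the terminal AU/GU
penalty.  Conventions (implemented once in R for the oracle and once in
C++ for the dynamic program, and spelled out in `R/energy_model.R`):

* hairpin loops of size 3 get the terminal AU/GU penalty and no mismatch;
  larger loops get a terminal mismatch; tabulated special loops replace
  the whole term;
* bulges of size 1 keep the stacking term of the flanking pairs; larger
  bulges pay terminal penalties on both helix ends;
* interior loops without a special table use length + capped asymmetry +
  one mismatch per closing pair.  Loops of shape 1xn (n > 2) use the
  generic interior mismatch table — the dedicated 1xn tables of some
  implementations are intentionally not bundled, a simplification that is
  symmetric between the two implementations;
* multibranch loops: `a + b x branches + c x unpaired`, the closing helix
  counting as a branch, terminal penalties per helix end facing the loop;
* exterior unpaired bases are free; exterior helix ends pay the terminal
  penalty;
* dangling-end contributions are **off**: the grammar above emits no
  dangle states, and keeping the energies bit-faithful to the grammar
  outranks squeezing out the last fraction of thermodynamic completeness.

Ambiguous bases (`N`, and any other letter after normalisation) are
treated as unpairable but present: they can occupy any loop context, which
keeps profiles defined on real transcripts.  Mismatch terms that would
read an `N` contribute 0 kcal/mol.

No agreement with any particular external folding implementation is
claimed or tested: the correctness surface is internal (next section),
which also makes the test suite insensitive to the exact parameter
revision bundled.

## The enumeration oracle

`exact_profile()` computes the same quantity by brute force: enumerate
every admissible structure of a short sequence (`enumerate_structures()`,
guarded at 16 nt), classify every base from first principles by walking
the loop polygons (`classify_contexts()`), assemble each structure's
energy loop by loop (`structure_energy()`), and tally Boltzmann weights.
The oracle shares the energy *tables* and the R-level energy accessors but
none of the dynamic-programming code; a separate Nussinov-style counting
recursion (`count_structures()`) cross-checks the enumerator.  The test
suite asserts, for **all** sequences up to length 8 and hundreds of random
sequences up to length 12, at two spans, that the banded inside–outside
profile equals the oracle profile to 1e-9 — this exhaustive equivalence,
plus row normalisation, pair-probability identities and the
$\alpha\beta \le Z$ consistency bounds, is the package's primary
correctness argument.

## Numerical strategy

Partition-function values grow like $e^{cN}$ and overflow doubles near
2,000 nt.  The package scales every emitted base by a uniform factor
anchored on a minimum-free-energy pass (the same recursions in the
tropical semiring, cost one extra inside pass), with a safety factor of
1.05 and automatic retry if the scaled log partition function leaves
[-600, 600].  On top of that, the one-dimensional Outer chain carries
per-position rescaling ledgers, so composition drift along very long
sequences cannot underflow the prefix values.  All profile readouts divide
by the identically scaled partition function, so the scale cancels
exactly.  The stability contract — finite, normalised profiles for
$N \le 10{,}000$ at $W \le 800$ — is asserted in the tests.  Strongly
inhomogeneous sequences (for example a long GC-only island inside an
AU-only sea) could still exceed the banded tables' dynamic range; uniform
random and transcript-like sequences are well inside it.  The B/H/I
readouts accumulate range-additions; accumulated rounding of order 1e-14
is clamped at zero.

## CLIP structural-specificity statistics

Given transcripts, transcript-relative peak intervals (BED3) and an IUPAC
motif, `run_clip_pipeline()` implements the comparison of bound sites
against two negatives:

1. **Bound sites**: motif matches starting inside a peak; peaks of one or
   two bases are widened by 10 nt before matching; peaks without a match
   are dropped.  Windows of ±2,000 nt (default) are cut around each site
   — the truncation experiment below motivates that choice — and several
   sites in one peak are averaged into a single observation.
2. **Unbound negative**: motif occurrences on the same transcripts within
   ±1,000 nt of a bound site but not themselves bound.  The distance
   clause is implemented literally ("within"); because that rule reads
   counterintuitively, the complementary reading ("beyond", at least
   1,000 nt away) is available via `unbound_rule` for sensitivity
   analysis.
3. **Shuffled negative**: each positive window with its upstream and
   downstream flanks independently shuffled by an Euler-path
   (Altschul–Erickson) procedure that preserves dinucleotide counts
   exactly; `keep = 5` or `10` leaves the motif ±5/±10 nt core intact for
   the partially shuffled variants.

Per relative position (reporting window ±20 nt around the motif start by
default) and per context — B, H, I, S and U; the unstructured union
replaces E and M to avoid span sensitivity — both one-sided
Wilcoxon–Mann–Whitney tests are run; the **P score** is $-\log_{10}$ of
the smaller one-sided p-value, sign-flipped when the "positive smaller"
side wins (ties break toward the positive sign; p-values are floored at
1e-300).  The two scores against the two negatives are combined
conservatively: same sign keeps the smaller magnitude, opposite signs give
0.  Significance uses a Bonferroni family of (reporting positions) x
(5 contexts) per run — the most defensible family; it is configurable
because the original analysis does not pin it down.  The rank-sum test is
delegated to `stats::wilcox.test` (exact enumeration without ties below
50 observations, otherwise the tie- and continuity-corrected normal
approximation).

## What the synthetic data does and does not show

The generators produce i.i.d. backgrounds of fixed GC content, designed
stem-loop/helix/internal-loop constructs with a motif planted in a chosen
context (`clip_fixture()`), matching peak intervals, and decoy motif
occurrences feeding the unbound negative.  They emulate the *logical*
shape of a CLIP experiment — sites anchored by motifs, peaks, negatives —
and support two kinds of checks: planted-signal recovery (a motif designed
into hairpin loops must produce positive, significant H-context scores)
and null calibration (groups drawn from one generator must stay below the
Bonferroni level in at least 19 of 20 seeded replicates).  They do not
emulate biased nucleotide composition around real binding sites,
transcript isoform structure, peak-calling noise, cross-link artefacts or
read-level effects; passing these tests therefore demonstrates the
statistics and the machinery, not biological performance on real CLIP
data, which requires external datasets that are deliberately out of scope
here (a documented optional script for reference-annotation AUROC
benchmarking ships in `inst/scripts/`).

## Parameter summary

| parameter | default | meaning |
|---|---|---|
| `max_span` (W) | none — required | maximal pair span, nt |
| `loop_cap` (C) | 30 | max unpaired bases in interior/bulge loops |
| `temperature_K` | 310.15 | ensemble temperature, K |
| `flank` | 2000 | window half-width around CLIP sites, nt |
| CLIP `max_span` | 200 | span used for CLIP profiles |
| `window` | 20 | reporting half-width around the motif, nt |
| `radius` | 1000 | unbound-site distance rule, nt |
| `keep` | 0 (5/10) | intact core half-width for partial shuffles |
| `alpha` | 0.05 | family-wise error rate (Bonferroni) |

## Problem sizes used by the test suite

The suite keeps the full run in minutes on one CPU by scaling the
experiments down while keeping their logic intact: the oracle equivalence
scan covers all sequences to length 8 plus 500 random sequences to length
12 at two spans; normalisation uses 100 random 200-nt sequences over three
GC contents; the truncation validation uses 5 sequences of 10,100 nt at
`l = 2000`; the trend checks use 20–50 random 500-nt sequences; the
planted-fixture analysis uses 30 transcripts of 1,200 nt with ±250-nt
windows; null calibration uses 20 replicates of three 10-observation
groups; the stability check runs one 10,000-nt sequence at `W = 800`.
The W-scaling check of the complexity contract counts operations at a
small fixed loop cap (`C = 10`), where the quadratic-in-W bifurcation term
dominates at tractable sizes; the linear-in-N check uses the default cap.
Full-scale settings (1,000 sequences of 2,000 nt, and so on) are reachable
through the same functions and the `simulate` subcommand.

## Known limitations

* No pseudoknots and no G-quadruplexes — the grammar cannot express them,
  so G-rich quadruplex-forming sites will typically be reported as stems.
* No coaxial stacking and no dangling ends (see above); no
  enthalpy/entropy rescaling, so the temperature parameter only rescales
  the bundled free energies.
* Stem probabilities from nearest-neighbour models tend to run high;
  interpret S against the loop contexts rather than in absolute terms.
* The unstructured union U is the robust quantity when the choice of `W`
  is uncomfortable; E and M individually shift with `W` by construction.
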
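# rnaprofile

Per-base RNA secondary-structure context probabilities, exactly and fast,
plus the statistics needed to ask which structural context an RNA-binding
protein (RBP) prefers at its binding sites.

RNA-binding proteins recognise their targets by sequence *and* structure: a
short sequence motif may be bound only when it sits in a hairpin loop, or
only when it is unstructured. Accessibility (the probability of being
single-stranded) cannot separate hairpin from bulge from internal from
multibranch loops. This package computes, for every base `i` of an RNA, the
full **structural profile**: the six probabilities that the base lies in a
bulge loop (B), exterior loop (E), hairpin loop (H), internal loop (I),
multibranch loop (M) or stem (S) under the Boltzmann ensemble,

    p(i, d) = (1/Z) * sum over structures with base i in context d of
              exp(-dG(structure) / RT),

with the Turner nearest-neighbour energy model (bundled Turner 2004
tables), a maximal base-pair span `W`, and an interior-loop size cap
`C = 30`. The computation is an exact banded inside–outside algorithm over
an unambiguous structure grammar — `O(N W^2)` time, `O(N W)` memory — so
profiles of 10,000-nt transcripts take seconds, not hours of stochastic
sampling. Each profile row sums to 1; the derived unstructured track
`U = E + M` is insensitive to `W`.

On top of the profiles, the package implements a CLIP-seq
structural-specificity analysis: motif-anchored binding sites inside peaks
versus two negatives (unbound motif occurrences nearby, and
dinucleotide-preserving shuffles of the flanks), compared per position and
context by one-sided Wilcoxon–Mann–Whitney tests and summarised as signed
`-log10 p` **P scores** with Bonferroni significance levels.

An exact enumeration oracle (structures listed one by one, contexts
classified from the loop polygons, energies assembled loop by loop)
provides ground truth on short sequences; the test suite checks the
dynamic program against it exhaustively. Synthetic-data generators build
every input the tests need, including CLIP fixtures with motifs planted in
chosen structural contexts.

## Worked example

```r
library(rnaprofile)
sp <- structural_profile("GGGCGCAAGCUUCGGCGCCC", max_span = 20, name = "demo")
sp
#> structural profile of 'demo' (20 nt, W = 20, C = 30)
#>   log Z = 13.6689
#>  position base         B         E         H         I         M        S
#>         1    G 0.0000000 9.957e-01 0.000e+00 0.000e+00 0.000e+00 0.004273
#>         2    G 0.0020726 4.702e-03 1.671e-08 1.882e-05 2.527e-14 0.993207
#>         ...
#>         7    A 0.0009733 2.369e-06 9.756e-01 2.231e-02 6.862e-15 0.001076
#>         8    A 0.0009733 2.369e-06 9.767e-01 1.989e-02 6.738e-15 0.002423
#>   ... (12 more positions)
summary(sp)
#> mean context probabilities of 'demo':
#>      B      E      H      I      M      S      U
#> 0.0007 0.1001 0.3940 0.0034 0.0000 0.5019 0.1001
```

Read this as: the first base is almost surely exterior (E = 0.996), bases
2–6 are stem with probability > 0.99, and bases 7–8 sit in a hairpin loop
with probability ~0.98 — the ensemble is dominated by a stem-loop whose
loop starts at base 7. `log Z = 13.67` is the log partition function;
`plot(sp)` draws the stacked per-position probabilities, and
`as.data.frame(sp)` / `write_profile(sp, path)` export them.

The same computation by brute-force enumeration (short sequences only,
guarded at 16 nt) agrees to machine precision:

```r
s <- "GGCGCAAAGCGCC"
max(abs(exact_profile(s, max_span = 13)$prob -
        structural_profile(s, max_span = 13)$prob))
#> [1] 7.771561e-16
```

Command line (installed under `exec/` of the package):

```sh
rnaprofile profile --in transcripts.fa --out profiles.tsv --max-span 100
rnaprofile clip --transcripts tx.fa --peaks peaks.bed --motif ACUK \
                --max-span 200 --out pscores.tsv
rnaprofile simulate clip-fixture --n 30 --context H --out-dir fixture/
```

`--max-span` is required on purpose: results depend on it (small spans
force exterior loops; large spans trade exterior for multibranch loops),
so the choice must be explicit.

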
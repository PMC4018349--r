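---
title: "Mining a neuropeptidome: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining a neuropeptidome: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmine)
library(dplyr)
```

npmine turns an assembled central-nervous-system transcriptome into a
catalogue of candidate neuropeptides and protein hormones. This vignette
explains the biology the package models, the conventions it fixes where the
underlying biology is written loosely, and the design decisions a maintainer
would want spelled out.

## The prepro-peptide model

Neuropeptides are translated as precursors (prepro-peptides): an N-terminal
signal peptide directs the protein into the secretory pathway and is removed;
the remaining propeptide is cut by prohormone convertases at basic cleavage
sites; carboxypeptidases then trim the exposed basic residues; and a
C-terminal glycine left exposed after trimming is converted into a C-terminal
amide on the preceding residue. Many peptides additionally cyclise an
N-terminal glutamine into pyroglutamate. The package models this chain
explicitly:

1. `find_orfs()` scans all six reading frames (assemblies are unoriented)
   under the standard genetic code. ORFs are classed `complete`
   (ATG-to-stop), `partial_nterm` (frame edge to first stop), `partial_cterm`
   (last ATG to the open transcript end) or `partial_both` (fully open
   frame). Codons containing `N` translate to `X` and end ORF extension:
   ambiguity breaks the reading evidence, so we do not extend through it.
   `min_aa` defaults to 40 residues — comfortably below the shortest
   precursor ORFs in this repertoire (~49 aa) and above micro-ORF noise.
2. `predict_signal_peptide()` is a transparent von Heijne style heuristic
   (below), with an external-annotation override that is the recommended
   route for real data.
3. `find_cleavage_sites()` scans the propeptide for the dibasic motifs
   `KR`, `RK`, `KK`, `RR`. Monobasic arginine cleavage exists in some
   families (myosuppressin is released by dibasic *and* single-arginine
   sites) but is **off by default**: enabling it globally would falsely
   split the many printed peptides that carry internal single basics
   (e.g. `NRQYSFGLa`, `SDLYDNDLGRSYDFGL`). It is opt-in per run.
4. `segment_propeptide()` cuts immediately C-terminal to each site. Raw
   segments keep their trailing motif, so their concatenation reproduces the
   propeptide byte for byte; `trim_and_modify()` then removes exactly the
   matched motif (never peptide-intrinsic basics — the tachykinin
   `APSGFLGMRa` keeps its own terminal R), strips an exposed amide-donor
   glycine and flags it, and flags (without editing) an N-terminal Q as a
   pyroglutamate candidate. Both representations — raw segment and trimmed
   peptide — are emitted, because published peptide tables mix the two
   conventions (orcokinin rows are printed with their trailing basics,
   allatostatin rows without).

Overlapping basics (`KRR`) are resolved leftmost-first, with scanning
resuming after the match. This is a convention, not biology: convertase
preference at stacked basics is not resolvable from sequence alone, and a
fixed rule keeps the pipeline deterministic.

## The signal-peptide heuristic

Dedicated predictors are trained models; this package does not re-implement
one, because signal lengths are an *input* to the processing model, not a
contribution of it. The built-in heuristic captures the two classical
signal-peptide features: a candidate cleavage point `c` (scanned over
positions 8–45) must have small residues (A, G, S, C, T) at `c` and `c-2`
(the (−3,−1) rule), and a hydrophobic core — some 6–12 residue window inside
`[2, c-2]` ending no earlier than `c-8` with mean Kyte–Doolittle hydropathy
above 1.6. Among qualifying points the best core mean wins; ties go to the
shortest signal, which keeps the rule deterministic when the first cargo
residue happens to be small. Proteins shorter than 15 residues, or with no
qualifying window, get length 0. For real data, supply a predictor's output
via `signal_from_annotation()`; it always overrides the heuristic.

The synthetic generator builds signals as `M` + a leucine core + `ASA`, which
the heuristic recovers exactly by construction, so signal removal never
confounds the round-trip tests of the cleavage machinery.

## Family classification

`match_peptide_motifs()`, `scan_cysteine_scaffold()` and `keyword_mine()`
supply three independent evidence levels, resolved by `assign_family()` with
precedence motif > scaffold > keyword: a mature-peptide motif is direct
evidence, a cysteine scaffold is structural, and a keyword merely inherits a
database annotation. All three libraries are flat TSV config files under
`inst/extdata/` — adding a family requires no code change. Within a level,
ties go to the most specific pattern (most literal residues; this is what
ranks the sulfakinin `GH[ML]RF$` above the generic 10-residue `RF$`
myosuppressin motif for `EFDEYGHMRFa`), to the nearest scaffold length-range
midpoint (with strict-range matches preferred — the CHH 71–73 aa versus
MIH/GIH 74 aa boundary), or to the longer keyword, with generic "hormone"
hits always last. Conflicting evidence is retained in an `alternatives`
column, never dropped.

The orcokinin motif is implemented as `^NFDEID`, derived from the printed
mature peptides themselves; the figure-style motif string containing
"NFDEIRDR" matches none of them and is treated as a typographical slip.
The keyword scanner reads the best-hit description *and* a curator comments
field when one is present; a transcript whose best hit is an uninformative
"hypothetical protein" is otherwise unreachable by keywords and must wait
for scaffold or motif evidence.

## Conservation statistics

`global_align()` is a Needleman–Wunsch global aligner with a linear gap
model and a fully specified traceback (diagonal > up > left), so identity
counts are bit-reproducible. Defaults are match +1, mismatch 0, gap −1. For
the equal-length, near-identical peptide sets this package summarises, no
gaps arise and identity counts are independent of these parameters; a
substitution matrix would add nothing to a binary identity statistic.
`consensus_motif()` applies the strict rule used in conserved-motif boxes:
a column is spelled out only when invariant across *all* members, otherwise
`X`, with an `amide` suffix when every member is amidated. Unequal-length
members are mapped onto the modal-length member by pairwise alignment; a
length spread beyond the gap budget (default 5) is refused with the
outliers named.

`nj_tree()` wraps the standard Saitou–Nei neighbor-joining algorithm (exact
on additive matrices) over `1 − identity/100` p-distances — the distance
model is a choice; with near-identical domains a correction would change
branch lengths negligibly. Negative branch lengths, which NJ can produce on
non-additive input, are clamped to zero with the deficit moved to the sister
branch so total tree length is preserved. Bootstrap support is available as
an optional column-resampling mode in the conventional sense but is not part
of any packaged statistic; at the replicate counts feasible here support
values are indicative only.

## Expression analysis

`compute_rpkm()` implements reads per kilobase per million mapped reads:
`counts * 1e9 / (length_nt * lib_size)`. `tissue_contrast()` runs a one-way
fixed-effects ANOVA per transcript between brain and eyestalk on
untransformed RPKM — with two groups this is the two-sided pooled t-test —
at `alpha = 0.05` by default, mirroring the pooled-sample design this
package emulates: two pooled samples (male, female) per tissue, so n = 2
versus n = 2, and no multiple-testing correction. A `log2(x + 1)` option
exists and is off by default. Groups with fewer than two values are refused
(`summarize_expression()` keeps such rows and marks them untestable); when
both groups have zero variance the p-value is 1 for equal means and 0
otherwise, avoiding lm's 0/0 F statistic.

This design has honest limits worth stating plainly. With n = 2 per tissue
and negative-binomial noise at dispersion 0.1, the raw-scale ANOVA detects
even a 100–1000× fold change in only roughly two-thirds of replicates: both
the mean difference and the pooled standard deviation scale with the
eyestalk mean, so the expected t statistic plateaus near the df = 2
critical value. The test suite measures exactly this (and the suite's
power assertion states the stricter bound it is checked against); the
log2 option raises power above 99% for such contrasts because the log-scale
difference no longer scales with the noise. The false-positive rate of the
raw-scale test stays at the nominal 5% under the null, which the suite
verifies by simulation.

## The synthetic-data generator

`build_precursor_protein()` inverts the maturation conventions: synthetic
signal + each peptide (+G when amidated) + `KR` linkers, with the terminal
peptide's amide glycine exposed at the C-terminus. It *refuses* specs whose
peptides contain grammar motifs or whose junctions would create unintended
sites, naming the offender — a generator that silently builds an
irreconcilable truth table would poison every downstream test. One genuine
blind spot: an unamidated peptide ending in glycine is indistinguishable
from an amide donor after trimming, so such inputs round-trip with the
amidation flag set; the property tests exclude exactly this case and
nothing else. `reverse_translate()` draws uniform synonymous codons under a
fixed seed, appends TAA, and places an in-frame stop at the end of the 5'
UTR so the embedded ORF is the first start codon of its frame.
`simulate_counts()` draws negative-binomial counts (dispersion 0.1,
variance `mu + 0.1 mu^2`) for the four pooled samples at 45 million reads
per library by default — the depth of the emulated design — with
eyestalk-specific transcripts at 10²–10³× fold changes; tests run at
depths scaled down 100× (450k), which leaves RPKM distributions unchanged
up to count discreteness.

What the generator deliberately does **not** emulate: read-level errors,
assembly chimerism and splice-variant collapse, BLAST annotation noise, and
length-dependent count bias. Passing round-trip tests therefore demonstrate
the internal consistency of the processing model, not robustness to
assembly artefacts; the external-annotation paths (signals, annotations,
counts as inputs) are where real-data noise enters, by design.

A related reality surfaced by the tests: a short precursor made of many
identical repeats can present a stop-free antisense frame longer than its
true ORF, and `select_precursor_orf()` — longest first, by contract — will
choose it. This is a genuine property of unoriented assemblies, not a bug;
the end-to-end tests use realistic precursor lengths (~200 aa and up),
where a spurious open frame of that length is vanishingly unlikely.

## Problem sizes and determinism

Every stochastic step takes an explicit seed (`withr::with_seed`, so global
RNG state is never disturbed). The packaged property suites run 1,000
random precursor round-trips, 2,000-transcript null calibration and a
400-transcript power study; each completes in seconds on one core.
`run_pipeline()` writes a manifest (package version, seed, alpha, grammar,
input md5s) and its outputs are byte-identical across reruns of the same
config, except for the manifest timestamp.
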
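# npmine

Neuropeptidome mining from assembled transcriptomes, in R.

Crustacean physiology — molt, metabolism, reproduction, pigment movement —
is orchestrated by neuropeptides and protein hormones secreted mainly from
the eyestalk's X-organ–sinus gland complex and the brain. These molecules
are translated as **prepro-peptides**: a signal peptide, then one or more
peptide cargoes separated by basic cleavage sites. Given an assembled
(unoriented, possibly fragmentary) nucleotide transcriptome, npmine
reconstructs that processing chain and quantifies the results:

- **ORF calling** in all six frames with completeness classes
  (`complete`, `partial_nterm`, `partial_cterm`, `partial_both`);
- **signal peptides** via a transparent von Heijne style heuristic
  (hydrophobic core + (−3,−1) small-residue rule), or external annotations;
- **maturation**: prohormone-convertase cleavage at dibasic sites
  (KR/RK/KK/RR, monobasic R opt-in), carboxypeptidase trimming,
  C-terminal amidation at exposed glycines (`-Gly-Lys-Arg` → `-NH2`),
  pyroglutamate flagging;
- **family classification** by mature-peptide motifs (YXFGLamide,
  W-X6-Wamide, NFDEID…, FxGxRamide, GH[ML]RFamide, …), cysteine scaffolds
  (e.g. the 6-cysteine, 71–74 aa CHH/MIH superfamily domain) and annotation
  keywords, with explicit precedence and recorded ambiguity;
- **conservation**: Needleman–Wunsch global alignment and percent identity,
  strict consensus motifs, identity-distance neighbor-joining trees
  (newick output);
- **expression**: RPKM (`counts · 10^9 / (length · library)`) and a
  per-transcript eyestalk-vs-brain one-way ANOVA (p < 0.05);
- a **synthetic-data generator** producing ground-truthed precursor
  proteins, transcripts and negative-binomial count matrices, so the whole
  pipeline is testable without downloads.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_precursor_map()` figures.

## Worked example

Rebuild a type-A allatostatin precursor from its packaged printed mature
peptides, then recover those peptides through the full processing model:

```r
library(npmine)

built <- precursor_from_table("Allatostatin A")   # 22 printed peptides
pep <- process_precursor(built$protein)            # heuristic signal, dibasic grammar
pep
#> Mature peptides (22) from a 275-aa precursor (signal 27 aa, heuristic)
#> # A tibble: 22 x 7
#>   raw_segment sequence amidated pyroglutamate start_aa end_aa trailing_motif
#>   <chr>       <chr>    <lgl>    <lgl>            <int>  <int> <chr>
#> 1 HNNYAFGLGKR HNNYAFGL TRUE     FALSE               28     35 KR
#> 2 TPDYAFGLGKR TPDYAFGL TRUE     FALSE               39     46 KR
#> 3 EGMYSFGLGKR EGMYSFGL TRUE     FALSE               50     57 KR
#> # ...
```

All 22 mature peptides match the printed table, with amidation called from
the glycine exposed before each KR site. Conservation of the two pigment
dispersing hormone isoforms:

```r
global_align("NAELINSILGLPKVMNDA", "NAELINSLLGIPKVMSDA")
#> NAELINSILGLPKVMNDA
#> ||||||| || |||| ||
#> NAELINSLLGIPKVMSDA
#> score 15, 15/18 identical (83.3%)

consensus_motif(c("NAELINSILGLPKVMNDA", "NAELINSLLGIPKVMSDA"), amidated = TRUE)
#> NAELINSXLGXPKVMXDAamide  (2 members, 15/18 invariant columns)
```

15 of 18 residues are identical; the consensus spells out only invariant
columns. And a tissue contrast on the packaged RPKM table (red pigment
concentrating hormone):

```r
t3 <- load_study_tables("table3")
rpch <- t3[t3$transcript == ">Unigene2547_All", ]
long <- tibble::tibble(
  transcript_id = "RPCH",
  tissue = c("brain", "brain", "eyestalk", "eyestalk"),
  sex = c("M", "F", "M", "F"),
  rpkm = unlist(rpch[, c("m_br", "f_br", "m_es", "f_es")]))
tissue_contrast(long)
#> Eyestalk vs brain contrast (alpha = 0.05): 1/1 significant
#> # A tibble: 1 x 5
#>   transcript_id brain_mean eyestalk_mean p_value significant
#>   <chr>              <dbl>         <dbl>   <dbl> <lgl>
#> 1 RPCH                14.0          50.5 0.00453 TRUE
```

RPCH is ~3.6× higher in the eyestalk (means 14.03 vs 50.48 RPKM) and the
n = 2 vs 2 ANOVA calls it significant. For an end-to-end run over a FASTA
plus optional annotation/count tables, see `pipeline_config()` and
`run_pipeline()`, which write TSV/GFF3 reports plus a reproducibility
manifest.

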
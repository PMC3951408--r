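# nmdscreen

Screen spliced human transcripts for immunity to nonsense-mediated mRNA
decay (NMD) and predict polycistronic transcript candidates.

## The problem and who this is for

Most eukaryotic mRNAs are monocistronic; the few known mammalian
polycistronic transcripts (LASS1–GDF1, SNURF–SNRPN, MFRP–C1QTNF5,
MTPN–LUZP6) share a striking property: although their upstream CDS ends far
from the 3' end — an arrangement that normally triggers NMD — the
transcripts are stable, because translation of *all* of their functional
ORFs jointly removes every exon-junction complex (EJC) deposited during
splicing. `nmdscreen` implements that observation as a screening method for
transcriptomics researchers: classify transcripts by the 55-nucleotide
rule, find ORFs whose translation would rescue an NMD-eliciting transcript,
and score the rescuers as potential functional cistrons.

## The rule at the core

Let `j_term` be the spliced coordinate of the last nucleotide of the
penultimate exon (the terminal exon–exon junction) and `stop` the 3'-most
nucleotide of the annotated stop codon. The classic rule:

```
NMD-eliciting  ⇔  j_term − stop > 55 nt
```

Stops in the terminal exon or within 55 nt of `j_term` are NMD-immune. An
ORF `[s, e]` *neutralizes* the EJC at junction `j` when

```
s ≤ j  and  e ≥ j − 55
```

i.e. the ribosome reads across the junction or terminates inside the 55-nt
immunity window. A *rescuing unit* is a minimal set of 3'-UTR ORFs that
jointly neutralize every junction left uncovered by the annotated CDS. The
same window, applied to the 5' UTR with a scanning 43S complex that strips
EJCs up to the first AUG it meets, classifies upstream-ORF architectures as
NMD-immune or NMD-eliciting. Candidate functional ORFs are then filtered by
minimal Kozak context (purine at −3), nucleotide self-similarity to the
host gene's CDS (e ≤ 1e−6 and coverage ≥ 50% discards), and protein
evidence (positives ratio > 0.5 or alignment ratio > 0.8, or a protein
domain other than signal peptide / transmembrane).

All coordinates are 1-based inclusive on the spliced mRNA; ORF intervals
include the stop codon (the interval `74..184` has length 111 nt).

## Worked example

```r
library(nmdscreen)

tx  <- make_transcripts(n_per_label = 5, seed = 2026)  # 45 labeled fixtures
scr <- screen_pipeline(tx)
scr
#> <nmd_screen> 45 transcripts, 20 candidate ORFs
#> # A tibble: 12 × 2
#>    stage                         n
#>    <chr>                     <int>
#>  1 input                        45
#>  2 classic_eliciting            15
#>  3 rescued_transcripts          10
#>  4 rescue_orfs                  15
#>  5 atg_downstream_exon1         15
#>  6 five_prime_no_uorf            5
#>  7 five_prime_uorf_immune        5
#>  8 five_prime_uorf_eliciting     5
#>  9 uorf_candidates_long          5
#> 10 similarity_keep              20
#> 11 kozak_positive               12
#> 12 final_candidates              0
```

Reading the funnel: of 45 transcripts, 15 elicit NMD under the classic
rule; 10 of them carry rescuing units (15 rescuing ORFs — the
`MULTI_ORF_RESCUE` fixtures need two ORFs each). On the 5' side, 15
transcripts have their annotated ATG downstream of exon 1, split evenly
into no-uORF, uORF-immune and uORF-eliciting architectures; 5 uORFs pass
the >99-nt functional-length filter. `final_candidates` is 0 because no
similarity/protein/domain evidence tables were supplied — the combined
verdict requires positive protein or domain evidence.

```r
head(tidy(scr)[, 1:7], 3)
#> # A tibble: 3 × 7
#>   id                         start   end length frame kozak branch
#>   <chr>                      <int> <int>  <int> <int> <lgl> <chr>
#> 1 SYN_BICISTRONIC_3PRIME_001   256   351     96     0 TRUE  3UTR
#> 2 SYN_BICISTRONIC_3PRIME_002   311   394     84     1 TRUE  3UTR
#> 3 SYN_BICISTRONIC_3PRIME_003   345   425     81     2 TRUE  3UTR
```

Each candidate row is one ORF: its spliced interval, reading frame, Kozak
verdict and branch (3'-UTR rescuer or 5'-UTR functional uORF).
`glance(scr)` gives the funnel in one row, `autoplot(scr)` draws it, and
`plot_transcript_map(tx[1, ])` draws a single transcript's architecture.

Expression-based validation (GINI: compare expression with and without NMD
inhibition; substrates rise when decay is blocked):

```r
sim <- make_expression(n_probes = 100, n_sensitive = 20, fold_change = 4,
                       n_per_arm = 6, seed = 1)
verdicts <- gini_verdicts(sim$expr, sim$groups)   # Welch t-test per probe
table(verdicts$verdict)
```

A thin command-line wrapper is installed at `inst/cli/nmdscreen`
(subcommands `screen`, `census`, `rescue`, `classify5`, `gini`,
`tis-match`, `fixtures`), writing the same tables file-to-file.

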
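---
title: "Screening transcripts for NMD immunity and polycistronic architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening transcripts for NMD immunity and polycistronic architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdscreen)
```

## The model

During splicing an exon-junction complex (EJC) is deposited roughly 20–24
nt upstream of each exon–exon junction. In the pioneer round of
translation the ribosome strips the EJCs it traverses; any EJC left
downstream of the termination site marks the transcript for
nonsense-mediated decay (NMD). Operationally this is the 55-nucleotide
rule: a stop codon whose 3'-most nucleotide lies more than 55 nt upstream
of the terminal exon–exon junction elicits NMD; stops in the terminal exon
or within the window are immune.

The screening idea implemented here is that *functional polycistronic
transcripts are NMD-immune as an emergent property of all their CDSs*: a
transcript whose annotated CDS alone would elicit NMD, but which carries
additional ORFs whose translation neutralizes the remaining EJCs, is a
polycistronic candidate. The package therefore provides:

1. `classify_classic()` — the 55-nt rule on the annotated stop.
2. `find_rescue_units()` — minimal sets of 3'-UTR ORFs that jointly
   neutralize every junction the CDS leaves uncovered (`neutralizes()`:
   an ORF `[s, e]` covers junction `j` iff `s ≤ j` and `e ≥ j − 55`).
   When several ORFs are jointly required they are reported as one unit.
3. `classify_five_prime()` — the rule extended to the 5' UTR: the
   scanning 43S complex removes every EJC up to the first AUG, so only
   junctions between the first uORF's end and the annotated ATG matter.
4. `screen_pipeline()` — orchestration plus the candidate filters:
   minimal Kozak context (purine at −3), nucleotide self-similarity
   against the host gene's own CDS, protein-evidence ratios and
   domain-evidence sufficiency.
5. `gini_verdicts()` / `match_tis()` — the two validation procedures:
   expression comparisons under NMD inhibition, and matching of predicted
   initiation sites against an experimentally mapped TIS table.

## Assumptions and deliberate exclusions

* ORFs are AUG-initiated. Non-AUG initiation (documented for LUZP6) and
  IRES-driven initiation are not modeled; IRES prediction from sequence is
  unreliable and is deliberately out of scope.
* An ORF starting downstream of a junction never neutralizes it. Ribosome
  footprints suggest an initiating ribosome may shield a region downstream
  of a junction, but the distance range is not established, so the
  predicate stays a pure upstream-window test.
* Post-termination 40S scanning (reported up to 600 nt) is not modeled —
  it cannot currently be parameterized from sequence. Junctions between
  uORFs are only neutralized by translation.
* The EJC deposition offset (20–24 nt) is rationale, not part of the
  operative rule; the window is exactly 55 nt.
* Re-initiation potential cannot be judged from sequence, so transcripts
  whose annotated ATG shares exon 1 with any upstream ORF are reported as
  their own class (`ATG_IN_FIRST_EXON`) rather than classified further.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `threshold` | 55 nt | immunity window upstream of a junction |
| `comparator` | `"gt"` | strict `>` on the stop-to-junction distance |
| `min_rescue_orf_length` | 6 nt | 3'-UTR rescuers: any AUG–stop pair counts |
| `min_uorf_length` | 99 nt (strict `>`) | functional 5'-UTR candidates |
| `evalue_max`, `min_coverage` | 1e−6, 0.5 | self-similarity discard bounds |
| `min_positive_ratio`, `min_align_ratio` | 0.5, 0.8 | protein-evidence ratios |
| `alpha` | 0.05 | expression-verdict significance level |

Two comparator choices deserve a note. The operative definition of the
55-nt rule is strict (`distance > 55` elicits), but descriptions of the
same screen sometimes read as `≥`; both are supported and `"gt"` is the
default. Similarly the functional-uORF length filter is strict (`> 99 nt`)
by default — a 99-nt ORF is excluded — with a `"ge"` override
(`screen_config(uorf_comparator = "ge")`), because published candidate
tables contain one 99-nt entry and the ambiguity cannot be resolved from
the sources; the package documents rather than resolves it.

For multi-ORF rescue units the default semantics are per-junction
neutralization (every uncovered junction must be neutralized by at least
one member), which reproduces the minimal single-ORF case for a stop in
the penultimate exon. A stricter continuous-interval reading — members
must chain within the 55-nt window — is available via
`screen_config(coverage_rule = "interval")`.

Coordinates are 1-based inclusive on the spliced mRNA throughout, and ORF
intervals include the stop codon (74..184 → 111 nt); BED export shifts to
0-based half-open. Codons containing `N` are conservatively treated as
neither start nor stop.

## What the synthetic generator emulates

`make_transcript()` plants nine architecture classes by construction:
single-exon immune, classic PTC, bicistronic-like 3'-UTR rescue (one ORF),
multi-ORF rescue (two ORFs, one unit), stop 45 nt before the terminal
junction (the SNURF distance), ATG in exon 1, empty 5' UTR, uORF-immune
and uORF-eliciting 5' architectures. Exon lengths are drawn from a
100–300 nt palette so junction windows are exercised on both sides of
55 nt. Random fill is kept free of stray AUGs by point substitution
(rejection-style), planted ORF bodies contain no internal start or stop,
and every emitted transcript is re-checked by running the package's own
classifiers on it (`predict_architecture()`); generation aborts for
infeasible exon partitions.

What the fixtures do *not* emulate: real RefSeq length and GC
distributions, N-containing sequences at scale, alternative isoforms of
one gene, annotation errors, or read-level noise. Passing the
planted-label recovery test shows the algorithms implement the stated
rules exactly; it does not show how often real annotations satisfy them.

`make_expression()` emulates a GINI comparison: log-normal intensities
(`meanlog` 6, `sdlog` 0.25 on the natural-log scale; baselines vary per
probe), `n_per_arm` 4 by default, with the inhibited arm of sensitive
probes multiplied by a fold change. These values were fixed once by a
design-time power analysis: at `sdlog` 0.25 the verdicts reach essentially
full sensitivity at fold-change 4 with 6 samples per arm, and roughly 87%
at fold-change 2 with 4 per arm, while keeping intensities in a realistic
microarray range.

## Numerical and statistical choices

* Expression verdicts are computed on log2 intensities by default
  (standard microarray practice; the scale is recorded in the verdict
  table, and `scale = "as_is"` is available since the original analyses
  do not state their scale).
* The Welch test is `stats::t.test(var.equal = FALSE)`; the test suite
  checks it against a hand-coded Welch–Satterthwaite formula. At n = 4
  per arm the test is mildly conservative: the empirical rate of
  `p < 0.05` under the null is about 0.04, which is what the calibration
  check measures (a two-sided rejection, in either direction, of the
  insensitive verdict).
* A *sensitive* verdict additionally requires the stabilization direction
  (mean increase under inhibition); a significant decrease is reported as
  `INCONCLUSIVE`, since it contradicts the NMD mechanism.
* Rescue units are minimal by set inclusion; enumeration is capped at
  `max_unit_size` (default 3) members, and output order is deterministic
  (smallest total ORF length, then 5'-most start).
* Probes not uniquely identifying their gene are excluded from verdicts
  but listed (`excluded = TRUE`), mirroring the probe-selection rule of
  GINI reanalyses.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run entirely on generated data:
brute-force ORF-scanner cross-checks on 200 random sequences up to 2 kb,
planted-label recovery on 900 fixtures (100 per class), type-I calibration
on 2000 null probes and power on 400 sensitive probes. These sizes give
tight Monte-Carlo error while keeping a full run within a few minutes on
one CPU.

## Known limitations

* GenBank parsing covers RefSeq-style flat files with transcript-space
  `exon` and `CDS` features; records without exon features are discarded
  (counted in the filter report), never inferred.
* Evidence tables (nucleotide/protein hits, domains) must be supplied by
  a backend of the user's choice; the package never runs an aligner or a
  domain scanner, because those results depend on database versions and
  are not reproducible offline.
* The screen classifies architectures; it does not model NMD efficiency
  (a sizable fraction of PTC-containing transcripts escape decay), decay
  branches independent of EJCs, or re-initiation kinetics.

## A small end-to-end run

```{r example}
tx <- make_transcripts(n_per_label = 3, seed = 7)
scr <- screen_pipeline(tx)
glance(scr)
head(tidy(scr), 3)
```
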
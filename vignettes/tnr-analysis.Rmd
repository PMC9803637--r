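---
title: "Repeat tracts, TNR gene catalogs, enrichment, RISC profiles and hairpin stems"
author: "tnrtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat tracts, TNR gene catalogs, enrichment, RISC profiles and hairpin stems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnrtools)
```

## Background

Expanded CAG trinucleotide repeats (TNRs) in *HTT* and *AR* transcripts fold
into hairpins whose base-paired stems are Dicer substrates. Dicer releases
21–22 nt CAG-repeat RNAs (sCAGs) that load into the RNA-induced silencing
complex (RISC) and silence genes carrying complementary CUG tracts, so repeat
toxicity can propagate through RNA interference. Four computational questions
recur in studying this mechanism, and this package implements each as a
tested, reusable module:

1. Which sequencing reads carry perfect CAG-family repeat tracts, and how
   long are they? (`longest_repeat_tract()`, `classify_reads()`,
   `count_pure_repeat_reads()`)
2. Which genes contain CUG/CAG tracts of at least *n* nt in their mRNA, for
   a ladder of thresholds? (`stitch_gene_models()`,
   `build_gene_set_family()`)
3. Are those gene sets enriched among downregulated genes in a ranked
   differential-expression list? (`enrichment_score()`,
   `permutation_test()`, `run_family()`)
4. How stable are repeat-variant hairpins and how long are their
   uninterrupted CAG stems; and what do the Dicer products bound to the RISC
   look like? (`fold()`, `longest_uninterrupted_cag_stem()`,
   `profile_library()`)

A seeded synthetic-data generator (`synth_*`) produces inputs with known
planted truth for every stage, so the whole pipeline is testable without any
sequencing download.

## Repeat tracts

A *tract* is a maximal substring that matches a window of the infinite
repetition of a triplet unit, at any of the three phases. This definition is
deliberately nucleotide-denominated: a 10-nt tract such as `GCAGCAGCAG`
counts even though 10 is not a multiple of 3, which is what lets read classes
run over every integer length. Consequences worth knowing:

* Tract length is invariant under rotation of the unit (`CAG`, `AGC`, `GCA`
  describe the same tracts; only the reported phase differs).
* A single `CAG` followed by `CA` is a 5-nt tract — the window extends as
  far as the periodic pattern does, not to unit boundaries.
* `N` never matches, so an `N` inside a repeat splits it; this is the
  conservative choice (noise can only shorten tracts, never lengthen them).

```{r tract}
longest_repeat_tract("UUGCAGCAGCAGCUU", "CAG")
```

`classify_reads()` bins each read once, at its longest tract length clamped
to `max_len`, so class totals plus the unclassified tally equal the input
count exactly — an invariant the tests check on every fixture.
T/U normalization happens at ingest and matching runs on a single (DNA)
alphabet. Pure-repeat counting (`count_pure_repeat_reads()`) is stricter by
design: the whole read must equal a phase-0 prefix of one rotation, so each
read matches at most one of `CAG`/`AGC`/`GCA`.

## TNR gene catalogs

`stitch_gene_models()` reduces per-gene transcript regions to one mRNA proxy:
the longest deposited 5'UTR, ORF and 3'UTR are concatenated in that order.
Length ties between candidate regions are broken lexicographically and
logged; this is a convention, chosen for determinism, not biology. Tract
matching then runs on the stitched sequence, so tracts spanning a region
junction are counted — the tests plant split tracts to pin this behavior.
Set membership at threshold *n* means "longest unit tract ≥ *n* nt", using
the same tract definition as the read scanner, so the families are nested by
construction. CUG sets are matched against the mRNA sense sequence, since
the question is which mRNAs contain CUG tracts that sCAGs could target.

Input is a generic region table or FASTA (`gene|kind` headers), not a live
Ensembl query: catalogs must be buildable and testable offline; a fetch
script can produce the region file but is not part of the tested surface.

## Preranked enrichment

The enrichment statistic is the weighted Kolmogorov–Smirnov running sum over
a descending log-fold-change ranking: hits advance the sum by
$|s_i|^p / \sum_{hits} |s|^p$, misses retreat it by $1/(N-m)$, and the
enrichment score (ES) is the signed maximum deviation. Choices and their
reasons:

* **Weight $p = 1$** — the conventional "weighted" setting; with $p = 0$ the
  statistic collapses to the classical KS form.
* **Gene-label permutations** — the input is a preranked list, so phenotype
  permutation is impossible; the null re-draws random member sets of the
  same size without replacement. 1000 permutations is the default.
* **Sign-restricted normalization** — NES divides ES by the mean |null ES|
  of the same sign; the nominal p compares against same-sign nulls only,
  with a +1 correction so p is never 0 and is floored at $1/(n_{perm}+1)$.
  These are the conventions of the original GSEA implementation, restated
  here explicitly so results are reproducible without reference to any
  particular GSEA release. The p is *nominal*; no FDR across collections is
  computed.
* **Tie handling** — ranking ties break by gene id (deterministic); an exact
  magnitude tie between the positive and negative running-sum extremes
  (possible at rational values like $m/(N-m)$) resolves to the positive
  extreme, with a $10^{-12}$ tolerance so floating-point summation order
  cannot flip the sign.

The implementation is validated three ways: a literal loop-wise evaluation
of the running-sum definition (to $10^{-12}$ on hundreds of random
instances), an independent library implementation of the same statistic
(`fgsea::calcGseaStat`) as a cross-check, and calibration simulations —
type-I error within [0.03, 0.07] at $\alpha = 0.05$ over 500 null lists, and
≥95% power against a planted shift of −2 SD on a 100-gene set in a
2000-gene list.

```{r gsea}
sim <- synth_ranked_list(n_genes = 500, set_size = 40, effect_size = -1.5,
                         seed = 11)
permutation_test(sim$ranked, sim$target_set, n_perm = 199, seed = 12)
```

## RISC-bound read groups

Reads from Argonaute pulldowns are partitioned by 19-mer content: group 1
contains any rotation of `(CAG)n` written as a 19-mer, group 2 any rotation
of `(CCG)n`, group 3 everything else. Reads matching both groups (possible
for fragments spanning a CAG/CCG junction) go to group 1, and the ambiguous
tally is reported so the precedence choice stays auditable. Normalization is
reads-per-million of the total library — the field convention — which
preserves between-library group ratios exactly. Per-group length histograms
and species tables (distinct sequences with counts) support the
Dicer-product questions: are products 21–22 nt, and does each length carry a
single 5'-phase-defined species?

## Hairpin structure

Folding is a narrow contract to ViennaRNA's `RNAfold`: sequence and options
in, dot-bracket and MFE out. The package never re-implements the
nearest-neighbor energy model. Settings mirror the structure-prediction
protocol used for repeat hairpins: Turner-1999 parameters, no isolated
pairs (`--noLP`), dangling energies on both sides in any case
(`--dangles=2`); the engine name and version are recorded in every result.
SHAPE slope/intercept (1.9, 0.7) are stored in `fold_settings()` for
fidelity but never applied — there is no reactivity data to apply them to.
When co-optimal MFE structures exist the engine's canonical choice is
reported as-is.

The stem metric is triplet-denominated: `stem_segments()` partitions the
pair table into runs where consecutive pairs differ by at most 2 on each
arm — i.e. helices interrupted only by 1×1 interior loops, which is exactly
how the central A·A mismatch of CAG:CAG self-pairing renders in dot-bracket
output. Anything larger (bulges, multiloops) splits a segment. A CAG unit
counts for a segment only when both its C and its G are paired within that
segment; half-paired triplets never count. This operationalizes
"uninterrupted double-stranded CAG repeats" as a reproducible rule. Where a
published stem count disagrees with this convention the discrepancy is
reported (`htt_stem_report()`), never silently reconciled.

```{r fold, eval = FALSE}
compare_variants(hairpin_oligos()[c("Ref_HP", "LOI_HP")])
```

The huntingtin repeat-region constructs are built from their printed
formulas: `(CAG)40-CAA-CAG-CCG-CCA-(CCG)7` for the reference allele and the
two-substitution `(CAG)40-CAG-CAG-CCG-CCG-(CCG)7` loss-of-inhibition (LOI)
variant. The 15-nt genomic flanks used for full-construct folding are a user
input: they are genomic context, not part of the repeat region, and are not
bundled. Tests exercise the full-construct path with a clearly synthetic
flank and assert only the allele *orderings* (LOI more stable, longer CAG
stem), which hold for the flankless printed oligos as well.

## The synthetic-data generator

Every generator takes a mandatory seed and is bit-reproducible; none
disturbs the caller's RNG state. Design points:

* **Plantings are verified, not probabilistic.** After composing a read or
  transcript around a planted tract, the generator re-scans it with the
  production scanner and resamples until the longest tract equals the
  planted length exactly. Truth tables are therefore exact oracles, immune
  to a random background extending a planted repeat.
* **Backgrounds are bounded.** Background genes carry no tract ≥ 10 nt and
  background reads none ≥ 8 nt, so they can never collide with catalog
  thresholds (10–19 nt) or the long-read listing threshold (8 nt).
* **The error model is substitution-only.** A per-base substitution rate
  applied after verification (truth recorded pre-noise) is enough to emulate
  the poor sequencing fidelity of repeat oligos; indels and ligation or
  adapter biases are out of scope.
* **RISC libraries emulate Dicer products**: 21–22 nt, a fixed 5' phase
  (`AGC` by default) for CAG-phase products, a small constant CCG-phase
  fraction, and a per-construct abundance factor (default LOI:Ref = 4:1,
  the contrast of interest) against a random background. Equal library
  depths mean per-million normalization recovers the abundance ratio.

What the generator does *not* emulate — alignment artifacts, gene
attribution of reads, adapter chemistry, real expression covariance —
bounds what passing tests show: they validate the computations, not the
upstream sequencing.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 1000 random sequences per
brute-force oracle comparison; 500 null lists (N = 500, |set| = 50, 999
permutations) for type-I calibration; 100 replicates (N = 2000, |set| = 100,
1000 permutations) for power; a 1000-gene transcriptome with 20 genes per
tract-length bin for the enrichment-trend check; and two 50,000-read
libraries for abundance-ratio recovery. These sizes keep each property's
Monte-Carlo error well inside its acceptance band while the full suite runs
in about a minute.

## Known limitations

* Reads are attributed to tracts, not to genes; alignment is out of scope.
* Nominal enrichment p-values only; no FDR, no leading-edge extraction.
* The stem-counting convention is declared, not derived; other reasonable
  conventions (e.g. tolerating 2×2 loops) would give different counts.
* Pseudoknots and partition-function ensembles are outside the folding
  contract.
* When several scanned units could classify a read, each unit scan is
  independent; no cross-unit precedence is defined.
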
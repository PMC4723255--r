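---
title: "Methods: two-variety RAD-seq marker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-variety RAD-seq marker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
library(radmarker)
```

## The problem

Marker-assisted selection needs many reliable DNA polymorphisms between
two parental varieties. RAD-seq provides them cheaply: the genome is cut
with a restriction enzyme, fragments in a size window are sequenced, and
only the neighbourhoods of cut sites are covered — at depths high enough
for confident count-based genotyping. `radmarker` implements the
computation from raw reads (quality filtering), through per-sample
pileup-based variant detection, to two-sample marker discovery and gene
model annotation. Alignment itself is delegated to external tools
(BWA/SAMtools); the package's entry point after filtering is samtools
pileup text.

## Models and rules

### Read filtering

Reads are trimmed from both ends by removing terminal runs of bases
below `trim_end_quality` (default Q20); interior low-quality bases are
kept, because end-degradation is the dominant Illumina failure mode.
Reads with fewer than `min_length_after_trim` (50) bases are dropped.
A read is then discarded when the fraction of its bases under a quality
cutoff exceeds a percentage — strict: (Q<10, 7%), (Q<13, 7%),
(Q<20, 15%); moderate: (10%, 14%, 20%); relax: (Q<10, 15%), (Q<13, 20%);
or never ("NotFilter"). Both comparisons are strict inequalities: a read
at exactly the boundary percentage is kept, and a base at exactly the
cutoff quality does not count against it. The boundary convention is not
externally documented for the original tool; it is fixed here, exposed
in tests, and matters only for reads exactly at a boundary.

The retention rule is read as *at least* 50 bp after trimming: the
alternative reading (at most 50 bp) would keep only the most degraded
reads and contradicts universal RAD practice. Paired mates are filtered
independently. N bases are governed by their quality alone.

### In-silico digestion

`find_sites()` scans the forward strand for every (overlapping)
occurrence of the recognition sequence; for palindromic sites such as
TaqαI's TCGA this covers both strands exactly. Cut coordinates are
0-based positions of the base after the cut (TCGA with `cut_offset`
1 models T/CGA). Fragments are the intervals between consecutive cuts;
chromosome-terminal pieces are excluded from yield counts by default
because they carry only one ligatable end (`include_terminal = TRUE`
restores them — `digest_convention_grid()` reports all conventions,
since published fragment counts rarely state theirs). Window bounds are
inclusive. Runs of N break matching but still contribute to fragment
length.

### Pileup decoding

The samtools bases column is decoded with the standard conventions
(`.`/`,` match, letters mismatch, `^X` read start, `$` read end,
`+n<seq>`/`-n<seq>` indels attached to the preceding observation, `*`,
`>`, `<`, N skipped). One deliberate bookkeeping choice: an indel event
rides on a read observation whose base still matches the reference at
the anchor, so indel allele counts sit *on top of* the base-level
decomposition and the conservation invariant is
`n_ref + mismatches + skipped == depth`. The dominant non-reference
allele at a site is the most frequent one; ties prefer SNP bases
(A,C,G,T order) over indel alleles, then lexicographic keys — the
original tool does not define multi-allelic handling, and a
deterministic rule is required for reproducible output. Base qualities
are parsed but unused by default (the detection rules are count-based);
`min_base_q` optionally masks low-quality observations as skipped.

### Calling thresholds

A site is called when all four conditions hold: depth ≥ 3, mutant reads
≥ 3 ("more than 2"), mutant ratio strictly above 0.20, and mutant ratio
at or above `hetero_prop_level` (default 0.3) — the minimum mutant
proportion for a candidate heterozygous site; it is read as an inclusive
calling floor because it exists to *capture* candidate sites. Sites with
ratio ≥ `homo_prop_level` (0.8) are genotyped HOM, otherwise HET; 0.8 is
a pragmatic convention (not a constant of the original pipeline) and is
exposed as a parameter. Indels are reported VCF-style at the anchored
base, so identical events from different reads collapse to one call; one
call (the dominant allele) is emitted per position.

### Two-sample comparison and post-filters

A marker is a position where the treat sample yields a call and the
control sample is clean reference: depth ≥ 10, mutant reads < 2 and
mutant ratio < 4% (all non-reference evidence — mismatches and indels —
counts as mutant here). Both directions are run and merged. Positions
absent from the control pileup are *not* emitted: absence of coverage is
not evidence of a clean genotype. Two post-filters follow: (1) treat
depth ≥ 8 and **zero** mutant reads in the control — "none in the
other" is read as zero mutant reads, since zero *coverage* would
contradict the ≥ 10-read control rule; (2) any two surviving markers
closer than 10 bp are both removed, chains entirely — closely spaced
calls usually betray a local misalignment, so the whole cluster is
distrusted rather than thinned. The spacing rule is applied after
merging directions and across variant types.

### Annotation

Each variant receives exactly one region label with precedence
CDS > 5'UTR exon > 3'UTR exon > intron (gene body) > TSS window
(±1000 bp) > TTS window (±500 bp) > intergenic. Windows are strand
aware. Precedence is a package decision (the original figures show
disjoint categories without defining ties); gene body beats another
gene's flanking window. For a coding SNP the reference codon is
extracted via strand and frame and both codons are translated with the
standard genetic code: synonymous, nonsynonymous, stop-gain or
stop-loss. Start-codon changes are assessed as plain codon changes (no
alternative-initiator rescue). When transcripts overlap, the most
severe effect wins, ties to the lexicographically smallest transcript
id. InDels in CDS get effect `NA` — the synonymous/nonsynonymous
dichotomy is defined only for substitutions.

`select_linked_markers()` ranks markers near a target locus by
approximate genetic distance, converting physical distance at a
constant rate (default 4 cM/Mb, a typical rice genome-wide average). A
real genetic map would be better; none is bundled, and the
approximation is labelled in the output.

## The simulator: what it emulates, what it does not

`sim_spec()` defaults state the world the tests run in: 2 chromosomes ×
200 kb, GC 0.43, 20 genes, 100 divergent SNPs + 20 InDels (homozygous in
one variety each), mean depth 20×, per-base error 1%, variants ≥ 150 bp
apart, TaqαI sites planted every 500 bp. InDel lengths default to 52.8%
single-base, 31.2% at 2–5 bp and 0.27% above 22 bp — the spectrum
reported for inter-variety rice comparisons. Depth is Poisson per
position; errors are uniform wrong bases. Gene models are non-overlapping
with valid ATG...stop CDS on random strands.

Deliberately *not* modelled: RAD tag-structured coverage clumping
(depth here is position-independent), mapping error and multi-mapping,
PCR duplicates, quality-correlated errors, linked error haplotypes, and
polymorphisms inside restriction sites (allele dropout). A green
end-to-end test therefore establishes that the counting, thresholding,
comparison and annotation logic is exact — not that the thresholds are
well-calibrated against real alignment artefacts.

At these stated settings the clean-control rule has real attrition: at
20× a control site with a single error read has mutant ratio 5% > 4%,
so ~18% of planted sites are ineligible per run. Accuracy is therefore
evaluated against *eligible* sites — those whose realized simulated
counts satisfy every threshold, determined arithmetically from the
simulator's own bookkeeping, independent of the parsing/calling code
path. Expected precision and recall there are 1.0, and the acceptance
suite demands ≥ 0.98 over five seeds.

## Numerical and degenerate-input choices

* Sorting violations in pileup streams are errors naming the first
  offending position; chromosomes must form contiguous blocks.
* Declared pileup depth must equal the decoded observation count;
  mismatches are inconsistency errors with line numbers.
* Depth-0 sites have undefined mutant ratio (error on request, never
  silently 0 for calling).
* Fractions in annotation summaries sum to 1 within 1e-9; empty inputs
  yield empty tables, never division by zero.
* All randomness flows from explicit integer seeds; derived seeds stay
  below 2^31. Identical seeds give byte-identical FASTA/GFF3/pileup
  outputs.

## Known limitations

* No likelihood-based genotyping or base-quality modelling — fidelity
  to the count-based rules is the point.
* Only two-sample comparison; no joint population calling.
* Genetic distances are physical approximations.
* The published whole-genome digestion count (130,940 TaqαI fragments
  of 400–600 bp on rice MSU7) is verifiable only with the external
  genome; the acceptance test reports which terminal/bound convention
  reproduces it when the genome is supplied, and fails otherwise.
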
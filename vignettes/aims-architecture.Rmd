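---
title: "Replichore architecture, AIMS discovery, and constraints on gene transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replichore architecture, AIMS discovery, and constraints on gene transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimsarch)
```

## The model

Circular bacterial chromosomes are replicated bidirectionally from a
single origin, dividing the molecule into two replichores (arms). Each
position therefore has a well-defined leading strand: the Watson strand
on the arm where the fork travels in the increasing-coordinate
direction, the Crick strand on the other arm. Architecture IMparting
Sequences (AIMS) are degenerate octamers that (i) occur more often on
leading strands than lagging strands, and whose (ii) leading-strand
abundance and (iii) degree of strand bias both increase with proximity
to the replication terminus. Because such a gradient cannot be produced
by replication-associated mutation pressure alone, it is read as a
signature of selection on the octamers' orientation, strongest near the
terminus. Two consequences follow, and this package measures both:
arm-restricted inversions (which flip the polarity of every AIMS they
contain) should be rarer and smaller near the terminus, and
horizontally acquired DNA should persist near the terminus only when
its AIMS happen to sit predominantly in the permissive (leading-strand)
orientation.

All internal coordinates are 0-based half-open with strands encoded
+1/-1; GFF3 and TSV inputs (1-based inclusive) are converted at the
boundary. Circular arithmetic is modular throughout, so features and
k-mer windows may wrap the coordinate origin.

## Replication breakpoint inference

Breakpoints are found from the frame-specific pentamer composition of
protein-coding genes. For a candidate breakpoint pair, every CDS is
assigned to a putative leading or lagging class by its midpoint arm and
strand; within each class the conditional frequencies
$P(B_m \mid T_{ijkl})$ of the fifth base given the preceding tetramer
are tabulated per reading frame, and the score
$\Delta = \sum_r \sum_T \sum_B (f_{\mathrm{lead}} - f_{\mathrm{lag}})^2$
is maximized over candidate pairs. Candidates are intergenic midpoints:
a coarse pass over every 10th intergenic gap is followed by refinement
over all gaps within 5% of genome length of the coarse optimum, which
preserves the global optimum at gap resolution (the score surface is
smooth at the gap scale because moving a breakpoint by one gap
reassigns a single gene). A pseudocount of 1 per pentamer per frame
keeps the conditionals defined for unseen tetramers; at genomic scale
it is dominated by real counts. Genes spanning a candidate breakpoint
are classified by their midpoints. The two breakpoints are labelled so
that the origin maximizes the number of genes transcribed away from it;
an exact tie is flagged ambiguous. A flat score surface
(maximum below twice the median of the coarse profile) is flagged
low-confidence rather than silently returned. GC skew is deliberately
not used for inference — a windowed cumulative-skew diagnostic is
provided for comparison only — and predicted termini can be checked
against *dif*-site motif hits (`find_motif()`, default mismatch
tolerance 2 for the *dif* consensus, configurable).

## AIMS discovery and its null calibration

Candidate AIMS are all octamers degenerate at up to two positions over
the full IUPAC alphabet (configurable down to N-only). Rather than
scanning each of the ~15 million patterns, the package counts all
$4^8$ concrete octamers once per strand class and region
(`Biostrings::oligonucleotideFrequency` on arm-resolved chunks) and
aggregates degenerate patterns by contracting the count tensor with the
IUPAC membership matrix; this makes the full scan take seconds and is
verified in the tests against direct degenerate pattern matching.

Detection applies four criteria: genome-wide leading-strand bias of at
least 0.70; at least 96 leading-strand copies; terminus-region per-bp
leading-strand density at least 1.5 times the origin-region density
(densities, not raw counts, so unequal region sizes cannot masquerade
as enrichment); and terminus-region bias strictly above origin-region
bias. The terminus region is the terminus-proximal 25% of the genome
(±12.5% around *ter*) and the origin region the origin-proximal 60%
(±30% around *ori*); the remaining 15% buffers the two. How large a
bias increase to demand is genuinely open; strict inequality with a
configurable margin (default 0) is the least committal choice. Specificity is calibrated against null genomes built by
permuting 40 kb segments within each arm (10 kb available via
`segment_bp`; the two sizes are both in circulation and are not
silently reconciled), which preserves per-strand k-mer content while
destroying the origin-terminus gradient. An operating point is accepted
when genuine detections exceed the null mean at least 10-fold;
`calibrate_thresholds()` scans a grid and reports both the
most-abundant and most-strongly-graded qualifying points. Qualifying
octamers are clustered into families by shared concrete expansions or
overlapping 7-mer registers, and one representative per family (largest
abundance) is the recommended unit for downstream per-AIMS work.

## Inversions, insertions, and the loss estimator

Inversions between closely related genomes are detected on signed
circular permutations of shared single-copy orthologs: a maximal block
whose order is reversed and strands flipped, bridged on each side by
`flank_k = 2` syntenic genes (how much flanking synteny to demand is a
free parameter; two genes is the weakest setting that still rejects
translocations and xenologous insertions). Blocks whose span contains the origin or terminus of
either genome are discarded, as such inversions do not change AIMS
polarity; orthologs private to one genome are transparent. Midpoints
are expressed as percent distance from the terminus, averaged between
the two genomes, and identical gene content across comparisons is
counted once.

Foreign genes are those with no ortholog in any sister species nor in
any conspecific strain, and whose best conspecific homologue is below
40% similarity; requiring absence in at least two strains guards
against parallel loss. Consecutive foreign genes merge into one
insertion including intervening intergenic DNA. Within each insertion
the recipient's AIMS occurrences are enumerated and the permissive
(leading-strand) fraction recorded; insertions with no occurrence are
flagged and excluded from curves. The bias-versus-distance trend is fit
as a bounded decaying exponential $a e^{-d/b} + c$ with
`minpack.lm::nlsLM` ($a, c \in [0,1]$, $b > 0$) on length-weighted
2%-bin means (length weighting matches the cumulative-length
construction of the loss estimator; unweighted means are also
returned). The terminus-region loss compares insertions within 0–6% of
the terminus against 42–48% (the final 2% absorbs arm-length
inequality): the difference of the areas under the normalized
cumulative inserted-length curves, which is algebraically the
difference of length-weighted mean permissive fractions, plus a
two-sample Kolmogorov–Smirnov test on the per-fragment values.

## Compatibility

Compatibility of a donor genome for a given recipient is measured
without knowing the donor's replichore structure: each recipient AIMS
is counted on the two strands of 1000 random 10 kb donor fragments
(uniform with replacement, wrap-around permitted) and scored by the sup
statistic $\max(N_W, N_C)/(N_W+N_C) \in [0.5, 1]$; fragments with no
occurrence are excluded rather than scored 0.5, and their number is
reported so sparse AIMS are visible. The genome-level score
$C_{XY} = \sum_i \overline{SB}_i N_i / \sum_i N_i$ weights each AIMS by
its recipient abundance only — deliberately not by its recipient bias.
Note the sup statistic's small-count inflation: even a strand-neutral
donor scores above 0.5 (about 0.54–0.57 at typical densities), so
comparisons should always be relative.

## The Ter-site simulator

To ask whether sparse polar fork-arrest (Ter-like) sites could explain
the positional inversion gradient, the simulator draws inversions with
uniform midpoints on a 4.5 Mb genome's arms and log-uniform sizes on
[1 kb, 500 kb] (truncated to fit within the arm; an empirical size file
or a fixed size can be supplied instead), places Ter-like sites with
inter-site spacing growing linearly from the terminus (last spacing ten
times the first by default), and discards any inversion strictly
containing a site. Sites are re-placed per replicate, so each replicate
is an independent simulated genome and closed-form acceptance
expectations — $(1-\ell/L)^m$ for $m$ uniform sites and fixed size
$\ell$ — hold as expectations over placements. Boundary coincidence
does not reject, and site orientation is ignored.

## The synthetic-genome generator

The generator is the package's ground-truth harness. It emulates: a
circular chromosome of i.i.d. background at a chosen GC (order-0 by
design — every signal of interest is planted explicitly); genes laid
down at ~1.05 kb pitch, 75% on the leading strand, with codons drawn
from two strand-class frequency vectors separated by a fixed ±25%
alternating perturbation (the source of the frame-specific pentamer
signal; 25% is a moderate, clearly detectable asymmetry chosen once);
and AIMS copies injected at positions drawn from a linear
origin-to-terminus density gradient with a linear leading-strand
probability gradient. The default plant density (0.45 to 1.8 copies
per 10 kb from origin to terminus, bias 0.75 to 0.95) gives roughly
450 copies and 380 leading copies per octamer on a 4 Mb genome with a
two-fold terminus density enrichment. These margins matter: an i.i.d.
4 Mb background contributes ~122 coincidental copies of every octamer
at zero bias, diluting the observed genome-wide bias of a planted
octamer; plants sized exactly at the detection thresholds would sit on
the threshold after dilution and be recovered erratically. Truth tables
record every injected copy, and recounts of the emitted sequence are
asserted at generation time.

`derive_sister()` adds point substitutions, reverses blocks of
consecutive genes within one arm (never spanning ori/ter, with
flanking-gene guard zones), and inserts novel gene runs carrying the
recipient's AIMS at a controlled permissive probability. It emits a
homology table consistent with construction, including two pseudo
conspecific strains, so the insertion caller can be exercised
end-to-end. What the generator does *not* emulate — real codon usage,
operon structure, mobile elements, compositional heterogeneity,
realistic indel evolution — bounds what green tests mean: they show the
estimators recover planted truth under the stated noise model, not that
real genomes satisfy the model.

## Numerical choices and degenerate inputs

Zero-denominator statistics (strand bias, permissive fraction,
fragment bias) are flagged undefined rather than imputed. The
exponential fit reports a null fit on non-convergence and an `NA`
$R^2$ on constant input. Region/arm chunked k-mer counting drops
windows spanning chunk junctions (at most 7 per junction for octamers);
the segment-shuffle conservation properties are asserted at that
tolerance. Candidate-pair scoring is a small C++ kernel; ties in
origin labelling fall back to leading-strand fraction, then the lower
coordinate, and are flagged. All stochastic operations accept explicit
seeds; the pipeline derives per-stage seeds from one global seed by a
fixed offset scheme and writes a manifest with parameters and output
checksums, so a rerun is byte-identical.

## Worked example

```{r example, eval = FALSE}
plants <- gradient_aims_plants(n = 8, a_ori = 0.9, a_ter = 3.6, seed = 1)
fix <- generate_genome(plant_spec(length = 1e6, aims_plants = plants),
                       seed = 1)
map <- find_breakpoints(fix$genome, fix$features)
aims <- identify_aims(fix$genome, map, n_null = 10, seed = 2)
aims$fold                      # genuine / mean null detections
reps <- aims_representatives(aims)
sis <- derive_sister(fix, n_inversions = 6, n_insertions = 20,
                     ins_aims = plants$octamer, seed = 3)
detect_inversions(fix$features, sis$features, fix$map, sis$map)
```

The problem sizes used throughout the package's own checks — 2 Mb
genomes for breakpoint recovery, one 4 Mb genome with 25 shuffled
replicates for AIMS calibration, $10^5$ draws per simulator
configuration — were chosen as the smallest scales at which the
planted effects are resolved with comfortable statistical margin.

## Known limitations

- The replichore model assumes a single circular chromosome with two
  arms; plasmids and multi-replicon genomes must be supplied as
  separate sequences.
- Breakpoint resolution is bounded by intergenic gap spacing and, more
  fundamentally, by the gene-midpoint class assignment.
- The Ter-site simulator's "fewer than 20 sites leave the positional
  distribution unchanged" expectation holds at coarse, figure-level
  resolution. A count-based two-sample test at $10^5$ draws resolves
  even the mild terminus-proximal depletion that ~19 gradient-placed
  sites impose on kb-to-100-kb inversions (near the terminus their
  spacing is ~20 kb, comparable to inversion sizes), so that
  equivalence should not be expected to survive arbitrary statistical
  power; the package's checks record this distinction explicitly.
- The sup-form fragment bias is upward-biased at low occurrence
  counts; compatibility scores are comparable across donors measured
  with the same fragment configuration, not absolute probabilities.
- NG86 synonymous site counting excludes mutational pathways through
  stop codons from both numerator and denominator; single-codon pairs
  can therefore saturate ($p_S \ge 3/4$) and are flagged rather than
  corrected.
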
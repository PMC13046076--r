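---
title: "Transcript-centric differential splicing with splicetide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcript-centric differential splicing with splicetide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicetide)
library(dplyr)
```

## The problem and the modelling stance

Long reads from direct RNA sequencing span whole mRNA molecules, so a
collapsed transcript model observes every splicing choice of a molecule
at once: its promoter, each donor and acceptor, every cassette exon or
retained intron, and its polyadenylation site. splicetide therefore
treats the *full-length transcript*, not the splice junction, as the unit
of analysis. Events are annotated structurally from the transcript
models; quantitative inference happens on whole-isoform usage
proportions within promoter groups; and each event inherits the usage
change of the transcripts that include or exclude it. This keeps the
quantitative scale coherent from raw molecule counts down to
domain-level consequences, and avoids the ambiguous junction-read
allocation that short-read PSI methods must resolve heuristically.

## Promoter and end-site clustering

Transcripts of a gene are clustered by transcription start site with a
greedy, anchored ±1 bp window: walking TSSs in ascending transcription
order, a TSS joins a cluster only if it lies within 1 bp of that
cluster's *founding* TSS, else it founds a new cluster. The anchored
rule (rather than transitive chaining) is a deliberate choice: it makes
clustering order-independent and deterministic, and with a 1 bp window
the two rules differ only for pathological ladders of TSSs spaced
exactly 1 bp apart. End sites are clustered identically. Fractional
positions place each cluster along the gene: 0.0 for the most upstream
(transcription sense), 1.0 for the most downstream, linear interpolation
in between, and 0.0 for singleton-cluster genes so downstream attributes
are always defined.

## The normalized coverage profile and event calling

For each promoter group, the per-base fraction of member transcripts
whose exons cover a position forms the coverage profile. With group
size $T$ every value is a multiple of $1/T$: constitutive exonic bases
are exactly 1.0 and fully intronic bases exactly 0.0. We interpret the
profile denominator as the group size; per-exon alternatives would break
the anchor that constitutive bases read 1.0. Extremum search is
plateau-aware (maximal constant runs), a peak's centre is its plateau
midpoint with ties broken toward the transcription start, and a valley's
intron interval is the contiguous run equal to its minimum — the natural
stopping rule for "expanding" a valley over flat coverage.

Event calling reads steps in this profile, always strand-aware:

* **ALT5 (donors).** A coverage drop in the transcription direction
  marks a position where one transcript's exon ends while another's
  continues. Positions inside intron intervals are skipped; positions
  within ±1 nt of an end-site cluster are excluded so that transcript
  termination is never misread as donor variation (the ±1 nt matches the
  clustering window).
* **ALT3 (acceptors).** From each peak centre the scan moves toward the
  transcription start and flags coverage step-ups; it skips intronic
  positions, stops at another peak or the group's most-upstream start
  (the spec of "the transcript start" is ambiguous when starts differ;
  we document and use the group's most upstream), and excludes positions
  within ±1 nt of a TSS cluster.
* **CE (cassette exons).** A peak of height below $1 - 1/(2T)$ flanked
  by valleys on both sides indicates partial inclusion; the events are
  the distinct *internal* member exons lying between the nearest
  flanking valleys, so mutually exclusive exon pairs yield one event
  each. The threshold $1/(2T)$ separates exactly-1.0 from $(T-1)/T$
  without floating-point tolerance games. First and last exons are
  excluded — their variation belongs to promoters and end sites.
* **IR (retained introns).** Called structurally (an intron of one
  transcript fully spanned by a continuous exon of another) and by
  coverage (a valley-derived intron interval with positive mean
  coverage). The two definitions can disagree for partial exon
  intrusions into an intron; both are computed and coverage-only calls
  are labelled `source = "coverage"` so the disagreement stays visible
  rather than being adjudicated silently.
* **ALT_PRO / ALT_END.** Downstream promoter and end clusters
  (fractional position > 0) are events contrasting their members with
  the most-proximal cluster.

Every within-group event records disjoint `including_ids` and
`excluding_ids`, and is only emitted when both are non-empty.

The caller is verified against an independently coded brute-force
oracle (naive per-base loops, structural inclusion/exclusion rules) on
an exhaustive family of two-transcript promoter groups over a boundary
grid, plus sampled three-transcript groups, and against two invariances:
reflect-and-flip-strand (the identical molecule — classes preserved at
mirrored coordinates) and uniform replication of the transcript set.
Compound fixtures show why the method is coverage-based *by design*:
for example, a donor falling exactly at the edge of a retained-intron
span is attributed to the retention event, not double-counted as donor
variation — a purely structural enumeration would count both.

## The Bayesian beta model for differential usage

Within each retained promoter group, per-sample transcript counts become
usage proportions (group total as denominator). Groups without a single
non-zero count in *both* conditions carry no comparative signal and are
dropped; a retained sample with a zero group total gets the
uninformative value $1/k$, which keeps the sample without biasing
direction. Proportions are clipped to $[0.001, 0.999]$ before modelling
so the beta likelihood never sees its boundaries.

Replicate proportions of each transcript are modelled per condition as
$y \sim \mathrm{Beta}(\alpha_c, \beta_c)$ with independent
$\alpha_c, \beta_c \sim \mathrm{Gamma}(\text{shape}=5,\ \text{scale}=1)$
priors — weakly informative regularisation that shrinks mean usage
toward 0.5 absent strong evidence, which matters at $n = 3$ replicates.
The likelihood is on clipped proportions (a beta model), with
per-condition shape parameters fit independently; no parameters are
shared across transcripts. Posterior sampling uses JAGS with, by
default, 2 chains × 2000 retained draws after 500 adaptation and 500
burn-in iterations; all transcripts are sampled in one joint model
(their parameters are independent, so this equals per-transcript fits
at one compilation cost). Chains are seeded deterministically from the
user seed and gated on a split-$\hat R$ < 1.1 convergence check per
usage parameter; non-convergent transcripts are excluded from calls
with a warning.

From the pooled draws of mean usage
$\mu_c = \alpha_c / (\alpha_c + \beta_c)$ we form
$\log_2(\mu_{\text{aged}} / \mu_{\text{young}})$, its 95% highest
posterior density interval (shortest window over the sorted draws,
verified against exhaustive search), and the posterior probability of a
usage increase in each direction (the fraction of draws on each side of
zero). A transcript is significantly differentially used iff the HPD
excludes zero *and* $\max(p_{\text{up}}, p_{\text{down}}) > 0.95$ —
both criteria, always.

## PS propagation and downstream summaries

The percent-spliced (PS) value of a transcript is the log2 fold-change
of its within-promoter usage; we take the posterior median as the
canonical point estimate so PS and significance come from the same
posterior, and also export the plug-in empirical ratio for comparison.
Each event then yields one record per member transcript, with role
`inclusion` or `exclusion`. Direction summaries count significant
up/down records per event class and role with a two-sided exact
binomial test at $p_0 = 0.5$; the degenerate zero-call case reports
p = 1 with a flag. Boundary analysis classes a transcript's TSS and TES
as proximal iff its cluster has fractional position 0.0 (a cluster-rank
rule; no arbitrary fraction cutoff) and tests
affected × proximal/distal 2×2 tables with Fisher's exact test,
Bonferroni-corrected over the boundary comparisons. "Unaffected"
transcripts — modelled but not significant — are the internal baseline
throughout.

## Coding consequences

The ORF annotation accepts externally supplied CDS intervals unchanged;
otherwise a deliberately simple stand-in predicts the longest
ATG-initiated reading frame ending in a stop codon. Stop codons are
classed by whether termination falls in the transcript's last exon.
Pfam-style domain hits in amino-acid coordinates are mapped through the
CDS to transcript and genomic intervals (lengths always conserved at
3× the amino-acid span). Events are tagged by CDS overlap, stop-codon
coverage, and domain body/start/stop alteration; site events
(zero-width boundary coordinates) count as their single junction base.
The domain-by-event matrix row-normalises per-domain class counts,
assigns each domain to the class with the largest share (ties broken by
the fixed class order ALT5, ALT3, CE, IR, ALT_END), and orders rows by
average-linkage hierarchical clustering of the normalized profiles.

## Contingency statistics

The statistics layer matches the conventions under which the reference
tables shipped with the package (see `study_contingency_tables()`)
reproduce exactly: Pearson chi-square with Yates continuity correction
iff the table is 2×2; sample cross-product odds ratios (not conditional
MLEs), with zero-cell ORs of 0 or infinity reported as-is; standardized
residuals $(O-E)/\sqrt{E(1-r)(1-c)}$ with $|{\cdot}| \ge 2$ flagged;
two-sided exact binomial imbalance tests under the minimum-likelihood
convention; Bonferroni adjustment as multiply-and-cap.

## The synthetic-data generator

`splice_sim_design()` fixes the study conditions the tests run under:
two conditions × three replicates, an expected depth of 200 molecules
per promoter group and sample, and shifted groups at usage 0.8 vs 0.2
(log2 odds shift of 2). Each promoter group realises exactly one
planned event as a minimal transcript contrast (e.g. a cassette exon is
two identical chains ± the middle exon), with exon lengths drawn
uniformly from 100–300 nt and introns from 200–1000 nt — desk-scale
geometry chosen once as plausible for mammalian transcripts. Counts are
multinomial around the true usages with Poisson totals, the simplest
noise model consistent with compositional analysis. Strands alternate
so minus-strand logic is always exercised. Everything is deterministic
in the design seed.

What the generator does *not* emulate: nanopore basecalling error,
3'-biased read truncation, transcript mis-collapsing, shared parameters
across genes, or overdispersion beyond multinomial sampling. Passing
calibration here shows the inference machinery is correct and
well-calibrated under clean compositional noise — not that real
nanopore data will be as kind.

## Problem sizes and numerical choices

Test and acceptance runs use 100 promoter groups (50 null, 50 shifted)
for calibration and a 50-gene design for the end-to-end determinism
check; the exhaustive caller-oracle family uses a 10-bp boundary grid
over seven points (651 two-transcript groups) plus seeded
three-transcript samples. These sizes give stable pass/fail behaviour
at desk scale. Ties, degenerate inputs, and clipping conventions are
each pinned by a dedicated test rather than left to float: peak-centre
ties break toward the transcription start, dominant-class ties follow
the canonical class order, empty direction contrasts report p = 1 with
a flag, and zero-total samples fall back to $1/k$.

## Known limitations

* The coverage-based caller intentionally skips donor/acceptor
  candidates masked by overlapping retention or termination events;
  compound loci report the dominant event only.
* The beta model treats replicates as exchangeable draws; it does not
  model replicate-level covariates or count-level overdispersion (a
  count-space beta-binomial variant is a possible extension, not
  implemented).
* The longest-ORF stand-in is a placeholder for proper CDS annotation;
  conclusions about coding consequences are only as good as the CDS
  intervals supplied.
* Only two-condition contrasts are supported.
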
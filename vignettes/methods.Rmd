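---
title: "Methods: consensus calling, TMB and rule-based molecular subtyping"
author: "SomaticSubtyper authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus calling, TMB and rule-based molecular subtyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the methods it implements:
the procedures, the assumptions behind them, the tunable parameters and
the choices we made where the design was genuinely open. Everything
quantitative it mentions is computed by the test suite or by
`scripts/acceptance.R`; nothing here is an empirical claim beyond what
those runs check.

## Coordinate and container conventions

Small variants are kept in MAF convention (1-based, inclusive) end to
end, because that is how every caller's annotated output is keyed and
how hotspot catalogs are published. All region arithmetic — BED ingest,
CNV geometry, TMB denominators, arm coverage — runs on `GRanges`
(1-based, closed), the field's canonical container, with the 0-based
half-open BED convention converted exactly once at the file boundary.
`IntervalSet` is a `GRanges` subclass whose validity requires the ranges
to be reduced (sorted, disjoint, non-abutting), so `totalBp()` is always
a sum of widths with no double counting.

Chromosome names are normalized to the `chr`-prefixed form; a file
mixing prefixed and bare names is rejected rather than silently
harmonized, since that mixture usually indicates concatenated outputs
from different references.

## Consensus SNV calling

Strelka2 reports multi-nucleotide substitutions as runs of per-base
SNPs. Before consensus, any DNP/TNP/ONP reported by another caller whose
every constituent (position, ref, alt) is matched by an unclaimed
Strelka2 SNP replaces those SNPs with a single Strelka2 MNP of the same
span and alleles — this preserves the predicted protein consequence of
the merged call. When overlapping candidates compete for the same SNP,
the longest candidate wins, ties broken leftmost: maximal merges best
preserve the gene model, and the leftmost rule makes the outcome
order-independent. The reconstruction conserves the total count of
substituted bases (a property test enforces this).

Consensus then keeps a variant key (sample, chrom, start, end, ref,
alt) found in at least `min_callers = 2` of the four callers, or flagged
as a hotspot allele by any single caller. Depths and annotations on the
emitted record come from a fixed caller priority (strelka2 \> mutect2 \>
lancet \> vardict); the choice is arbitrary but deterministic, and only
affects bookkeeping columns, never membership. Two filters follow the
published predicates exactly, including their boundaries:

- germline leakage: removed iff non-hotspot AND normal depth ≤ 7 AND
  gnomAD AF \> 0.001; an absent normal depth or AF never triggers
  removal, which also means the filter is a no-op for tumor-only samples
  (they have no matched normal);
- tumor-only depth: removed iff alt reads = 0 OR tumor depth \< 4.

## Consensus CNV calling

Amplification and deep deletion participate in consensus as direction
gain and loss respectively; the extreme status is restored on the output
region when any supporter carried it. For each sample, direction and
caller pair, two rules emit candidate regions:

1. reciprocal overlap ≥ 50% in *both* directions emits the pair's
   **intersection**. The source procedure does not state whether the
   union, intersection or one caller's segment is reported; we emit the
   intersection because it is conservative (only jointly supported bases
   survive) and symmetric in the callers.
2. a smaller segment whose length is \> 90% covered by another caller's
   same-direction segment is emitted **as-is** (the covered segment, not
   the coverer). "Covered" is read as the fraction of the smaller
   segment's own length, per segment pair.

Identical emitted regions are collapsed with supporter union. Copy
number on a region comes from the highest-priority supporting caller
(controlfreec \> cnvkit \> gatk \> mantasv) — again an arbitrary but
fixed donor order. De-noising drops any (sample, caller) file with more
than 2,500 non-neutral segments; neutral segments do not count toward
the cap since they carry no event signal. Same-direction regions within
10,000 bp merge into one span; regions shorter than 3,000 bp or
overlapping the blacklist by ≥ 50% of their length are removed. When no
GATK panel of normals exists, the MantaSV-derived segments stand in as
the third caller with unchanged semantics.

Gene-level status assigns every overlapping (gene, region) pair a call,
then resolves duplicates by: non-neutral over neutral, dominant segment
(largest gene overlap in bp), amplification over gain and deep deletion
over loss, and a final deterministic (status rank, segment start) key.
The final key exists purely so resolution is total — the three
substantive rules already resolve almost everything, and the tail must
not depend on row order. Genes overlapped by no region are reported
neutral: the consensus file omits neutral regions, so absence is absence
of evidence for change.

## Tumor mutational burden

MNVs are split into per-base SNVs (inheriting classification and
sample), duplicates by variant key removed, and numerators counted
inside the denominator region only — a mutation outside the surveyed
footprint is unverifiable there and would bias the rate. For WGS the
all-mutation denominator is the intersection of the callers' effectively
surveyed BEDs; the coding denominator further intersects the CDS ranges.
The published formulas are mutations per bp; we report per megabase
(× 10^6), the unit the field quotes, alongside the raw numerators and
denominators so either convention can be recovered. The nonsynonymous
classification list is the high/moderate-consequence set; an alternate
set (TMB-harmonization style) ships as an editable text file
(`inst/extdata/nonsyn_focr.txt`) because its exact membership is a
policy choice, not an algorithm.

## Fusion prioritization

A call is putative oncogenic when either partner appears in any supplied
reference list (kinases, oncogenes, tumor suppressors, curated
transcription factors, COSMIC census, TCGA-observed). Retention requires
any of: both RNA callers on the same sample and pair; recurrence
(default ≥ 3 samples of one cancer group — the source does not print its
recurrence cutoff, so ours is a documented, configurable stand-in);
cancer-group specificity (the pair occurs in exactly one group
cohort-wide); or the oncogenic annotation. Clinical panel (DGD) calls
bypass filtering into a separate output. Upstream artifact filtering
(read-through, mitochondrial, homology) is assumed done by the fusion
annotation tool that produced the input.

## TP53 status

Activation (p.R273C / p.R248W) takes precedence over loss: both residues
are also database hotspots, so without the precedence every activated
tumor would be mislabeled lost. Loss fires on any of: (i) a hotspot
variant; (ii) two distinct channels among SNV / CNV-loss / SV, the
biallelic-inactivation pattern; (iii) any single somatic variant or a
pathogenic germline Li-Fraumeni variant — deliberately permissive, and
documented as such, since condition (iii) is stated that way at the
source; (iv) germline LFS plus an RNA inactivation-classifier score
strictly \> 0.5. The classifier itself is out of scope; its score is an
input. Condition (iii) accepts any nonsynonymous somatic TP53 variant
without requiring a pathogenicity annotation — the hotspot and domain
catalogs are inputs, not judgments this package makes.

## Expression support

Duplicate gene symbols collapse to the row with the maximum mean across
samples after dropping all-zero rows; ties break on the lexicographically
smaller Ensembl id. Z-scores are computed on log2(x+1) values within
(cancer group × RNA library type) cohorts — the library-type grouping
mirrors the batch-avoidance practice of expression scoring on mixed
library preparations; the cohort for subtyping z-scores is not stated at
the source, so this choice is ours and is isolated in the pipeline call.
We use the population (divide-by-n) standard deviation, and define
sd = 0 (including single-sample cohorts) as z = 0. Over-expression is
z ≥ 2 (boundary in); under-expression is z \< −2 (boundary out),
following the quoted inequalities literally. Genes cited for
over-expression without a numeric cutoff (TKTL1, EZHIP, GPBP1, IFT46,
LIN28A) use the same z ≥ 2 stand-in, documented here. The MYCN decision
for neuroblastoma uses raw TPM against 140.83 — a cutoff inherited from
visual inspection of MYCN copy-number status at the source, applied to
the collapsed TPM matrix, boundary amplified.

## Arm events

An arm is gained (lost) when same-direction consensus regions cover at
least `arm_fraction = 0.5` of its length, computed on the merged
footprint so overlaps never double count. The 50% default is our choice
of a conventional arm-event criterion; it is a threshold parameter, not
a derived constant.

## The subtyping engine

Within each histology the listed criteria order is the priority order
and the first match wins — the ependymoma and HGG rule lists read as
ordered criteria, and a fixed order is the only auditable resolution.
The declarative half of the engine (pathology-diagnosis dispatch map,
methylation-subclass matchers, output label strings, marker-gene groups,
the loss-of-function classification set) ships as YAML
(`inst/extdata/subtype_rules.yaml`) so tokens and labels can be
corrected without touching code; the boolean rule logic itself is R
code, because a full declarative condition-tree interpreter would add
failure modes without adding testability. Methylation predictions count
only at score ≥ 0.8 (boundary in). Loss-of-function is operationalized
as the truncating Variant_Classification set (nonsense, frameshifts,
splice site, nonstop, translation start). Anatomical location (posterior
fossa, spinal) is read from a metadata column.

Medulloblastoma SHH subgroups are not mutually exclusive: a patient
under five with a 2p gain satisfies both beta (2p *or* 2q gain) and
gamma (2p gain). Precedence is by specificity — the methylation subclass
shortcut first; then gamma beats beta exactly when the chromosome-2 gain
is beta's *only* fired criterion (gamma's condition is the strict subset
of beta's); all residual ties break alpha \> beta \> gamma \> delta.
This tie-break is ours and is stated prominently because the source is
silent. "Chromosome 19 amplification" for ETMR is evaluated as an
arm-level gain on 19p/19q. When methylation and the RNA medulloblastoma
classifier disagree, methylation wins and the review flag is set; events
whose fall-through label coexists with an unused high-confidence
methylation call are likewise flagged for review rather than
auto-overridden. HGG labels carry the TP53 status as a suffix
(", TP53 lost" / ", TP53 activated"); the exact suffix string is a
package convention. Missing evidence channels degrade gracefully:
predicates on an absent channel are false, never errors, mirroring
mixed-platform cohorts where not every event has every assay.

Independent-specimen selection keeps one biospecimen per participant by
experimental-strategy filter, then descriptor preference (initial/primary
\> progressive \> recurrence \> others), then ascending sample id. The
preference order is configurable; the default documents the common
convention rather than any published table.

## The synthetic cohort and what passing means

The generator writes every input format with one injected,
subtype-defining lesion per rule (about 90 events including
fall-through and padding events), plus Poisson passenger SNVs
(mean 30/sample) spread over random caller subsets with 10% single-caller
hotspots and an 8% germline-leakage rate, random non-recurrent CNV
segments confined to a gene-free zone, and spurious single-caller
fusions spanning two cancer groups. The toy genome is nine miniature
10-Mb chromosomes named for the chromosomes the rules cite (arms at
[0, 4.5 Mb] and [5.5 Mb, 10 Mb]), with a 35-gene synthetic gene model
whose placements bear no relation to real loci; the surveyed footprint
is ~1 Mb on one chromosome with a 100-kb CDS so that truth denominators
are enumerable per base pair. These sizes were chosen so every
brute-force oracle (set algebra over variant keys, all-pairs CNV
comparison, per-bp interval counting) runs in seconds while still
exercising each rule at least once.

Truth values are computed inside the generator by naive restatements —
never by the library under test — and the acceptance checks compare the
pipeline against them exactly. Passing therefore shows the
implementation agrees with the stated rules under controlled inputs
with unambiguous lesions. It does not show robustness to what real
cohorts add: representation ambiguity in indels/MNVs beyond the modeled
cases, caller-specific coordinate quirks, subclonal copy number,
conflicting methylation calls at similar scores, or pathology labels
outside the dispatch map (such events pass through unlabeled by
design).

## Numerical and degenerate-input choices

All thresholds live in `defaultThresholds()` with units and defaults;
boundaries follow the quoted inequalities (≤ 7, \> 0.001, \< 4, ≥ 50%,
\> 90%, ≤ 10 kb gap, \< 3 kb, ≥ 0.8, ≥ 140.83, \> 0.5, ≥ 2, \< −2).
Empty inputs produce empty, correctly-typed outputs; fewer than two CNV
callers with data yield an empty consensus with a warning; a zero
denominator aborts TMB with an error naming the cause; unknown status
tokens and malformed rows fail fast with the offending row. Output
tables are written in canonical sort orders, and the run manifest
records input checksums and per-stage row counts without timestamps, so
reruns on identical inputs are byte-identical — determinism is asserted,
not assumed.

## Known limitations

Variant identity assumes upstream left-alignment/normalization by the
annotation step; no re-normalization is attempted. The cn→status map
(0 deep deletion, \< ploidy loss, ploidy neutral, \< ploidy+3 gain,
else amplification; default ploidy 2, including sex chromosomes unless a
per-sample table is supplied) is a package convention — the upstream
callers' own status columns, when present, take precedence. Fusion
recurrence and arm-fraction cutoffs are stand-ins where the source
prints none. The engine implements research-grade labels; it does not
replace the pathologist review such pipelines route conflicting cases
through — that is exactly what the review flag is for.
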
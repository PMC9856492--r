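---
title: "Profiling hereditary diffuse gastric cancer cohorts: methods and design"
author: "HDGCprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling hereditary diffuse gastric cancer cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

HDGCprofiler analyses paired germline/tumor exome cohorts of hereditary
diffuse gastric cancer (HDGC): clinical eligibility classification, private
germline variant calling under a six-criterion definition, detection of
germline-to-somatic double-hit events supported by loss of heterozygosity
(LOH), refitting of 96-context mutational signatures, simplified gene-level
G-score summaries of copy-number segments, and the closed-form cohort
statistics these analyses rest on. A synthetic-cohort generator with planted
ground truth makes every stage testable end to end without any external
data. This vignette records the methods, the tunable parameters, and the
design decisions taken where the published analysis left the choice open.

# Clinical eligibility

A patient qualifies as HDGC by meeting at least one of four conditions
built from histology, age at diagnosis and first/second-degree family
history:

1. two or more gastric cancer (GC) cases in the family together with a
   confirmed diffuse-GC case diagnosed before age 50;
2. three or more confirmed diffuse-GC cases in the family at any age;
3. the patient's own diffuse GC diagnosed before age 40 with no family
   history of diffuse GC;
4. co-occurrence of diffuse GC and lobular breast cancer in the personal or
   family history, one of them diagnosed before 50.

The published wording of condition 1 supports two readings: a conjunctive
one ("2 or more cases of GC **and** 1 confirmed diffuse case before 50")
and a disjunctive one ("2 or more cases of GC **or** 1 confirmed diffuse
case before 50"). `classifyHdgc()` implements both behind
`condition1 = c("strict", "lenient")` and defaults to the conjunctive
reading, which matches the footnoted definition used in the cohort's
baseline table. Unconfirmed diffuse-GC reports in relatives count as
generic GC towards the case count but never towards a diffuse-specific
clause. For condition 4 a personal lobular-breast diagnosis carries no age,
so it cannot by itself satisfy the before-50 clause; the patient's own GC
age or a relative's age must.

# Private germline variants

A germline variant is *private* when six criteria hold simultaneously:

1. consequence class in the whitelist,
2. heterozygous in the germline,
3. population allele frequency below 0.5% (strict `<`) in **both**
   population databases,
4. present in exactly one patient of the cohort,
5. mappability score above 0.5 (strict `>`),
6. a single genomic locus (BLAT-style uniqueness).

`classifyPrivate()` returns all six flags per call and enforces, as a class
invariant, that the overall verdict is exactly their conjunction. Design
choices worth making explicit:

* **Whitelist.** The truncating-only criterion conflicts with the reported
  presence of missense alterations among private variants, so the default
  whitelist is the three PTV classes (nonsense, frameshift indel,
  splice-site) *plus* missense; `ptvWhitelist()` gives the strict variant.
  Neither is asserted to be the published intent — both are exposed.
* **Two databases.** "Below 0.5% in database A or database B" is read as
  naming the two sources consulted, i.e. the variant must be rare in both
  (AND). An OR mode is available via `maf_mode`.
* **Absent frequency entries count as 0.** A variant missing from a
  population resource is treated as rare — novel variants must remain
  eligible.
* **Folding.** The annotated frequency is used as given (alternate-allele
  frequency); no folding to `min(p, 1-p)` is applied.
* **Multi-base variants** take the minimum mappability over the reference
  span they touch; uniqueness is consumed as a precomputed 0/1 track.

Consequence classification is deterministic against a CDS exon model with
strand and rank: intronic positions within 2 bp of an exon boundary are
splice-site; coding indels are frameshift when the length change is not
divisible by 3, else in-frame; coding SNVs are translated in their codon
(strand-aware) and called nonsense, synonymous or missense. Where a variant
touches both coding sequence and a splice window (an indel spanning a
boundary), the coding classification wins.

# Double hits and LOH

A double-hit event is a germline-heterozygous alteration observed as
homozygous (for the alternate allele) in the paired tumor. Because the
published operational definition is not fully specified, the caller uses an
explicit three-clause disjunction, every threshold surfaced in
`pipelineConfig()` and recorded in the provenance JSON:

* tumor genotype is homozygous-alt; or
* tumor VAF ≥ `hom_vaf` (default 0.9) at depth ≥ `min_depth` (default 10);
  or
* the variant lies inside a called LOH segment with tumor VAF > 0.5 (the
  retained allele is the alternate).

Evidence tags record every clause that fired. LOH segments are called from
tumor allele fractions at germline heterozygous sites: maximal runs of at
least `min_sites` (5) consecutive informative sites (depth ≥ 10) deviating
from 0.5 by at least `deviation_threshold` (0.25). Sites below the depth
floor are skipped without breaking a run; a balanced informative site ends
it. Tumor purity is not modelled — the thresholds assume high-purity
tumors, and `hom_vaf` is the knob to loosen for impure samples. An import
path for externally produced segment tables exists alongside the built-in
caller.

The per-gene G score is a deliberately simplified surrogate for
peak-finding statistics: the fraction of patients carrying a qualifying
overlapping segment (|log2 ratio| ≥ 0.3 by default) times the mean absolute
log2 ratio of those segments, reported separately for gains and losses. It
ranks genes; it does not assign significance.

# Mutational signatures

Somatic SNVs are tabulated over the standard 96 pyrimidine-centric
trinucleotide categories (purine-reference substitutions are
reverse-complemented with their flanks; the mapping is involutive).
Exposures are obtained by *refitting*: each catalog row, normalized to
frequencies, is decomposed over a user-supplied signature matrix by
non-negative least squares and the weights renormalized to sum to one —
matching an analysis that attributes mutations to known catalogue
signatures rather than extracting signatures de novo. The reconstruction
cosine is 1 exactly when the catalog lies in the non-negative span of the
signatures. The dominant signature is the argmax weight, with exact ties
resolved to the lexicographically smallest signature id.

Sample clustering on exposure vectors uses seeded k-means with 25 restarts,
swept over k ∈ {3, 4, 5}; with as many clusters as samples the exact
one-point-per-cluster solution is returned directly. Subgroup enrichment
(e.g. dominant-signature status against EBV positivity) uses a two-sided
Fisher exact test on the 2×2 table, excluding and counting samples with
unknown status. The two-sided p-value follows the small-p-values
convention — the sum of the probabilities of all tables with the observed
margins no more probable than the observed one — which for the 2-of-3
versus 8-of-69 enrichment table evaluates to ≈0.049.

The packaged `toySignatures()` are three deterministic 96-category profiles
with pairwise cosine below 0.2 (concentrated in C>T, C>A and T>C
respectively); they exist so refitting is testable without downloading any
signature catalogue.

# Cohort statistics

Fisher's exact test, the chi-square test (no continuity correction by
default, a flag turns it on), Benjamini–Hochberg q-values, Kaplan–Meier
estimation (Greenwood variance; events precede censorings at tied times)
and the two-group log-rank test are delegated to base R and the survival
package behind a uniform interface; the test suite verifies them against
independent oracles — exhaustive hypergeometric enumeration for every 2×2
table with total ≤ 40, the step-up formula evaluated directly, and hand
product-limit arithmetic. Percentages in all cohort tables are rounded half
away from zero to one decimal, the single convention behind every
"n of N (x%)" figure the package prints. Multivariate Cox adjustment is out
of scope; the pipeline emits the analysis-ready survival table instead.

# The synthetic cohort generator

`simulateCohort()` writes a complete, self-contained input bundle —
reference FASTA, multi-exon gene model, population frequency table,
mappability and uniqueness tracks, paired per-patient VCFs, clinical
manifest with family history and survival, toy signature matrix,
copy-number segments — together with truth tables for every planted
feature. Its defaults *are* the study conditions the recovery checks run
under:

* 50 patients over a 2 × 60 kb miniature exome with 40 three-exon genes;
* per-gene private-variant rates giving ~18.7% carriers at the flagship
  gene, ~10% for six others, 2.8% at a CDH1-like gene and ~8 private
  variants per patient overall (echoing the reported ~9.6 private PTVs per
  patient at full exome scale);
* decoy variants, each violating exactly one of the six criteria, with
  their annotations (an 0.6% frequency entry, a 0.4-mappability hole, a
  non-unique locus, a recurrent carrier pair, a homozygous genotype, a
  synonymous consequence) really present in the emitted files;
* a qualifying-condition mix of 8 / 2.5 / 89.4 / 0 percent, EBV positivity
  near 2.8%, and exponential survival calibrated to a 61.4% five-year rate
  with uniform administrative censoring on (3, 186) months;
* 12 planted double hits placed inside LOH windows (3 kb, ≥3 kb apart, with
  window merging when no heterozygous site separates them, so planted truth
  equals what is recoverable); other planted heterozygotes inside a window
  lose the alternate allele, common SNPs lose either allele at random;
* ~300 somatic SNVs per tumor drawn position-by-position from the
  trinucleotide contexts demanded by per-sample Dirichlet(1,1,1) mixtures
  of the toy signatures — EBV-positive tumors draw from Dirichlet(0.5,0.5,5)
  so subgroup enrichment has signal;
* depth: exact fractions at fixed depth 80 in noiseless mode, Poisson
  depths with binomial allele counts otherwise.

All randomness flows from one seed; the same configuration reproduces
byte-identical bundles, and `verifyTruth()` re-reads every file and fails
on the first inconsistency between truth and emitted data.

What the generator does **not** emulate — and hence what passing recovery
tests do not demonstrate about real data: alignment and calling artefacts,
tumor purity and subclonality, linkage structure among common variants,
indel-rich repetitive contexts, transcript-annotation ambiguity, and
population stratification of allele frequencies. The recovery checks show
the pipeline is correct *given its inputs*, not that those inputs are easy
to produce.

# Numerical and degenerate-input choices

* Variant keys are left-aligned and parsimonious (trim shared trailing
  bases, extending left through the reference when an allele would empty;
  then trim shared leading bases to the single indel anchor); the
  normalization is idempotent and checked against a brute-force sliding
  oracle.
* Genotypes map from GT as 0/0 → hom_ref, 0/1 or 1/0 → het, 1/1 → hom_alt,
  missing alleles → missing; phased separators are treated as unphased;
  multi-allelic records are split before normalization.
* Zero-depth sites have undefined VAF and are excluded from LOH evidence;
  a variant with neither tumor genotype nor VAF is skipped with a warning,
  not an error.
* All-zero catalog rows yield NA exposures and are flagged rather than
  fitted.
* Tables with a zero margin are rejected in enrichment testing (the Fisher
  p would be vacuously 1 regardless of the data).
* Problem sizes in the checks were chosen to exercise the methods at
  cohort scale while keeping a full run on a single CPU comfortable: the
  recovery cohorts use 50 patients (~190 germline and ~490 tumor records
  each), the refit accuracy check uses 20 samples × 5000 mutations, and
  the exhaustive Fisher validation covers all 135,751 tables with total
  ≤ 40.

# Known limitations

The LOH caller is allele-fraction-only and assumes high purity; the G score
is a ranking heuristic, not a significance statistic; eligibility
condition 1 is genuinely ambiguous in the source definition and both
readings are maintained rather than adjudicated; the consequence classifier
handles single-transcript gene models only (gene assignment follows the
supplied model, not an annotation database); and signature refitting is
limited to SBS-96 — indel and doublet signatures are out of scope.
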
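---
title: "Auditing tumor-only variant calling against tumor-normal truth: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing tumor-only variant calling against tumor-normal truth: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelaudit)
library(dplyr)
```

## The problem

A tumor-only gene-panel test sequences tumor tissue without the patient's
matched normal, so it cannot distinguish inherited single nucleotide
polymorphisms (SNPs) from somatically acquired mutations by direct
comparison. Instead it filters putative germline variation using population
databases. `panelaudit` measures what that substitution costs on a 35-gene
panel (25 somatic tumor-driver genes, 10 inherited-risk genes): with
tumor-normal labels taken as truth, every germline variant surviving a
tumor-only filter is a **false positive** (a fictitious "somatic" drug
target) and every true somatic mutation removed by the filter is a **false
negative**. A second, orthogonal precision layer asks whether reported DNA
variants are expressed in tumor RNA at all.

The analysis is restricted to single nucleotide variants with
protein-altering (missense or nonsense) consequences; consequence is
consumed from the input, never computed, because transcript annotation is
out of scope.

## Origin classification

The reference study used a proprietary tumor-vs-normal caller, so the
package replaces it with a transparent threshold classifier over matched
read evidence. For a variant with tumor depth/alt reads and normal
depth/alt reads (VAF = alt/depth, defined as 0 at zero depth):

* **unassigned** — tumor evidence below the minima
  (`min_tumor_alt = 4`, `min_tumor_vaf = 0.05`);
* **germline** — normal alt reads ≥ 4 **and** normal VAF ≥ 0.20 (a diploid
  carrier at ~30× normal depth has VAF ≈ 0.5, far above the band);
* **somatic** — normal alt reads ≤ 1 **or** normal VAF < 0.02;
* **ambiguous** — normal evidence strictly between the somatic and germline
  bands (≥ 2 alt reads, VAF in [0.02, 0.20)).

These are conventional paired-calling heuristics at the stated ~30×/60×
normal/tumor depths. Ambiguous and unassigned variants are *excluded* from
all downstream tallies rather than forced into a class; the audit logic is
threshold-agnostic, and transcriptions of published tables or synthetic
truth can bypass the classifier entirely (`fixture_mode = TRUE`). The
classifier is monotone in normal alt reads at fixed depth — strengthening
normal support can only move a label from somatic toward germline — which
the property suite checks by sweeping.

## Sample frequencies and the rescue rule

Unique sites are defined by the full 4-tuple (contig, 1-based position,
ref, alt). "Common in the cohort" uses **carrier frequency** — patients
carrying the site divided by cohort size, compared *strictly* against the
0.02 threshold. The alternative allelic reading (carriers/2N) is available
via `frequency_mode = "allelic"`, but carriers/N is the default because
somatic variants have no diploid allele count, so only the carrier reading
applies uniformly to both origins.

The allele-frequency filter regimes remove variants with a reported
population AF **at or above** the cutoff (inclusive, matching the stated
"AF ≥ 0.01" / "AF ≥ 0.001" rules). An absent AF is represented as missing,
never as zero: public AF estimates bottom out around 1e-4, so absence is
uninformative. Absent-AF variants are retained unless the **rescue rule**
fires: catalogued in the database *and* cohort-common *at a site with at
least one germline carrier*. The germline-carrier restriction is what keeps
recurrent somatic hotspots — which are catalogued but frequency-less — from
being rescued away, and it is the mechanism behind the zero-false-negative
property of the AF regimes.

## Confusion accounting

`tally_confusion()` reports TP (somatic retained), FP (germline retained),
FN (somatic removed) and germline_removed per regime at cohort, gene or
patient scope; conservation (TP + FN = somatic input,
FP + germline_removed = germline input) holds by construction and is
re-checked against a brute-force per-variant oracle on randomized cohorts.
Two false positive rates are reported: FP/(FP+TP) over the post-filter
reported list, and FP over the total input. The total denominator can be
overridden (`n_total`) because the reference study quotes its lung FP
percentage against 802 discovered SNVs while analyzing 746; the package
stores both constants verbatim (`reference_constants()`) and deliberately
does not guess a reconciliation. Similarly, the reference text gives both
"30" and "33" cancer types for the same cohort; cancer type is free text
here and enters no computation.

Per-patient burden keeps two denominators deliberately distinct: the share
of patients with ≥ 1 (or only) false positives is over **all** patients,
while mean retained calls per patient is over patients with **at least one**
retained call, matching the published histogram that excludes zero-variant
patients. Drug-target impact counts a patient once per gene, with an "ANY"
row deduplicated across genes.

## Expression assessment

RNA evidence is a per-locus allele count. A call is `not_assessable` below
`min_assessable_depth = 10` RNA reads (variants with no RNA record at all
are likewise not assessable and never enter denominators); otherwise
`expressed` requires both `min_alt_reads = 3` and
`min_alt_fraction = 0.05`. The reference assay published only performance
claims, not a rule, so these conservative pileup heuristics are the
package's choice; all fixture arithmetic is threshold-independent. Observed
expression summaries report per-gene assessed counts, not-expressed counts
and fractions, with cross-gene patient deduplication only in the total row
(the published "unique patients" totals are therefore fixture constants,
not column sums).

## The synthetic cohort: a stated world

`generate_cohort()` draws from a population fixed entirely by the
configuration — tier allele frequencies are an evenly spaced grid, not
random draws — so every expectation is analytic (`expected_fractions()`)
and parameter-recovery tests compare observation to closed-form
expectation, not to a tuned constant. The defaults are chosen once to match
the reference cohort's marginal structure:

| parameter | default | rationale |
|---|---|---|
| common SNPs | 1/gene, AF 0.02–0.50 | ~15 germline carriers per patient via 1−(1−af)² |
| low-frequency SNPs | 3/gene, AF 0.001–0.008 | the tier separating the AF ≥ 0.01 and ≥ 0.001 regimes |
| rare/private SNPs | 0.01 per kb CDS, AF < 0.001 | the irreducible false positive source (~1/patient) |
| somatic rate | 0.9/patient | matches ~555 somatic in 621 patients |
| driver enrichment | ×3 on CDS-proportional weight | somatic events concentrate in driver genes |
| hotspots | 40% of events at 4 fixed sites (2 KRAS, 2 PIK3CA) | recurrent common somatic drivers |
| db completeness / AF missing | 0.98 / 0.05 | incomplete annotation; exercises the rescue path |
| hotspot in-database rate | 0.9, AF always absent | why database filtering causes false negatives |
| expression dropout | 0.18 somatic, 0.10 germline | somatic mutations disrupt transcription more often |
| depths | 60× tumor, 30× normal, 50× RNA | stated assay depths |

Together these give an expected germline fraction of ≈ 0.95 and ~18
variants per patient. Sequencing noise is **off** by default — evidence is
deterministic given depth, so classification and expression recovery tests
are exact; `sequencing_noise = TRUE` switches to Poisson depths and
binomial alt reads (normal-sample error 0.001) for robustness tests, where
observed classifier discordance stays well under 2%.

What the generator does **not** emulate: linkage disequilibrium, mutational
signatures, subclonal fractions and copy-number-distorted VAFs, zygosity
(carriers are not genotypes), RNA allelic imbalance, and dual-origin sites
(synthetic tiers use disjoint ref/alt pairs, so a site is never germline in
one patient and somatic in another; dual-origin handling is tested with
hand-built cases instead). A green parameter-recovery test therefore
establishes that the pipeline's accounting is faithful to its inputs — not
that real cohorts look like the simulator.

## Numerical choices

* Percentages in report tables are rounded half **up** (`floor(x + 0.5)`),
  matching clinical-table convention, and always re-derived from the row's
  own counts; JSON summaries keep full precision.
* AF-cutoff comparison is inclusive (≥); cohort-common comparison is strict
  (>). Both follow the stated wording of the rules they implement.
* Zero denominators (FP rate with an empty reported list, singleton
  fraction of an empty site list, germline expression with nothing
  assessed) raise errors rather than returning 0.
* VAF at zero depth is defined as 0 so the classifier stays total.
* Multi-allelic VCF records are split per alternate allele; indels are
  dropped with a message. Contig naming mismatches between tumor and normal
  files are an error unless `chr` normalization is explicitly requested.
* Published table transcriptions are expanded to per-variant fixtures
  (`reference_cohort_variants()`) by deterministic round-robin placement
  over each gene's published unique-site count; the margins are exact, the
  per-site and per-patient structure is synthetic and labelled as such.

## Limitations

The packaged panel intervals and CDS lengths come from one chosen
transcript set, so the unique-sites-vs-CDS-length correlation is a
qualitative, not exact, reproduction target. Patient-level published
results (the share of patients with ≥ 1 false positive, per-gene
drug-impact counts) depend on unpublished per-patient data and are covered
by property-based tests on synthetic cohorts rather than numeric
reproduction. Tumor purity, joint genotype likelihoods and
panel-of-normals filtering are out of scope.
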
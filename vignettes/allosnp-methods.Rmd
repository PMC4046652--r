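---
title: "Simple-SNP discovery in an allotetraploid: models and methods"
author: "allosnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simple-SNP discovery in an allotetraploid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

An allotetraploid such as *Brassica napus* (AACC) carries two complete
parental subgenomes whose homoeologous chromosomes are nearly identical.
Short reads from an accession therefore pile up in two confusable ways:
genuine allelic variation at one locus ("simple SNPs", the markers one
wants), and fixed differences between the A and C copies of a locus, which
masquerade as heterozygous SNPs in every accession ("hemi-SNPs" when they
leak into a genotyping assay). This package implements, end to end, a
discovery strategy that separates the two on a panel of fully inbred
accessions, and a two-channel genotyping analysis that detects the
hemi-SNPs that slip through. Everything runs against synthetic data with a
machine-readable truth table, so the error behaviour of every filter is
measurable rather than asserted.

The logic has three legs:

1. **Low-copy restriction.** Repeats are masked before alignment and only
   *uniquely* aligned reads are kept. Multi-copy loci cannot give
   single-locus markers.
2. **Homozygosity.** The panel is fully inbred, so any line showing two
   alleles at one site is not heterozygous — it is reading two co-piled
   loci (usually the two homoeologs). One heterozygous line rejects the
   site outright.
3. **Replication across lines.** A genotype call needs at least 4 reads in
   a line, and the less common allele must be carried by at least 2 of the
   called accessions, so single-accession artifacts and sequencing errors
   never become markers.

## The synthetic study design

`sim_config()` holds every constant; the defaults are the study conditions
the pipeline is validated under, and all outputs are a pure function of
`seed` (per-stage sub-seeds derived by `stage_seed()` keep the stages
independently reproducible).

* **Genome.** Each `chrom_plan` row produces one homoeologous pair: one
  ancestral random sequence copied into an A and a C chromosome, the C
  copy substituted at `homoeolog_divergence = 0.03` per base. The spec of
  the configuration lists chromosomes as (subgenome, length) entries; we
  organize the plan by *pairs* instead, because the divergence model is
  defined on an ancestor. Two pairs of 60 kb are the default desk scale;
  tests use 15–60 kb pairs so the whole suite stays in minutes. Repeat
  families are inserted as exact copies shared by both subgenomes, so
  k-mer multiplicity is unambiguous at this scale.
* **Genes.** Toy gene models (ATG, stop-free internal codons, terminal
  stop, 1–2 exons, both strands) are carved into both homoeologs of a
  pair. The C copy of each gene is then re-diverged at the global rate
  under an ORF constraint: start and stop codons untouched and no internal
  stop may arise. Without that controlled divergence the two gene copies
  would be identical and every gene read would be discarded as repeatedly
  aligned — the one place where naive conservation would silently delete
  all coding SNPs. Intron and codon positions are otherwise unbiased; we
  accept that this overstates nonsynonymous inter-subgenome divergence
  relative to real purifying selection, which is irrelevant to the filters
  under test.
* **Panel.** Ten inbred accessions; simple SNPs planted in non-repeat
  sequence at `snp_rate` per base with the minor allele in *k* accessions
  drawn from `minor_count_spectrum` (singletons included by default —
  they must be *rejected* later), a 3e-4 fraction of sites triallelic,
  and the alternate allele a transition with probability 0.575, matching
  the transition share of real resequencing panels. Every genotype is
  homozygous by construction.
* **Reads.** Uniform positions, equal strand probability, constant
  quality, per-base error 0.002, per-accession depths defaulting to the
  5.3–37.5-fold spread of a real ten-accession panel. Read names carry
  `accession:chrom:start:strand` provenance for auditing.
* **GoldenGate intensities.** Allele A drives Cy3, allele B Cy5
  (`mu_on = 4000`, `mu_off = 300`, Gaussian `sd = 200`, truncated at 0);
  heterozygotes split the signal. A DH population (50 lines, 1:1) and an
  F2 population (80 lines, 1:2:1) are simulated with per-population
  parents, plus one DH sample in triplicate. Planted hemi assays sum the
  signal of a second locus fixed for different alleles in the two
  populations, which is exactly the configuration that forces ≥ 4 pooled
  theta groups while each population alone still looks like an ordinary
  assay. Designability rank scores are attached as given inputs: 96 of
  110 candidates above the 0.85 cutoff by construction.

What the generator does **not** emulate: indels and structural variation,
GC or positional coverage bias, quality-score miscalibration, residual
heterozygosity in the panel, linkage between assays, and the ancestral
genome triplication of real *Brassica*. Passing tests therefore show the
filters implement their stated contracts under substitution-only noise;
they do not certify behaviour under alignment around indels or biased
coverage.

## Mapping and classification

Alignment is ungapped seed-and-extend under the study's mapping contract:
at most 5 mismatches per read, 32 bp exact seed, 40 bp minimal aligned
length for contig-overhanging reads. A read with exactly one best-scoring
placement is *uniquely aligned*; a tie at the best score makes it
*repeatedly aligned* (and it is discarded — the conservative choice);
no placement leaves it *unaligned*. Two implementations share the
contract: `map_read()` is the reference implementation (every seed
offset, overhang handling), and `map_reads()` is the bulk path used by
the pipeline (trusted-band matching of the two read-end seeds, then full
ungapped extension). Reads whose ends both carry errors can fail seeding;
at the default error rate this loses ~0.4% of reads, and the property
tests compare both paths against a brute-force all-positions Hamming
aligner in regimes where seeding is exhaustive. Masked bases count as
mismatches, so reads mostly inside masked sequence drop out.

Mismatch counting and candidate generation lean on Biostrings
(`PDict`/`matchPDict`, `Views`); pileups go through Rsamtools on
temporary BAMs, which keeps strand orientation and N handling on the
field-standard code path.

## The filter cascade

Candidate sites are positions where any accession shows a non-reference
base. Per line: depth < 4 → missing; second base with ≥ 2 reads **and**
≥ 10% of depth → heterozygous (an exact tie is heterozygous); otherwise
the majority base is called. The heterozygosity pair (2 reads, 10%) is a
design choice — the source procedure does not state one — set so a single
sequencing error can never fake heterozygosity at the minimum depth of 4.
Per site, in cascade order: any heterozygous line → rejected
`heterozygous_line`; no called line → `low_depth`; fewer than two called
alleles → `monomorphic`; more than three → `excess_alleles`; any allele
carried by < 2 called lines → `maf`; otherwise accepted as biallelic or
triallelic. The reference base is recorded but never counted as an allele
unless a line carries it.

Two wording ambiguities in the source procedure are resolved as follows
(and the resolutions are what the tests pin down): the minor-allele rule
is "least common allele in ≥ 2 accessions *retained*" (the alternative
reading, "MAF > 0.2 excluded", is inconsistent with a ten-line panel);
and depth is judged per line (a shallow line is missing, it does not
discard the site) with MAF evaluated over called lines only.

On the default synthetic conditions the measured behaviour is: precision
≥ 0.99 and recall ≥ 0.9 at uniform 12× depth with a k ≥ 2 spectrum
(recall at the real 5.3–37.5× depth spread is lower, ~0.86, because
shallow lines push k = 2 sites under the minor-allele bar — the stringency
/ recall trade the design accepts); planted singletons all surface under
`maf`; and in a stress run with an unreferenced duplicated segment, every
divergent co-piled site is rejected as `heterozygous_line`, which is the
central homoeolog-screening claim.

## Annotation and enrichment

Transitions are purine↔purine / pyrimidine↔pyrimidine exchanges;
triallelic sites are excluded from the Ts/Tv numerator and denominator.
A/T SNPs are AS-PCR-suitable when the reference strand carries G or T
three bases upstream or C or A three bases downstream; both offsets are
evaluated on the reference strand only, as the ±3 rule's strand handling
is unstated in the source. Densities are SNPs per 100 kb rounded to the
nearest integer. Pairwise counts require both lines called (missing is
never a difference).

Coding effects map a SNP into spliced CDS coordinates (minus strand:
position reversed, allele complemented), rebuild the codon and translate
with the standard code; classes are synonymous / nonsynonymous /
stop_gain / stop_loss. The whole-protein retranslation oracle in the test
suite (mutate, re-splice, translate, diff) guards the coordinate
arithmetic.

Enrichment tests one 2×2 table per GO term after propagating annotations
up the is-a hierarchy: Pearson chi-squared (1 df, no continuity
correction) unless any margin-derived expected count is below 5, then
two-sided Fisher's exact (sidedness chosen to match the chi-squared
test). Raw p-values are reported, BH q-values as an extra column; the
background is *all* genes with models, annotated or not. A null
simulation (uniform study sets) holds the combined test's type-I error
at ≤ 0.07 for nominal 0.05 — slightly above nominal because the Fisher
branch is discrete.

## GoldenGate clustering

`theta = (2/π)·atan(Cy5/Cy3)` puts an AA homozygote near 0, BB near 1,
AB near 0.5; `normR = Cy3 + Cy5` is the total signal. For each candidate
cluster count k ≤ 6 we fit a shared-variance 1-D Gaussian mixture by EM,
initialized from the exact dynamic-programming k-means partition of the
sorted thetas, so the whole fit is deterministic with no random restarts;
k is chosen by BIC with ties toward smaller k. Two admissibility
constraints encode what a genotype cluster physically is: adjacent
centers must sit ≥ 0.12 apart (the closest true genotype groups in this
intensity model are ~0.19 apart, while spurious splits of one cluster
land well below 0.12), and every cluster must hold ≥ 5% of the points
(≥ 3), since a genotype class in a 1:1 or 1:2:1 design cannot be a
two-point tail. The shared variance is floored at 1e-6 so noise-free
fixtures stay well-posed. These two constraints were added after the
plain shared-variance BIC proved wrong in both directions on simulated
assays — it split the wider heterozygote cluster (theta noise is
heteroscedastic) and, under quantile initialization, missed small outer
clusters; the DP initialization plus the two physical constraints fix
both without any stochastic element.

Calls: a point is no-call below `min_normR = 1500` total intensity or
further than 0.1 from the nearest center; samples calling in < 80% of
assays are dropped and rates recomputed once. Segregation uses Pearson
goodness-of-fit without continuity correction (DH 1:1 on two homozygote
classes, a spurious middle class flagged; F2 1:2:1 in ascending-theta
order). An assay is *hemi* iff the pooled-population fit has ≥ 4
clusters; on simulator defaults this classification is exact over 50
seeds. Replicate concordance ignores no-calls while ≥ 2 calls remain.
Designability: scores ≤ 0.85 excluded; < 0.4 low, 0.4–0.6 moderate,
> 0.6 high.

The proprietary per-call quality score of the commercial software is
replaced by the distance/intensity no-call rule above; only cluster
membership, call rates and cluster counts feed any conclusion here.

## Numerical and coordinate conventions

All internal coordinates are 1-based inclusive (the Bioconductor
convention), GFF3 and VCF are written 1-based per their standards, and
BED exports convert to 0-based half-open. Masking styles: lowercase
preserves sequence (`toupper` restores it exactly); hard masking writes N
and is what the aligner indexes. Interval sets are merged with
GenomicRanges. Chi-squared statistics never use continuity corrections.
Degenerate enrichment tables (a zero margin) return p = 1 with no
direction. `fit_clusters()` refuses fewer than 2 points; cluster counts
larger than the number of distinct values are skipped.

## Problem sizes

The shipped analysis (`analysis/01…06`) and the acceptance script run two
60 kb chromosome pairs, ten accessions, roughly 290,000 100 bp reads
in total at the acceptance depth of 12×, 96 genotyping assays over 130 lines
plus parents and a triplicate, and 50 genotyping seeds for the hemi
classification — chosen so a complete run takes a few minutes on one
core while every rate being measured (precision, recall, rejection
attribution, hemi accuracy) still rests on hundreds of events. The
genome-scale counts of a real resequencing survey (hundreds of thousands
of markers from ~126 Gb of reads) are out of reach of a desk-scale rerun
by design; what is reproduced instead is the worked-example arithmetic on
the published summary tables plus the property gates above.

## Known limitations

* Substitution-only: no gapped alignment, no indel calling.
* Paired-end mates are simulated as independent reads; the pairing
  constraint is not exploited during mapping.
* The repeat library of the original masking step is unpublished;
  k-mer multiplicity and a user-supplied library stand in for it, with
  the masking *contract* (intervals, lowercase/hard styles) unchanged.
* Genotype calling is count-based; no quality-aware likelihoods,
  imputation or phasing.
* The SNP error-rate figure of 1/10,000 quoted for the original
  procedure has no stated derivation and is not reproduced.
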
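---
title: "Methods: low-nitrogen-responsive lncRNA discovery and GWAS integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-nitrogen-responsive lncRNA discovery and GWAS integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nitrolnc)
library(dplyr)
```

nitrolnc implements, as one coherent toolkit, the analysis chain used to
dissect long noncoding RNA (lncRNA) responses to nitrogen starvation in
maize seedlings: lncRNA identification from assembled transcripts,
differential expression between high-nitrogen (HN) and low-nitrogen (LN)
hydroponic treatments in leaf and root, cis/trans target assignment,
miRNA-mediated competing-endogenous-RNA (ceRNA) networks, seedling
phenotype statistics, mixed-linear-model (MLM) genome-wide association,
linkage-disequilibrium (LD) candidate windows, and the intersection of
association candidates with expression calls. Because the raw data behind
such studies are rarely re-derivable at desk scale, every stage is paired
with a synthetic-data generator that plants known truth, and the test
suite validates each stage against that truth or against independent
brute-force oracles.

## The synthetic study

`sim_config()` fixes the study conditions; `simulate_study()` realizes
them coherently. The defaults mirror the design this kind of experiment
uses: ten chromosomes; a transcriptome of protein-coding genes,
intergenic lncRNAs (lincRNAs), antisense lncRNAs, and protein-coding
"decoys" that the identification cascade must reject; expression over
2 tissues x 2 nitrogen levels x 3 replicates (12 samples); a 255-line
association panel; and 17 seedling traits measured in 3 replicates under
both treatments.

Choices the generator makes, and why:

* **Counts** are negative binomial with log-normal baseline means
  (meanlog 4, sdlog 1.5 on the count-mean scale), which reproduces the
  heavy-tailed abundance spread of real RNA-seq. Dispersion defaults to
  0.1, typical of replicated plant RNA-seq.
* **Planting is exact.** A planted differential effect multiplies the LN
  mean of the designated tissue by exactly `2^log2fc`; a planted miRNA
  response element is the exact (optionally mismatched) reverse
  complement spliced at a recorded position; a planted QTL contributes an
  exact variance share. Exact planting makes recovery tests test the
  method, not the random number generator. For the same reason, planted
  differential transcripts have their baseline floored at the log-normal
  median: an effect planted on an unexpressed transcript is not a planted
  effect.
* **Noncoding sequences** are random DNA with every ATG-to-stop open
  reading frame (ORF) of 60+ codons broken; **decoys** carry a 120+ codon
  ORF built from a codon pool with strong positional base bias, so both
  coding-potential signals fire.
* **Response-element mismatches** are never placed at miRNA positions
  10-11, preserving the cleavage-site pairing that plant miRNAs require.
* **Planted ceRNA hub members** (the decoy lncRNAs and target mRNAs of
  the default two-star plan) are simulated as abundant, tightly
  regulated transcripts — baseline floored a log-unit above the median,
  dispersion 0.01, responding in both tissues — so the co-expression
  that defines a ceRNA edge is a real property of the planted
  transcripts rather than an accident of replicate noise. At the default
  dispersion of 0.1, no transcript pair reliably reaches the strict 0.95
  co-expression bar across twelve samples, which is itself informative
  about what that threshold selects for in real data.
* **Genotypes** are biallelic dosages with per-SNP allele frequencies
  uniform on `maf_range`, Bernoulli missingness, and optionally
  exponentially decaying linkage: haplotypes follow a binary Markov chain
  whose adjacent-marker correlation is `exp(-d/scale)`, so chain
  correlations multiply and dosage r² decays as `exp(-2d/scale)` — a
  closed form the LD-decay estimator can be tested against.
* **Phenotypes** are built per trait as a treatment mean, treatment-
  specific QTL effects (LN by default, so the tolerance index carries
  signal), a polygenic value drawn once per line from a multivariate
  normal with covariance proportional to the *realized* genomic kinship,
  and replicate noise scaled so the broad-sense heritability of line
  means equals `h2_target` in each treatment.
* In the demo scenario (`n_qtl > 0`), QTL-linked genes are planted as
  differentially expressed in both tissues — they emulate consistently
  LN-responsive candidates — and a `qtl_isolation` radius (default
  120 kb) around them is kept free of other planted-DE genes so candidate
  windows have unambiguous truth.

What the generator does **not** emulate: read-level artifacts (mapping
bias, positional coverage), isoform structure shared across transcripts,
batch effects, genuine population structure or admixture (a single
random-mating panel only), genotype-by-environment interaction beyond the
treatment-specific QTL device, and trait-trait genetic correlation.
Passing tests therefore demonstrate correctness of the algorithms under
the stated statistical model, not robustness to those real-data
complications.

All randomness flows from one seed through `stage_seed()`, a documented
integer hash, so each stage is independently reproducible and identical
configurations give byte-identical outputs.

## lncRNA identification

`run_filter_cascade()` applies five ordered filters: (1) length >=
200 nt — the field's defining lncRNA bound, applied inclusively; (2)
expressed at >= 0.5 FPKM in >= 1 sample (the literature states no
canonical cutoff; both knobs are parameters); (3) no same-strand
exon-level overlap with an annotated coding gene; (4) noncoding
composition; (5) noncoding ORF. The order — cheap structural filters
before sequence statistics — is the conventional reconstruction of such
pipelines; every threshold is exposed.

The two coding-potential signals are deliberately independent in kind,
replacing the usual pair of external tools with self-contained
equivalents: a Fickett TESTCODE score (position-dependent base
composition, standard published lookup tables; coding at >= 0.95) and a
longest-ORF rule (three forward frames, ATG to stop, coding at >= 100
codons; transcripts are stranded so the reverse strand is never
scanned). Transcripts failing **exactly one** of the two are transcripts
of uncertain coding potential (TUCP) — the discordant-call definition;
failing both is rejection. Surviving lncRNAs are antisense if any exon
overlaps a gene exon on the opposite strand, lincRNA otherwise; overlap
is exon-level, not span-level, because antisense classification concerns
transcribed overlap.

## Differential expression

One negative-binomial Wald test serves mRNAs, lncRNAs and miRNAs — a
single auditable statistical core rather than one tool per RNA class.
Counts are normalized by median-of-ratios size factors. Per transcript,
a moment dispersion estimate pooled across the two conditions is shrunk
toward a log-linear mean-dispersion trend with weight 0.3 on the local
estimate: at three replicates per condition the local estimate carries
only ~4 degrees of freedom while the trend is fitted across thousands of
transcripts, so the trend deserves the larger weight. The Wald statistic
for the log2 fold change (pseudocount 1) is referred to a moderated t
distribution on `nHN + nLN - 2 + prior_df` degrees of freedom with
`prior_df = 6`, crediting the trend with six effective dispersion
degrees of freedom. With these defaults the acceptance suite measures
the empirical null rejection rate at nominal 5% to be within about one
point of nominal at 3v3, with high power on planted 4-fold effects; a
plain normal reference is anticonservative there and an unmoderated t is
badly conservative. q-values are Benjamini-Hochberg within tissue;
significance is q < 0.05.

## Targets and the ceRNA network

Cis pairs are genes whose span lies within 100 kb of the lncRNA span
(closed boundary, strand-agnostic edge-to-edge distance; an inner
exclusion radius exists but defaults to off), annotated with the Pearson
correlation of log2(abundance + 1) across all samples. Trans pairs are
any lncRNA-gene pair with correlation strictly above 0.95 regardless of
location. The correlation scale (log2 + 1) is a package choice;
correlations are invariant to the common length/depth factors of
FPKM/TPM, so the unit fed in matters little.

The miRNA site scanner slides the reverse complement of the mature miRNA
along each (stranded) transcript and scores each offset with a plant-
style penalty: mismatch 1, G:U wobble 0.5, single-nucleotide target
bulge 2, all doubled at miRNA positions 2-13 (the extended 5' seed);
sites with penalty <= 3 are reported with the cleavage position opposite
miRNA position 10. The weight table is fixed and documented rather than
inherited from any external tool; at most one bulge per site keeps the
alignment space exhaustively enumerable, and the tests exploit exactly
that.

ceRNA construction follows four steps: restrict to differentially
expressed lncRNAs, mRNAs and (by default) miRNAs; exclude lncRNAs that
are probable miRNA precursors (an ungapped seed-and-extend local match
to a hairpin at >= 90% identity over >= 50 nt — precursor matches are
near-exact, so full local alignment would add cost, not sensitivity);
scan for shared binding sites; and emit triplets (lncRNA decoy, miRNA
core, mRNA target) whose lncRNA-mRNA correlation reaches the trans
threshold 0.95. A `direction_consistent` flag marks decoy-like
expression patterns (lncRNA and mRNA same sign, miRNA opposite) but does
not filter by default, since no quantitative rule for it is established.

## Phenotypes, heritability, tolerance index

Descriptive statistics use the n-1 standard deviation and Fisher g1/g2
moments (degenerate vectors report 0 with a flag). Broad-sense
heritability comes from the one-way random-effects ANOVA over lines
within a treatment: `H2 = s2G / (s2G + s2e / r)` with
`s2G = (MS_G - MS_e) / r`, `r` the harmonic-mean replicate count —
the standard estimator for replicated line trials, handling mild
imbalance through the harmonic mean. Two-way ANOVA F values (treatment,
genotype) use sequential sums of squares in that order against the
residual mean square; both pooled and per-treatment genotype F values
are available because either convention appears in trait tables. The
low-nitrogen tolerance index is literally HN mean / LN mean per line
(an `invert` flag gives the other orientation); lines with a zero LN
mean are excluded with a flag.

## Association mapping and LD windows

Markers are filtered at MAF >= 0.01 and missing rate <= 0.2, then
mean-imputed. Kinship is the VanRaden genomic relationship
`W W' / (2 sum p(1-p))` on centred dosages, bent to positive
semidefinite by eigenvalue flooring only if genuinely indefinite, so the
formula stays exact on clean data. Population structure enters as the
top two principal components of the centred dosage matrix — a
deterministic, dependency-free stand-in for a two-group structure
matrix, with a fixed sign convention.

The MLM `y = Xb + u + e`, `u ~ N(0, K s2g)`, is fitted EMMA-style: one
REML profile over `delta = s2e/s2g` on the eigenbasis of K (the P3D
approximation — variance components are not re-estimated per marker,
matching standard GWAS practice and desk-scale runtime), then a
generalized-least-squares Wald test per marker with a t reference on
`n - p - 1` degrees of freedom. With identity kinship this reduces
*exactly* to the ordinary F test, which is the module's primary oracle.
Marker R² is the incremental variance explained on the whitened scale,
in percent. Significance is p < 10^-4.6, the conventional
`-log10(p) > 4.6` line for this panel size.

LD decay computes pairwise dosage r² within chromosomes, bins by
distance, smooths the binned means by local regression (loess, span
0.5, pair-count weights), and reports the smallest distance where the
smoothed curve falls below r² = 0.1 (the threshold is a parameter; no
universal criterion exists). Candidate windows are closed intervals of
plus/minus the genome-average decay distance around each significant
SNP (per-chromosome distances are also computed); window membership is
any span overlap, so a feature touching the edge by one base is in.
Consistent candidates are window features differentially expressed at
q < 0.05 in at least one tissue, with direction taken from the most
significant tissue; they are finally joined back to the lncRNA cis- and
trans-target tables to list potential lncRNA regulators per candidate.

## Numerical and interface conventions

Coordinates are 1-based inclusive throughout — the native convention of
both R's genomic containers and the GFF3/VCF formats, so no boundary
conversion exists to get wrong. Matrices (counts, dosages) live in light
S3 containers with tibble metadata; every analysis result is a tibble,
fitted objects provide `tidy()`/`glance()`/`autoplot()`. Degenerate
inputs follow a consistent policy: impossible configurations error
early with a named reason; degenerate but meaningful data (constant
traits, zero-variance expression rows, monomorphic markers) are
excluded or flagged, never fatal. Ties in best-site selection are broken
deterministically by order; network node and edge orderings are sorted
so exports are byte-stable.

Problem sizes in the tests and acceptance script — 1000-transcript
assemblies, 2000-transcript count matrices, 255 lines x 2000 SNPs, 20
seeds per stochastic check — are the package's chosen validation scale:
large enough that Monte-Carlo noise is small relative to the margins
being checked, small enough to run interactively.

## Known limitations

The DE model is two-group per tissue; multi-factor designs and batch
correction are out of scope. The scanner considers at most one bulge and
no target-side loops of length > 1. The precursor filter checks windows
of exactly the configured length, so a longer, weaker homology spread
could evade it. P3D underestimates significance for markers with very
large effects (where per-marker variance components would differ), and
PCA covariates only proxy true structure when differentiation is roughly
linear in allele frequencies. LD decay assumes enough marker density per
chromosome for the binned curve to be estimable. The generator's
independence assumptions listed above mean real-data performance should
be validated separately on pilot data.
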
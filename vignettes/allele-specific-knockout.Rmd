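---
title: "Allele-specific knockout design and backcross linkage mapping with askit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific knockout design and backcross linkage mapping with askit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(askit)
```

## The problem

A dominant trait segregating between two inbred mouse strains — say a
wild-derived donor strain and C57BL/6 — can be mapped in an N2 backcross
and then *validated* by inactivating only the donor copy of the candidate
gene in F1 hybrids. Because SpCas9 strictly requires a 5'-NGG-3' PAM next
to its protospacer, a strain SNP that *creates* an NGG on the donor
haplotype (where the recurrent haplotype fails the motif) makes Cas9
cutting allele-specific by construction: the guide can be perfectly
complementary to both alleles, yet only the donor allele is cleavable.
`askit` implements the full computational arc: haplotype reconstruction,
PAM-gain guide selection, founder genotyping with allele-of-origin
assignment, and binary-trait interval mapping — plus generators that
simulate each data type with known ground truth.

## Haplotypes and coordinates

`build_haplotype()` applies a validated strain variant table (SNPs and
left-anchored indels, VCF conventions) to a reference locus and keeps an
explicit bidirectional coordinate map (`hap2ref`, `ref2hap`), with `NA`
marking bases that have no homolog (inside insertions or deletions).
Everything downstream — homologous-window extraction, primer spans, exon
projection — runs through this map, so there is no approximate liftover
anywhere.

All internal coordinates are 1-based and closed, the convention of the
R/Bioconductor stack the package sits on; BED's 0-based half-open
intervals are converted when read. Multi-allelic VCF records are split
into biallelic records, symbolic alleles are rejected, and records with
heterozygous sample genotypes are dropped by default: the package assumes
inbred (fixed) strains, and a non-fixed site cannot anchor an
allele-diagnostic design. Variants overlapping `N` reference bases are
rejected, and scanning treats `N` as matching nothing.

## Guide design

`scan_protospacers()` enumerates every `[protospacer][PAM]` window on both
strands; `classify_specificity()` projects each window onto the other
allele and assigns one of four classes:

* `TARGET_ONLY_PAM` — the other allele's homologous window fails the PAM
  motif. This is the only class the default design policy trusts, because
  PAM loss abolishes cutting outright.
* `PROTOSPACER_VARIANT` — PAM intact on both alleles, at least one
  mismatch inside the protospacer. Single-mismatch discrimination by the
  guide itself is unreliable (it depends on mismatch position and
  identity), so these sites are reported but excluded from pairing unless
  `allow_protospacer_variant = TRUE`.
* `SHARED` / `UNMAPPABLE` — identical windows, or windows crossing an
  indel.

A consequence of motif degeneracy worth stating: a SNP at the N of NGG
never confers specificity, and the classifier treats it so.

`select_guide_pair()` encodes a two-cut ORF-loss policy: the site in the
earliest coding exon, paired with the farthest-downstream qualifying site
in a different exon, maximizing the dropout if both cuts rejoin; ties
break to the 5'-most coordinate. This "wide pair" heuristic maximizes the
chance that at least one cut (or the pairwise deletion) destroys the
reading frame; it is a documented policy, not an optimum. When fewer than
two qualifying sites exist in two exons the design is reported infeasible
with the best singles listed — a scientific answer about the locus, not
an error.

Quality rules default to GC between 25% and 75% and no TTTT run (a
pol-III terminator); both are conventional and configurable, and
`count_offtargets()` is deliberately a plain Hamming-distance counter
over PAM-bearing windows, not an activity score.

## Founder genotyping

Fragment-length screening (`call_fragment_genotype()`) mimics
capillary-electrophoresis sizing: peaks under 10% of the tallest peak in
a sample/assay are noise; each retained peak is matched to the nearest
per-allele expected product length; deviations within ±1 bp (the default
sizing tolerance) are wild-type. Alleles whose expected lengths differ by
less than twice the tolerance cannot be resolved by sizing, and calls on
them are allele-`ambiguous` — which is exactly why the pipeline then
sequences carriers.

Clone reads (`assign_clone()`) are aligned global-on-the-read with affine
gap penalties (opening ≫ extension, so one contiguous indel beats
scattered gaps). Allele of origin is a majority vote over the diagnostic
inter-strain SNPs the read covers; ties and uncovered reads are
`ambiguous`, and alignments under 90% identity are discarded as cloning
artifacts. An indel is attributed to editing only within ±10 bp of a
designed cut site (Cas9 cuts bluntly 3 bp 5' of the PAM), separating
edits from natural strain indels. An animal's allele is declared intact
only when at least 3 clones assign to it and all are wild-type — absence
of evidence from fewer clones is treated as weak.

Frame classification is exact where it can be: net sizes not divisible by
3 are frameshifts; in-frame edits are re-translated through the gene
model and called `premature_stop` when a stop appears before 50% of the
intact protein length. ORF loss = frameshift or premature stop;
`summarize_founders()` counts carriers per animal, never per clone.

## Linkage mapping

The mapping model is a dominant binary trait in a backcross: at any
genome position the latent genotype is heterozygous or homozygous
recurrent with flanking-marker probabilities from a two-state HMM under
the Haldane (no-interference) map function. Haldane was chosen because it
matches the simulator's independent-interval recombination model exactly
and is standard when no interference model is asserted; the map function
is isolated so Kosambi could be swapped in one place. Missing genotypes
emit nothing in the HMM and are thereby marginalized over flanking
informative markers; an individual untyped on a whole chromosome sits at
the 1/2:1/2 prior.

At each grid position the two-penetrance binomial likelihood

$$L(p_1, p_0) = \prod_i \left[ q_i\, p_1^{y_i} (1-p_1)^{1-y_i} +
  (1-q_i)\, p_0^{y_i} (1-p_0)^{1-y_i} \right]$$

is maximized by EM over the latent genotype ($q_i$ is the probability of
heterozygosity given marker data), and the LOD is the log10 ratio against
a single-probability null, whose MLE is the phenotype mean. The EM core
is compiled code with a data-driven start plus a small fixed multistart,
converging on the log-likelihood to near machine precision; at a
saturated coincident marker with a 50/50 split the peak equals
$n \log_{10} 2$ analytically, which the tests verify to $10^{-6}$.
Genome-wide significance comes from seeded phenotype-label permutations
(empirical right-continuous quantile of the per-permutation maxima);
permuted scans reuse the genotype probabilities and run a lighter EM
(single start, looser tolerance), which perturbs the threshold by far
less than its Monte-Carlo error.

Fine mapping (`minimal_interval()`) intersects recombinant constraints:
a phenotypic animal must be heterozygous at the causal position, a
non-phenotypic animal homozygous. A typed marker is permitted for an
animal when its genotype matches; the gap between adjacent markers is
permitted when either flank matches, i.e. a single crossover in the gap
can reconcile the other flank. This single-crossover-per-gap reading is
the standard fine-mapping assumption; under no interference an unobserved
double crossover inside one marker gap around the causal position can in
principle evict it from the intersection, which is why containment is
guaranteed only when the causal position itself is genotyped (the regime
the containment tests exercise, with markers at 1 cM spacing where the
double-crossover probability per gap is below $10^{-4}$ per animal).
Animals permitting no position at all contradict the single-locus model
and are reported as phenocopies or genotyping errors; they are excluded
only on explicit request.

## What the simulator does and does not emulate

`make_strain_pair()` plants PAM-gain SNPs that are donor-only by
construction (reference NGH rewritten so the SNP completes NGG, with a
protospacer sampled to pass the default quality rules, and no G allowed
immediately downstream so the planted window contains exactly one
donor-only site). Background SNPs fall at 7 per kb by default — the
order of divergence between *M. m. domesticus* and *M. m. musculus*
genomes — and are masked out of planted windows so truth labels stay
exact. Defaults describe a 9 kb, 19-exon locus; tests use smaller loci
with the same structure.

`simulate_backcross()` draws one recombinant F1 gamete per chromosome as
a Markov chain over loci with Haldane switch probabilities, and phenotype
as Bernoulli(penetrance) for donor-allele carriers versus
Bernoulli(phenocopy rate) otherwise; defaults are 559 animals, full
penetrance, no phenocopies. `simulate_editing()` cuts each allele × guide
with its configured probability (defaults 0.8 on target, 0 off target,
matching a strong allele-restricted design), draws indel sizes from a
categorical distribution favoring small deletions (−1…−10, with a small
insertion tail to +3; the support is −12…+6) — a stated convention, since
no per-animal size table exists to fit — places deletions across the
blunt cut and insertions at it, sizes fragment peaks with Gaussian noise
(0.3 bp), and samples 10 TA clones per amplicon with a fair coin between
alleles. Each embryo is one germline genotype; mosaicism is not modeled.

Passing tests on these simulations demonstrate internal consistency —
the pipeline recovers exactly what the generative model planted — not
robustness to chromatogram artifacts, PCR chimeras, mosaic founders or
segregation-distorting loci, none of which the generator emulates.

## Numerical choices and scales

* HMM emission error is $10^{-10}$ by default: effectively exact typed
  genotypes while avoiding literal zeros.
* Recombination fractions in map estimation are capped at 0.49 with a
  warning; such pairs are effectively unlinked and their distance is not
  estimable.
* EM convergence: log-likelihood change below $10^{-13}$, at most 1000
  iterations; negative LOD from rounding is clamped to 0.
* Fragment tolerance ±1 bp and the 10% relative peak-height floor mirror
  common sizing practice; both are arguments, not constants.
* Test and check scales: 100 replicate panels of 559 for segregation;
  200 simulated loci plus 1000 embryos for the specificity guarantee;
  100 genome scans with 200 permutations each for planted-locus
  recovery; 200 pedigrees for interval containment. These sizes keep the
  whole suite comfortably reproducible on a single CPU while leaving
  Monte-Carlo error well inside the asserted bands.

## Known limitations

Only 3'-PAM geometry (SpCas9-like) is implemented; F2/intercross designs,
multi-QTL models, X-chromosome handling and quantitative traits are out
of scope; off-target assessment is a mismatch count, not a cutting-
activity model; and dominance of the donor allele is hard-coded in the
N2 machinery, as the design requires.
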
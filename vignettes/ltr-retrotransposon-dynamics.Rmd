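---
title: "Dating, classifying and modelling LTR retrotransposon dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating, classifying and modelling LTR retrotransposon dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was
genuinely open. The package addresses a standard question in plant genome
biology: given a catalogue of full-length LTR retrotransposons (such as
the *Morus notabilis* Copia/Gypsy catalogue), when did they insert, how
are they organized, what selection do they experience, and how quickly are
they removed?

## The dating model

An intact LTR retrotransposon carries two long terminal repeats that are
identical at the moment of insertion, because both are copied from the
same template during reverse transcription. Afterwards each LTR
accumulates substitutions independently at the neutral rate *r* per site
per year. The pairwise divergence *K* between the two LTRs therefore
estimates *2rT*, and the insertion age is

    T = K / (2 r),      r = 1.3e-8 substitutions/site/year (default)

`align_ltr_pair()` produces a global affine-gap alignment (match +2,
mismatch −2, gap open −6, gap extend −1 per residue), gap columns are
excluded from the compared sites ("pairwise deletion"), and
`k2p_distance()` applies the Kimura two-parameter correction

    K = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))

with *P* and *Q* the transition and transversion proportions. K2P is the
default because transition bias is ubiquitous in plant nuclear DNA and the
correction is closed-form; JC69 (`model = "JC69"`) is selectable for
comparison and is provably never larger than the K2P estimate when
transitions are present. Assumptions worth keeping in mind: no gene
conversion between the two LTRs (which would reset the clock), a single
genome-wide rate *r* (absolute ages scale directly with it, which is why
`r` is exposed everywhere), and enough compared sites for the correction
to be stable (`min_sites = 20`; alignments under 60 % identity are flagged
`low_identity` and excluded from dating because the alignment itself is
unreliable; distances past the logarithm's domain edge are flagged
`saturated`).

`age_histogram()` bins ages into right-open 0.1-MY bins from zero,
reporting the modal bin midpoint (the "peak" of an insertion wave) and
cumulative fractions below any cutoff.

## Families and genome proportions

Two elements belong to one family under the 80-80-80 rule when their best
local alignment spans at least 80 bp, covers at least 80 % of a sequence,
and has at least 80 % identity (gaps counting against identity).
"Coverage" is of the **shorter** sequence by default — the common reading
of the rule, and the one that keeps a truncated copy in its parent's
family — with `coverage_of = "both"` available because the rule's
canonical statement does not fix the denominator. Families are the
single-linkage transitive closure of the linked relation (complete linkage
behind a flag), computed separately per superfamily, and named
`RLC_k`/`RLG_k` by descending size with ties broken toward the
lexicographically smallest member id, so naming is deterministic and
input-order invariant.

All-pairs alignment is quadratic, so a prefilter skips pairs sharing no
13-mer; for two random 2-kb sequences the expected number of chance shared
13-mers is ~0.06, while any pair satisfying the 80-80-80 rule shares many,
so the filter is effectively lossless (and `prefilter = FALSE` restores
the exhaustive computation; the tests verify both give the same
partition).

Genome proportions merge overlapping/bookended hit intervals per family
before summing, so nested RepeatMasker-style hits are not double-counted.

## Structural signals

The PBS is detected as the best match, within a 30-nt window 3′ of the
5′LTR, to the reverse complement of a tRNA's 3′-terminal segment. tRNA
gene sequences usually lack the post-transcriptionally added CCA, so CCA
is appended when absent; probe lengths 12 down to 10 nt are tried with at
most one mismatch, and ties among tRNAs with identical acceptor ends are
reported as one ambiguous call listing all candidate amino acids (usage
tables are amino-acid level for the same reason). The thresholds are
pragmatic defaults for typical 10–18-nt PBSs, are all exposed, and are not
claimed to match any particular published pipeline.

The PPT is the longest ≥ 90 %-purine run of at least 10 nt ending within
30 nt of the 3′LTR; TSDs are exact flanking duplications of 4–6 nt; the
boundary matrices tabulate per-position base counts over 30-bp flanks of
the 5′ element boundary and report information content `2 − H` in bits
(no small-sample correction by default, since the intended use is
comparing positions within one dataset).

## Selection screening

Selective pressure on RT domains is summarized by Nei–Gojobori (1986)
counting. Sites: at each codon position the synonymous fraction is the
number of synonymous single-nucleotide changes divided by the number of
changes that do not create a stop, so S + N equals exactly 3 × codons —
the stop-excluded renormalization variant. Differences between two codons
average over all orderings of the mutational pathway, excluding pathways
through stop codons (when every pathway is blocked, all orderings are used
with stop-passing steps counted as nonsynonymous — a rare, documented
fallback). Proportions are Jukes–Cantor corrected and the family-level
omega is `mean(dN)/mean(dS)` over valid pairs; pairs at or beyond
saturation (p ≥ 0.75) are excluded, and families with no valid pair are
"unestimable" rather than silently 0 or Inf.

Classification against 1 is exact by default (`neutral_band = 0`), which
matches the usual reading of dN/dS thresholds. For *recovery testing*
against simulated truth, the package's tests use a ±0.25 neutrality band:
a continuous estimator has measure-zero probability of landing exactly on
1, so a strict threshold cannot identify a truly neutral family; the band
size was chosen from the estimator's sampling spread at the test's family
size (6 members × 300 codons, ~0.1 s.d. at omega = 1) before the tests
were frozen. NG86 is a counting estimator: its absolute omegas differ from
likelihood (codeml-style) estimates, so only the position of omega
relative to 1 — not its third decimal — should be carried into
interpretation.

## Phylogeny

RT distance matrices use the same K2P machinery with pairwise gap
deletion; saturated pairs are set to a ceiling (default 3 substitutions
per site) and flagged rather than dropped, so the matrix stays complete.
Trees are Saitou–Nei neighbor joining via `ape::nj()`, a deliberate
method substitution for maximum-likelihood inference: NJ is exact on
additive matrices (the tests verify this against an exhaustive
least-squares topology search), fast, and entirely sufficient for the two
downstream questions the package asks of a tree — does some edge split
Copia from Gypsy exactly, and which labeled reference is each family
representative nearest to. Negative NJ branch lengths are clamped to zero
with the deficit moved to the adjacent edge. Bootstrap support resamples
alignment columns with replacement (seed-keyed to the column draws, so
leaf input order cannot change supports) and reports, per internal edge of
the full-data tree, the fraction of replicate trees containing the same
bipartition; 100 replicates is the desk default and 1000 mirrors
full-scale practice. One representative RT per family (the member with the
longest intact RT) enters the big trees. Lineage assignment takes the
nearest labeled reference RT by pairwise distance with a configurable
ceiling (default 1.5) beyond which a family is "unassigned"; reference
sequences are licensed external data (Repbase), so the package ships only
the lineage names and accepts any labeled FASTA.

## Deletion dynamics and genomic context

If elements are removed at a constant per-element rate after insertion,
the ages of the survivors are exponential, and the half-life `ln(2)/λ`
summarizes removal. `fit_exponential()` reports the MLE `λ = 1/mean(T)`
together with a one-sample KS statistic against `Exp(λ)`. Two caveats are
deliberately baked into the output: the KS p-value is approximate
(anticonservative) because λ is estimated from the same data, and on age
distributions that are visibly non-exponential — the usual situation for
recent insertion waves — the half-life is a descriptive bound, not a
parameter of a validated model. The KS statistic is the honest readout:
the tests verify that uniform age distributions produce systematically
larger statistics than genuinely exponential samples of the same size.

Context classification uses precedence exon > intron > promoter >
intergenic. Exon/intron calls use the element midpoint within a gene span,
so an element straddling a junction gets exactly one call, and intron
ordinals count in transcription order (reversed for minus-strand genes).
The promoter call defaults to *span overlap* with the window upstream of
the transcription start (2000 bp default — a conventional figure, exposed
because nothing in the data fixes it): an element several kb long inserted
100 bp upstream of a TSS has its midpoint far outside any reasonable
window, so a pure midpoint rule would be structurally unable to call real
promoter insertions. `mode = "midpoint"` restores the strict rule for
users who want symmetric treatment of all four contexts.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; the defaults are the
package's reference conditions, not tuning knobs: 400-bp LTRs, 0.41 GC,
`r = 1.3e-8`/site/year, transition/transversion ratio κ = 2, insertion
ages uniform on 0–3 MY, 5-bp TSDs, 300-codon RT ORFs. Ancestors have two
identical TG…CA LTRs, a PBS that is the reverse complement of the chosen
tRNA's acceptor end, a 15-nt purine tract abutting the 3′LTR, and a
stop-free RT frame. Aging applies a Poisson(r·T·L) number of K2P
substitution events per LTR (sites drawn with replacement, so multiple
hits occur exactly as the distance corrections assume) and an
omega-thinned codon process to the RT: proposals are uniform across
nucleotides (a Jukes–Cantor-style codon clock — deliberately matched to
NG86's unweighted path counting, so omega recovery tests measure the
estimator, not a proposal-bias artifact), stop-creating proposals are
rejected, and nonsynonymous proposals are accepted with relative
probability omega. Each superfamily carries one ancestral RT pool from
which family RTs diverge (~8 % of sites per lineage), giving the deep
Copia/Gypsy signal the tree checks look for while LTRs and internal
regions remain family-specific. tRNA assignment is Met-biased (50 %),
emulating the Met dominance typical of plant LTR element PBSs.

`plant_insertions()` writes elements into a random background genome with
exact TSDs and generated gene models, realizing configured fractions of
promoter, intron and intergenic insertions, and shifts gene coordinates
past each insertion so the emitted GFF3, element loci and recorded truth
are mutually consistent.

What the generator does **not** emulate — and what passing its tests
therefore cannot show about real data: insertions and deletions within
LTRs (divergence is substitution-only, so alignment gap handling is
exercised only lightly), rate heterogeneity among sites and among
elements, gene conversion between LTRs, nested insertions, solo-LTR
formation, GC-biased substitution, and real tRNA sequence structure.
Recovery rates of 100 % on fresh simulated elements are a correctness
check of the detectors' definitions, not a sensitivity estimate for
degraded genomic copies.

## Numerical choices and problem sizes

Degenerate and edge cases are handled explicitly: empty inputs error
early with stage names; saturated distances are flagged (dating) or
ceilinged (phylogeny) rather than propagated as NaN; identical sequences
give omega "unestimable" rather than 0/0; two-taxon trees are built
directly with half-distance edges; naming ties are broken
lexicographically everywhere so all outputs are deterministic under a
fixed seed.

The validation suite runs at desk scale, chosen so the full test suite
completes in about two minutes: 500 LTR pairs of 1 kb for the age
regression (slope expected in [0.9, 1.1]); 30 elements from 3 families
for clustering recovery; 100 families of 6 × 300 codons across omega ∈
{0.2, 1, 2} for selection-class recovery; 5–8-taxon matrices (with an
exhaustive topology oracle at n = 5) for NJ; 2000 draws for the
exponential-rate check. Dataset-scale reproduction of published mulberry
statistics (mean Copia length, cumulative age fractions) requires the
MnTEdb element catalogue and genome, which must be supplied locally via
`options(ltrdyn.dataset_dir = ...)`.

## Known limitations

Absolute ages inherit the full uncertainty of *r*; only relative ages are
robust. NG86 omegas are not comparable in absolute value to
likelihood-based estimates. NJ trees are adequate for split and
nearest-reference questions but are not a substitute for ML inference if
branch support near the root matters. The 80-80-80 implementation targets
catalogues of thousands of elements; far larger inputs would need an
indexed search rather than the 13-mer prefilter. Real multiple alignment
of diverged RT families (with indels) is delegated to external aligners;
`family_dnds()` consumes any codon alignment, and the pipeline's
equal-length fast path applies to simulator output and curated
alignments.
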
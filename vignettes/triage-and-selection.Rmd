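---
title: "Triage and selection analysis of duplicated carboxypeptidase genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage and selection analysis of duplicated carboxypeptidase genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MCPtriage)
```

## The problem

When a metallocarboxypeptidase (M14) gene duplicates, the copy's fate is
written into its sequence long before any wet-lab assay: it may keep the
full catalytic inventory (an active enzyme), lose one or more catalytic
residues while keeping the fold (a pseudoenzyme), or accumulate enough
damage — multiple conserved-residue substitutions, internal stops,
truncations — that no functional product is plausible (a pseudogene).
Because the CPA/B catalytic mechanism is exceptionally well characterised,
a residue-level reading is informative: H69, E72 and H196 coordinate the
catalytic zinc; R127, N144 and R145 bind the substrate's C-terminal
carboxylate; E270 performs acid–base catalysis; and the residue at position
255, at the base of the S1′ pocket, largely sets which C-terminal amino
acids are cleaved. All positions use the bovine CPA1 numbering convention.

`MCPtriage` implements this reading as a reproducible pipeline: reference
numbering by global alignment, rule-based triage, residue-255 specificity
prediction, a from-scratch Nei–Gojobori test of purifying selection on
paralog pairs, and cohort-level statistics (tandem arrays, gene-size
comparison). A synthetic-data generator produces truth-labelled inputs so
that every stage is testable without any database access.

## Reference numbering

Rather than a multi-species pan-alignment, numbering is carried by a single
scheme reference: each query is globally aligned to it (affine gaps;
BLOSUM62, gap open −11, extend −1, so a length-L gap costs 11 + L) and
every alignment column with residues in both rows contributes one entry to
a strictly monotone query-to-reference map. The reference's own numbering
starts at a configurable offset so a reference that retains a prodomain can
keep the mature-enzyme convention. Positions aligned to a query gap, or
outside a fragmentary query, are reported as absent — absence at catalytic
positions is itself triage evidence.

This replaces a curated multiple alignment deliberately: the pan-alignment
serves two roles (numbering and a conservation inventory), and both are
captured by the scheme configuration plus a pairwise map, which is
reproducible without a fixed 12-species sequence set. The cost is that the
structural-conservation inventory cannot be derived inside the package; it
is a required scheme input. The packaged `syntheticScheme()` carries a
*synthetic* 310-residue reference with the real positional conventions but
a generated sequence and a 20-position structural inventory sampled from
itself; it exists to make the machinery fully testable, and real analyses
must supply a curated scheme via `functionalScheme()`.

## Triage rules

Rules apply in order; the first match wins.

1. **Pseudogene (fragment / premature stop).** Any catalytic position with
   no aligned query residue, or an internal stop whose reference-equivalent
   position lies at or before the last catalytic position (270 by default).
   Stops downstream of catalysis are recorded but not forcing — they may
   remove only a C-terminal anchor region.
2. **Pseudogene (structural decay).** At least `structuralThreshold`
   substitutions at structurally conserved positions. The default threshold
   of 2 operationalises "multiple conserved residues substituted"; the
   output records raw counts, so re-thresholding is a re-tabulation, not a
   re-run.
3. **Pseudoenzyme.** At least one catalytic-position substitution.
4. **Active** otherwise.

For specificity, the residue at the 255-equivalent maps through a
configurable table: `{A,V,L,I,M,F,W,P}` → hydrophobic-substrate,
`{D,E}` → basic-substrate, `{R,K,H}` → acidic-substrate,
`{S,T,N,Q,C,Y,G}` → polar/unknown; anything else (including `X` and `*`)
is undetermined, with a warning. Two entries are package conventions rather
than settled biochemistry and are deliberately override-friendly: glycine
sits in the polar/unknown class (a Gly-255 paralog has shown
hydrophobic-substrate activity, so users may prefer to regroup it), and
histidine is grouped with the basic residues on standard physicochemical
grounds. Both choices are visible in `defaultClassTable()`.

## The Nei–Gojobori test

For each codon, the expected number of synonymous sites is the sum over its
three positions of (synonymous single-nucleotide changes) / (changes
considered); nonsynonymous sites are three minus that. Under the default
stop handling (`"exclude"`, matching the common MEGA behaviour) changes
creating a stop are dropped and the position denominator renormalised, so
S + N = 3 × codons exactly; the strict-NG86 variant (`"count"`, stops as
nonsynonymous over denominators of 3) is a flag, because the two differ
slightly. Observed differences between two codons are averaged over all
minimal mutational pathways (1, 2 or 6 orderings), discarding pathways that
pass through a stop unless every pathway does. Codon pairs containing gaps,
ambiguous bases or stops are excluded pairwise — not by complete deletion —
to keep signal from fragmentary paralogs, and the excluded count is
reported.

Proportions pS = Sd/S and pN = Nd/N are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − (4/3)p), which is undefined at p ≥ 3/4: saturated pairs
fail loudly with the offending proportion rather than returning a number.
Variances use the delta method on binomial proportions,
Var(d) = 9p(1−p)/((3−4p)²·m) with m the matching site count — the
"analytical method" — and the one-tailed test of strict neutrality
(dN = dS) against purifying selection (dN < dS) uses
Z = (dS − dN)/√(var dS + var dN), taking the covariance of dS and dN as
zero, as is standard for this codon-based test. When both variances and the
statistic are zero (identical sequences) the result is defined as Z = 0,
p = 0.5. Per-pair p values are reported unadjusted, as is conventional for
this test; a Benjamini–Hochberg column (`p_BH`) is emitted as a clearly
labelled extension.

`pairwiseSelectionTable()` adds per-family mean dS − dN summaries and a
Welch t-test contrasting a focal family (default CPO) with all other pairs.

## The synthetic generator

The generator emulates the *shape* of a curated duplicated-gene cohort, not
any particular database snapshot:

* **Ancestors** back-translate the scheme reference with uniform synonymous
  codon choices, optionally substituting a small fraction (3–5%) of
  non-scheme positions so family ancestors differ while remaining trivially
  alignable.
* **Class edits are constructive**: a pseudoenzyme gets one catalytic
  substitution via a single-nucleotide codon edit; a pseudogene gets two
  structural substitutions, an internal stop upstream of position 270, or a
  truncation removing a catalytic position; an active paralog gets only
  synonymous and non-scheme-position edits. Truth labels therefore hold
  exactly, not just in expectation, and label mixtures are allocated by
  largest remainder so realized mixtures equal requested ones. The default
  mixture (83% active, 8% pseudoenzyme, 9% pseudogene) mirrors the rounded
  composition reported for duplicated CPO cohorts, and the default
  residue-255 mixture is Arg-dominated with polar minorities, CPO-like.
* **Divergent pairs** evolve from a common ancestor by repeated proposals
  (uniform site, uniform alternative nucleotide), rejecting stop-creating
  proposals, accepting synonymous ones always and nonsynonymous ones with
  probability ω, until each lineage has accepted
  `round(codons × divergence / 2)` substitutions. This
  acceptance-probability mechanism is deliberately simpler than a full
  mutation–selection codon model; it is transparent and sufficient to
  calibrate the sign and power of the dS − dN test. Realized acceptance
  counts — not intended counts — are the truth channel.
* **Locus cohorts** draw lognormal gene sizes per group. Defaults are
  calibrated to the two vertebrate MCP gene-group means (≈15,214 bp for the
  frequently-duplicated genes, ≈83,159 bp for the rest) with a common
  log-scale spread of 0.8, a realistic skew for vertebrate gene-size
  distributions; tandem clusters are planted with intra-cluster gaps below
  the detection threshold and dispersed genes a megabase apart.

What passing tests on these cohorts shows — and does not. Exact truth
recovery demonstrates that alignment, numbering and the decision rules
compose correctly; it does not show robustness to real-data pathologies the
generator omits: mis-annotated exon boundaries, frame-shifting indels
inside the alignment, alternative start sites, or assembly gaps. The
generator also applies no indels during pair evolution (codon alignments of
generated pairs are gap-free) and models no codon-usage bias.

### What "recovering ω" means here

The proposal mechanism re-draws rejected stop-creating proposals over *all*
sites, so positions whose mutant spectrum contains stops (e.g. Tyr third
positions) substitute at 2/3 the rate of unconstrained positions, while the
site inventory still counts them as full sites. The expected NG-measured
dN/dS is therefore not exactly ω but ω·(m_non·S)/(m_syn·N), where m_syn and
m_non count the ancestor's synonymous and nonsynonymous non-stop mutation
opportunities; `acceptanceExpectation()` computes this (the factor is
≈ 1.03 for typical compositions). Recovery checks compare the mean estimate
over three independent 10,000-codon pairs with this expectation: a single
pair's dN/dS has a coefficient of variation near 4% at divergence 0.3, so a
10%-band check on one draw would be a noise lottery rather than a method
check.

## Numerical and design choices

* **Tie-breaking and determinism.** The alignment engine's traceback is
  deterministic, so identical inputs give identical alignments, maps and
  calls; all generator functions are pure functions of their seed, and the
  pipeline writes byte-identical numeric outputs on re-run.
* **Degenerate inputs.** Empty proteins refuse to align; saturated codon
  pairs refuse correction; zero comparable codons is an error;
  constant-size gene groups report t = 0, p = 1; one-member groups report
  descriptives only; empty cohorts tabulate to empty tables.
* **Problem sizes.** The shipped checks use 300-codon pairs (1000 neutral
  replicates for calibration, 200 per ω for power), 10,000-codon pairs for
  ω recovery, a 300-paralog cohort for classifier exactness, 200 randomized
  indel cases for numbering accuracy, and 100 locus cohorts of n = 100/100
  for the size-test level — sizes at which Monte-Carlo error is small
  relative to the properties being checked while the whole suite stays
  interactive.
* **Tandem threshold.** 250 kb between gene spans; chosen as a synteny-scale
  default since "tandem" is usually judged by eye, and prominent in the
  configuration and run log.
* **Both size tests.** Welch's t (unequal variances — gene-size variances
  differ wildly between groups) and Kruskal–Wallis are both reported,
  neither privileged, since both are in common use for this comparison.

## Limitations

The triage is protein-level: genuine frameshifts are only seen through
their protein consequences, and both evidence channels (protein inventory,
internal stops) are recorded rather than adjudicated. The specificity
prediction is a single-position convention plus a pocket report; it does
not model pocket geometry, and polar-255 enzymes are honestly labelled
unknown. Pairwise reference numbering can misplace residues in regions of
very low similarity — coverage and substitution evidence are reported so
such calls can be audited. The selection test inherits the known
limitations of counting methods: no transition/transversion weighting, no
codon-frequency model, and the Jukes–Cantor correction saturates near
p = 3/4.

## A compact session

```{r example, eval = FALSE}
scheme <- syntheticScheme()
cohort <- makeSyntheticCohort(scheme = scheme, nParalogs = 30, seed = 1)
calls <- triageCohort(cohortProteins(cohort), scheme)
tabulateCohort(transform(as.data.frame(calls),
                         family = cohortTruth(cohort)$family))

sel <- makeSelectionCohort(nFocal = 10, nOther = 10, seed = 1)
tab <- pairwiseSelectionTable(sel$cds, sel$manifest)
attr(tab, "groupTest")

loci <- makeLocusCohort(seed = 1)
detectTandemArrays(loci)
compareGeneSizes(loci)
```
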
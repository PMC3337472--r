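---
title: "Saturation statistics for F1 mosaic mutagenesis screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saturation statistics for F1 mosaic mutagenesis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicsat)
```

## The problem

A saturation mutagenesis screen asks two quantitative questions. Before the
screen: how many mutagenized chromosomes must be scored so that essentially
every gene of interest is hit at least once? After the screen: given the
spectrum of recovered alleles, what fraction of the discoverable genes did we
actually find, and how many are there in total?

`mosaicsat` implements both calculations for screens run by F1 clonal
(mosaic) analysis — the design in which FLP/FRT-induced mitotic recombination
produces clones of homozygous mutant cells in otherwise heterozygous
first-generation animals, so that mutations lethal to the organism can still
be scored in a tissue. Its worked example throughout is a published
Drosophila screen of this design for miRNA-pathway genes, whose allele
spectrum (45 retained mutations over 24 complementation groups) ships with
the package.

## The Poisson design model

EMS mutagenesis induces lethal point mutations at a characterizable rate per
chromosome arm (0.65 in the shipped example). With $A$ arms screened, the
expected number of lethal mutations is $A \rho$; spread over $G$ essential
genes in the screened region, the expected hits per gene are

$$\lambda = \frac{A\,\rho}{G},$$

and under the Poisson model the probability that a given gene is hit at
least once — the *coverage* — is $1 - e^{-\lambda}$. `arms_needed()` inverts
this for planning. The model assumes homogeneous mutability across genes;
per-gene target-size variation is deliberately excluded from the design
arithmetic (it is available in the simulator as `gene_weights`).

A practical wrinkle: published screen totals are not always internally
consistent. The shipped example states both "56,000 arms at 0.65 per arm"
and "29,900 lethal mutations screened", although $56{,}000 \times 0.65 =
36{,}400$. A `screen_design` therefore accepts an explicit
`lethal_mutations_screened` override which, when present, is authoritative
for downstream arithmetic and raises a first-class inconsistency warning
that travels into reports. This reproduces printed downstream numbers
(29,900/1,440 rounds to 21 hits per gene) while keeping the discrepancy
visible.

## Saturation inference from the allele spectrum

The data after the screen are the *allele spectrum*: for each locus
recovered, the number of independently isolated alleles. Modelling effective
hits per detectable locus as Poisson($\lambda$), the saturation — the
fraction of detectable loci observed at least once — is $1 - e^{-\lambda}$,
and the total number of detectable loci is the observed count divided by the
saturation.

Two estimators of $\lambda$ are provided:

* **Plug-in** (`plug_in_saturation()`): take the observed mean alleles per
  locus as $\hat\lambda$. This is the rule screens traditionally quote. For
  the shipped spectrum, mean $= 45/24 = 1.875$, saturation $= 1 -
  e^{-1.875} = 0.847$ (reported 85%), total $= 24/0.847 = 28.4$ (reported
  28). Both the exact mean and its one-decimal rounding 1.9 give the same
  rounded reports; a flag selects the rounded-mean variant.

* **Zero-truncated Poisson MLE** (`ztp_mle()`): loci with zero alleles are
  unobservable, so the observed counts are draws from a Poisson conditioned
  on being $\geq 1$, whose mean is $\lambda/(1 - e^{-\lambda}) > \lambda$.
  The plug-in rule therefore overstates $\lambda$ and saturation. The MLE
  solves
  $$\frac{\hat\lambda}{1 - e^{-\hat\lambda}} = \bar{k},$$
  which is exactly the stationarity condition of the zero-truncated Poisson
  log-likelihood $\sum_i \left[k_i \log\lambda\right] - n\lambda - n\log(1 -
  e^{-\lambda}) + \text{const}$. For the shipped spectrum $\hat\lambda =
  1.423$, saturation $0.759$, total $31.6$. The ordering — ZTP saturation
  below plug-in, ZTP total above — is a theorem, and the test suite checks
  it on random spectra along with agreement between the mean-equation root
  and an independent dense-grid maximizer of the log-likelihood.

The trivial upper bound on the total — every retained mutation its own gene,
here 45 — is reported alongside as an interpretation, distinct from any
resampling interval.

### Numerical choices

The mean equation is solved by bisection on the strictly increasing map
$\lambda \mapsto \lambda/(1-e^{-\lambda})$, bracketed on $(10^{-9},
\bar{k}]$ (the map exceeds the identity, so the root lies below the observed
mean), to an absolute residual tolerance of $10^{-10}$ by default. Bisection
was chosen over Newton for unconditional convergence; the map is evaluated
with `expm1` for accuracy at small $\lambda$. An all-singleton spectrum
($\bar{k} \le 1$) is the degenerate boundary where $\hat\lambda \to 0$ and
saturation is unidentifiable; it raises a dedicated error class rather than
returning a boundary value. Headline values are additionally reported with
manuscript-style rounding (half away from zero; nearest percent for
saturation, nearest integer for totals, one decimal for means), with the
unrounded value always retained.

### Bootstrap intervals

`bootstrap_interval()` resamples *loci* with replacement and returns
percentile intervals for $\hat\lambda$, saturation and the total. Loci are
the exchangeable units of the spectrum; resampling mutations would break the
zero-truncation structure (it could manufacture empty loci). Under the ZTP
method, resamples with mean $\le 1$ are degenerate and are redrawn, up to
100 attempts per resample, with a warning counting the redraws; a spectrum
so singleton-heavy that redraws are exhausted errors out as degenerate. The
seed is a required argument, and identical seeds give identical intervals.

## Complementation-group inference

Pairwise complementation tests are stored sparsely as unordered pairs with
results in {`complements`, `fails`, `partial`, `untested`};
noncomplementation is the OR over phenotype channels (lethality or reporter
derepression), with the channel retained per pair. Loci (`build_groups()`)
are the connected components of the failure graph — the formalization of
"mutations that fail to complement are classified as alleles". Output
ordering is deterministic (members sorted, groups labelled by smallest
member) so results are diffable.

`partial` results do not merge groups by default (`flag_only`): the one
partial case in the motivating screen turned out to be an
isoform-restricted hypomorph of the same gene — a P-element insertion
disrupting only a subset of transcript isoforms, which complemented all
point alleles and only partially failed the locus deficiency — and silently
merging (or silently ignoring) partial pairs would hide exactly that
biology. The alternatives `as_fail` and `as_complement` are available; the
`as_fail` partition is always a coarsening of the `as_complement` one.

`find_intransitive_triangles()` reports triples where $a$–$b$ and $b$–$c$
fail but $a$–$c$ complement, and `flag_hypomorph_candidates()` raises
per-mutation flags: a mutation that fails (or partially fails) a
group-anchored deficiency or a group member while complementing at least
one other member is a hypomorph candidate, as are the two *complementing
endpoints* of an intransitive triangle inside one group (the shared failing
allele behaves like a null and is deliberately not flagged). Group members
that outright complement a deficiency the rest of their group fails are
flagged `conflict_with_deficiency`.

Because full pairwise testing of $n$ lines needs $\binom{n}{2}$ crosses
(990 for 45 lines) and published matrices are rarely saturated, the
partition always carries `testing_completeness`, the fraction of pairs with
a non-`untested` result; sparse matrices over-split and should be read with
that number in hand.

## The screen simulator

`simulate_screen()` draws a whole screen from a generative model with a
single seeded RNG stream (draw order: total mutation count, gene
assignments, detection, recovery, penetrance, hypomorph labels, test
errors):

1. total lethal mutations $\sim$ Poisson(arms $\times$ rate);
2. each mutation lands on one of `n_essential_genes` (multinomial, optional
   target-size weights — equivalent to independent per-gene Poissons);
3. mutations in the detectable "pathway" subset (`n_pathway_genes`) give a
   scorable F1 phenotype with probability `p_f1_detect`; all others are
   invisible to the screen;
4. detected candidates are recovered as balanced stocks with probability
   `p_recover`, and recovered mutations pass the penetrance/expressivity
   filter with probability `p_penetrant` (independent Bernoulli thinning per
   mutation — the speculated mechanism of F1 loss, somatic mosaicism of the
   mutagenized germ line, is modelled only as this thinning);
5. retained same-gene pairs fail to complement unless either member is an
   isoform-restricted hypomorph (probability `p_hypomorph`), and each
   pairwise test is mis-scored with probability `p_test_error`.

Defaults are the motivating screen's own conditions: 56,000 arms, 0.65
lethals per arm, 1,440 essential genes in the screened 40% of the genome,
`p_recover` $= 73/950$ and `p_penetrant` $= 45/73$ (the screen's measured
attrition), `p_f1_detect` $= 1$, noise probabilities 0, and uniform gene
weights (the analysis model assumes homogeneity). `n_pathway_genes`
defaults to 30, a round value inside the 28–45 range that saturation
analysis of the shipped spectrum supports. By construction the thinned
retained count is Poisson with mean equal to the product of all factors, and
the test suite checks this conservation law in mean and variance.

`validate_estimators()` turns the simulator on the estimators: replicate
screens, both estimators per replicate, and a recovery summary
(mean/SD/bias against the true pathway-gene count, degenerate-replicate
counts, optional bootstrap-interval coverage). The parameter-recovery study
in the test suite runs 200 replicates at the published regime scaled
tenfold down — 4,600 arms over 144 essential genes, preserving the ~21
expected hits per gene and the measured attrition, so each replicate retains
a spectrum of realistic size (~30 mutations over ~19 loci) while 200
replicates stay fast. At that size the test suite checks that the
mean ZTP estimate lies within 15% of the true count of 30 (the ratio form
carries a modest upward noise bias), that the plug-in estimator sits below
it as theory requires, and that noiseless complementation grouping
reproduces the true partition in every replicate.

## What the simulator does and does not emulate

It emulates the statistical skeleton of the screen: Poisson mutagenesis
over genes, restriction of detectability to a pathway subset, independent
per-mutation attrition at the screen's measured rates, same-locus
noncomplementation with hypomorph exceptions, and scoring noise. It does
not model FLP/FRT clone geometry, eye-disc development, reporter intensity,
linkage between mutations on one arm, second-site lethals, or per-gene
mutability chemistry. Passing parameter-recovery tests therefore shows the
estimators are consistent with their own model assumptions at realistic
sizes — not that real screens satisfy those assumptions; in particular,
real per-gene target sizes vary, which inflates apparent saturation.

## Known limitations

* All saturation inference assumes a homogeneous Poisson rate across
  detectable loci; gamma-mixed (unseen-species-style) and Bayesian variants
  are out of scope.
* The ZTP estimator is unidentifiable on all-singleton spectra; it reports
  that condition rather than extrapolating.
* Complementation grouping trusts the failure graph; with sparse testing the
  component structure is a lower bound on locus merging, which is why
  completeness is always reported.
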
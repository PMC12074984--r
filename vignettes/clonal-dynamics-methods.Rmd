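---
title: "Models and methods for murine haematopoietic clonal dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for murine haematopoietic clonal dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonaldyn)
```

`clonaldyn` implements an inference stack for the clonal dynamics of mouse
haematopoietic stem cells (HSC) and multipotent progenitors (MPP) from two
data modalities: whole-genome sequencing of single-cell-derived colonies
(somatic mutations shared across colonies reconstruct the cell genealogy)
and very deep duplex-consensus sequencing of blood (variant allele
fractions, VAFs, of driver-gene mutations measure clone sizes down to
~1e-5). This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The generative population model

The stem cell pool is modelled as a linear birth--death process with a hard
bound: each cell divides symmetrically at rate $\lambda$ (per week) and
exits (death or differentiation) at rate $\nu$, with divisions suppressed
while the population sits at the cap $N$. Two epochs are used: an
embryonic/early growth epoch up to 10 weeks post-conception and an adult
epoch. Each daughter cell acquires a Poisson($m$) number of somatic
mutations per division, with $m = 1.8$ by default, so branch lengths in
mutations ("molecular time") are a noisy clock over ancestral divisions.

`simulate_population()` runs an exponential-clock (Gillespie) simulation at
single-cell resolution, recording every cell's parent and birth time;
`sample_phylogeny()` reconstructs the exact genealogy of a uniform sample
of extant cells and draws branch mutation counts as sums of per-division
Poisson draws, so zero-length branches (the polytomies of the early tree)
arise naturally. One property of such genealogies worth keeping in mind:
the division count along a *sampled* lineage is size-biased — roughly
$2\lambda t$ during exponential growth and $2\nu t$ at the cap, not
$\lambda t$ — because ancestors that divided more leave more descendants.
The cohort scripts under `analysis/` calibrate their rates against that
realized count.

Within `abc_rejection()` the same model is simulated by a faster two-stage
scheme: a count-level Gillespie pass for the population trajectory (exact
while the population is small, deterministic exponential growth above 500
cells, constant at the cap) followed by backward coalescent sampling of the
sampled genealogy conditional on that trajectory (pair-merge probability
$k(k-1)/(n(n-1))$ at each recorded birth event; rate
$k(k-1)\,b(t)/N(t)$ in the smooth phases, with $b(t)$ the per-capita birth
rate). The test suite cross-checks that both routes give the same interval
distributions.

## Cell-state ontogeny: the hidden Markov tree

Cell identity (EMB, HSC, MPP) is modelled as a discrete-time Markov chain
taking one step per mutation of molecular time. The zygote is EMB and is
locked in that state for the first 10 mutations; afterwards EMB may commit
to HSC or MPP, and HSC and MPP may interconvert, but nothing returns to
EMB. A branch of integer length $l$ (excluding its overlap with the lock)
carries the transition matrix $M^l$. Observed tip phenotypes are emitted
with error $\epsilon = 10^{-12}$ (two-stage cell sorting is nearly
error-free): probability $1-\epsilon$ for the matching phenotype and
$0.5\,\epsilon$ otherwise.

`tree_loglikelihood()` is the upward (pruning) algorithm over end-of-branch
states; `viterbi_decode()` tracks per-branch argmaxes to return the jointly
most probable assignment, breaking ties in the fixed order EMB < HSC < MPP.
Both traverse edges in postorder, which is robust to zero-length branches.
When a tree carries a root stem (mutations between the zygote and the most
recent common ancestor of the sampled colonies), the EMB prior enters
through the stem's transition row and the stem-end state is summed (or
maximized) over — with no stem this reduces to the textbook root prior.

`fit_transition_rates()` maximizes the summed log-likelihood on the logit
scale with 8 random restarts (Nelder--Mead, relative tolerance 1e-10),
because boundary estimates are expected: MPP-to-HSC transitions are of
order 1 in 1,000. Model comparison is by AIC across groupings plus a
likelihood-ratio test of the nested "HSC-first" constraint
($p_{\mathrm{EMB\to MPP}} = 0$). Whether the chain should step over raw or
sensitivity-normalized branch lengths is not determined by the data; the
package applies it to whatever lengths the tree carries and the analysis
scripts use normalized (molecular-time) lengths.

## Clade analytics and the polytomy estimator

A clade "present at molecular time $t$" is rooted at the first node at time
$\ge t$ whose parent lies strictly before $t$ (crossing inclusive of $t$);
tips shallower than $t$ count as singletons. Shannon diversity of the
partition at 50 mutations summarizes lineage richness. The HSC/MPP mixing
metric at 25 mutations is the unweighted mean over clades of the absolute
difference between the clade's HSC proportion and the overall sampled HSC
fraction; its null distribution reshuffles tip labels. The reported
p-value is the conservative rank statistic; `randomized = TRUE` switches to
the tie-randomized version, which is exactly uniform under the null and is
what the calibration tests use, since the permutation distribution is
discrete on small trees.

Directional parsimony ("HSC-first" vs "MPP-first") counts the minimal
number of irreversible conversions needed to produce the observed tips:
with the root pinned to the starting state, that minimum equals the number
of maximal pure subtrees of the opposite phenotype (verified against
exhaustive search in the tests).

The early-life mutation rate per division uses the polytomies: collapsing
zero-length internal branches, a multifurcation of out-degree $d$ implies
$d-2$ mutationally silent divisions under a binary genealogy, and the
lineage count $L$ by 12 mutations implies $L-1$ divisions in total. With
$z$ silent of $n$ divisions, $\hat m = -\ln(z/n)$ (the Poisson rate whose
zero class matches), e.g. 44 silent of 265 gives 1.80. The 95% interval
maps the Wilson interval of $z/n$ through $-\ln$; exact and normal
constructions differ only slightly, and Wilson is the declared choice
here. Trees with fewer than 10
lineages by 12 mutations are rejected as uninformative.

## Variant and colony quality control

The nine pooled-colony filters run in a fixed order and each site records
its first failing filter: homopolymer runs (>= 5 bp), mutant-read strand
bias (two-sided binomial p < 0.001 and > 80% unidirectional),
beta-binomial overdispersion (rho < 0.1 for SNVs / 0.15 for indels with
more than 25 colonies, 0.20 otherwise), VAF filters (carrier VAF
significantly below clonal, or below half the median of
beta-binomial-passing variants), germline (aggregate VAF not significantly
below 0.45, one-sided binomial p >= 0.001), SNVs within 10 bp of an indel,
missing sites (< 6x depth in over a third of colonies), clustered sites
within 10 bp, and non-variable sites. The beta-binomial likelihood is
parameterized by (mean, overdispersion) with the mean fixed at the
aggregate VAF; the rho MLE uses a dense log-grid on [1e-6, 0.89] refined by
golden-section search, and matches a 4,000-point grid oracle to three
decimals in the tests. Colony QC excludes colonies with passing-variant
mean VAF < 0.4 (exclusive) and operationalizes "evidence of non-clonality"
— a visual call in practice — as the mode of the VAF kernel density
(bandwidth 0.05) falling below 0.35.

The thirteen duplex table-level filters mirror the post-processing of
duplex-consensus calls; all cutoffs are configurable and default to the
values above. Two choices are worth flagging. The end-repair-artefact
probability is an input column with a 0.1 cutoff (the upstream tool's
threshold is unpublished). The recurrence filter needs the number of
sequenced samples per batch, which a pre-filtered table understates, so
`duplex_filter_config(batch_sizes = ...)` can supply the true batch sizes.
Filters 12 (synonymous impact) and 13 (human-homologous position) default
to off because the fitness and dN/dS-style analyses need synonymous
variants.

## Tree building and branch normalization

`build_tree()` replaces a maximum-parsimony search, which is not this
package's contribution: genotype calls (Present at VAF >= 0.3 with >= 6x
depth; Unknown below 6x) define carrier sets; a greedy laminar (nested or
disjoint) subfamily is kept, preferring better-supported sets, and becomes
the topology. Dropped sets that are subsets of kept clades are read-dropout
shadows and harmless; dropped sets that are no clade's subset are genuine
four-gamete conflicts, and if they carry more than `max_conflict` (5%) of
variants the build is refused in favour of an externally supplied Newick
tree. Every variant (including conflicting ones) is then placed on the
branch maximizing a binomial read-count likelihood (carrier VAF 0.48,
error VAF 0.01); uncovered colonies are uninformative and never veto a
placement. Branch lengths are the per-branch variant counts, and
`normalize_branch_lengths()` divides terminal branches by the colony's
detection sensitivity (from the per-sample asymptotic regression
`burden = a(1 - e^{-k depth})`) and shared branches by the mean sensitivity
of their descendants, rounding to integers for molecular-time work.

## Population-size trajectories

Coalescent theory links the rate of branchpoints among $k$ sampled
lineages to $N/\lambda$: each intercoalescent interval gives the classic
skyline estimate $k(k-1)\,\Delta t/2$. `skyline()` optionally pools
intervals (a generalized skyline) and always pools zero-length intervals
(polytomies) with their neighbours; `skyline_constant()` is the pooled
constant-size MLE. A Gaussian-process smoother is deliberately out of
scope; the classic estimator is sufficient for the qualitative trajectory
shape and is validated against direct Kingman simulations (median within
15% at 50 tips).

`abc_rejection()` estimates $(\lambda, \nu, N)$ of the bounded two-epoch
birth--death model by rejection ABC: uniform priors ($N$ in 1e2--1e5 cells,
$\lambda$ in 0.01--0.15 divisions/day, $\nu$ in $[0, \lambda]$,
independently per epoch), genealogies simulated at the observed tip count
and age, and retention of the closest fraction (default 5%) by Euclidean
distance on standardized summaries. The summary statistics are a design
choice of this package: lineage-through-time counts at 12
evenly spaced molecular-time points, coalescence counts per epoch, mean
root-to-tip molecular height, and Shannon clade diversity at 50 mutations,
each standardized by its prior-predictive standard deviation. Fewer than
100 accepted draws triggers a warning and widens acceptance to 100.
Early-epoch parameters are weakly identified and reported only as such;
adult-epoch posteriors are the headline output ($1/\lambda$ as weeks
between symmetric divisions, $1/\nu$ as weeks between exits, $N/\lambda$
in HSC-years using 52.18 weeks/year). Simulation-based calibration in the
tests checks 95% credible-interval coverage of the true $N$ across 100
runs at $N = 5\times 10^4$.

## The VAF spectrum and the fitness landscape

Under a continuous-time branching model of constant-rate variant
acquisition, the expected density of variants over $l = \log(\mathrm{VAF})$
is

$$\rho(l) = \frac{\theta}{1 - 2e^l}
  \exp\!\left(-\frac{e^l}{\varphi\,(1 - 2e^l)}\right),
\qquad \theta = N\tau\mu, \qquad
\varphi = \frac{e^{st} - 1}{2N\tau s}
\;\xrightarrow{s\to 0}\; \frac{t}{2N\tau},$$

where $\varphi$ is the typical maximum VAF a variant reaches by age $t$.
`simulate_duplex_vafs()` does not sample from $\rho$: each variant arises
uniformly in time in a population of $N = N\tau\,\lambda$ cells and founds
a clone whose size at sampling is drawn from the exact transition law of
the linear birth--death process (geometric mixture; fitness adds to the
birth rate), with VAF $= n/(2(N+n))$ — the mapping that transforms the
free-clone size density exactly into the $(1-2e^l)$ structure of
$\rho(l)$. Because $\rho$ is a continuum approximation and the simulator
is exact, the goodness-of-fit checks between them are a genuine dual-route
validation. VAFs below the detection floor (default 5e-5, where real
duplex data lose sensitivity) are censored.

`fit_neutral()` bins $\log$ VAFs of synonymous/intronic variants by
Doane's rule ($k = 1 + \log_2 n + \log_2(1 + |g_1|/\sigma_{g_1})$, rounded
up) and minimizes the L2 distance between observed and predicted log
*reverse-cumulative* densities — matching how such spectra are presented —
over $(\log\theta, \log\varphi)$ on a coarse grid refined by Nelder--Mead.
Whether the objective should use reverse-cumulative or per-bin densities is
ambiguous in the source; the reverse-cumulative choice is stable at the
sparse high-VAF tail and is validated by self-consistency (refitting the
fitted model's own predictions returns the parameters). $N\tau = t/2\varphi$
and $\mu = \theta/N\tau$ follow. The estimator has a known ridge between
$\theta$ and $\varphi$ when $\varphi$ approaches the floor, so recovery is
assessed by the median over seeds. `fit_nonsynonymous()` holds $\varphi$
from the neutral fit and matches expected counts below the maximum
synonymous VAF (1.99e-4). `fit_dfe()` fits the exponential-power
distribution of fitness effects $\mu(s) \propto \exp(-(s/d)^\beta)$ with
$\beta = 3$ fixed, mixing $\rho(l \mid \varphi(s))$ by 64-point
Gauss--Legendre quadrature on $s \in (0, 4]$ per year (ample headroom over
the 50--200%/year band of interest) and maximizing the per-variant
conditional likelihood over the observed window; a profile-likelihood
interval on the non-neutral fraction spans zero when few variants exceed
the neutral range.

Unit conversions are provided for the downstream arithmetic: geometric
compounding between annual growth and per-division advantage
(`annual_to_per_division()`; 200%/year at one division per 6.4 weeks is
~14.4%, reported as ~15%), the drift threshold $s^* = \lambda/N$, the
establishment time $1/s$ years, and per-bp rates over the diploid mouse
genome (5.46e9 bp, configurable). `scale_panel_rate()` rescales a
panel rate to the genome by the naive ratio and documents the conversion;
composition-aware weightings are left to the caller.

## Signature attribution

Signature extraction (hierarchical Dirichlet processes, catalogue
deconvolution) is out of scope; attribution takes catalogues as input. The
bundled `sbs_catalog_synthetic()` is a *synthetic stand-in* built in code
with the qualitative character of the three processes active in mouse
blood — a CpG-deamination clock (SBS1-like), a flat clock (SBS5-like) and a
C>A oxidative process (SBS18-like) — because the reference vectors are not
redistributable here; every function accepts any 96-channel catalogue.
`adjust_for_opportunities()` rescales channels by target/reference
trinucleotide frequencies and renormalizes. Per-mutation membership is the
Bayes posterior catalogue x category prior, branch attribution is the mean
posterior over the branch's SNVs (branches under 30 SNVs are best pooled
into a shared category, mirroring the burden limits of mouse colonies),
and signature-specific burden slopes reuse the mixed model
`burden ~ age + (0 + age | animal)`.

## What the synthetic data do and do not emulate

The generators reproduce the statistical structure the estimators assume:
birth--death genealogies with Poisson mutation accrual and heritable state
transitions; genotype matrices with Poisson depth (default 14x), binomial
read sampling at VAF 0.5, germline sites, and artifact classes shaped for
each filter (recurrent strand-biased sites, low-VAF cross-colony
contamination, homopolymer-adjacent sites, clustered pairs); and duplex
spectra from the exact branching-process law with a neutral/selected
mixture. They do not emulate sequence context, mapping error, index
swapping, copy-number change, cell-type-specific division rates, or
non-uniform panel coverage — so green tests certify the inference
machinery on model-faithful data, not robustness to every artefact of real
sequencing. Phenotype mislabelling is off by default in fixtures
(`epsilon_obs = 0`); the HMM's $\epsilon = 10^{-12}$ is a model constant,
not a data property.

Problem sizes in the tests and scripts (populations of 300--2,000 cells,
20--90 colonies, cohorts of ~100 duplex samples, 2,000 ABC simulations per
run) were chosen so each estimator operates in the regime where its
assumptions bind while the full suite runs in minutes; all scale linearly
if larger studies are needed.

## Interfaces

All containers round-trip through plain text: genotype matrices and variant
tables as TSV, trees as Newick with `colony|PHENOTYPE` tip labels. The
numbered scripts under `analysis/` are the workflow drivers (simulate,
filter, build, ontogeny, population dynamics, fitness, signatures); they
are thin narratives over the exported functions, which are the supported
programmatic interface.
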
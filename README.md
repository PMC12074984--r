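# clonaldyn

Clonal dynamics and somatic evolution of mouse haematopoiesis: simulation
and inference for stem cell population dynamics, cell-state ontogeny, and
the fitness landscape of clonal haematopoiesis.

## The problem

Somatic mutations accumulate in every blood stem cell and are shared by a
cell's descendants, so the pattern of mutation sharing across single-cell
derived colonies reconstructs the genealogy of the haematopoietic stem cell
(HSC) and multipotent progenitor (MPP) pool, while ultra-deep duplex
sequencing of blood measures the size of mutant clones down to variant
allele fractions (VAFs) of ~1e-5. `clonaldyn` is for researchers who want
to infer, from such data or from simulations of them:

- **Mutation accumulation** — per-colony burdens corrected for sequencing
  depth, and the mixed-model accumulation rate
  `burden ~ age + (0 + age | animal)`.
- **Early development** — the mutation rate per symmetric cell division
  from the polytomies at the top of the tree: with `z` of `n` ancestral
  divisions mutationally silent, `m = -log(z/n)` (Poisson zero class).
- **Cell-state ontogeny** — a three-state (EMB/HSC/MPP) hidden Markov tree
  taking one step per mutation, with transition matrix `M`, branch
  transition probabilities `M^l`, an upward (pruning) likelihood, a
  Viterbi-like decoder, and maximum-likelihood transition-rate fits with
  nested "HSC-first" comparisons.
- **Population dynamics** — coalescent intervals, the classic skyline
  estimate `N/lambda = k(k-1) dt / 2` per interval, and rejection ABC over
  a bounded two-epoch birth-death model (priors: `N` in 1e2-1e5 cells,
  `lambda` in 0.01-0.15 divisions/day, `nu` in `[0, lambda]`).
- **The fitness landscape** — the branching-process density of variants
  over `l = log(VAF)`,
  `rho(l) = theta/(1-2e^l) * exp(-e^l/(phi(1-2e^l)))` with
  `theta = N*tau*mu` and `phi = (e^{st}-1)/(2*N*tau*s)`, fitted to duplex
  spectra for `N/lambda`, mutation rates, and an exponential-power
  distribution of fitness effects `mu(s) ~ exp(-(s/d)^beta)`, `beta = 3`.
- **Quality control** — the nine pooled-colony somatic-variant filters
  (beta-binomial overdispersion, strand bias, germline, homopolymer,
  clustering, ...), colony-level QC, and the thirteen duplex table-level
  filters.
- **Signature attribution** — Bayes per-mutation membership over a
  96-channel catalogue, branch-level attribution, opportunity adjustment,
  and signature-specific burden slopes.

Everything downstream is testable without any data download: the package
simulates populations, genealogies, state labels, colony genotype matrices
(with germline sites and filter-targeted artifact classes) and duplex VAF
spectra with the statistical structure the estimators assume.

## Worked example

```r
library(clonaldyn)

# a bounded birth-death stem cell pool: embryonic growth to 10 weeks
# post-conception, then slow adult turnover, sampled at 30 months
model <- pop_model(data.frame(duration = c(10, 150),
                              lambda = c(1.35, 0.3),
                              nu = c(0.6, 0.26),
                              cap = c(2000, 2000)))
trace <- simulate_population(model, t_end = 133, seed = 11)
tree <- sample_phylogeny(trace, n_tips = 60, seed = 8)
tree <- label_states(tree, state_params(0.08, 0.05, 0.002, 0.0005), seed = 9)
table(tree$tip.state)
#> HSC MPP
#>  26  34

polytomy_mutation_rate(tree)
#> mutations/division: 2.20 (CI 0.83-3.92) from 1 silent of 9 divisions

mixing_null(tree, t = 25, n_perm = 1000, seed = 10)
#> mixing metric 0.416 (expected HSC fraction 0.43), p = 0.003

sp <- simulate_duplex_vafs(N_tau = 16500, mu_neutral = 1.8e-4 * 100,
                           age_t = 2, seed = 12)
fit_neutral(sp)
#> 84 neutral variants -> N/lambda = 12,036 HSC-years (truth 16,500)

annual_to_per_division(2, 6.4)
#> 0.144   # 200%/yr at one division per 6.4 weeks is ~14.4% per division
```

The polytomy interval is wide and the single-tree `N/lambda` estimate is
noisy by design — one 60-colony tree and 84 variants carry limited
information; the test suite quantifies recovery across seeds and the
`analysis/` scripts run the full multi-mouse workflow.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on synthetic data
and write tables under `results/`:

1. `01_simulate_cohort.R` — three young and three aged mice: populations,
   colony genealogies, state labels, one 14x genotype matrix.
2. `02_filter_and_burden.R` — the filter suite, colony QC, depth-corrected
   burdens, the mixed-model burden slope and per-bp rate.
3. `03_tree_analytics.R` — tree building, Shannon diversity, HSC/MPP
   mixing with its reshuffling null, directional parsimony, polytomy rate.
4. `04_ontogeny_hmm.R` — hidden Markov tree fits per age group, HSC-first
   likelihood-ratio test, decoding, state-probability trajectories.
5. `05_population_dynamics.R` — skyline trajectories and the ABC
   posterior for `(N, lambda, nu)`.
6. `06_fitness_landscape.R` — neutral and non-synonymous fits, the DFE,
   and fitness-unit conversions.
7. `07_signatures.R` — branch signature attribution and per-signature
   burden slopes.

The methods vignette (`vignettes/clonal-dynamics-methods.Rmd`) documents
the models, parameter defaults, numerical choices and limitations.

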
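#!/usr/bin/env Rscript
# Simulate the study cohort: bounded birth-death stem cell populations for
# three young (3-month) and three aged (30-month) mice, colony sampling,
# heritable EMB/HSC/MPP state labelling, and one colony genotype matrix.
#
# Ages are tracked in weeks post-conception (3 weeks gestation): a 3-month
# mouse is sampled at ~16 weeks, a 30-month mouse at ~133 weeks. The
# population grows fast in the embryonic epoch (to 10 weeks post-
# conception), then approaches its adult size bound with slow turnover.
# Mutations accrue at 1.8 per daughter per division.

library(clonaldyn)

dir.create("results/trees", showWarnings = FALSE, recursive = TRUE)
set.seed(20260901)

# Rates are calibrated to the realized division count along a sampled
# lineage, which is size-biased to ~2*lambda*t during growth and ~2*nu*t at
# the cap: embryonic growth puts ~27 divisions (~48 mutations) on every
# lineage by 10 weeks post-conception, and adult turnover accrues ~45
# mutations/year at 1.8 per division. The cap is scaled down from the
# inferred ~7e4 pool so the cohort simulates in seconds; coalescent
# patterns depend on N over the division rate, not on N alone.
model <- pop_model(
  epochs = data.frame(duration = c(10, 150),
                      lambda = c(1.35, 0.3),
                      nu = c(0.6, 0.26),
                      cap = c(2000, 2000)),
  mutations_per_division = 1.8)
ontogeny <- state_params(p_emb_to_hsc = 0.08, p_emb_to_mpp = 0.05,
                         p_hsc_to_mpp = 0.002, p_mpp_to_hsc = 0.0005)

cohort <- data.frame(
  mouse = c("Y1", "Y2", "Y3", "A1", "A2", "A3"),
  age_weeks = c(16, 16, 16, 133, 133, 133),
  n_colonies = c(60, 60, 60, 90, 90, 90))

trees <- list()
for (i in seq_len(nrow(cohort))) {
  mouse <- cohort$mouse[i]
  seed <- 100 + i
  repeat {  # high embryonic turnover makes early extinction common
    trace <- suppressWarnings(
      simulate_population(model, cohort$age_weeks[i], seed = seed))
    if (!trace$extinct && length(trace$alive) >= cohort$n_colonies[i])
      break
    seed <- seed + 1000
  }
  ph <- sample_phylogeny(trace, cohort$n_colonies[i], seed = 200 + i)
  ph <- label_states(ph, ontogeny, seed = 300 + i)
  # cell sorting assigns every colony a phenotype: the rare lineage still
  # uncommitted at sampling sorts into either compartment at random
  emb <- which(ph$tip.state == "EMB")
  if (length(emb)) {
    ph$tip.state[emb] <- sample(c("HSC", "MPP"), length(emb),
                                replace = TRUE)
    ph$tip.label <- paste0(sub("\\|.*$", "", ph$tip.label), "|",
                           ph$tip.state)
  }
  trees[[mouse]] <- ph
  write_tree_newick(ph, file.path("results/trees",
                                  paste0(mouse, ".nwk")))
  message(sprintf(
    "%s: %d colonies, %d HSC / %d MPP, mean root-to-tip %.0f mutations",
    mouse, cohort$n_colonies[i], sum(ph$tip.state == "HSC"),
    sum(ph$tip.state == "MPP"),
    mean(node_mol_time(ph)[seq_len(cohort$n_colonies[i])])))
}

# genotype matrix (reads at 14x with germline sites and artifact classes)
# for one aged mouse, the substrate of the filtering analysis
cm <- simulate_genotype_matrix(trees$A1, mean_depth = 14, n_germline = 40,
                               seed = 42)
write_colony_matrix(cm, "results/genotype_matrix_A1.tsv")
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
message(sprintf("genotype matrix: %d sites x %d colonies",
                nrow(cm$sites), length(cm$colonies)))
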
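#!/usr/bin/env Rscript
# Mutational-signature attribution on the simulated cohort: draw branch
# mutations from the bundled synthetic SBS1/SBS5/SBS18-like catalogue with
# an early-life SBS18 bias, attribute per-branch proportions with the Bayes
# membership formula, and fit signature-specific burden slopes with age.

library(clonaldyn)

dir.create("results", showWarnings = FALSE)
set.seed(20260907)

cat96 <- sbs_catalog_synthetic()
# opportunity adjustment: mildly different trinucleotide composition of the
# mouse genome relative to the catalogue's reference composition
ctx <- unique(clonaldyn:::.context_of_channel())
ref_freq <- setNames(rep(1 / 32, 32), ctx)
target_freq <- setNames(rep(1 / 32, 32) * runif(32, 0.8, 1.25), ctx)
cat_adj <- adjust_for_opportunities(cat96, ref_freq, target_freq)

cohort <- read.csv("results/cohort.csv")
burdens <- list(); ages <- animals <- c()
for (i in seq_len(nrow(cohort))) {
  mouse <- cohort$mouse[i]
  tr <- read_tree_newick(file.path("results/trees", paste0(mouse, ".nwk")))
  n_tip <- length(tr$tip.label)
  depth <- node_mol_time(tr)
  # per-colony mutation channels: early mutations (first 30 of molecular
  # time) lean on the oxidative-damage signature, later ones on the clocks
  sig_burden <- matrix(0, n_tip, 3,
                       dimnames = list(NULL, colnames(cat_adj)))
  for (tp in seq_len(n_tip)) {
    n_mut <- round(depth[tp])
    t_mut <- sort(runif(n_mut, 0, depth[tp]))
    w_early <- c(0.15, 0.25, 0.60)   # SBS1, SBS5, SBS18 weights
    w_late <- c(0.25, 0.70, 0.05)
    sig <- ifelse(t_mut < 30,
                  sample(1:3, n_mut, TRUE, prob = w_early),
                  sample(1:3, n_mut, TRUE, prob = w_late))
    chan <- vapply(sig, function(k)
      sample(rownames(cat_adj), 1, prob = cat_adj[, k]), character(1))
    post <- branch_attribution(chan, rep(1 / 3, 3), cat_adj)
    sig_burden[tp, ] <- post * n_mut
  }
  burdens[[mouse]] <- sig_burden
  ages <- c(ages, rep((cohort$age_weeks[i] - 3) / 52.18, n_tip))
  animals <- c(animals, rep(mouse, n_tip))
}
B <- do.call(rbind, burdens)
fits <- suppressWarnings(signature_burden_rate(B, ages, animals))
tab <- do.call(rbind, lapply(names(fits), function(s)
  data.frame(signature = s, slope = fits[[s]]$slope,
             lo = fits[[s]]$slope_ci[1], hi = fits[[s]]$slope_ci[2],
             intercept = fits[[s]]$intercept)))
write.csv(tab, "results/signature_burden_rates.csv", row.names = FALSE)
print(tab, row.names = FALSE)
message("clock-like signatures rise with age; the oxidative-damage-like ",
        "signature concentrates in the early-life intercept")
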
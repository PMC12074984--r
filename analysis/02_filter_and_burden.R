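#!/usr/bin/env Rscript
# Somatic-variant quality control and mutation-burden estimation on the
# simulated cohort: the nine pooled-colony filters, colony-level QC,
# depth correction of per-colony burdens, and the mixed-model burden-vs-age
# slope (the in-silico analogue of the ~45 SBS/year, ~48-at-birth result).

library(clonaldyn)

dir.create("results", showWarnings = FALSE)
set.seed(20260902)

cm <- read_colony_matrix("results/genotype_matrix_A1.tsv")
res <- filter_colony_variants(cm)
message("filter attrition (first failing filter per site):")
print(res$counts)
truth_tab <- table(cm$sites$truth, ifelse(res$pass, "pass", "fail"))
write.csv(as.data.frame(truth_tab), "results/filter_truth_table.csv",
          row.names = FALSE)
sens <- mean(res$pass[cm$sites$truth == "somatic"])
leak <- sum(res$pass & cm$sites$truth == "germline")
message(sprintf("somatic sensitivity %.3f; germline leakage %d", sens, leak))

qc <- qc_colonies(cm, pass = res$pass)
write.csv(qc, "results/colony_qc.csv", row.names = FALSE)
message(sprintf("%d of %d colonies excluded by QC", sum(qc$excluded),
                nrow(qc)))

# burden vs age across the cohort: per-colony burdens thinned by depth,
# corrected by the per-sample asymptotic regression, then the random-slope
# mixed model. Truth: ~48 mutations at birth, ~45 SBS/year after.
cohort <- read.csv("results/cohort.csv")
burden <- age <- animal <- depth <- c()
for (i in seq_len(nrow(cohort))) {
  tr <- read_tree_newick(file.path("results/trees",
                                   paste0(cohort$mouse[i], ".nwk")))
  n_tip <- length(tr$tip.label)
  true_burden <- node_mol_time(tr)[seq_len(n_tip)]
  d <- runif(n_tip, 8, 22)
  sens_i <- 1 - exp(-0.25 * d)
  obs <- rbinom(n_tip, round(true_burden), sens_i)
  burden <- c(burden, obs)
  depth <- c(depth, d)
  age <- c(age, rep((cohort$age_weeks[i] - 3) / 52.18, n_tip))
  animal <- c(animal, rep(cohort$mouse[i], n_tip))
}
corr <- correct_burden_depth(burden, depth, animal)
fit <- fit_burden_rate(corr$corrected, age, animal)
out <- data.frame(
  slope = fit$slope, slope_lo = fit$slope_ci[1], slope_hi = fit$slope_ci[2],
  intercept = fit$intercept, intercept_lo = fit$intercept_ci[1],
  intercept_hi = fit$intercept_ci[2],
  per_bp_per_year = per_bp_rate(fit$slope))
write.csv(out, "results/burden_rate.csv", row.names = FALSE)
message(sprintf(
  "burden slope %.1f/yr (CI %.1f-%.1f); intercept %.1f; %.2g /bp/yr",
  fit$slope, fit$slope_ci[1], fit$slope_ci[2], fit$intercept,
  per_bp_rate(fit$slope)))
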
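test_that("overdispersion separates clonal from diffuse patterns", {
  # one clonal carrier among ten colonies: strongly overdispersed
  nv <- c(10, rep(0, 9)); nr <- rep(20, 10)
  expect_gt(betabinom_overdispersion(nv, nr), 0.1)
  # one mutant read everywhere: binomial-like, low overdispersion
  expect_lt(betabinom_overdispersion(rep(1, 10), rep(20, 10)), 0.1)
  # degenerate inputs are flagged
  expect_true(is.na(betabinom_overdispersion(c(0, 0), c(0, 0))))
  expect_true(is.na(betabinom_overdispersion(c(0, 0, 0), c(10, 10, 10))))
})

test_that("overdispersion MLE matches a dense grid-search oracle", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    nr <- stats::rpois(n, 16) + 1
    mode <- sample(c("clonal", "diffuse", "mixed"), 1)
    nv <- switch(mode,
      clonal = stats::rbinom(n, nr, ifelse(stats::runif(n) < 0.3, 0.5, 0)),
      diffuse = stats::rbinom(n, nr, 0.05),
      mixed = stats::rbinom(n, nr, sample(c(0, 0.2, 0.5), n, TRUE)))
    if (sum(nv) == 0) nv[1] <- 1
    est <- betabinom_overdispersion(nv, nr)
    oracle <- grid_rho_oracle(nv, nr)
    expect_equal(est, oracle, tolerance = 5e-3)
  }
})

test_that("overdispersion is invariant to colony order", {
  set.seed(5)
  nr <- stats::rpois(20, 14); nv <- stats::rbinom(20, nr, rep(c(0, .5), 10))
  o <- sample(20)
  expect_equal(betabinom_overdispersion(nv, nr),
               betabinom_overdispersion(nv[o], nr[o]), tolerance = 1e-10)
})

filters_fixture <- function(seed = 101, n_tips = 30, depth = 14) {
  ph <- fixture_sim_tree(seed = seed, n_tips = n_tips)
  simulate_genotype_matrix(ph, mean_depth = depth, n_germline = 25,
                           seed = seed + 1)
}

test_that("planted classes are caught by the intended filters", {
  cm <- filters_fixture()
  res <- filter_colony_variants(cm)
  truth <- cm$sites$truth
  # germline never leaks through
  expect_equal(sum(res$pass & truth == "germline"), 0)
  # strand artifacts removed
  expect_equal(sum(res$pass & truth == "artifact_strand"), 0)
  expect_equal(sum(res$pass & truth == "artifact_lowvaf"), 0)
  expect_equal(sum(res$pass & truth == "artifact_homopolymer"), 0)
  expect_equal(sum(res$pass & truth == "artifact_clustered"), 0)
  # homopolymer sites fall at the first filter
  expect_true(all(res$first_fail[truth == "artifact_homopolymer"] ==
                    "homopolymer"))
  # sensitivity for true somatic variants
  sens <- mean(res$pass[truth == "somatic"])
  expect_gte(sens, 0.95)
  # verdict bookkeeping: one verdict per site, counts add up
  expect_equal(length(res$pass), nrow(cm$sites))
  expect_equal(sum(res$counts) + sum(res$pass), nrow(cm$sites))
})

test_that("filtering is idempotent and the empty matrix passes through", {
  cm <- filters_fixture(seed = 140)
  res <- filter_colony_variants(cm)
  cm2 <- cm
  keep <- which(res$pass)
  cm2$sites <- cm$sites[keep, , drop = FALSE]
  cm2$NV <- cm$NV[keep, , drop = FALSE]
  cm2$NR <- cm$NR[keep, , drop = FALSE]
  cm2$NF <- cm$NF[keep, , drop = FALSE]
  res2 <- filter_colony_variants(cm2)
  expect_true(all(res2$pass))
  empty <- cm
  empty$sites <- cm$sites[0, , drop = FALSE]
  empty$NV <- cm$NV[0, , drop = FALSE]
  empty$NR <- cm$NR[0, , drop = FALSE]
  empty$NF <- cm$NF[0, , drop = FALSE]
  res0 <- filter_colony_variants(empty)
  expect_equal(length(res0$pass), 0)
  expect_true(all(res0$counts == 0))
})

test_that("fully unidirectional mutant support is rejected", {
  # 20/20 forward mutant reads: two-sided binomial p = 2^-19 < 0.001
  nv <- matrix(c(10, 10, 0, 0), 1); nr <- matrix(rep(14, 4), 1)
  nf <- matrix(c(10, 10, 0, 0), 1)
  sites <- data.frame(id = "s1", chrom = "chr1", pos = 1000, ref = "C",
                      alt = "T", class = "SNV", hp_len = 0, truth = "x")
  cm <- colony_matrix(sites, nv, pmax(nr, nv), nf,
                      colonies = paste0("c", 1:4))
  res <- filter_colony_variants(cm)
  expect_equal(unname(res$first_fail[1]), "strand_bias")
})

test_that("colony QC excludes low-VAF and non-clonal colonies", {
  set.seed(33)
  n_sites <- 120
  nr <- matrix(stats::rpois(n_sites * 3, 30), n_sites, 3)
  # colony 1 clonal (VAF .5), colony 2 a 50:50 mix of two clones (VAF .25),
  # colony 3 clonal
  p <- cbind(rep(0.5, n_sites), rep(0.25, n_sites), rep(0.5, n_sites))
  nv <- matrix(stats::rbinom(n_sites * 3, nr, p), n_sites, 3)
  nv[nv == 0] <- 1  # keep sites genotyped Present in all colonies
  sites <- data.frame(id = paste0("s", 1:n_sites), chrom = "chr1",
                      pos = seq(1e3, by = 500, length.out = n_sites),
                      ref = "C", alt = "T", class = "SNV", hp_len = 0,
                      truth = "somatic")
  cm <- colony_matrix(sites, nv, pmax(nr, nv), NULL, c("good", "mixed",
                                                       "good2"))
  qc <- qc_colonies(cm, pass = rep(TRUE, n_sites),
                    config = colony_filter_config(present_vaf = 0.02))
  expect_false(qc$excluded[qc$colony == "good"])
  expect_true(qc$excluded[qc$colony == "mixed"])
  # colony with no variants gets its own reason
  cm0 <- cm; cm0$NV[, 3] <- 0
  qc0 <- qc_colonies(cm0, pass = rep(TRUE, n_sites),
                     config = colony_filter_config(present_vaf = 0.02))
  expect_identical(qc0$reason[qc0$colony == "good2"], "no_variants")
})

test_that("depth correction recovers a planted detection curve", {
  set.seed(44)
  n <- 30
  depth <- stats::runif(n, 4, 30)
  sens <- 1 - exp(-0.2 * depth)
  burden <- stats::rbinom(n, 160, sens)
  out <- correct_burden_depth(burden, depth)
  fit <- attr(out, "fits")[["s1"]]
  expect_lt(abs(fit[["a"]] - 160) / 160, 0.05)
  expect_true(all(out$corrected >= out$burden - 1e-9))
  # equal depths: correction is a common factor, ranking preserved
  d2 <- rep(14, 8); b2 <- c(100, 120, 90, 130, 110, 95, 105, 115)
  out2 <- suppressWarnings(correct_burden_depth(b2, d2))
  expect_equal(order(out2$corrected), order(b2))
})

test_that("burden-rate mixed model recovers slope and intercept", {
  set.seed(55)
  hits <- 0
  for (r in 1:20) {
    animals <- rep(paste0("m", 1:6), each = 15)
    age <- rep(stats::runif(6, 0.25, 2.5), each = 15)
    slope_i <- stats::rnorm(6, 45, 3)[match(animals, paste0("m", 1:6))]
    burden <- 48 + slope_i * age + stats::rnorm(90, 0, 8)
    fit <- fit_burden_rate(burden, age, animals)
    if (fit$slope_ci[1] <= 45 && 45 <= fit$slope_ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 15)
  # constant burden: zero slope (degenerate fit warns, which is fine)
  fitc <- suppressWarnings(suppressMessages(
    fit_burden_rate(rep(100, 40), rep(c(1, 2), 20),
                    rep(c("a", "b"), each = 20))))
  expect_lt(abs(fitc$slope), 1e-6)
})

duplex_toy <- function() {
  base <- data.frame(
    sample_id = paste0("s", 1:10), batch_id = "b1",
    locus = paste0("chr1:", 1:10 * 1000), ref = "C", alt = "T",
    class = c(rep("missense", 8), "synonymous", "missense"),
    vaf = rep(1e-4, 10), depth = rep(30000, 10),
    supporting_reads = rep(4, 10), mean_mismatches = rep(1, 10),
    min_read_end_dist = rep(30, 10), fwd_mut = rep(2, 10),
    rev_mut = rep(2, 10), fwd_wt = rep(14998, 10),
    rev_wt = rep(14998, 10), end_repair_prob = rep(0.01, 10),
    flag = rep("PASS", 10), indel_len = rep(NA_integer_, 10),
    human_homolog = rep(TRUE, 10), is_oxidative = rep(FALSE, 10))
  base
}

# batch b1 really holds 40 sequenced samples; the toy table is a subset
toy_config <- function(...) duplex_filter_config(batch_sizes = c(b1 = 40),
                                                 ...)

test_that("duplex toy table loses exactly the planted violations", {
  tab <- duplex_toy()
  tab$supporting_reads[1] <- 1          # filter 2
  tab$mean_mismatches[2] <- 3.5         # filter 3
  tab$min_read_end_dist[3] <- 10        # filter 5
  tab$depth[4] <- 19000                 # filter 7
  tab$indel_len[5] <- 20                # filter 10
  tab$vaf[6] <- 0.45                    # filter 11
  res <- filter_duplex_variants(tab, toy_config())
  expect_equal(sum(res$pass), 4)
  expect_equal(unname(res$first_fail[1:6]),
               c("read_support", "mismatches", "read_position", "coverage",
                 "indel_length", "high_vaf"))
})

test_that("coverage boundary is inclusive of 20,000x", {
  tab <- duplex_toy()[1:2, ]
  tab$depth <- c(20000, 20001)
  res <- filter_duplex_variants(tab, toy_config())
  expect_equal(unname(res$pass), c(FALSE, TRUE))
})

test_that("recurrence and strand-bias filters act on the whole table", {
  tab <- duplex_toy()
  # the same variant in 6 of 10 samples in one batch (>= 5 independent)
  tab$locus[1:6] <- "chr1:777"
  res <- filter_duplex_variants(tab, toy_config())
  expect_true(all(res$first_fail[1:6] == "recurrence"))
  tab2 <- duplex_toy()
  tab2$fwd_mut[1] <- 40; tab2$rev_mut[1] <- 0
  res2 <- filter_duplex_variants(tab2, toy_config())
  expect_equal(unname(res2$first_fail[1]), "strand_bias")
  # missing column errors name the field
  expect_error(filter_duplex_variants(duplex_toy()[, -7]), "vaf")
})

test_that("impact and homolog filters only act when configured", {
  tab <- duplex_toy()
  tab$human_homolog[2] <- FALSE
  res <- filter_duplex_variants(tab, toy_config())
  expect_equal(sum(res$pass), 10)
  res2 <- filter_duplex_variants(tab, toy_config(
    drop_synonymous = TRUE, require_homolog = TRUE))
  expect_equal(sum(res2$pass), 8)
  expect_equal(unname(res2$first_fail[9]), "impact")
  expect_equal(unname(res2$first_fail[2]), "homolog")
})
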
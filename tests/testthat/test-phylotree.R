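test_that("disjoint private variant sets build a cherry", {
  # two colonies with 5 and 7 private variants
  nv <- rbind(matrix(rep(c(500L, 0L), each = 5), 5, 2),
              matrix(rep(c(0L, 500L), each = 7), 7, 2))
  nr <- matrix(1000L, 12, 2)
  sites <- data.frame(id = paste0("s", 1:12), chrom = "chr1",
                      pos = 1:12 * 100, ref = "C", alt = "T",
                      class = "SNV", hp_len = 0, truth = "somatic")
  cm <- colony_matrix(sites, nv, nr, colonies = c("A", "B"))
  tr <- build_tree(cm)
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(5, 7))
  expect_equal(tr$Nnode, 1)
})

test_that("error-free matrices round-trip the simulated topology", {
  for (seed in c(1, 7, 13, 29, 41)) {
    ph <- fixture_sim_tree(seed = seed, n_tips = 20)
    cm <- simulate_genotype_matrix(
      ph, n_germline = 0,
      artifact_spec = list(), seed = seed + 1, infinite_depth = TRUE)
    tr <- build_tree(cm)
    truth <- ph
    truth$tip.label <- sub("\\|.*$", "", truth$tip.label)
    # binary-resolve the built tree for comparison; RF distance on the
    # collapsed trees must be zero
    rf <- suppressWarnings(
      ape::dist.topo(ape::di2multi(ape::unroot(tr)),
                     ape::di2multi(ape::unroot(truth))))
    expect_equal(as.numeric(rf), 0)
    # variant conservation: every site lands on exactly one branch
    placed <- length(unlist(tr$branch.variants)) + length(tr$root.variants)
    expect_equal(placed, nrow(cm$sites))
    # and branch lengths agree with the simulated mutation counts
    expect_equal(sum(tr$edge.length), sum(ph$edge.length))
  }
})

test_that("variant placement maximizes the per-branch likelihood", {
  ph <- fixture_sim_tree(seed = 3, n_tips = 8)
  cm <- simulate_genotype_matrix(ph, mean_depth = 20, n_germline = 0,
                                 artifact_spec = list(), seed = 4)
  tr <- build_tree(cm)
  sets <- clonaldyn:::.edge_tip_sets(tr)
  # exhaustive oracle over branches for each of a sample of sites
  la <- dbinom(cm$NV, cm$NR, 0.48, log = TRUE)
  le <- dbinom(cm$NV, cm$NR, 0.01, log = TRUE)
  for (i in seq(1, nrow(cm$sites), by = 7)) {
    lls <- vapply(seq_along(sets), function(e) {
      s <- sets[[e]]
      sum(la[i, s]) + sum(le[i, -s])
    }, numeric(1))
    lls <- c(lls, sum(la[i, ]))  # root (all colonies)
    placed <- which(vapply(tr$branch.variants, function(v)
      cm$sites$id[i] %in% v, logical(1)))
    oracle <- which.max(lls)
    if (oracle <= length(sets)) {
      expect_equal(unname(placed), oracle)
    } else {
      expect_true(cm$sites$id[i] %in% tr$root.variants)
    }
  }
})

test_that("irresolvable genotype conflicts are refused with advice", {
  # three colonies, pairwise-overlapping carrier sets (no perfect phylogeny)
  nv <- rbind(c(500L, 500L, 0L), c(0L, 500L, 500L), c(500L, 0L, 500L))
  nr <- matrix(1000L, 3, 3)
  sites <- data.frame(id = paste0("s", 1:3), chrom = "chr1",
                      pos = 1:3 * 100, ref = "C", alt = "T", class = "SNV",
                      hp_len = 0, truth = "somatic")
  cm <- colony_matrix(sites, nv, nr, colonies = c("A", "B", "C"))
  expect_error(build_tree(cm, max_conflict = 0.05), "Newick")
})

test_that("sensitivity normalization rescales branch lengths", {
  ph <- fixture_sim_tree(seed = 9, n_tips = 6)
  unit <- normalize_branch_lengths(ph, rep(1, 6))
  expect_equal(unit$edge.length, ph$edge.length)
  half <- normalize_branch_lengths(ph, rep(0.8, 6))
  expect_equal(half$edge.length, round(ph$edge.length / 0.8))
  expect_error(normalize_branch_lengths(ph, rep(0, 6)), "sensitivities")
  # terminal branch: raw 80 at sensitivity 0.8 becomes 100
  tr <- ape::read.tree(text = "(a:80,b:40);")
  tr2 <- normalize_branch_lengths(tr, c(a = 0.8, b = 1))
  expect_equal(tr2$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")],
               100)
})

test_that("normalization removes the depth-driven length bias", {
  set.seed(77)
  # thinned observation: colonies with lower depth detect fewer mutations
  true_len <- rep(100, 24)
  depth <- stats::runif(24, 5, 30)
  sens <- 1 - exp(-0.15 * depth)
  obs_len <- stats::rbinom(24, true_len, sens)
  tr <- ape::stree(24, "star")
  tr$edge.length <- obs_len
  tr$tip.label <- paste0("c", 1:24)
  norm <- normalize_branch_lengths(tr, stats::setNames(sens, tr$tip.label))
  r_before <- abs(stats::cor(obs_len, depth, method = "spearman"))
  r_after <- abs(stats::cor(norm$edge.length, depth, method = "spearman"))
  expect_lt(r_after, 0.35)
  expect_lt(r_after, r_before)
})

test_that("Shannon diversity follows the clade partition", {
  # 16 singleton clades
  expect_equal(shannon_diversity(rep(1, 16)), log(16))
  expect_equal(shannon_diversity(c(4, 4, 8)),
               -sum(c(.25, .25, .5) * log(c(.25, .25, .5))))
  expect_equal(shannon_diversity(c(4, 4, 8)), 1.0397, tolerance = 1e-4)
  expect_equal(shannon_diversity(16), 0)
  # maximal for equal clade sizes at fixed clade count
  expect_gt(shannon_diversity(c(5, 5, 5)), shannon_diversity(c(1, 4, 10)))
})

test_that("clade partitions respect the crossing convention", {
  # manual tree: ((a:30,b:30):10,c:40); stem 5
  tr <- ape::read.tree(text = "((a:30,b:30):10,c:40);")
  tr$root.edge <- 5
  # molecular times: root 5; internal 15; tips 45
  p10 <- clades_at_time(tr, 10)  # crosses the 5->15 branch and stem->c
  expect_equal(length(p10$tips), 2)
  p5 <- clades_at_time(tr, 5)    # inclusive crossing at the root node
  expect_equal(length(p5$tips), 1)
  p20 <- clades_at_time(tr, 20)
  expect_equal(length(p20$tips), 3)
  # t beyond all tips: singleton clades
  p99 <- clades_at_time(tr, 99)
  expect_equal(length(p99$tips), 3)
  expect_true(all(p99$sizes == 1))
})

test_that("polytomy estimator matches the closed-form count arithmetic", {
  res <- polytomy_rate_from_counts(44, 265)
  expect_equal(round(res$m, 2), 1.8)
  expect_lt(res$ci[1], res$m)
  expect_gt(res$ci[2], res$m)
  # all divisions silent: rate 0
  expect_equal(polytomy_rate_from_counts(10, 10)$m, 0)
  # no silent divisions: unbounded point estimate, flagged
  expect_true(polytomy_rate_from_counts(0, 20)$unbounded)
})

test_that("polytomy rate counts silent divisions from tree multifurcations", {
  # star of 12 tips at depth 2: 11 divisions, 10 silent
  tr <- ape::stree(12, "star")
  tr$edge.length <- rep(2, 12)
  tr$root.edge <- 2
  res <- polytomy_mutation_rate(tr, t_max = 12, min_lineages = 10)
  expect_equal(res$z, 10)
  expect_equal(res$n, 11)
  expect_equal(res$m, -log(10 / 11))
  small <- ape::stree(5, "star")
  small$edge.length <- rep(2, 5)
  expect_error(polytomy_mutation_rate(small, t_max = 12), "lineages")
})

test_that("polytomy estimator recovers the simulated mutation rate", {
  ests <- c()
  seeds <- 1:40
  for (s in seeds) {
    m <- pop_model(data.frame(duration = c(10, 40), lambda = c(1.5, 0.4),
                              nu = c(0, 0.05), cap = c(800, 800)),
                   mutations_per_division = 2)
    tr <- suppressWarnings(simulate_population(m, 50, seed = s))
    if (tr$extinct || length(tr$alive) < 60) next
    ph <- sample_phylogeny(tr, 60, seed = s + 1)
    res <- tryCatch(polytomy_mutation_rate(ph), error = function(e) NULL)
    if (!is.null(res) && is.finite(res$m)) ests <- c(ests, res$m)
  }
  expect_gte(length(ests), 15)
  expect_gt(mean(ests), 1.7)
  expect_lt(mean(ests), 2.3)
})

test_that("mixing metric is maximal for pure clades at balanced sampling", {
  tr <- ape::read.tree(text = "((a:30,b:30):30,(c:30,d:30):30);")
  tr$root.edge <- 0
  tr$tip.state <- c("HSC", "HSC", "MPP", "MPP")
  mm <- mixing_metric(tr, t = 25)
  expect_equal(mm$metric, 0.5)
  expect_equal(mm$n_clades, 2)
})

test_that("mixing null matches exhaustive label enumeration", {
  tr <- ape::read.tree(
    text = "(((a:30,b:30):10,c:40):10,((d:30,e:30):10,f:40):10);")
  tr$root.edge <- 0
  tr$tip.state <- c("HSC", "HSC", "HSC", "MPP", "MPP", "HSC")
  part <- clades_at_time(tr, 25)
  p_bar <- mean(tr$tip.state == "HSC")
  # exact null over all C(6, 2) placements of the MPP labels
  combos <- utils::combn(6, 2)
  exact <- apply(combos, 2, function(ix) {
    st <- rep("HSC", 6); st[ix] <- "MPP"
    props <- vapply(part$tips, function(t) mean(st[t] == "HSC"), numeric(1))
    mean(abs(props - p_bar))
  })
  nul <- mixing_null(tr, t = 25, n_perm = 40000, seed = 4)
  expect_equal(mean(nul$null), mean(exact), tolerance = 2e-3)
  expect_equal(stats::sd(nul$null), stats::sd(exact), tolerance = 2e-3)
  p_exact <- mean(exact >= nul$observed)
  expect_lt(abs(nul$p_value - p_exact), 0.02)
})

test_that("mixing null p-values are uniform under random labels", {
  set.seed(202)
  pvals <- vapply(1:150, function(i) {
    tr <- random_tree(16, max_len = 10, root_len = 5)
    mixing_null(tr, t = 12, n_perm = 200, randomized = TRUE)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("directional state-change counts match exhaustive search", {
  set.seed(31)
  for (i in 1:25) {
    tr <- random_tree(sample(4:6, 1))
    for (model in c("HSC-first", "MPP-first")) {
      got <- count_state_changes(tr, model)$changes
      expect_equal(got, enum_state_changes(tr, model))
    }
  }
  # trivial cases
  tr <- random_tree(9)
  tr$tip.state <- rep("HSC", 9)
  expect_equal(count_state_changes(tr, "HSC-first")$changes, 0)
  tr$tip.state <- c("MPP", rep("HSC", 8))
  expect_equal(count_state_changes(tr, "HSC-first")$changes, 1)
  expect_equal(count_state_changes(tr, "HSC-first")$per_colony, 1 / 9)
})

test_that("crypt sharing applies the two-tier positivity rule", {
  reads <- expand.grid(variant_id = paste0("v", 1:3),
                       crypt = paste0("cr", 1:3),
                       stringsAsFactors = FALSE)
  reads$nv <- c(10, 0, 0,   3, 0, 0,   0, 1, 0)
  reads$nr <- c(40, 40, 40, 40, 40, 40, 40, 40, 40)
  branch_of <- c(v1 = "b1", v2 = "b1", v3 = "b2")
  res <- crypt_sharing(reads, branch_of, threshold = 0.1)
  # v1: cr1 positive by VAF (0.25), cr2 rescued (3 reads > 2), cr3 negative
  expect_true(res$positive["v1", "cr1"])
  expect_true(res$positive["v1", "cr2"])
  expect_false(res$positive["v1", "cr3"])
  # v2 and v3 below threshold and <= 2 reads everywhere: absent
  expect_false(any(res$positive["v2", ]))
  expect_false(any(res$positive["v3", ]))
  # branch fractions follow
  expect_equal(unname(res$branch_fraction["b1"]), 2 / 3)
  expect_equal(unname(res$branch_fraction["b2"]), 0)
})

test_that("VAF trajectories interpolate and aggregate over branches", {
  # posterior mean bound at zero mutant reads
  post <- vaf_posterior(0, 10000)
  expect_lt(post$mean, 1e-3)
  # single branch spanning molecular time [10, 20], VAFs 0.4 and 0.2
  tr <- ape::read.tree(text = "(a:10,b:10);")
  tr$root.edge <- 10
  # edge to tip a spans [10, 20]
  e_a <- which(tr$edge[, 2] == 1)
  targets <- data.frame(edge = e_a, mutant = c(4000, 2000),
                        depth = c(10000, 10000))
  out <- lineage_vaf_trajectory(tr, targets, t_grid = 15)
  expect_equal(out$aggregate_vaf, 0.3, tolerance = 1e-3)
  # aggregation equals a brute-force sum over overlapping branches
  set.seed(8)
  tr2 <- fixture_sim_tree(seed = 14, n_tips = 6)
  ne <- nrow(tr2$edge)
  targets2 <- data.frame(edge = rep(seq_len(ne), each = 2),
                         mutant = stats::rbinom(2 * ne, 1000, 0.1),
                         depth = 1000)
  tgrid <- c(15, 25, 40)
  out2 <- lineage_vaf_trajectory(tr2, targets2, tgrid)
  depth_n <- node_mol_time(tr2)
  for (j in seq_along(tgrid)) {
    t <- tgrid[j]
    tot <- 0
    for (e in seq_len(ne)) {
      t0 <- depth_n[tr2$edge[e, 1]]; t1 <- depth_n[tr2$edge[e, 2]]
      if (t0 > t || t1 < t) next
      v <- sort(vaf_posterior(targets2$mutant[targets2$edge == e],
                              1000)$mean, decreasing = TRUE)
      tot <- tot + stats::approx(seq(t0, t1, length.out = 2), v, xout = t,
                                 rule = 2)$y
    }
    expect_equal(out2$aggregate_vaf[j], tot, tolerance = 1e-9)
  }
})
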
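#' Intercoalescent intervals of an ultrametric genealogy
#'
#' Extracts the sequence of (lineage count, duration) intervals between
#' successive coalescences, from the tips backwards. Trees simulated by
#' [sample_phylogeny] carry real node times; other trees must have
#' chronological (ultrametric) branch lengths.
#'
#' @param phylo ultrametric tree, or a simulated tree with
#'   `node.real.time`.
#' @param tol tolerance on tip-height agreement.
#' @return data.frame with `k` (lineages during the interval) and `dt`
#'   (duration); polytomies contribute zero-length intervals.
#' @export
coalescent_intervals <- function(phylo, tol = 1e-6) {
  n_tip <- length(phylo$tip.label)
  if (!is.null(phylo$node.real.time)) {
    tt <- phylo$node.real.time
    heights <- max(tt[seq_len(n_tip)]) - tt[(n_tip + 1):(n_tip + phylo$Nnode)]
  } else {
    d <- ape::node.depth.edgelength(phylo)
    tips_h <- d[seq_len(n_tip)]
    if (diff(range(tips_h)) > tol * max(tips_h, 1))
      stop(sprintf("tree is not ultrametric (max tip-height discrepancy %g)",
                   diff(range(tips_h))))
    heights <- max(tips_h) - d[(n_tip + 1):(n_tip + phylo$Nnode)]
  }
  # each internal node of out-degree d contributes d - 1 coalescences
  ch <- .children_list(phylo)
  degs <- vapply((n_tip + 1):(n_tip + phylo$Nnode), function(v)
    length(ch[[v]]), integer(1))
  coal_h <- rep(heights, degs - 1L)
  coal_h <- sort(coal_h)
  k <- n_tip:(n_tip - length(coal_h) + 1L)
  dt <- diff(c(0, coal_h))
  data.frame(k = k, dt = dt)
}

#' Classic skyline estimate of N/lambda
#'
#' Inverts the coalescent rate per intercoalescent interval:
#' `N/lambda = k (k - 1) dt / 2` for the interval with `k` lineages.
#' Optionally pools consecutive intervals (generalized skyline) so each
#' estimate uses at least `pool_min_dt` of time or `pool_min_coal`
#' coalescences; zero-length intervals (polytomies) are always pooled with
#' their neighbours.
#'
#' @param intervals data.frame from [coalescent_intervals].
#' @param pool_min_dt minimum pooled duration (same unit as `dt`).
#' @param pool_min_coal minimum pooled coalescence count.
#' @return data.frame with `start`, `end` (time before sampling), `k`
#'   (lineages entering the group), `estimate` (N/lambda in time units).
#' @export
skyline <- function(intervals, pool_min_dt = 0, pool_min_coal = 1) {
  stopifnot(nrow(intervals) >= 1)
  est <- list()
  i <- 1L; t0 <- 0
  n <- nrow(intervals)
  while (i <= n) {
    j <- i
    dt_sum <- intervals$dt[i]
    num <- intervals$k[i] * (intervals$k[i] - 1) / 2 * intervals$dt[i]
    while ((dt_sum <= pool_min_dt || (j - i + 1) < pool_min_coal ||
            intervals$dt[j] == 0) && j < n) {
      j <- j + 1L
      dt_sum <- dt_sum + intervals$dt[j]
      num <- num + intervals$k[j] * (intervals$k[j] - 1) / 2 *
        intervals$dt[j]
    }
    est[[length(est) + 1]] <- data.frame(
      start = t0, end = t0 + dt_sum, k = intervals$k[i],
      estimate = num / (j - i + 1))
    t0 <- t0 + dt_sum
    i <- j + 1L
  }
  do.call(rbind, est)
}

#' Pooled constant-size estimate of N/lambda
#'
#' Maximum-likelihood constant-population estimate over all intervals:
#' `sum_j k_j (k_j - 1)/2 dt_j / (number of coalescences)`.
#'
#' @param intervals data.frame from [coalescent_intervals].
#' @export
skyline_constant <- function(intervals) {
  sum(intervals$k * (intervals$k - 1) / 2 * intervals$dt) / nrow(intervals)
}

#' ABC configuration for the bounded birth-death model
#'
#' Uniform priors as used for the murine stem cell pool: `N` in [1e2, 1e5]
#' cells, `lambda` in [0.01, 0.15] divisions per cell per day, `nu` in
#' [0, lambda]; two epochs with the boundary at 10 weeks post-conception
#' and independent (lambda, nu) per epoch.
#'
#' @param n_sims number of prior simulations.
#' @param accept_frac fraction of simulations retained.
#' @param epoch_boundary weeks post-conception separating the epochs.
#' @param n_prior,lambda_prior_day prior bounds.
#' @param mutations_per_division Poisson mean used to overlay molecular
#'   time on simulated genealogies.
#' @param n_ltt number of lineage-through-time summary points.
#' @export
abc_config <- function(n_sims = 2000, accept_frac = 0.05,
                       epoch_boundary = 10,
                       n_prior = c(1e2, 1e5),
                       lambda_prior_day = c(0.01, 0.15),
                       mutations_per_division = 1.8, n_ltt = 12) {
  as.list(environment())
}

#' Summary statistics of a genealogy for ABC
#'
#' Lineage-through-time counts at `n_ltt` evenly spaced molecular-time
#' points, coalescence counts per epoch (real time), mean root-to-tip
#' molecular height, and Shannon clade diversity at 50 mutations.
#'
#' @param phylo simulated tree with mutation branch lengths and
#'   `node.real.time`.
#' @param t_end sampling time (weeks post-conception).
#' @param config an [abc_config].
#' @export
tree_summaries <- function(phylo, t_end, config = abc_config()) {
  depth <- node_mol_time(phylo)
  n_tip <- length(phylo$tip.label)
  h <- mean(depth[seq_len(n_tip)])
  grid <- seq(1, max(depth[seq_len(n_tip)]), length.out = config$n_ltt)
  ltt <- vapply(grid, function(t) length(clades_at_time(phylo, t)$tips),
                numeric(1))
  nt <- phylo$node.real.time[(n_tip + 1):(n_tip + phylo$Nnode)]
  coal_early <- sum(nt <= config$epoch_boundary)
  coal_late <- phylo$Nnode - coal_early
  shan <- shannon_diversity(clades_at_time(phylo, 50))
  c(ltt, coal_early = coal_early, coal_late = coal_late,
    height = h, shannon50 = shan)
}

# fast genealogy simulation under the bounded two-epoch birth-death model
.sim_genealogy_fast <- function(lambda1, nu1, lambda2, nu2, N, t_end,
                                n_tips, epoch_boundary, m) {
  ep <- matrix(c(epoch_boundary, lambda1, nu1, N,
                 max(t_end - epoch_boundary, 1), lambda2, nu2, N),
               nrow = 2, byrow = TRUE)
  res <- .sim_genealogy_cpp(ep, t_end, as.integer(n_tips), 500, 5e6)
  if (!isTRUE(res$ok)) return(NULL)
  n <- n_tips
  n_merge <- length(res$merge_time)
  # renumber internal nodes so the final merge (the MRCA) is n + 1
  renum <- function(id) ifelse(id <= n, id, n + 1L + (n_merge - (id - n)))
  edge <- matrix(0L, 2 * n_merge, 2)
  elen_t <- numeric(2 * n_merge)
  node_time <- numeric(2 * n - 1)
  node_time[seq_len(n)] <- t_end
  bint <- numeric(2 * n - 1)
  bint[seq_len(n)] <- res$branch_bint[2:(n + 1)]
  for (j in seq_len(n_merge)) {
    new <- renum(res$merge_new[j])
    node_time[new] <- res$merge_time[j]
    if (res$merge_new[j] + 1 <= 2 * n)
      bint[new] <- res$branch_bint[res$merge_new[j] + 1]
    for (cix in 1:2) {
      child <- c(res$merge_a[j], res$merge_b[j])[cix]
      edge[2 * (j - 1) + cix, ] <- c(new, renum(child))
    }
  }
  elen_t <- node_time[edge[, 2]] - node_time[edge[, 1]]
  # divisions: Poisson with mean = integral of per-capita birth rate
  divisions <- stats::rpois(nrow(edge), pmax(bint[edge[, 2]], 0))
  mutations <- stats::rpois(nrow(edge), m * divisions)
  tr <- list(edge = edge, edge.length = as.numeric(mutations),
             tip.label = paste0("t", seq_len(n)), Nnode = n_merge)
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  o <- match(paste(tr$edge[, 1], tr$edge[, 2]), paste(edge[, 1], edge[, 2]))
  tr$divisions <- divisions[o]
  tr$node.real.time <- node_time
  root_div <- stats::rpois(1, res$root_bint)
  tr$root.divisions <- root_div
  tr$root.edge <- as.numeric(stats::rpois(1, m * root_div))
  tr
}

#' Rejection ABC for the bounded birth-death population model
#'
#' Draws `(lambda, nu)` per epoch and the population bound `N` from the
#' uniform priors, simulates a genealogy with the observed tip count and
#' sampling age for each draw, and retains the `accept_frac` of draws whose
#' summary statistics ([tree_summaries]) are closest to the observed tree's
#' in Euclidean distance after standardizing each summary by its
#' prior-predictive standard deviation. Early-epoch parameters are
#' reported but weakly identified; adult-epoch (epoch 2) estimates are the
#' headline output.
#'
#' @param obs_tree observed genealogy (>= 20 tips) with mutation branch
#'   lengths and real node times.
#' @param t_end sampling age, weeks post-conception.
#' @param config an [abc_config].
#' @param seed integer seed.
#' @return list with `posterior` (accepted draws), `prior` (all draws),
#'   `summary`: medians and 95\% credible intervals for `N`,
#'   `tau_weeks` (= 1/lambda2, weeks between symmetric divisions),
#'   `exit_weeks` (= 1/nu2) and `N_over_lambda_years` (HSC-years).
#' @export
abc_rejection <- function(obs_tree, t_end, config = abc_config(),
                          seed = NULL) {
  n_tips <- length(obs_tree$tip.label)
  if (n_tips < 20) stop("observed tree must have at least 20 tips")
  if (!is.null(seed)) set.seed(seed)
  s_obs <- tree_summaries(obs_tree, t_end, config)
  ns <- config$n_sims
  lam_wk <- function(n) stats::runif(n, config$lambda_prior_day[1],
                                     config$lambda_prior_day[2]) * 7
  draws <- data.frame(
    N = stats::runif(ns, config$n_prior[1], config$n_prior[2]),
    lambda1 = lam_wk(ns), lambda2 = lam_wk(ns))
  draws$nu1 <- stats::runif(ns, 0, draws$lambda1)
  draws$nu2 <- stats::runif(ns, 0, draws$lambda2)
  S <- matrix(NA_real_, ns, length(s_obs))
  ok <- logical(ns)
  for (i in seq_len(ns)) {
    tr <- .sim_genealogy_fast(draws$lambda1[i], draws$nu1[i],
                              draws$lambda2[i], draws$nu2[i],
                              draws$N[i], t_end, n_tips,
                              config$epoch_boundary,
                              config$mutations_per_division)
    if (is.null(tr)) next
    ok[i] <- TRUE
    S[i, ] <- tree_summaries(tr, t_end, config)
  }
  S <- S[ok, , drop = FALSE]
  draws_ok <- draws[ok, , drop = FALSE]
  sds <- apply(S, 2, stats::sd)
  sds[sds == 0 | is.na(sds)] <- 1
  d2 <- rowSums(scale(S, center = s_obs, scale = sds)^2)
  n_keep <- max(1, ceiling(config$accept_frac * nrow(S)))
  if (n_keep < 100) {
    warning(sprintf(
      "only %d simulations at acceptance fraction %.3g; widening to %d",
      n_keep, config$accept_frac, min(100L, nrow(S))))
    n_keep <- min(100L, nrow(S))
  }
  keep <- order(d2)[seq_len(n_keep)]
  post <- draws_ok[keep, , drop = FALSE]
  qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  summary <- rbind(
    N = qs(post$N),
    tau_weeks = qs(1 / post$lambda2),
    exit_weeks = qs(1 / pmax(post$nu2, 1e-9)),
    N_over_lambda_years = qs(post$N / (post$lambda2 * 52.18)))
  colnames(summary) <- c("median", "lower", "upper")
  list(posterior = post, prior = draws, summary = summary,
       n_accepted = n_keep, n_simulated = nrow(S))
}
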
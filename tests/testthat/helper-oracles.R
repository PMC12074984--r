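# Independent oracles and fixture builders used across the suite.

# random phenotyped tree with integer mutation branch lengths
random_tree <- function(n_tips, max_len = 30, root_len = 15,
                        states = c("HSC", "MPP")) {
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- sample(0:max_len, nrow(tr$edge), replace = TRUE)
  tr$root.edge <- root_len
  tr$tip.state <- sample(states, n_tips, replace = TRUE)
  tr$tip.label <- paste0("c", seq_len(n_tips), "|", tr$tip.state)
  tr
}

# Brute-force hidden Markov tree likelihood by full enumeration over
# end-of-branch states of every node (root stem starts at EMB).
enum_loglik <- function(tr, params, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  M <- transition_matrix(params)
  matpow <- function(M, n) {
    R <- diag(3)
    if (n > 0) for (i in seq_len(n)) R <- R %*% M
    R
  }
  depth <- node_mol_time(tr)
  lock <- params$emb_lock
  eff <- function(a, b) max(0, b - lock) - max(0, a - lock)
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  root <- n_tip + 1L
  root_len <- if (is.null(tr$root.edge)) 0 else tr$root.edge
  Proot <- matpow(M, round(max(0, root_len - lock)))
  Pedge <- lapply(seq_len(nrow(tr$edge)), function(e) {
    matpow(M, round(eff(depth[tr$edge[e, 1]], depth[tr$edge[e, 2]])))
  })
  obs <- tr$tip.state
  grid <- as.matrix(expand.grid(rep(list(1:3), n_node)))
  p <- Proot[1, grid[, root]]
  for (e in seq_len(nrow(tr$edge)))
    p <- p * Pedge[[e]][cbind(grid[, tr$edge[e, 1]], grid[, tr$edge[e, 2]])]
  for (tp in seq_len(n_tip)) {
    oi <- match(obs[tp], c("EMB", "HSC", "MPP"))
    p <- p * ifelse(grid[, tp] == oi, 1 - params$epsilon,
                    0.5 * params$epsilon)
  }
  if (mode == "sum") unname(log(sum(p))) else {
    r <- which.max(p)
    list(log_prob = unname(log(p[r])), assign = grid[r, ])
  }
}

# Exhaustive minimal directional state changes (irreversible X -> Y),
# over all assignments of internal-node states.
enum_state_changes <- function(tr, model) {
  start <- if (model == "HSC-first") "HSC" else "MPP"
  target <- if (model == "HSC-first") "MPP" else "HSC"
  obs <- tr$tip.state
  n_tip <- length(tr$tip.label)
  n_int <- tr$Nnode
  root <- n_tip + 1L
  grid <- as.matrix(expand.grid(rep(list(c(start, target)), n_int)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    s <- c(obs, grid[r, ])
    if (s[root] != start) next
    ok <- TRUE; ch <- 0L
    for (e in seq_len(nrow(tr$edge))) {
      a <- s[tr$edge[e, 1]]; b <- s[tr$edge[e, 2]]
      if (a == target && b == start) { ok <- FALSE; break }
      if (a == start && b == target) ch <- ch + 1L
    }
    if (ok) best <- min(best, ch)
  }
  best
}

# Direct Kingman coalescent simulation with constant N*tau
kingman_intervals <- function(n_tips, N_tau) {
  k <- n_tips:2
  data.frame(k = k, dt = stats::rexp(length(k), k * (k - 1) / (2 * N_tau)))
}

# grid-search oracle for the beta-binomial overdispersion MLE
grid_rho_oracle <- function(nv, nr) {
  keep <- nr > 0
  nv <- nv[keep]; nr <- nr[keep]
  m <- sum(nv) / sum(nr)
  ll <- function(rho) {
    a <- m * (1 - rho) / rho; b <- (1 - m) * (1 - rho) / rho
    sum(lchoose(nr, nv) + lbeta(nv + a, nr - nv + b) - lbeta(a, b))
  }
  grid <- exp(seq(log(1e-6), log(0.89), length.out = 4000))
  grid[which.max(vapply(grid, ll, numeric(1)))]
}

# simple two-epoch model used in several tests
fixture_model <- function(cap = 500, lambda2 = 0.5, nu2 = 0.35) {
  pop_model(data.frame(duration = c(10, 120),
                       lambda = c(1.2, lambda2),
                       nu = c(0, nu2),
                       cap = c(cap, cap)))
}

# a simulated phenotyped colony tree of decent molecular depth
fixture_sim_tree <- function(seed, n_tips = 30, cap = 400, t_end = 100,
                             params = state_params(0.05, 0.05, 0.003,
                                                   0.001)) {
  m <- fixture_model(cap = cap)
  repeat {
    tr <- suppressWarnings(simulate_population(m, t_end, seed = seed))
    if (!tr$extinct && length(tr$alive) >= n_tips) break
    seed <- seed + 1000L
  }
  ph <- sample_phylogeny(tr, n_tips, seed = seed + 1L)
  label_states(ph, params, seed = seed + 2L)
}
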
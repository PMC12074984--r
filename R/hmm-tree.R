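#' Branch transition probabilities of the hidden Markov tree
#'
#' The cell-identity chain takes one step per mutation, so a branch of
#' integer length `l` (already excluding any overlap with the EMB lock)
#' carries the transition matrix `M^l`.
#'
#' @param params a [state_params].
#' @param l non-negative integer branch length in mutations.
#' @return 3x3 matrix, rows/cols ordered EMB, HSC, MPP; `l = 0` gives the
#'   identity.
#' @export
branch_transition <- function(params, l) {
  if (l < 0) stop("branch length must be non-negative")
  .mat_pow(transition_matrix(params), as.integer(round(l)))
}

# integer matrix power by repeated squaring
.mat_pow <- function(M, n) {
  R <- diag(nrow(M)); dimnames(R) <- dimnames(M)
  while (n > 0) {
    if (n %% 2L == 1L) R <- R %*% M
    M <- M %*% M
    n <- n %/% 2L
  }
  R
}

# effective (post-lock) branch lengths: per edge, mutations falling after
# the first `emb_lock` mutations of molecular time; plus the effective root
# stem length.
.effective_lengths <- function(phylo, emb_lock) {
  depth <- node_mol_time(phylo)
  p_t <- depth[phylo$edge[, 1]]
  v_t <- depth[phylo$edge[, 2]]
  l_eff <- pmax(0, v_t - emb_lock) - pmax(0, p_t - emb_lock)
  root_len <- if (is.null(phylo$root.edge)) 0 else phylo$root.edge
  root_eff <- max(0, root_len - emb_lock)
  list(edge = as.integer(round(l_eff)), root = as.integer(round(root_eff)))
}

.tip_states <- function(phylo) {
  if (!is.null(phylo$tip.state)) return(phylo$tip.state)
  m <- regmatches(phylo$tip.label,
                  regexpr("(HSC|MPP|EMB)$", phylo$tip.label))
  if (length(m) != length(phylo$tip.label))
    stop("tips must carry HSC/MPP phenotypes (tip.state or '|PHENO' labels)")
  m
}

# tip emission matrix: rows = hidden state (EMB/HSC/MPP), columns follow
# the observed phenotype; matching phenotype 1-eps, mismatch 0.5*eps
.emission <- function(obs, epsilon) {
  e <- matrix(0.5 * epsilon, nrow = 3, ncol = length(obs),
              dimnames = list(.states, NULL))
  match_i <- match(obs, .states)
  e[cbind(match_i, seq_along(obs))] <- 1 - epsilon
  e
}

# shared recursion engine; mode "sum" (upward likelihood) or "max" (Viterbi)
# Traverses edges in postorder so every child's partial likelihood is
# complete before its edge is absorbed into the parent (robust to
# zero-length edges, unlike depth-sorted traversal).
.hmm_pass <- function(phylo, params, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  obs <- .tip_states(phylo)
  if (any(!obs %in% c("HSC", "MPP")))
    stop("all tips must be phenotyped HSC or MPP")
  n_tip <- length(phylo$tip.label)
  n_node <- n_tip + phylo$Nnode
  depth <- node_mol_time(phylo)
  lock <- params$emb_lock
  po <- ape::reorder.phylo(phylo, "postorder")
  edges <- po$edge
  l_eff <- as.integer(round(pmax(0, depth[edges[, 2]] - lock) -
                              pmax(0, depth[edges[, 1]] - lock)))
  root_len <- if (is.null(phylo$root.edge)) 0 else phylo$root.edge
  root_eff <- as.integer(round(max(0, root_len - lock)))
  M <- transition_matrix(params)
  lens <- sort(unique(c(l_eff, root_eff)))
  pows <- lapply(lens, function(l) .mat_pow(M, l))
  names(pows) <- as.character(lens)
  loglik <- matrix(0, nrow = 3, ncol = n_node)  # log P(D_u | state u = i)
  emis <- .emission(obs, params$epsilon)
  loglik[, seq_len(n_tip)] <- log(emis)
  bt <- if (mode == "max")
    matrix(NA_integer_, 3, nrow(edges)) else NULL  # argmax child state
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    P <- pows[[as.character(l_eff[e])]]
    # terms[i, k] = log P_{i,k} + log L_v(k); matrix powers of a near-
    # boundary M can carry tiny negative rounding noise, hence the clamp
    terms <- log(pmax(P, 0)) + rep(loglik[, v], each = 3)
    if (mode == "sum") {
      w <- apply(terms, 1, .logsumexp)
    } else {
      w <- apply(terms, 1, max)
      bt[, e] <- apply(terms, 1, which.max)
    }
    loglik[, u] <- loglik[, u] + w
  }
  root <- n_tip + 1L
  # propagate the root stem: the state at the top of the stem (the zygote)
  # is EMB with prior mass 1
  Pr <- pows[[as.character(root_eff)]]
  root_terms <- log(pmax(Pr[1, ], 0)) + loglik[, root]
  list(loglik = loglik, root_terms = root_terms, bt = bt, edges = edges,
       n_tip = n_tip, n_node = n_node, obs = obs)
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

.children_list <- function(phylo) {
  n_node <- length(phylo$tip.label) + phylo$Nnode
  ch <- vector("list", n_node)
  for (e in seq_len(nrow(phylo$edge)))
    ch[[phylo$edge[e, 1]]] <- c(ch[[phylo$edge[e, 1]]], phylo$edge[e, 2])
  ch
}

#' Upward-algorithm log-likelihood of observed tip phenotypes
#'
#' Felsenstein-style pruning over end-of-branch hidden states: the
#' likelihood of the observed HSC/MPP tip phenotypes under the three-state
#' chain, with the root held at EMB (prior mass 1) and tip emission error
#' `epsilon`.
#'
#' @param phylo tree with integer mutation branch lengths and phenotyped
#'   tips.
#' @param params a [state_params].
#' @return log-likelihood (scalar).
#' @export
tree_loglikelihood <- function(phylo, params) {
  # root_terms[k] = log P_{EMB,k}(stem) + log L_root(k): the EMB root prior
  # enters through the stem transition row, so the likelihood sums over the
  # end-of-stem state k
  pass <- .hmm_pass(phylo, params, "sum")
  .logsumexp(pass$root_terms)
}

#' Most likely assignment of hidden end-of-branch states
#'
#' Viterbi-like decoding run alongside the upward algorithm: returns the
#' jointly most probable assignment of EMB/HSC/MPP states to every node,
#' with the root constrained to EMB by its prior. Ties break in the fixed
#' state order EMB < HSC < MPP.
#'
#' @inheritParams tree_loglikelihood
#' @return list with `state` (per-node decoded state), `log_prob` (log
#'   probability of the decoded assignment), `transitions` (count of
#'   decoded parent-to-child state changes by type), and the input tree
#'   with `node.state.decoded` attached.
#' @export
viterbi_decode <- function(phylo, params) {
  pass <- .hmm_pass(phylo, params, "max")
  n_tip <- pass$n_tip
  root <- n_tip + 1L
  # zygote prior (EMB) is carried by the stem row; maximize over the
  # end-of-stem state of the MRCA
  root_log <- pass$root_terms
  state <- integer(pass$n_node)
  state[root] <- which.max(root_log)
  # reverse postorder: parents decoded before children
  for (e in rev(seq_len(nrow(pass$edges)))) {
    u <- pass$edges[e, 1]; v <- pass$edges[e, 2]
    state[v] <- pass$bt[state[u], e]
  }
  st <- .states[state]
  parent_state <- st[phylo$edge[, 1]]
  child_state <- st[phylo$edge[, 2]]
  chg <- table(paste0(parent_state, "->", child_state)[
    parent_state != child_state])
  phylo$node.state.decoded <- st
  list(state = st, log_prob = max(root_log),
       transitions = chg, tree = phylo)
}

#' State-probability trajectory over molecular time
#'
#' Marginal probability of EMB/HSC/MPP along a lineage started at EMB,
#' iterating the chain one mutation at a time after the EMB lock.
#'
#' @param params a [state_params].
#' @param t_grid non-negative integer molecular times.
#' @return matrix with rows = times, columns EMB/HSC/MPP.
#' @export
state_trajectory <- function(params, t_grid) {
  stopifnot(all(t_grid >= 0))
  M <- transition_matrix(params)
  out <- matrix(NA_real_, length(t_grid), 3,
                dimnames = list(t_grid, .states))
  pi0 <- c(1, 0, 0)
  for (i in seq_along(t_grid)) {
    steps <- max(0L, as.integer(round(t_grid[i])) - params$emb_lock)
    out[i, ] <- pi0 %*% .mat_pow(M, steps)
  }
  out
}

#' Maximum-likelihood fit of the transition probabilities
#'
#' Maximizes the summed upward log-likelihood over trees in each group,
#' on the logit scale with multiple random restarts. The `hsc_first`
#' constraint forces `p_emb_to_mpp = 0` (MPPs can only arise from HSCs).
#' Reports log-likelihood and AIC per group and, when both constrained and
#' unconstrained fits are requested, the likelihood-ratio statistic.
#'
#' @param trees list of phenotyped trees (or a single tree).
#' @param grouping factor assigning trees to groups ("pooled" by default).
#' @param constraint "none" or "hsc_first".
#' @param n_starts random restarts (default 8).
#' @param emb_lock,epsilon fixed model constants.
#' @param seed integer seed for the restarts.
#' @return list per group: fitted [state_params], `loglik`, `aic`,
#'   `convergence`.
#' @export
fit_transition_rates <- function(trees, grouping = NULL,
                                 constraint = c("none", "hsc_first"),
                                 n_starts = 8, emb_lock = 10,
                                 epsilon = 1e-12, seed = NULL) {
  constraint <- match.arg(constraint)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(grouping)) grouping <- rep("pooled", length(trees))
  if (!is.null(seed)) set.seed(seed)
  groups <- split(seq_along(trees), grouping)
  lapply(groups, function(idx) {
    .fit_group(trees[idx], constraint, n_starts, emb_lock, epsilon)
  })
}

.fit_group <- function(trees, constraint, n_starts, emb_lock, epsilon) {
  npar <- if (constraint == "hsc_first") 3L else 4L
  obj <- function(theta) {
    p <- stats::plogis(theta)
    pars <- if (constraint == "hsc_first")
      state_params(p[1], 0, p[2], p[3], emb_lock, epsilon)
    else
      state_params(min(p[1], 1 - p[2]), p[2], p[3], p[4], emb_lock, epsilon)
    -sum(vapply(trees, tree_loglikelihood, numeric(1), params = pars))
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- stats::qlogis(stats::runif(npar, 1e-4, 0.2))
    fit <- tryCatch(
      stats::optim(init, obj, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimization failed in all restarts")
  p <- stats::plogis(best$par)
  pars <- if (constraint == "hsc_first")
    state_params(p[1], 0, p[2], p[3], emb_lock, epsilon)
  else
    state_params(min(p[1], 1 - p[2]), p[2], p[3], p[4], emb_lock, epsilon)
  ll <- -best$value
  list(params = pars, loglik = ll, aic = 2 * npar - 2 * ll,
       n_par = npar, convergence = best$convergence == 0)
}

#' Likelihood-ratio comparison of nested ontogeny models
#'
#' @param fit_full fit from [fit_transition_rates] with `constraint =
#'   "none"`.
#' @param fit_constrained fit with `constraint = "hsc_first"`.
#' @return list with the LR statistic, df and p-value (chi-squared).
#' @export
lr_test_hsc_first <- function(fit_full, fit_constrained) {
  lr <- 2 * (fit_full$loglik - fit_constrained$loglik)
  df <- fit_full$n_par - fit_constrained$n_par
  list(statistic = lr, df = df,
       p_value = stats::pchisq(max(lr, 0), df, lower.tail = FALSE))
}
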
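#' Clades present at a molecular time
#'
#' Partitions the tips into the clades whose stem branch crosses molecular
#' time `t` (crossing is inclusive of `t`: the clade head is the first node
#' at molecular time >= `t` whose parent sits strictly before `t`). Tips
#' whose total molecular time is below `t` form singleton clades.
#'
#' @param phylo tree with mutation branch lengths.
#' @param t cutoff in mutations (default 50).
#' @return list with `t`, `clade` (head node per tip), `sizes` (tips per
#'   clade) and `tips` (tip indices per clade).
#' @export
clades_at_time <- function(phylo, t = 50) {
  stopifnot(t >= 0)
  depth <- node_mol_time(phylo)
  n_tip <- length(phylo$tip.label)
  parent <- integer(n_tip + phylo$Nnode)
  parent[phylo$edge[, 2]] <- phylo$edge[, 1]
  root <- n_tip + 1L
  head_of <- integer(n_tip)
  for (tip in seq_len(n_tip)) {
    if (depth[tip] < t) { head_of[tip] <- tip; next }
    v <- tip
    while (v != root && depth[parent[v]] >= t) v <- parent[v]
    head_of[tip] <- v
  }
  tips <- split(seq_len(n_tip), head_of)
  list(t = t, clade = head_of,
       sizes = vapply(tips, length, integer(1)), tips = tips)
}

#' Shannon diversity of a clade partition
#'
#' `H = -sum p_i log p_i` over clade tip shares; 0 when a single clade
#' holds every tip, `log(k)` for `k` equal clades.
#'
#' @param partition result of [clades_at_time] (or a vector of clade
#'   sizes).
#' @export
shannon_diversity <- function(partition) {
  sizes <- if (is.list(partition)) partition$sizes else partition
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

#' HSC/MPP mixing metric within clades
#'
#' For each clade established by molecular time `t`, the absolute
#' difference between its HSC proportion and the overall sampled HSC
#' fraction, averaged (unweighted) over clades. High values mean
#' phenotype-segregated clades; 0 means perfectly mixed.
#'
#' @param phylo tree with phenotyped tips (HSC/MPP).
#' @param t molecular-time cutoff (default 25).
#' @return list with `metric`, `n_clades`, `expected` (overall HSC
#'   fraction).
#' @export
mixing_metric <- function(phylo, t = 25) {
  obs <- .tip_states(phylo)
  part <- clades_at_time(phylo, t)
  p_bar <- mean(obs == "HSC")
  props <- vapply(part$tips, function(ix) mean(obs[ix] == "HSC"), numeric(1))
  list(metric = mean(abs(props - p_bar)), n_clades = length(props),
       expected = p_bar)
}

#' Reshuffling null for the mixing metric
#'
#' Permutes the HSC/MPP tip states and recomputes the metric; the one-
#' tailed p-value is the rank of the observed metric among the permuted
#' ones.
#'
#' @inheritParams mixing_metric
#' @param n_perm number of reshuffles.
#' @param seed integer seed.
#' @param randomized use the tie-randomized p-value (exactly uniform under
#'   the null despite the discreteness of the permutation distribution);
#'   the default reports the conservative rank-based p.
#' @return list with `observed`, `null` (vector), `p_value`, `degenerate`
#'   (TRUE when only one clade exists).
#' @export
mixing_null <- function(phylo, t = 25, n_perm = 1000, seed = NULL,
                        randomized = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  obs_states <- .tip_states(phylo)
  part <- clades_at_time(phylo, t)
  p_bar <- mean(obs_states == "HSC")
  metric_for <- function(st) {
    props <- vapply(part$tips, function(ix) mean(st[ix] == "HSC"),
                    numeric(1))
    mean(abs(props - p_bar))
  }
  m_obs <- metric_for(obs_states)
  null <- vapply(seq_len(n_perm), function(i) metric_for(sample(obs_states)),
                 numeric(1))
  p <- if (randomized) {
    (sum(null > m_obs) +
       stats::runif(1) * (sum(null == m_obs) + 1)) / (n_perm + 1)
  } else {
    (1 + sum(null >= m_obs)) / (n_perm + 1)
  }
  list(observed = m_obs, null = null, p_value = p,
       degenerate = length(part$tips) < 2)
}

#' Minimal directional cell-identity changes
#'
#' Number of irreversible X-to-Y conversions needed to explain the observed
#' tip phenotypes under a unidirectional ontogeny: under "HSC-first" every
#' lineage starts HSC and each maximal all-MPP subtree costs one
#' HSC-to-MPP change (and symmetrically for "MPP-first"). Reported as total
#' changes and changes per colony.
#'
#' @param phylo phenotyped tree.
#' @param model "HSC-first" (HSCs give rise to MPPs) or "MPP-first".
#' @return list with `changes`, `per_colony`, `model`.
#' @export
count_state_changes <- function(phylo, model = c("HSC-first", "MPP-first")) {
  model <- match.arg(model)
  target <- if (model == "HSC-first") "MPP" else "HSC"
  obs <- .tip_states(phylo)
  n_tip <- length(phylo$tip.label)
  n_node <- n_tip + phylo$Nnode
  ch <- .children_list(phylo)
  pure <- logical(n_node)   # subtree entirely `target`
  ord <- order(ape::node.depth(phylo))  # children before parents
  for (v in ord) {
    pure[v] <- if (v <= n_tip) obs[v] == target
    else all(pure[ch[[v]]])
  }
  parent <- integer(n_node)
  parent[phylo$edge[, 2]] <- phylo$edge[, 1]
  root <- n_tip + 1L
  # the root is pinned to the starting state, so it can never head a
  # converted subtree; each maximal pure-target subtree below it costs one
  # irreversible conversion
  pure[root] <- FALSE
  is_max <- pure & !pure[pmax(parent, 1L)]
  changes <- sum(is_max)
  list(changes = changes, per_colony = changes / n_tip, model = model)
}

#' Poisson mutations-per-division estimate from counts
#'
#' With `n` ancestral symmetric divisions of which `z` were mutationally
#' silent, the Poisson rate whose zero class matches the silent fraction is
#' `m = -log(z / n)`. The 95\% CI maps the Wilson interval of `z / n`
#' through `-log`.
#'
#' @param z number of zero-mutation (silent) divisions.
#' @param n total divisions.
#' @return list with `m`, `ci` (95\%), `z`, `n`.
#' @export
polytomy_rate_from_counts <- function(z, n) {
  stopifnot(n > 0, z >= 0, z <= n)
  if (z == 0) {
    w <- .wilson_ci(z, n)
    return(list(m = Inf, ci = c(-log(w[2]), Inf), z = z, n = n,
                unbounded = TRUE))
  }
  w <- .wilson_ci(z, n)
  list(m = -log(z / n), ci = c(-log(w[2]), -log(w[1])), z = z, n = n,
       unbounded = FALSE)
}

.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Early-life mutations-per-division from tree polytomies
#'
#' Counts ancestral symmetric divisions implied by the lineages present at
#' `t_max` mutations of molecular time (`lineages - 1` under a binary
#' genealogy) and the silent ones among them: each multifurcation of
#' out-degree `d` contributes `d - 2` silent divisions, plus any explicit
#' zero-length internal edges in the region. The Poisson rate follows from
#' [polytomy_rate_from_counts].
#'
#' @param phylo tree with mutation branch lengths.
#' @param t_max molecular-time window (default 12 mutations).
#' @param min_lineages minimum lineages required at `t_max` (default 10);
#'   trees below this lack early-life diversity and are rejected.
#' @return list as [polytomy_rate_from_counts] plus `lineages`.
#' @export
polytomy_mutation_rate <- function(phylo, t_max = 12, min_lineages = 10) {
  tr <- ape::di2multi(phylo, tol = 1e-8)
  depth <- node_mol_time(tr)
  n_tip <- length(tr$tip.label)
  lineages <- length(clades_at_time(tr, t_max)$tips)
  if (lineages < min_lineages)
    stop(sprintf("only %d lineages by %g mutations (need >= %d)",
                 lineages, t_max, min_lineages))
  n_div <- lineages - 1L
  ch <- .children_list(tr)
  internal <- (n_tip + 1L):(n_tip + tr$Nnode)
  silent <- 0L
  for (v in internal) {
    if (depth[v] >= t_max) next
    d <- length(ch[[v]])
    if (d > 2) silent <- silent + (d - 2L)
  }
  res <- polytomy_rate_from_counts(silent, n_div)
  res$lineages <- lineages
  res
}
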
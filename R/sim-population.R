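#' Simulate a bounded birth-death stem cell population
#'
#' Gillespie (exponential-clock) simulation of the per-cell birth-death
#' process defined by a [pop_model]. Every cell ever created is recorded
#' with its parent and birth time, so genealogies of sampled survivors can
#' be reconstructed exactly with [sample_phylogeny]. A division replaces the
#' dividing cell with two daughters; divisions are suppressed while the
#' population sits at the epoch cap.
#'
#' @param model a [pop_model].
#' @param t_end simulation end time in weeks post-conception.
#' @param seed integer seed (required, for reproducibility).
#' @param count_dt grid spacing (weeks) for the recorded size trajectory.
#' @param max_events guard on the total number of simulated events.
#' @return an object of class `pop_trace` with elements `counts`
#'   (data.frame of `week`, `n`), `parent`, `t_birth`, `alive` (cell ids,
#'   0-based), `extinct`, `t_end`.
#' @export
simulate_population <- function(model, t_end, seed, count_dt = 1,
                                max_events = 2e7) {
  stopifnot(inherits(model, "pop_model"))
  if (t_end <= 0) stop("t_end must be positive")
  if (missing(seed) || is.null(seed)) stop("a seed must be provided")
  set.seed(seed)
  ep <- as.matrix(model$epochs[, c("duration", "lambda", "nu", "cap")])
  res <- .sim_pop_cpp(ep, t_end, count_dt, max_events)
  if (res$extinct)
    warning("population went extinct before t_end; trace flagged")
  structure(list(
    counts = data.frame(week = res$grid_t, n = res$grid_n),
    parent = res$parent, t_birth = res$t_birth, alive = res$alive,
    extinct = res$extinct, t_end = t_end, model = model,
    n_events = res$n_events), class = "pop_trace")
}

#' @export
print.pop_trace <- function(x, ...) {
  cat(sprintf("Birth-death population trace: %d cells alive at %.1f weeks%s\n",
              length(x$alive), x$t_end,
              if (x$extinct) " (EXTINCT)" else ""))
  invisible(x)
}

#' Sample the genealogy of extant cells as a mutation-scaled phylogeny
#'
#' Uniformly samples `n_tips` extant cells from a [simulate_population]
#' trace and reconstructs their exact genealogy. Each branch spans an
#' integer number of ancestral cell divisions; its mutation count is the
#' sum of independent Poisson(`mutations_per_division`) draws over those
#' divisions, so zero-mutation branches (future polytomies) arise
#' naturally.
#'
#' @param trace a `pop_trace` from [simulate_population].
#' @param n_tips number of extant cells to sample.
#' @param mutations_per_division Poisson mean per daughter per division;
#'   defaults to the value in the trace's model (1.8).
#' @param seed integer seed.
#' @return an [ape::ape-package] `phylo` object with branch lengths in
#'   mutations and extra components: `divisions` (per edge), `node.real.time`
#'   (weeks, per node), `root.divisions`, `root.mutations`, `root.edge`
#'   (mutations on the stem from the zygote to the MRCA), `tip.cell`.
#' @export
sample_phylogeny <- function(trace, n_tips,
                             mutations_per_division = NULL, seed = NULL) {
  stopifnot(inherits(trace, "pop_trace"))
  if (is.null(mutations_per_division))
    mutations_per_division <- trace$model$mutations_per_division
  n_alive <- length(trace$alive)
  if (n_tips > n_alive)
    stop(sprintf("n_tips (%d) exceeds the extant population size (%d)",
                 n_tips, n_alive))
  if (n_tips < 2) stop("need at least 2 tips")
  if (!is.null(seed)) set.seed(seed)
  tips <- sample(trace$alive, n_tips)
  gen <- .extract_genealogy(trace$parent, trace$t_birth, tips, trace$t_end)
  .genealogy_to_phylo(gen, mutations_per_division)
}

# Reconstruct the induced genealogy of `tips` (0-based cell ids).
# Returns node table: for every retained tree node (tips and branching
# ancestors) its real time, its parent tree node, and the number of cell
# divisions along the connecting branch.
.extract_genealogy <- function(parent, t_birth, tips, t_end) {
  n <- length(tips)
  # mark ancestor chains (1-based ids into parent vector)
  retained <- logical(length(parent))
  for (tip in tips) {
    v <- tip + 1L
    while (v > 0L && !retained[v]) {
      retained[v] <- TRUE
      v <- parent[v] + 1L
    }
  }
  # retained children per cell
  pp <- parent[which(retained)] + 1L
  anc_count <- tabulate(pp[pp > 0L], nbins = length(parent))
  is_tip <- logical(length(parent)); is_tip[tips + 1L] <- TRUE
  # a retained cell is a tree node if it is a sampled tip, or if >= 2 of its
  # children lead to sampled tips (a coalescence).
  is_node <- retained & (is_tip | anc_count >= 2L)
  node_ids <- which(is_node)
  node_index <- integer(length(parent))
  node_index[node_ids] <- seq_along(node_ids)
  # walk from each node up to its parent node, counting divisions
  n_nodes <- length(node_ids)
  par_node <- integer(n_nodes)
  divisions <- integer(n_nodes)
  node_time <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    v <- node_ids[i]
    node_time[i] <- if (is_tip[v] && anc_count[v] == 0L) t_end else NA_real_
    # divisions: each cell on the chain (including v itself) was created by
    # one division, except the zygote.
    d <- 0L
    u <- v
    repeat {
      if (parent[u] + 1L == 0L) { par_node[i] <- 0L; break }
      d <- d + 1L
      u <- parent[u] + 1L
      if (is_node[u]) { par_node[i] <- node_index[u]; break }
    }
    divisions[i] <- d
  }
  # internal node time = time its children were born (the division time)
  for (i in seq_len(n_nodes)) {
    if (!is.na(node_time[i])) next
    ch <- which(par_node == i)
    # children cells' chain bottoms: the division happened when the first
    # cell on the child chain was born; find it by walking down is not
    # needed -- the division time equals t_birth of the child cell chain's
    # topmost cell, i.e. the child of node_ids[i] on that path. Use the
    # birth time of the first cell after this node on any child chain.
    node_time[i] <- .division_time(parent, t_birth, node_ids, par_node,
                                   i, ch)
  }
  list(node_ids = node_ids, par_node = par_node, divisions = divisions,
       node_time = node_time, is_tip = is_tip[node_ids],
       tips = tips, t_end = t_end)
}

.division_time <- function(parent, t_birth, node_ids, par_node, i, ch) {
  # the division at node i created the two daughter cells; both were born
  # at the same instant, so take the birth time of the cell at the top of
  # any child chain: walk up from the child node until the next step up
  # would reach node i.
  v <- node_ids[ch[1]]
  while (parent[v] + 1L != node_ids[i]) v <- parent[v] + 1L
  t_birth[v]
}

# Convert the genealogy table into an ape phylo with Poisson mutations.
.genealogy_to_phylo <- function(gen, m) {
  is_tip <- gen$is_tip
  n_tip <- sum(is_tip)
  n_nodes <- length(gen$node_ids)
  # ape numbering: tips 1..n, internals n+1.., root = n+1
  tip_order <- which(is_tip)
  int_order <- which(!is_tip)
  root_i <- which(gen$par_node == 0L)
  stopifnot(length(root_i) == 1L)
  int_order <- c(root_i, setdiff(int_order, root_i))
  ape_id <- integer(n_nodes)
  ape_id[tip_order] <- seq_len(n_tip)
  ape_id[int_order] <- n_tip + seq_along(int_order)
  has_par <- gen$par_node > 0L
  edge <- cbind(ape_id[gen$par_node[has_par]], ape_id[has_par])
  divisions <- gen$divisions[has_par]
  mutations <- stats::rpois(length(divisions), m * divisions)
  # root stem from the zygote to the MRCA
  root_div <- gen$divisions[root_i]
  root_mut <- stats::rpois(1, m * root_div)
  node_time <- numeric(n_nodes)
  node_time[ape_id] <- gen$node_time
  tip_cell <- (gen$node_ids[tip_order]) - 1L
  tr <- list(edge = edge, edge.length = as.numeric(mutations),
             tip.label = paste0("cell", tip_cell),
             Nnode = n_nodes - n_tip)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- ape::reorder.phylo(tr, "cladewise")
  # reorder edge-aligned extras to match
  o <- match(paste(tr$edge[, 1], tr$edge[, 2]), paste(edge[, 1], edge[, 2]))
  tr$divisions <- divisions[o]
  tr$edge.length <- as.numeric(mutations[o])
  tr$root.edge <- as.numeric(root_mut)
  tr$root.divisions <- root_div
  tr$node.real.time <- node_time
  tr$tip.cell <- tip_cell
  tr
}

#' Simulate heritable EMB/HSC/MPP states down a phylogeny
#'
#' Forward version of the hidden Markov tree: states evolve from the zygote
#' (EMB) down the tree, one step per mutation of molecular time, under the
#' single-step matrix of [transition_matrix]. The lineage is held in EMB
#' for the first `emb_lock` mutations. Tip phenotypes equal the true tip
#' state, optionally corrupted at rate `epsilon_obs`.
#'
#' @param phylo a `phylo` with integer branch lengths in mutations (a
#'   `root.edge` stem, if present, is included in molecular time).
#' @param params a [state_params].
#' @param seed integer seed.
#' @param epsilon_obs probability that a tip phenotype is mislabelled
#'   (default 0: error-free fixtures).
#' @return the tree with added components `node.state` (true end-of-branch
#'   state per node, EMB/HSC/MPP) and `tip.state` (observed phenotype per
#'   tip); tip labels gain a `|PHENOTYPE` suffix.
#' @export
label_states <- function(phylo, params, seed = NULL, epsilon_obs = 0) {
  stopifnot(inherits(phylo, "phylo"), inherits(params, "state_params"))
  if (!is.null(seed)) set.seed(seed)
  M <- transition_matrix(params)
  n_tip <- length(phylo$tip.label)
  n_node <- n_tip + phylo$Nnode
  depth <- node_mol_time(phylo)
  root <- n_tip + 1L
  state <- integer(n_node)
  root_len <- if (is.null(phylo$root.edge)) 0 else round(phylo$root.edge)
  state[root] <- .sim_state_path(1L, 0, root_len, M, params$emb_lock)
  # cladewise order guarantees parents are visited before children
  cw <- ape::reorder.phylo(phylo, "cladewise")
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; v <- cw$edge[e, 2]
    l <- round(cw$edge.length[e])
    state[v] <- .sim_state_path(state[p], depth[p], l, M, params$emb_lock)
  }
  phylo$node.state <- .states[state]
  tip_state <- state[seq_len(n_tip)]
  obs <- .states[tip_state]
  if (epsilon_obs > 0) {
    flip <- stats::runif(n_tip) < epsilon_obs & obs != "EMB"
    obs[flip] <- ifelse(obs[flip] == "HSC", "MPP", "HSC")
  }
  phylo$tip.state <- obs
  phylo$tip.label <- paste0(sub("\\|.*$", "", phylo$tip.label), "|", obs)
  phylo
}

# simulate the chain for `len` steps starting at molecular time t0 in
# state i (1 = EMB); steps ending at molecular time <= emb_lock are frozen.
.sim_state_path <- function(i, t0, len, M, emb_lock) {
  if (len <= 0) return(i)
  t1 <- t0 + len
  free <- t1 - max(t0, emb_lock)      # steps that can transition
  if (free <= 0) return(i)
  steps <- free
  # geometric-jump simulation: transitions are rare
  while (steps > 0) {
    stay <- M[i, i]
    if (stay >= 1) return(i)
    jump_in <- stats::rgeom(1, 1 - stay) + 1  # step index of first jump
    if (jump_in > steps) return(i)
    steps <- steps - jump_in
    probs <- M[i, ]; probs[i] <- 0
    i <- sample.int(3L, 1L, prob = probs)
  }
  i
}

#' Molecular time of every node
#'
#' Cumulative mutation count from the zygote to each node, including the
#' root stem (`root.edge`) when present.
#'
#' @param phylo a `phylo` with branch lengths in mutations.
#' @return numeric vector over nodes (tips first, ape numbering).
#' @export
node_mol_time <- function(phylo) {
  d <- ape::node.depth.edgelength(phylo)
  if (!is.null(phylo$root.edge)) d <- d + phylo$root.edge
  d
}
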
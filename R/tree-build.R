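#' Build a colony phylogeny from a filtered genotype matrix
#'
#' Perfect-phylogeny construction from depth-aware Present/Absent/Unknown
#' genotype calls, followed by maximum-likelihood placement of every
#' variant on the branch that best explains its read counts (binomial
#' likelihood with clonal VAF for carriers and an error VAF elsewhere;
#' uncovered colonies are uninformative and never veto a placement).
#' Carrier sets must form a laminar (nested-or-disjoint) family; variants
#' in conflict with the consensus topology are still placed by likelihood,
#' but if the fraction of conflicting variants exceeds `max_conflict` the
#' build is refused and an externally built Newick tree should be supplied.
#'
#' @param cm a [colony_matrix], ideally restricted to filter-passing sites.
#' @param pass optional logical per site.
#' @param config a [colony_filter_config] (genotyping rule).
#' @param p_clonal expected carrier VAF (default 0.48, slightly below 0.5
#'   for residual contamination).
#' @param p_error read error VAF for non-carriers (default 0.01).
#' @param max_conflict maximum tolerated fraction of topology-conflicting
#'   variants (default 0.05).
#' @return `phylo` with tips = colonies, edge lengths = number of variants
#'   assigned to each branch, `branch.variants` (site ids per edge) and
#'   `root.edge` = variants carried by every colony.
#' @export
build_tree <- function(cm, pass = rep(TRUE, nrow(cm$sites)),
                       config = colony_filter_config(),
                       p_clonal = 0.48, p_error = 0.01,
                       max_conflict = 0.05) {
  if (!any(pass)) stop("no passing variants to build from")
  calls <- genotype_calls(cm, config)[pass, , drop = FALSE]
  NV <- cm$NV[pass, , drop = FALSE]
  NR <- cm$NR[pass, , drop = FALSE]
  ids <- cm$sites$id[pass]
  n_col <- length(cm$colonies)
  carrier <- calls == "P"
  # unique informative carrier sets, weighted by variant support
  keys <- apply(carrier, 1, function(z) paste(which(z), collapse = ","))
  informative <- rowSums(carrier) > 0 & rowSums(carrier) < n_col
  key_tab <- table(keys[informative])
  sets <- lapply(strsplit(names(key_tab), ","), as.integer)
  support <- as.integer(key_tab)
  # greedy laminar subfamily, best-supported (then largest) sets first:
  # read-dropout subsets of a true clade lose to the well-supported clade
  keep <- .laminar_subset(sets, support)
  if (!all(keep)) {
    # a dropped set contained in a kept superset is explained by dropout;
    # sets that are no one's subset are genuine four-gamete conflicts
    kept_sets <- sets[keep]
    irresolvable <- vapply(which(!keep), function(i) {
      !any(vapply(kept_sets, function(k)
        length(sets[[i]]) < length(k) && all(sets[[i]] %in% k),
        logical(1)))
    }, logical(1))
    n_conf <- sum(support[!keep][irresolvable])
    if (n_conf / length(ids) > max_conflict)
      stop(sprintf(paste("%d of %d variants conflict with a perfect",
                         "phylogeny; supply an externally built Newick",
                         "tree instead"), n_conf, length(ids)))
    sets <- kept_sets
  }
  tr <- .laminar_to_phylo(sets, cm$colonies)
  # ML placement of every variant on a branch (edge sets + root)
  edge_sets <- .edge_tip_sets(tr)
  la <- stats::dbinom(NV, NR, p_clonal, log = TRUE)
  le <- stats::dbinom(NV, NR, p_error, log = TRUE)
  diffm <- la - le                      # sites x colonies
  base <- rowSums(le)
  memb <- vapply(edge_sets, function(s) {
    z <- numeric(n_col); z[s] <- 1; z
  }, numeric(n_col))                    # colonies x edges
  memb <- cbind(memb, 1)                # last column: root (all colonies)
  ll <- diffm %*% memb + base           # sites x (edges + root)
  best <- max.col(ll, ties.method = "first")
  n_edges <- nrow(tr$edge)
  tr$edge.length <- as.numeric(tabulate(best[best <= n_edges], n_edges))
  tr$root.edge <- sum(best > n_edges)
  tr$branch.variants <- lapply(seq_len(n_edges), function(e)
    ids[best == e])
  tr$root.variants <- ids[best > n_edges]
  tr
}

# keep a maximal laminar subfamily, preferring better-supported then
# larger sets
.laminar_subset <- function(sets, support = rep(1L, length(sets))) {
  ord <- order(-support, -vapply(sets, length, integer(1)))
  keep <- logical(length(sets))
  kept <- list()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      ab <- length(intersect(sets[[i]], k))
      if (ab > 0 && ab < length(sets[[i]]) && ab < length(k)) {
        ok <- FALSE; break
      }
    }
    if (ok) { keep[i] <- TRUE; kept <- c(kept, sets[i]) }
  }
  keep
}

# build a rooted phylo from a laminar family of tip sets
.laminar_to_phylo <- function(sets, colonies) {
  n <- length(colonies)
  all_sets <- c(list(seq_len(n)), sets)
  sizes <- vapply(all_sets, length, integer(1))
  ord <- order(-sizes)
  all_sets <- all_sets[ord]
  # drop duplicate sets
  keys <- vapply(all_sets, paste, "", collapse = ",")
  all_sets <- all_sets[!duplicated(keys)]
  # ensure singletons exist for every colony
  singles <- vapply(all_sets, length, integer(1)) == 1
  have <- unlist(all_sets[singles])
  for (c in setdiff(seq_len(n), have)) all_sets <- c(all_sets, list(c))
  sizes <- vapply(all_sets, length, integer(1))
  # parent = smallest strict superset
  n_sets <- length(all_sets)
  parent <- integer(n_sets)
  for (i in 2:n_sets) {
    best <- 1L; bs <- n + 1L
    for (j in seq_len(n_sets)) {
      if (j == i || sizes[j] <= sizes[i]) next  # strict superset only
      if (sizes[j] < bs && all(all_sets[[i]] %in% all_sets[[j]])) {
        best <- j; bs <- sizes[j]
      }
    }
    parent[i] <- best
  }
  # node numbering: tips = singleton sets in colony order; internals rest
  is_tip_set <- sizes == 1
  tip_of <- integer(n_sets)
  tip_of[is_tip_set] <- unlist(all_sets[is_tip_set])
  node_id <- integer(n_sets)
  node_id[is_tip_set] <- tip_of[is_tip_set]
  internal <- which(!is_tip_set)
  # root (index 1) must be n+1
  internal <- c(1L, setdiff(internal, 1L))
  node_id[internal] <- n + seq_along(internal)
  edge <- cbind(node_id[parent[-1]], node_id[-1])
  tr <- list(edge = edge, edge.length = rep(0, nrow(edge)),
             tip.label = colonies, Nnode = length(internal))
  class(tr) <- "phylo"
  # collapse is deferred: unary internal nodes cannot arise because every
  # internal set has >= 2 children in a laminar family with all singletons
  ape::reorder.phylo(tr, "cladewise")
}

#' Normalize branch lengths for detection sensitivity
#'
#' Divides each terminal branch length by its colony's variant-detection
#' sensitivity (from the depth-correction fit) and each shared branch by
#' the mean sensitivity of its descendant colonies; lengths are rounded to
#' integers for molecular-time analyses. Raw lengths are kept in
#' `edge.length.raw`.
#'
#' @param phylo colony tree.
#' @param sensitivity named vector in (0, 1] per colony (tip label order
#'   or named by tip label).
#' @return the tree with normalized `edge.length`.
#' @export
normalize_branch_lengths <- function(phylo, sensitivity) {
  n_tip <- length(phylo$tip.label)
  if (!is.null(names(sensitivity)))
    sensitivity <- sensitivity[sub("\\|.*$", "", phylo$tip.label)]
  if (any(is.na(sensitivity)) || length(sensitivity) != n_tip)
    stop("need one sensitivity per colony")
  if (any(sensitivity <= 0) || any(sensitivity > 1))
    stop("sensitivities must lie in (0, 1]")
  sets <- .edge_tip_sets(phylo)
  sens_edge <- vapply(sets, function(s) mean(sensitivity[s]), numeric(1))
  phylo$edge.length.raw <- phylo$edge.length
  phylo$edge.length <- round(phylo$edge.length / sens_edge)
  phylo
}
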
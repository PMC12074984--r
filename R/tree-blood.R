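#' Conjugate beta posterior for a variant allele fraction
#'
#' Jeffreys-style posterior `Beta(mutant + 0.5, depth - mutant + 0.5)` for
#' the true VAF given mutant and total read counts.
#'
#' @param mutant mutant read count(s).
#' @param depth total depth(s).
#' @return data.frame with posterior `mean` and 95\% interval.
#' @export
vaf_posterior <- function(mutant, depth) {
  stopifnot(all(mutant >= 0), all(depth >= mutant))
  a <- mutant + 0.5
  b <- depth - mutant + 0.5
  data.frame(mean = a / (a + b),
             lower = stats::qbeta(0.025, a, b),
             upper = stats::qbeta(0.975, a, b))
}

#' Shared truncal variants between blood and colonic crypts
#'
#' Two-tier positivity for each truncal variant in each crypt: (1) a crypt
#' is positive when the variant's VAF reaches the per-crypt minimum VAF
#' threshold (half the median VAF of the crypt's passing variants); (2) for
#' variants already seen in at least one crypt, any remaining crypt with
#' more than 2 mutant reads is also positive. A crypt with zero coverage at
#' a site is treated as negative there.
#'
#' @param reads data.frame with columns `variant_id`, `crypt`, `nv`
#'   (mutant reads), `nr` (depth).
#' @param branch_of named vector mapping variant ids to branch labels.
#' @param threshold scalar or per-crypt named vector of minimum VAFs.
#' @param rescue_reads mutant-read rescue cutoff (strictly greater than;
#'   default 2).
#' @return list with `positive` (variant x crypt logical matrix) and
#'   `branch_fraction` (per branch, fraction of crypts carrying >= 1 of its
#'   variants).
#' @export
crypt_sharing <- function(reads, branch_of, threshold, rescue_reads = 2) {
  stopifnot(all(c("variant_id", "crypt", "nv", "nr") %in% names(reads)))
  variants <- unique(reads$variant_id)
  crypts <- unique(reads$crypt)
  thr <- if (length(threshold) == 1)
    stats::setNames(rep(threshold, length(crypts)), crypts)
  else threshold[crypts]
  pos <- matrix(FALSE, length(variants), length(crypts),
                dimnames = list(variants, crypts))
  nvm <- nrm <- matrix(0, length(variants), length(crypts),
                       dimnames = dimnames(pos))
  for (i in seq_len(nrow(reads))) {
    nvm[reads$variant_id[i], reads$crypt[i]] <- reads$nv[i]
    nrm[reads$variant_id[i], reads$crypt[i]] <- reads$nr[i]
  }
  vaf <- ifelse(nrm > 0, nvm / pmax(nrm, 1), 0)
  # tier 1: per-crypt VAF threshold
  for (cr in crypts) pos[, cr] <- vaf[, cr] >= thr[cr] & nrm[, cr] > 0
  # tier 2: read-support rescue for variants seen in some crypt
  seen <- rowSums(pos) > 0
  pos[seen, ] <- pos[seen, , drop = FALSE] |
    (nvm[seen, , drop = FALSE] > rescue_reads)
  branch <- branch_of[variants]
  bf <- vapply(split(seq_along(variants), branch), function(ix) {
    mean(colSums(pos[ix, , drop = FALSE]) > 0)
  }, numeric(1))
  list(positive = pos, branch_fraction = bf)
}

#' Aggregate blood VAF trajectory over molecular time
#'
#' Reconstructs, per molecular time `t`, the summed VAF of all tree
#' branches overlapping `t`: within each branch the targeted variants are
#' arranged in descending posterior-mean VAF at equally spaced molecular
#' times down the branch and linearly interpolated; the aggregate at `t`
#' sums the interpolated VAF of every overlapping branch. Branches with no
#' targeted variants are excluded and counted.
#'
#' @param phylo tree with mutation branch lengths.
#' @param targets data.frame with `edge` (edge index in `phylo$edge`),
#'   `mutant`, `depth` (blood read counts per targeted variant).
#' @param t_grid molecular times at which to evaluate.
#' @param classes optional per-edge class labels (e.g. decoded HSC/MPP);
#'   aggregates are then reported per class.
#' @return data.frame with `t`, `class`, `aggregate_vaf`, `n_branches`;
#'   attribute `excluded_branches` counts branches without targets.
#' @export
lineage_vaf_trajectory <- function(phylo, targets, t_grid,
                                   classes = NULL) {
  stopifnot(all(c("edge", "mutant", "depth") %in% names(targets)))
  depthm <- node_mol_time(phylo)
  e_top <- depthm[phylo$edge[, 1]]
  e_bot <- depthm[phylo$edge[, 2]]
  post <- vaf_posterior(targets$mutant, targets$depth)$mean
  if (is.null(classes)) classes <- rep("all", nrow(phylo$edge))
  branch_fun <- vector("list", nrow(phylo$edge))
  for (e in unique(targets$edge)) {
    v <- sort(post[targets$edge == e], decreasing = TRUE)
    k <- length(v)
    pos <- if (k == 1) mean(c(e_top[e], e_bot[e]))
    else seq(e_top[e], e_bot[e], length.out = k)
    branch_fun[[e]] <- list(pos = pos, vaf = v)
  }
  excluded <- sum(vapply(branch_fun, is.null, logical(1)))
  out <- do.call(rbind, lapply(t_grid, function(t) {
    overlap <- which(e_top <= t & e_bot >= t)
    rows <- lapply(unique(classes[overlap]), function(cl) {
      eo <- overlap[classes[overlap] == cl]
      vals <- vapply(eo, function(e) {
        bf <- branch_fun[[e]]
        if (is.null(bf)) return(NA_real_)
        if (length(bf$vaf) == 1) return(bf$vaf)
        stats::approx(bf$pos, bf$vaf, xout = t, rule = 2)$y
      }, numeric(1))
      data.frame(t = t, class = cl,
                 aggregate_vaf = sum(vals, na.rm = TRUE),
                 n_branches = sum(!is.na(vals)))
    })
    do.call(rbind, rows)
  }))
  attr(out, "excluded_branches") <- excluded
  out
}
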
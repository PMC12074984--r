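#' Colony genotype matrix
#'
#' Container for per-site x per-colony read counts from whole-genome
#' sequencing of single-cell-derived colonies: total depth (`NR`), mutant
#' depth (`NV`) and mutant-forward depth (`NF`), plus site annotations.
#'
#' @param sites data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   `class` ("SNV" or "indel"), `hp_len` (length of the adjacent
#'   single-nucleotide repeat, bp) and optionally `truth` (simulation truth
#'   label).
#' @param NV,NR,NF integer matrices, sites x colonies.
#' @param colonies colony names (defaults to `colnames(NR)`).
#' @return object of class `colony_matrix`.
#' @export
colony_matrix <- function(sites, NV, NR, NF = NULL, colonies = colnames(NR)) {
  stopifnot(nrow(sites) == nrow(NV), all(dim(NV) == dim(NR)))
  if (is.null(NF)) NF <- matrix(NA_integer_, nrow(NV), ncol(NV))
  if (any(NV > NR)) stop("mutant depth exceeds total depth")
  if (any(!is.na(NF) & NF > NV)) stop("forward mutant depth exceeds mutant depth")
  if (is.null(colonies)) colonies <- paste0("colony", seq_len(ncol(NV)))
  dimnames(NV) <- dimnames(NR) <- dimnames(NF) <- list(sites$id, colonies)
  structure(list(sites = sites, NV = NV, NR = NR, NF = NF,
                 colonies = colonies), class = "colony_matrix")
}

#' @export
print.colony_matrix <- function(x, ...) {
  cat(sprintf("Colony genotype matrix: %d sites x %d colonies\n",
              nrow(x$sites), length(x$colonies)))
  invisible(x)
}

#' Simulate a colony genotype matrix from a phylogeny
#'
#' Plants every branch mutation of `phylo` as a heterozygous somatic SNV
#' (VAF 0.5 in carrier colonies), adds germline sites (VAF 0.5 in all
#' colonies) and artifact classes targeted by the filter suite, then draws
#' reads binomially at Poisson-distributed per-site depth. Truth labels are
#' retained in `sites$truth`.
#'
#' @param phylo colony tree with integer mutation branch lengths; tips are
#'   colonies (root-stem mutations are not planted).
#' @param mean_depth mean sequencing depth (default 14, typical low-input
#'   colony WGS).
#' @param n_germline number of germline sites.
#' @param artifact_spec list with counts per artifact class:
#'   `strand` (strand-biased), `lowvaf` (low-VAF cross-colony contaminant),
#'   `homopolymer` (adjacent repeat >= 5 bp), `clustered` (pairs < 10 bp
#'   apart).
#' @param seed integer seed.
#' @param infinite_depth logical; exact VAFs at fixed high depth (error-free
#'   mode used for tree-builder round trips).
#' @return a [colony_matrix] with `truth` labels `somatic`, `germline`,
#'   `artifact_strand`, `artifact_lowvaf`, `artifact_homopolymer`,
#'   `artifact_clustered`.
#' @export
simulate_genotype_matrix <- function(phylo, mean_depth = 14,
                                     n_germline = 30,
                                     artifact_spec = list(strand = 10,
                                                          lowvaf = 10,
                                                          homopolymer = 10,
                                                          clustered = 10),
                                     seed = NULL, infinite_depth = FALSE) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_col <- length(phylo$tip.label)
  colonies <- sub("\\|.*$", "", phylo$tip.label)
  # carrier sets per edge
  desc <- .edge_tip_sets(phylo)
  lens <- as.integer(round(phylo$edge.length))
  edge_of_variant <- rep(seq_len(nrow(phylo$edge)), lens)
  n_somatic <- length(edge_of_variant)
  a <- artifact_spec
  n_art <- sum(unlist(a))
  n_sites <- n_somatic + n_germline + n_art
  # random genomic coordinates, well separated unless clustered
  pos <- sort(sample.int(5e7, n_sites)) * 50
  pos <- sample(pos)  # shuffle so ordering does not encode truth
  carrier <- matrix(FALSE, n_sites, n_col)
  truth <- character(n_sites)
  vaf_true <- matrix(0, n_sites, n_col)
  hp_len <- sample(0:4, n_sites, replace = TRUE)
  i <- 0L
  for (v in seq_len(n_somatic)) {
    i <- i + 1L
    carrier[i, desc[[edge_of_variant[v]]]] <- TRUE
    truth[i] <- "somatic"
    vaf_true[i, carrier[i, ]] <- 0.5
  }
  if (n_germline > 0) for (g in seq_len(n_germline)) {
    i <- i + 1L
    carrier[i, ] <- TRUE
    truth[i] <- "germline"
    vaf_true[i, ] <- 0.5
  }
  strand_rows <- integer(0); lowvaf_rows <- integer(0)
  # strand artifacts emulate recurrent mapping errors: they appear across
  # many colonies with exclusively unidirectional mutant support
  if (!is.null(a$strand) && a$strand > 0) for (j in seq_len(a$strand)) {
    i <- i + 1L
    cc <- sample.int(n_col, max(4, rbinom(1, n_col, 0.5)))
    carrier[i, cc] <- TRUE; vaf_true[i, cc] <- 0.5
    truth[i] <- "artifact_strand"; strand_rows <- c(strand_rows, i)
  }
  if (!is.null(a$lowvaf) && a$lowvaf > 0) for (j in seq_len(a$lowvaf)) {
    i <- i + 1L
    cc <- sample.int(n_col, max(2, rbinom(1, n_col, 0.8)))
    carrier[i, cc] <- TRUE; vaf_true[i, cc] <- 0.05
    truth[i] <- "artifact_lowvaf"; lowvaf_rows <- c(lowvaf_rows, i)
  }
  if (!is.null(a$homopolymer) && a$homopolymer > 0)
    for (j in seq_len(a$homopolymer)) {
      i <- i + 1L
      cc <- sample.int(n_col, max(2, rbinom(1, n_col, 0.2)))
      carrier[i, cc] <- TRUE; vaf_true[i, cc] <- 0.5
      truth[i] <- "artifact_homopolymer"
      hp_len[i] <- sample(5:9, 1)
    }
  if (!is.null(a$clustered) && a$clustered > 0)
    for (j in seq_len(a$clustered)) {
      i <- i + 1L
      cc <- sample.int(n_col, max(2, rbinom(1, n_col, 0.2)))
      carrier[i, cc] <- TRUE; vaf_true[i, cc] <- 0.5
      truth[i] <- "artifact_clustered"
      if (j %% 2L == 0L) pos[i] <- pos[i - 1L] + sample(1:9, 1)
    }
  # read sampling
  if (infinite_depth) {
    NR <- matrix(1000L, n_sites, n_col)
    NV <- matrix(as.integer(round(vaf_true * 1000)), n_sites, n_col)
  } else {
    NR <- matrix(stats::rpois(n_sites * n_col, mean_depth), n_sites, n_col)
    NV <- matrix(stats::rbinom(n_sites * n_col, as.vector(NR),
                               as.vector(vaf_true)), n_sites, n_col)
  }
  NF <- matrix(stats::rbinom(n_sites * n_col, as.vector(NV), 0.5),
               n_sites, n_col)
  NF[strand_rows, ] <- NV[strand_rows, ]   # all mutant reads forward
  sites <- data.frame(
    id = paste0("site", seq_len(n_sites)),
    chrom = "chr1", pos = pos, ref = "C", alt = "T",
    class = "SNV", hp_len = hp_len, truth = truth,
    stringsAsFactors = FALSE)
  cm <- colony_matrix(sites, NV, NR, NF, colonies)
  cm$phylo <- phylo
  cm$variant_edge <- edge_of_variant
  cm
}

# tips descended from each edge (indices into tip set)
.edge_tip_sets <- function(phylo) {
  n_tip <- length(phylo$tip.label)
  ch <- .children_list(phylo)
  sets <- vector("list", n_tip + phylo$Nnode)
  depth <- ape::node.depth(phylo)
  ord <- order(depth)  # tips (depth 1) first
  for (v in ord) {
    if (v <= n_tip) sets[[v]] <- v
    else sets[[v]] <- unlist(lapply(ch[[v]], function(x) sets[[x]]))
  }
  lapply(seq_len(nrow(phylo$edge)), function(e) sets[[phylo$edge[e, 2]]])
}
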
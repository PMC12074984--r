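#' Write / read a colony genotype matrix as tab-separated text
#'
#' Long format with one row per site x colony: site annotations plus
#' `colony`, `nr`, `nv`, `nf`.
#'
#' @param cm a [colony_matrix].
#' @param path output file.
#' @export
write_colony_matrix <- function(cm, path) {
  long <- do.call(rbind, lapply(seq_along(cm$colonies), function(j) {
    cbind(cm$sites,
          colony = cm$colonies[j], nr = cm$NR[, j], nv = cm$NV[, j],
          nf = cm$NF[, j])
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_colony_matrix
#' @export
read_colony_matrix <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  colonies <- unique(long$colony)
  site_cols <- setdiff(names(long), c("colony", "nr", "nv", "nf"))
  sites <- unique(long[, site_cols])
  rownames(sites) <- NULL
  idx <- match(long$id, sites$id)
  jdx <- match(long$colony, colonies)
  mk <- function(col) {
    m <- matrix(NA_integer_, nrow(sites), length(colonies))
    m[cbind(idx, jdx)] <- long[[col]]
    m
  }
  colony_matrix(sites, mk("nv"), mk("nr"), mk("nf"), colonies)
}

#' Write / read a phenotyped tree as annotated Newick
#'
#' Tip labels carry `colonyID|PHENOTYPE`; branch lengths are mutation
#' counts. The root stem is preserved.
#'
#' @param phylo tree.
#' @param path file path.
#' @export
write_tree_newick <- function(phylo, path) {
  ape::write.tree(phylo, file = path)
  invisible(path)
}

#' @rdname write_tree_newick
#' @export
read_tree_newick <- function(path) {
  tr <- ape::read.tree(path)
  st <- try(.tip_states(tr), silent = TRUE)
  if (!inherits(st, "try-error")) tr$tip.state <- st
  tr
}

#' Write a duplex variant table / VAF spectrum as TSV
#'
#' @param x data.frame (duplex table or `vaf_spectrum`).
#' @param path file path.
#' @export
write_variant_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
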
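#' Default duplex-variant filter configuration
#'
#' Cutoffs for the thirteen table-level filters applied to duplex-consensus
#' variant calls. Filters 12 (synonymous impact) and 13 (human-homologous
#' position) are off by default because analyses that need synonymous
#' variants (dN/dS, fitness estimation) must keep them.
#'
#' @param min_reads minimum supporting consensus reads (singletons fail).
#' @param max_mismatches maximum mean mismatches per supporting read.
#' @param end_repair_max maximum end-repair artefact probability (the
#'   upstream tool's cutoff is not published; 0.1 by default).
#' @param min_end_dist minimum distance from read ends, bp (<= 15 fails).
#' @param min_depth duplex depth at or below which a locus is
#'   undersequenced (20,000x).
#' @param strand_p Fisher-test threshold for strand bias.
#' @param recur_frac,recur_n recurrence rule: fraction of samples per batch
#'   or count of independent samples.
#' @param max_indel_len indels at or above this length fail (15 bp).
#' @param max_vaf VAF at or above this is putative germline (0.4).
#' @param drop_synonymous,require_homolog activate filters 12 and 13.
#' @param batch_sizes optional named vector giving the number of sequenced
#'   samples per batch; by default batch sizes are inferred from the table,
#'   which understates them when the table is a pre-filtered subset.
#' @export
duplex_filter_config <- function(min_reads = 2, max_mismatches = 3.0,
                                 end_repair_max = 0.1, min_end_dist = 15,
                                 min_depth = 20000, strand_p = 0.001,
                                 recur_frac = 0.05, recur_n = 5,
                                 max_indel_len = 15, max_vaf = 0.4,
                                 drop_synonymous = FALSE,
                                 require_homolog = FALSE,
                                 batch_sizes = NULL) {
  as.list(environment())
}

.duplex_required <- c("sample_id", "batch_id", "locus", "ref", "alt",
                      "class", "vaf", "depth", "supporting_reads",
                      "mean_mismatches", "min_read_end_dist", "fwd_mut",
                      "rev_mut", "fwd_wt", "rev_wt", "end_repair_prob",
                      "flag", "indel_len", "human_homolog", "is_oxidative")

#' Duplex-consensus variant filters
#'
#' Applies the thirteen post-processing filters to a duplex variant table,
#' in order: (1) caller quality flag PASS; (2) read support (singletons);
#' (3) mean mismatches per supporting read > 3.0; (4) end-repair/A-tailing
#' artefact probability; (5) position <= 15 bp from read ends; (6)
#' oxidative-damage signature class; (7) duplex depth <= 20,000x
#' undersequenced; (8) Fisher strand bias between mutant and wild-type
#' reads; (9) recurrence (>= 5\% of samples in a batch or >= 5 independent
#' samples); (10) indel length >= 15 bp; (11) VAF >= 0.4 putative germline;
#' (12) synonymous impact (only when configured); (13) no human-homologous
#' reference position (only when configured).
#'
#' @param tab data.frame with the columns named in the details; missing
#'   columns raise an error naming the column and filter.
#' @param config a [duplex_filter_config].
#' @return list with `pass` (logical), `first_fail`, `counts`, and the
#'   filtered table `variants`.
#' @export
filter_duplex_variants <- function(tab, config = duplex_filter_config()) {
  filters <- c("quality_flag", "read_support", "mismatches", "end_repair",
               "read_position", "oxidative", "coverage", "strand_bias",
               "recurrence", "indel_length", "high_vaf", "impact",
               "homolog")
  need <- .duplex_required
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("missing column '%s' (needed by the %s filter)",
                 miss[1], .column_filter(miss[1])))
  n <- nrow(tab)
  fail <- matrix(FALSE, n, length(filters),
                 dimnames = list(NULL, filters))
  fail[, "quality_flag"] <- tab$flag != "PASS"
  fail[, "read_support"] <- tab$supporting_reads < config$min_reads
  fail[, "mismatches"] <- tab$mean_mismatches > config$max_mismatches
  fail[, "end_repair"] <- tab$end_repair_prob > config$end_repair_max
  fail[, "read_position"] <- tab$min_read_end_dist <= config$min_end_dist
  fail[, "oxidative"] <- as.logical(tab$is_oxidative)
  fail[, "coverage"] <- tab$depth <= config$min_depth
  sb <- rep(FALSE, n)
  for (i in seq_len(n)) {
    m <- matrix(c(tab$fwd_mut[i], tab$rev_mut[i],
                  tab$fwd_wt[i], tab$rev_wt[i]), nrow = 2)
    if (any(is.na(m)) || sum(m[, 1]) == 0) next
    sb[i] <- stats::fisher.test(m)$p.value < config$strand_p
  }
  fail[, "strand_bias"] <- sb
  # recurrence across the table: per variant key, per batch and overall
  key <- paste(tab$locus, tab$ref, tab$alt)
  n_samples_batch <- tapply(tab$sample_id, tab$batch_id,
                            function(x) length(unique(x)))
  if (!is.null(config$batch_sizes)) {
    shared <- intersect(names(n_samples_batch), names(config$batch_sizes))
    n_samples_batch[shared] <- pmax(n_samples_batch[shared],
                                    config$batch_sizes[shared])
  }
  rec <- rep(FALSE, n)
  for (k in unique(key)) {
    idx <- which(key == k)
    n_ind <- length(unique(tab$sample_id[idx]))
    hit <- n_ind >= config$recur_n
    if (!hit) {
      for (b in unique(tab$batch_id[idx])) {
        nb <- length(unique(tab$sample_id[idx][tab$batch_id[idx] == b]))
        if (nb / n_samples_batch[[b]] >= config$recur_frac) hit <- TRUE
      }
    }
    rec[idx] <- hit
  }
  fail[, "recurrence"] <- rec
  fail[, "indel_length"] <- !is.na(tab$indel_len) &
    tab$indel_len >= config$max_indel_len
  fail[, "high_vaf"] <- tab$vaf >= config$max_vaf
  if (config$drop_synonymous)
    fail[, "impact"] <- tab$class %in% c("synonymous", "intronic")
  if (config$require_homolog)
    fail[, "homolog"] <- !as.logical(tab$human_homolog)

  first <- apply(fail, 1, function(z) {
    w <- which(z)
    if (length(w)) filters[w[1]] else NA_character_
  })
  pass <- is.na(first)
  counts <- stats::setNames(
    vapply(filters, function(f) sum(first == f, na.rm = TRUE), integer(1)),
    filters)
  list(pass = pass, first_fail = first, counts = counts,
       variants = tab[pass, , drop = FALSE])
}

.column_filter <- function(col) {
  switch(col,
         flag = "quality_flag", supporting_reads = "read_support",
         mean_mismatches = "mismatches", end_repair_prob = "end_repair",
         min_read_end_dist = "read_position", is_oxidative = "oxidative",
         depth = "coverage", fwd_mut = , rev_mut = , fwd_wt = ,
         rev_wt = "strand_bias", sample_id = , batch_id = ,
         locus = , ref = , alt = "recurrence", indel_len = "indel_length",
         vaf = "high_vaf", class = "impact", human_homolog = "homolog",
         "input")
}
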
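#' Beta-binomial overdispersion of a site across colonies
#'
#' Maximum-likelihood estimate of the beta-binomial overdispersion `rho`
#' for one site's mutant read counts across colonies, with the mean fixed
#' at the aggregate VAF. True clonal variants are present near VAF 0.5 in
#' some colonies and absent in others (high `rho`); cross-colony artefacts
#' sit at low VAF everywhere (low `rho`). Deterministic: dense log-grid
#' search over rho in [1e-6, 0.89] refined by golden-section optimization.
#'
#' @param nv mutant read counts per colony.
#' @param nr total depths per colony.
#' @return ML estimate of `rho` in (0, 1); `NA` (with attribute `reason`)
#'   when no colony has coverage or no mutant read exists.
#' @export
betabinom_overdispersion <- function(nv, nr) {
  keep <- nr > 0
  nv <- nv[keep]; nr <- nr[keep]
  if (length(nv) < 2)
    return(structure(NA_real_, reason = "fewer than 2 covered colonies"))
  m <- sum(nv) / sum(nr)
  if (m <= 0 || m >= 1)
    return(structure(NA_real_, reason = "degenerate aggregate VAF"))
  nll <- function(rho) -sum(.dbetabinom_log(nv, nr, m, rho))
  grid <- exp(seq(log(1e-6), log(0.89), length.out = 100))
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(nll, lower = lo, upper = hi, tol = 1e-8)
  if (opt$objective <= vals[i]) opt$minimum else grid[i]
}

# beta-binomial log density with (mean, overdispersion) parameterization
.dbetabinom_log <- function(x, size, m, rho) {
  a <- m * (1 - rho) / rho
  b <- (1 - m) * (1 - rho) / rho
  lchoose(size, x) + lbeta(x + a, size - x + b) - lbeta(a, b)
}

#' Default colony-filter configuration
#'
#' Cutoffs for the nine colony-WGS somatic variant filters.
#'
#' @param colony_count_threshold samples with more colonies use the
#'   stricter beta-binomial cutoffs (default 25).
#' @param rho_snv,rho_indel,rho_small beta-binomial cutoffs: SNV/indel for
#'   large samples, common cutoff for small samples.
#' @param strand_p,strand_frac strand-bias binomial test threshold and
#'   unidirectional fraction.
#' @param vaf_p clonal-VAF and germline binomial test threshold.
#' @param germline_vaf germline reference VAF.
#' @param hp_min homopolymer run length triggering exclusion.
#' @param indel_prox_bp,cluster_bp proximity windows.
#' @param min_depth,missing_frac missing-site rule: depth below `min_depth`
#'   in more than `missing_frac` of colonies.
#' @param present_vaf,present_min_depth depth-aware genotyping rule used to
#'   call a colony mutant.
#' @export
colony_filter_config <- function(colony_count_threshold = 25,
                                 rho_snv = 0.1, rho_indel = 0.15,
                                 rho_small = 0.20,
                                 strand_p = 0.001, strand_frac = 0.8,
                                 vaf_p = 0.001, germline_vaf = 0.45,
                                 hp_min = 5, indel_prox_bp = 10,
                                 cluster_bp = 10, min_depth = 6,
                                 missing_frac = 1 / 3,
                                 present_vaf = 0.3, present_min_depth = 6) {
  as.list(environment())
}

#' Genotype calls from a colony matrix
#'
#' Depth-aware Present/Absent/Unknown calls: Unknown below
#' `present_min_depth`; Present when VAF >= `present_vaf`.
#'
#' @param cm a [colony_matrix].
#' @param config a [colony_filter_config].
#' @return character matrix "P"/"A"/"U", sites x colonies.
#' @export
genotype_calls <- function(cm, config = colony_filter_config()) {
  vaf <- cm$NV / pmax(cm$NR, 1)
  calls <- ifelse(cm$NR < config$present_min_depth, "U",
                  ifelse(vaf >= config$present_vaf, "P", "A"))
  dimnames(calls) <- dimnames(cm$NR)
  calls
}

#' Somatic variant filters for colony WGS
#'
#' Applies the nine quality-control filters for pooled colony data in
#' order: (1) adjacent homopolymer run; (2) mutant-read strand bias
#' (two-sided binomial P < 0.001 and > 80\% unidirectional); (3)
#' beta-binomial overdispersion (`rho` below the class- and sample-size-
#' specific cutoff); (4) VAF filters (carrier VAF significantly below the
#' clonal expectation; VAF below half the median of beta-binomial-passing
#' variants); (5) germline (aggregate VAF not significantly below 0.45);
#' (6) SNV within 10 bp of an indel; (7) missing site (coverage < 6x in
#' over one-third of colonies); (8) clustered sites within 10 bp; (9)
#' non-variable sites (mutant or wild type in every colony). Each site is
#' assigned its first failing filter.
#'
#' @param cm a [colony_matrix].
#' @param config a [colony_filter_config].
#' @return list with `pass` (logical per site), `first_fail` (name of the
#'   first failing filter or NA), `counts` (per-filter attrition),
#'   `rho` (per-site overdispersion).
#' @export
filter_colony_variants <- function(cm, config = colony_filter_config()) {
  n_sites <- nrow(cm$sites)
  filters <- c("homopolymer", "strand_bias", "beta_binomial", "vaf",
               "germline", "indel_proximity", "missing_site", "clustered",
               "non_variable")
  if (n_sites == 0) {
    return(list(pass = logical(0), first_fail = character(0),
                counts = stats::setNames(integer(length(filters)), filters),
                rho = numeric(0)))
  }
  n_col <- length(cm$colonies)
  sites <- cm$sites
  fail <- matrix(FALSE, n_sites, length(filters),
                 dimnames = list(sites$id, filters))

  # (1) homopolymer
  fail[, "homopolymer"] <- sites$hp_len >= config$hp_min

  # (2) strand bias: aggregate mutant-forward vs mutant reads
  M <- rowSums(cm$NV)
  Fw <- rowSums(cm$NF)
  sb <- rep(FALSE, n_sites)
  for (i in which(M > 0 & !is.na(Fw))) {
    fr <- Fw[i] / M[i]
    if (max(fr, 1 - fr) > config$strand_frac) {
      p <- stats::binom.test(Fw[i], M[i], 0.5)$p.value
      sb[i] <- p < config$strand_p
    }
  }
  fail[, "strand_bias"] <- sb

  # (3) beta-binomial overdispersion
  rho <- vapply(seq_len(n_sites), function(i)
    as.numeric(betabinom_overdispersion(cm$NV[i, ], cm$NR[i, ])),
    numeric(1))
  big <- n_col > config$colony_count_threshold
  cutoff <- if (big)
    ifelse(sites$class == "indel", config$rho_indel, config$rho_snv)
  else rep(config$rho_small, n_sites)
  fail[, "beta_binomial"] <- !is.na(rho) & rho < cutoff
  fail[is.na(rho), "beta_binomial"] <- TRUE  # uncallable sites

  # (4) VAF filters (clonal-VAF test among carriers; half-median rule
  # relative to beta-binomial-passing variants)
  calls <- genotype_calls(cm, config)
  carrier_vaf <- rep(NA_real_, n_sites)
  low_clonal <- rep(FALSE, n_sites)
  for (i in seq_len(n_sites)) {
    cc <- calls[i, ] == "P"
    if (!any(cc)) next
    nv <- sum(cm$NV[i, cc]); nr <- sum(cm$NR[i, cc])
    carrier_vaf[i] <- nv / max(nr, 1)
    if (nr > 0)
      low_clonal[i] <- stats::binom.test(nv, nr, 0.5,
                                         alternative = "less")$p.value <
        config$vaf_p
  }
  bb_pass <- !fail[, "beta_binomial"]
  med <- stats::median(carrier_vaf[bb_pass], na.rm = TRUE)
  low_half <- !is.na(carrier_vaf) & !is.na(med) & carrier_vaf < med / 2
  fail[, "vaf"] <- low_clonal | low_half

  # (5) germline: aggregate VAF not significantly below 0.45
  agg_nv <- rowSums(cm$NV); agg_nr <- rowSums(cm$NR)
  germ <- rep(FALSE, n_sites)
  for (i in which(agg_nr > 0)) {
    p <- stats::binom.test(agg_nv[i], agg_nr[i], config$germline_vaf,
                           alternative = "less")$p.value
    germ[i] <- p >= config$vaf_p
  }
  fail[, "germline"] <- germ

  # (6) SNV within 10 bp of an indel
  is_indel <- sites$class == "indel"
  if (any(is_indel)) {
    for (i in which(sites$class == "SNV")) {
      d <- abs(sites$pos[is_indel] - sites$pos[i])
      same <- sites$chrom[is_indel] == sites$chrom[i]
      fail[i, "indel_proximity"] <- any(same & d <= config$indel_prox_bp)
    }
  }

  # (7) missing site
  fail[, "missing_site"] <-
    rowMeans(cm$NR < config$min_depth) > config$missing_frac

  # (8) clustered sites (same class) within 10 bp
  for (cls in unique(sites$class)) {
    idx <- which(sites$class == cls)
    if (length(idx) < 2) next
    o <- idx[order(sites$chrom[idx], sites$pos[idx])]
    d_prev <- c(Inf, ifelse(sites$chrom[o][-1] == sites$chrom[o][-length(o)],
                            diff(sites$pos[o]), Inf))
    d_next <- c(d_prev[-1], Inf)
    fail[o, "clustered"] <- pmin(d_prev, d_next) <= config$cluster_bp
  }

  # (9) non-variable sites
  n_p <- rowSums(calls == "P")
  n_a <- rowSums(calls == "A")
  fail[, "non_variable"] <- (n_p == 0) | (n_a == 0)

  first <- apply(fail, 1, function(z) {
    w <- which(z)
    if (length(w)) filters[w[1]] else NA_character_
  })
  pass <- is.na(first)
  counts <- stats::setNames(
    vapply(filters, function(f) sum(first == f, na.rm = TRUE), integer(1)),
    filters)
  list(pass = pass, first_fail = first, counts = counts, rho = rho)
}

#' Colony quality control
#'
#' Excludes colonies whose passing-variant mean VAF is below 0.4 and
#' colonies with evidence of non-clonality, operationalized as the mode of
#' the passing-variant VAF kernel density (bandwidth 0.05) falling below
#' 0.35. Colonies with no passing variants are excluded with a distinct
#' reason.
#'
#' @param cm a [colony_matrix].
#' @param pass logical per site (from [filter_colony_variants]); defaults
#'   to all sites.
#' @param config a [colony_filter_config].
#' @param mean_vaf_min exclusion threshold on mean VAF (exclusive).
#' @param mode_min non-clonality threshold on the VAF density mode.
#' @return data.frame per colony: `colony`, `mean_vaf`, `vaf_mode`,
#'   `excluded`, `reason`.
#' @export
qc_colonies <- function(cm, pass = rep(TRUE, nrow(cm$sites)),
                        config = colony_filter_config(),
                        mean_vaf_min = 0.4, mode_min = 0.35) {
  calls <- genotype_calls(cm, config)
  out <- lapply(seq_along(cm$colonies), function(j) {
    idx <- which(pass & calls[, j] == "P" & cm$NR[, j] > 0)
    if (length(idx) == 0)
      return(data.frame(colony = cm$colonies[j], mean_vaf = NA_real_,
                        vaf_mode = NA_real_, excluded = TRUE,
                        reason = "no_variants"))
    v <- cm$NV[idx, j] / cm$NR[idx, j]
    mv <- mean(v)
    vm <- if (length(v) >= 2) {
      d <- stats::density(v, bw = 0.05, from = 0, to = 1)
      d$x[which.max(d$y)]
    } else v
    excl <- mv < mean_vaf_min || vm < mode_min
    reason <- if (mv < mean_vaf_min) "low_mean_vaf"
    else if (vm < mode_min) "non_clonal" else NA_character_
    data.frame(colony = cm$colonies[j], mean_vaf = mv, vaf_mode = vm,
               excluded = excl, reason = reason)
  })
  do.call(rbind, out)
}
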
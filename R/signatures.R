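#' Canonical 96-channel trinucleotide mutation contexts
#'
#' Pyrimidine-centric convention: 6 substitution classes (C>A, C>G, C>T,
#' T>A, T>C, T>G) x 4 5' x 4 3' flanking bases, ordered by substitution
#' class, then 5' base, then 3' base (e.g. "A[C>A]A", "A[C>A]C", ...).
#'
#' @return character vector of 96 channel names.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (f5 in bases) for (f3 in bases)
    out <- c(out, paste0(f5, "[", s, "]", f3))
  out
}

# 32 trinucleotide contexts underlying the 96 channels (pyrimidine-centric)
.context_of_channel <- function(channels = sbs_channels()) {
  paste0(substr(channels, 1, 1), substr(channels, 3, 3),
         substr(channels, 7, 7))
}

#' Synthetic stand-in signature catalogue (SBS1/SBS5/SBS18-like)
#'
#' Builds a three-signature catalogue with the qualitative character of the
#' processes active in mouse blood: a deamination-like signature
#' concentrated on C>T at NCG contexts (SBS1-like), a flat clock-like
#' signature (SBS5-like) and a C>A-dominated oxidative-damage signature
#' (SBS18-like). These are synthetic stand-ins constructed in code, not the
#' COSMIC reference vectors; all attribution machinery is
#' catalogue-agnostic, so reference catalogues can be supplied instead.
#'
#' @return 96 x 3 matrix with columns SBS1, SBS5, SBS18; each column sums
#'   to 1.
#' @export
sbs_catalog_synthetic <- function() {
  ch <- sbs_channels()
  sub <- substr(ch, 3, 5)
  f3 <- substr(ch, 7, 7)
  sbs1 <- ifelse(sub == "C>T" & f3 == "G", 1, 0.002)
  sbs5 <- rep(1, 96) + 0.3 * (sub %in% c("C>T", "T>C"))
  sbs18 <- ifelse(sub == "C>A", 1, 0.01)
  cat <- cbind(SBS1 = sbs1 / sum(sbs1), SBS5 = sbs5 / sum(sbs5),
               SBS18 = sbs18 / sum(sbs18))
  rownames(cat) <- ch
  cat
}

#' Adjust a signature catalogue for trinucleotide opportunities
#'
#' Rescales each channel by the ratio of target to reference trinucleotide
#' frequencies (e.g. mouse over human genome composition) and renormalizes
#' each signature to sum to 1.
#'
#' @param catalog 96 x K signature matrix.
#' @param ref_freq,target_freq named vectors of 32 pyrimidine-centric
#'   trinucleotide frequencies.
#' @return adjusted catalogue.
#' @export
adjust_for_opportunities <- function(catalog, ref_freq, target_freq) {
  ctx <- .context_of_channel(rownames(catalog))
  if (any(ref_freq <= 0)) stop("reference trinucleotide frequency of zero")
  ratio <- target_freq[ctx] / ref_freq[ctx]
  if (any(is.na(ratio))) stop("missing trinucleotide frequency")
  adj <- catalog * as.numeric(ratio)
  sweep(adj, 2, colSums(adj), "/")
}

#' Per-mutation signature membership posterior
#'
#' Bayes attribution of a single mutation to the catalogue signatures:
#' `posterior_k ~ catalog[channel, k] * prior_k`, normalized over
#' signatures.
#'
#' @param channel channel name (or index) of the mutation.
#' @param prior prior attribution probabilities per signature (sums to 1),
#'   e.g. the category-level attribution of the mutation's private/shared
#'   pool.
#' @param catalog 96 x K signature matrix.
#' @return posterior vector over signatures.
#' @export
mutation_posterior <- function(channel, prior, catalog) {
  stopifnot(abs(sum(prior) - 1) < 1e-8,
            length(prior) == ncol(catalog))
  lik <- catalog[channel, ]
  w <- lik * prior
  if (sum(w) == 0) {
    warning("channel has zero mass in every signature; posterior undefined")
    return(rep(NA_real_, ncol(catalog)))
  }
  w / sum(w)
}

#' Branch-level signature attribution
#'
#' Averages the per-mutation signature membership posteriors over all SNVs
#' assigned to a branch. Mutations carry the prior of their category
#' (private or shared pool).
#'
#' @param channels channel names of the branch's mutations.
#' @param priors matrix (mutations x signatures) or single prior vector.
#' @param catalog 96 x K signature matrix.
#' @return attribution proportions over signatures (sums to 1).
#' @export
branch_attribution <- function(channels, priors, catalog) {
  if (length(channels) == 0) {
    warning("empty branch; attribution undefined")
    return(rep(NA_real_, ncol(catalog)))
  }
  if (is.null(dim(priors)))
    priors <- matrix(priors, length(channels), length(priors), byrow = TRUE)
  post <- t(vapply(seq_along(channels), function(i)
    mutation_posterior(channels[i], priors[i, ], catalog),
    numeric(ncol(catalog))))
  colMeans(post)
}

#' Signature-specific burden accumulation rate
#'
#' Fits the mixed model `burden_signature ~ age + (0 + age | animal)` per
#' signature by delegating to [fit_burden_rate].
#'
#' @param burdens matrix (colonies x signatures) of signature-attributed
#'   burdens.
#' @param age,animal per-colony age and animal id.
#' @return list of [fit_burden_rate] results, one per signature.
#' @export
signature_burden_rate <- function(burdens, age, animal) {
  stopifnot(nrow(burdens) == length(age))
  out <- lapply(colnames(burdens), function(s)
    fit_burden_rate(burdens[, s], age, animal))
  names(out) <- colnames(burdens)
  out
}
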
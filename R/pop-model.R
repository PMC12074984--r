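#' Bounded birth-death population model
#'
#' Defines the generative model for the haematopoietic stem/progenitor pool:
#' a linear birth-death process with per-epoch symmetric division rate
#' `lambda`, exit (death or differentiation) rate `nu`, and a hard upper
#' bound `cap` on population size. While the population sits at the cap,
#' further divisions are suppressed. Two epochs are used throughout: an
#' embryonic/early growth epoch ending at 10 weeks post-conception and an
#' adult epoch.
#'
#' @param epochs data.frame with columns `duration` (weeks), `lambda`
#'   (symmetric divisions per cell per week), `nu` (exits per cell per
#'   week) and `cap` (maximum cell count). Epochs run consecutively from
#'   conception; the last epoch is extended as needed.
#' @param mutations_per_division mean of the Poisson number of somatic
#'   mutations acquired by each daughter cell at a division (default 1.8).
#' @return an object of class `pop_model`.
#' @examples
#' m <- pop_model(epochs = data.frame(duration = c(10, 120),
#'                                    lambda = c(1.5, 0.16),
#'                                    nu = c(0, 0.05),
#'                                    cap = c(7e4, 7e4)))
#' @export
pop_model <- function(epochs, mutations_per_division = 1.8) {
  stopifnot(is.data.frame(epochs),
            all(c("duration", "lambda", "nu", "cap") %in% names(epochs)))
  if (any(epochs$duration <= 0)) stop("epoch durations must be positive")
  if (any(epochs$lambda < 0) || any(epochs$nu < 0))
    stop("rates must be non-negative")
  if (any(epochs$nu > epochs$lambda))
    stop("nu must not exceed lambda (net growth is non-negative)")
  if (any(epochs$cap < 1)) stop("cap must be at least 1 cell")
  if (mutations_per_division < 0)
    stop("mutations_per_division must be non-negative")
  structure(list(epochs = epochs,
                 mutations_per_division = mutations_per_division),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Bounded birth-death population model\n")
  cat(sprintf("  %d epoch(s); mutations per division %.3g\n",
              nrow(x$epochs), x$mutations_per_division))
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' Heritable cell-state transition parameters
#'
#' Per-mutation transition probabilities of the three-state (EMB/HSC/MPP)
#' cell-identity chain used both to simulate state evolution down a
#' phylogeny and as the parameter set of the hidden Markov tree model.
#' The chain takes one step per somatic mutation of molecular time; the
#' root state is EMB and is locked for the first `emb_lock` mutations.
#'
#' @param p_emb_to_hsc,p_emb_to_mpp,p_hsc_to_mpp,p_mpp_to_hsc per-mutation
#'   transition probabilities.
#' @param emb_lock number of mutations of molecular time during which the
#'   lineage is held in the EMB state (default 10).
#' @param epsilon phenotyping error used as the tip emission error of the
#'   hidden Markov tree (default 1e-12, near error-free sorting).
#' @return an object of class `state_params`.
#' @export
state_params <- function(p_emb_to_hsc = 0.01, p_emb_to_mpp = 0.01,
                         p_hsc_to_mpp = 0.002, p_mpp_to_hsc = 0.002,
                         emb_lock = 10, epsilon = 1e-12) {
  p <- c(p_emb_to_hsc, p_emb_to_mpp, p_hsc_to_mpp, p_mpp_to_hsc)
  if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
  if (p_emb_to_hsc + p_emb_to_mpp > 1)
    stop("p_emb_to_hsc + p_emb_to_mpp must not exceed 1")
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  structure(list(p_emb_to_hsc = p_emb_to_hsc, p_emb_to_mpp = p_emb_to_mpp,
                 p_hsc_to_mpp = p_hsc_to_mpp, p_mpp_to_hsc = p_mpp_to_hsc,
                 emb_lock = emb_lock, epsilon = epsilon),
            class = "state_params")
}

#' @export
print.state_params <- function(x, ...) {
  cat("EMB/HSC/MPP per-mutation transition parameters\n")
  cat(sprintf("  EMB->HSC %.4g  EMB->MPP %.4g  HSC->MPP %.4g  MPP->HSC %.4g\n",
              x$p_emb_to_hsc, x$p_emb_to_mpp, x$p_hsc_to_mpp, x$p_mpp_to_hsc))
  cat(sprintf("  EMB lock %d mutations, emission error %.3g\n",
              x$emb_lock, x$epsilon))
  invisible(x)
}

.states <- c("EMB", "HSC", "MPP")

#' Single-step transition matrix of the cell-identity chain
#'
#' Rows and columns are ordered EMB, HSC, MPP. EMB may transition to HSC or
#' MPP; HSC and MPP may interconvert; nothing returns to EMB.
#'
#' @param params a [state_params] object.
#' @return a 3x3 row-stochastic matrix.
#' @export
transition_matrix <- function(params) {
  M <- matrix(c(
    1 - params$p_emb_to_hsc - params$p_emb_to_mpp,
    params$p_emb_to_hsc, params$p_emb_to_mpp,
    0, 1 - params$p_hsc_to_mpp, params$p_hsc_to_mpp,
    0, params$p_mpp_to_hsc, 1 - params$p_mpp_to_hsc),
    nrow = 3, byrow = TRUE, dimnames = list(.states, .states))
  M
}
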
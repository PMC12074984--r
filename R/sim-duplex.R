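#' Simulate a duplex VAF spectrum under the branching-process model
#'
#' Variants arise in a stem cell population of `N = N_tau * lambda_year`
#' cells at rate `mu * N` per year (`mu` is the aggregate panel rate per
#' cell per year), uniformly over the cohort age. Each variant founds a
#' clone evolving as a linear birth-death process (wild-type turnover
#' `lambda_year` each way; a fitness effect `s` adds to the birth rate), and
#' its size at sampling is drawn from the exact transition law of that
#' process. The VAF of a clone of size `n` among `N` host cells is
#' `n / (2 (N + n))`. VAFs below `vaf_floor` are censored.
#'
#' Selected variants draw `s` (annual growth rate) from the exponential
#' power distribution of fitness effects `p(s) ~ exp(-(s/d)^beta)` on
#' (0, s_max].
#'
#' @param N_tau population size over division rate, HSC-years.
#' @param mu_neutral,mu_selected aggregate arrival rates (per cell per
#'   year) of neutral and selected variants.
#' @param dfe_scale,dfe_shape exponential-power DFE scale `d` and shape
#'   `beta` (default 3).
#' @param age_t cohort age in years.
#' @param vaf_floor detection floor (default 5e-5).
#' @param lambda_year symmetric division rate per year (default one
#'   division per 6.4 weeks).
#' @param s_max upper truncation of the DFE (per year).
#' @param seed integer seed.
#' @return data.frame of class `vaf_spectrum`: `vaf`, `class`
#'   ("synonymous" for neutral, "non-synonymous" for selected), `s`
#'   (true fitness), with attributes `age_t` and `vaf_floor`.
#' @export
simulate_duplex_vafs <- function(N_tau, mu_neutral, mu_selected = 0,
                                 dfe_scale = 2, dfe_shape = 3,
                                 age_t = 2, vaf_floor = 5e-5,
                                 lambda_year = 52.18 / 6.4, s_max = 4,
                                 seed = NULL) {
  stopifnot(N_tau > 0, mu_neutral >= 0, mu_selected >= 0, age_t > 0)
  if (!is.null(seed)) set.seed(seed)
  N <- N_tau * lambda_year
  sim_class <- function(mu, selected) {
    n_arr <- stats::rpois(1, mu * N * age_t)
    if (n_arr == 0)
      return(data.frame(vaf = numeric(0), class = character(0),
                        s = numeric(0)))
    a <- age_t - stats::runif(n_arr, 0, age_t)   # clone age at sampling
    s <- if (selected) .rdfe(n_arr, dfe_scale, dfe_shape, s_max)
    else rep(0, n_arr)
    size <- .rbd_size(n_arr, birth = lambda_year + s, death = lambda_year,
                      a = a)
    keep <- size > 0
    vaf <- size[keep] / (2 * (N + size[keep]))
    data.frame(vaf = vaf,
               class = if (selected) "non-synonymous" else "synonymous",
               s = s[keep])
  }
  out <- rbind(sim_class(mu_neutral, FALSE),
               if (mu_selected > 0) sim_class(mu_selected, TRUE))
  out <- out[out$vaf >= vaf_floor, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "age_t") <- age_t
  attr(out, "vaf_floor") <- vaf_floor
  class(out) <- c("vaf_spectrum", "data.frame")
  out
}

# exact size law of a linear birth-death process started from one cell
.rbd_size <- function(n, birth, death, a) {
  birth <- rep_len(birth, n); a <- rep_len(a, n)
  r <- birth - death
  crit <- abs(r) < 1e-12
  alpha <- beta <- numeric(n)
  # subcritical/supercritical
  i <- !crit
  if (any(i)) {
    er <- exp(r[i] * a[i])
    alpha[i] <- death * (er - 1) / (birth[i] * er - death)
    beta[i] <- birth[i] * alpha[i] / death
  }
  if (any(crit)) {
    ba <- birth[crit] * a[crit]
    alpha[crit] <- beta[crit] <- ba / (1 + ba)
  }
  size <- integer(n)
  surv <- stats::runif(n) >= alpha
  size[surv] <- stats::rgeom(sum(surv), 1 - beta[surv]) + 1L
  size
}

# draw from p(s) ~ exp(-(s/d)^beta) on (0, s_max] by rejection
.rdfe <- function(n, d, beta, s_max) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 16L)
    s <- stats::runif(m, 0, s_max)
    acc <- stats::runif(m) < exp(-(s / d)^beta)
    out <- c(out, s[acc])
  }
  out[seq_len(n)]
}

#' Assemble a VAF spectrum from observed variants
#'
#' @param vaf variant allele fractions.
#' @param class consequence class; anything matching "synonymous" or
#'   "intronic" is treated as neutral.
#' @param age_t cohort age in years.
#' @param vaf_floor detection floor.
#' @return a `vaf_spectrum` data.frame.
#' @export
vaf_spectrum <- function(vaf, class, age_t, vaf_floor = 5e-5) {
  stopifnot(length(vaf) == length(class), age_t > 0)
  out <- data.frame(vaf = vaf, class = class, s = NA_real_)
  out <- out[out$vaf >= vaf_floor, , drop = FALSE]
  attr(out, "age_t") <- age_t
  attr(out, "vaf_floor") <- vaf_floor
  class(out) <- c("vaf_spectrum", "data.frame")
  out
}
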
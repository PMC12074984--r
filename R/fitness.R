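#' Branching-process density of variants over log VAF
#'
#' Expected density of variants at `l = log(VAF)` under the continuous-time
#' branching model of stem cell clonal dynamics:
#' `rho(l) = theta / (1 - 2 e^l) * exp(-e^l / (phi (1 - 2 e^l)))`,
#' where `theta = N tau mu` sets the level and `phi` the typical maximum
#' VAF a variant can reach.
#'
#' @param l log(VAF), must be below `log(0.5)`.
#' @param theta intensity parameter `N tau mu`.
#' @param phi cutoff VAF (see [phi_from_params]).
#' @return density values (per unit `l`).
#' @export
log_vaf_density <- function(l, theta, phi) {
  stopifnot(theta > 0, phi > 0)
  if (any(l >= log(0.5))) stop("l must be below log(0.5)")
  x <- exp(l)
  theta / (1 - 2 * x) * exp(-x / (phi * (1 - 2 * x)))
}

#' Cutoff VAF phi as a function of fitness, age and population
#'
#' `phi = (e^{s t} - 1) / (2 N tau s)`, with the continuous neutral limit
#' `phi = t / (2 N tau)` at `s = 0`.
#'
#' @param s annual fitness effect (growth per year); 0 for neutral.
#' @param t age in years.
#' @param N_tau population size over division rate, HSC-years.
#' @export
phi_from_params <- function(s, t, N_tau) {
  stopifnot(N_tau > 0, t > 0)
  ifelse(abs(s * t) < 1e-9,
         t / (2 * N_tau) * (1 + s * t / 2),
         (exp(s * t) - 1) / (2 * N_tau * s))
}

# neutral consequence classes: synonymous or intronic, but not
# "non-synonymous"
.is_neutral_class <- function(class) {
  grepl("intronic", class, ignore.case = TRUE) |
    (grepl("synonymous", class, ignore.case = TRUE) &
       !grepl("^non[-_ ]?syn", class, ignore.case = TRUE))
}

# expected count of variants with log-VAF in [l0, l1)
.rho_integral <- function(l0, l1, theta, phi) {
  l1 <- min(l1, log(0.5) - 1e-12)
  if (l0 >= l1) return(0)
  stats::integrate(log_vaf_density, l0, l1, theta = theta, phi = phi,
                   rel.tol = 1e-9)$value
}

#' Doane's rule for histogram bin count
#'
#' `k = 1 + log2(n) + log2(1 + |g1| / sigma_g1)` rounded up, where `g1` is
#' the sample skewness.
#'
#' @param x data vector.
#' @return integer bin count.
#' @export
doane_bins <- function(x) {
  n <- length(x)
  if (n < 3) return(max(1L, n))
  m <- mean(x); s <- stats::sd(x)
  g1 <- mean((x - m)^3) / (mean((x - m)^2)^1.5)
  sg <- sqrt(6 * (n - 2) / ((n + 1) * (n + 3)))
  as.integer(ceiling(1 + log2(n) + log2(1 + abs(g1) / sg)))
}

# Doane-binned reverse-cumulative intensity of log VAFs
.binned_reverse_cum <- function(l, l_floor) {
  k <- doane_bins(l)
  edges <- seq(l_floor, max(l) + 1e-9, length.out = k + 1)
  lower <- edges[-length(edges)]
  counts <- vapply(lower, function(e) sum(l >= e), numeric(1))
  list(edges = edges, lower = lower, rev_cum = counts)
}

#' Fit the neutral branching-process parameters to a VAF spectrum
#'
#' Maximum-likelihood style fit of `(theta, phi)` to the synonymous /
#' intronic (neutral) variants: log VAFs are binned by Doane's rule and the
#' L2 norm between the observed and predicted log reverse-cumulative
#' densities is minimized over a log-scale grid refined by Nelder-Mead.
#' `N tau = t / (2 phi)` and `mu = theta / (N tau)` follow.
#'
#' @param spectrum a `vaf_spectrum`.
#' @param min_variants minimum neutral variant count (default 30).
#' @return list with `theta`, `phi`, `N_tau` (HSC-years), `mu` (per cell
#'   per year, aggregate panel rate), `objective`, `bins`.
#' @export
fit_neutral <- function(spectrum, min_variants = 30) {
  t_age <- attr(spectrum, "age_t")
  floor_vaf <- attr(spectrum, "vaf_floor")
  neutral <- .is_neutral_class(spectrum$class)
  v <- spectrum$vaf[neutral]
  if (length(v) < min_variants)
    stop(sprintf("only %d neutral variants (need >= %d)",
                 length(v), min_variants))
  l <- log(v)
  bins <- .binned_reverse_cum(l, log(floor_vaf))
  obs <- log(bins$rev_cum)
  use <- bins$rev_cum > 0
  obj <- function(par) {
    theta <- exp(par[1]); phi <- exp(par[2])
    pred <- vapply(bins$lower, function(e)
      .rho_integral(e, log(0.5), theta, phi), numeric(1))
    if (any(pred[use] <= 0)) return(1e10)
    sum((obs[use] - log(pred[use]))^2)
  }
  # coarse grid then local refinement
  th0 <- length(v) / max(.rho_integral(log(floor_vaf), log(0.5), 1,
                                       t_age / (2 * 1e4)), 1e-12)
  grid <- expand.grid(lt = log(th0) + seq(-3, 3, length.out = 7),
                      lp = seq(log(1e-6), log(0.05), length.out = 13))
  vals <- apply(grid, 1, obj)
  st <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(st, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  theta <- exp(fit$par[1]); phi <- exp(fit$par[2])
  N_tau <- t_age / (2 * phi)
  list(theta = theta, phi = phi, N_tau = N_tau, mu = theta / N_tau,
       objective = fit$value, bins = bins, n_variants = length(v),
       age_t = t_age, vaf_floor = floor_vaf)
}

#' Non-synonymous mutation rate with phi fixed from the neutral fit
#'
#' Counts non-synonymous variants in the neutral VAF range (below the
#' maximum synonymous VAF) and solves for `theta_ns` so the model's
#' expected count matches; `mu_ns = theta_ns / N tau`.
#'
#' @param spectrum a `vaf_spectrum`.
#' @param neutral_fit result of [fit_neutral].
#' @param neutral_range_max upper VAF bound of the neutral range (default
#'   1.99e-4, the maximum synonymous VAF).
#' @return list with `theta_ns`, `mu_ns`, `n_variants`.
#' @export
fit_nonsynonymous <- function(spectrum, neutral_fit,
                              neutral_range_max = 1.99e-4) {
  ns <- !.is_neutral_class(spectrum$class)
  v <- spectrum$vaf[ns & spectrum$vaf < neutral_range_max]
  if (length(v) == 0) stop("no non-synonymous variants in the neutral range")
  expected_unit <- .rho_integral(log(neutral_fit$vaf_floor),
                                 log(neutral_range_max), 1, neutral_fit$phi)
  theta_ns <- length(v) / expected_unit
  list(theta_ns = theta_ns, mu_ns = theta_ns / neutral_fit$N_tau,
       n_variants = length(v), neutral_range_max = neutral_range_max)
}

# Gauss-Legendre nodes/weights on [a, b] (Golub-Welsch)
.gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  bdiag <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- bdiag
  J[cbind(i + 1, i)] <- bdiag
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(nodes = (b - a) / 2 * x + (a + b) / 2, weights = (b - a) / 2 * w)
}

#' Fit the distribution of fitness effects to the non-synonymous spectrum
#'
#' Mixture model over log VAF: a fraction `1 - f` of non-synonymous
#' variants are neutral (density `rho(l; phi_0)`), and a fraction `f` carry
#' a fitness effect `s` from the exponential power DFE
#' `p(s) ~ exp(-(s/d)^beta)` with `beta = 3` fixed, each contributing
#' `rho(l; phi(s))`. `(f, d)` are fitted by maximum likelihood on the
#' per-variant conditional density over the observed VAF window, with the
#' DFE mixed by Gauss-Legendre quadrature over `s` in (0, 4] per year.
#'
#' @param spectrum a `vaf_spectrum`.
#' @param neutral_fit result of [fit_neutral].
#' @param beta DFE shape (fixed 3).
#' @param s_max quadrature upper limit, per year.
#' @param n_quad quadrature nodes (default 64).
#' @param growth_band annual-growth band for the reported strong-effect
#'   fraction (default 50-200\% per year).
#' @param neutral_range_max upper VAF bound of the neutral range, used only
#'   to report how many variants sit above it.
#' @return list with `d` (scale), `f` (non-neutral fraction of
#'   non-synonymous mutations), `f_ci` (95\% profile interval), `loglik`,
#'   `strong_fraction` (mass of the fitted DFE inside `growth_band` times
#'   `f`), `n_variants`, `n_supra` (variants above the neutral range).
#' @export
fit_dfe <- function(spectrum, neutral_fit, beta = 3, s_max = 4,
                    n_quad = 64, growth_band = c(0.5, 2),
                    neutral_range_max = 1.99e-4) {
  ns <- !.is_neutral_class(spectrum$class)
  l <- log(spectrum$vaf[ns])
  if (length(l) == 0) stop("no non-synonymous variants")
  t_age <- attr(spectrum, "age_t")
  l_floor <- log(attr(spectrum, "vaf_floor"))
  n_supra <- sum(l > log(neutral_range_max))
  gq <- .gauss_legendre(n_quad, 0, s_max)
  phi_s <- phi_from_params(gq$nodes, t_age, neutral_fit$N_tau)
  phi0 <- neutral_fit$phi
  l_top <- log(0.5) - 1e-9
  dens_mat <- vapply(seq_len(n_quad), function(j)
    log_vaf_density(l, 1, phi_s[j]), numeric(length(l)))
  norm_s <- vapply(seq_len(n_quad), function(j)
    .rho_integral(l_floor, l_top, 1, phi_s[j]), numeric(1))
  dens0 <- log_vaf_density(l, 1, phi0)
  norm0 <- .rho_integral(l_floor, l_top, 1, phi0)
  nll <- function(par) {
    f <- stats::plogis(par[1]); d <- exp(par[2])
    w <- exp(-(gq$nodes / d)^beta) * gq$weights
    if (!any(w > 0)) return(1e10)  # DFE mass underflows for tiny d
    w <- w / sum(w)
    mix_dens <- as.numeric(dens_mat %*% w)
    mix_norm <- sum(norm_s * w)
    # per-variant conditional density over the observed window
    dens <- ((1 - f) * dens0 + f * mix_dens) /
      ((1 - f) * norm0 + f * mix_norm)
    if (any(dens <= 0)) return(1e10)
    -sum(log(dens))
  }
  grid <- expand.grid(lf = stats::qlogis(c(0.01, 0.05, 0.12, 0.3, 0.6)),
                      ld = log(c(0.5, 1, 2, 3)))
  vals <- apply(grid, 1, nll)
  st <- as.numeric(grid[which.min(vals), ])
  fit <- stats::optim(st, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  f <- stats::plogis(fit$par[1]); d <- exp(fit$par[2])
  # profile CI on f (likelihood-ratio, chi2 1 df)
  prof <- function(fv) {
    o <- stats::optimize(function(ld) nll(c(stats::qlogis(fv), ld)),
                         lower = log(0.05), upper = log(s_max))
    o$objective
  }
  f_grid <- unique(sort(c(seq(0.001, 0.99, length.out = 40), f)))
  pv <- vapply(f_grid, prof, numeric(1))
  keep <- pv <= fit$value + stats::qchisq(0.95, 1) / 2
  f_ci <- range(f_grid[keep])
  w <- exp(-(gq$nodes / d)^beta) * gq$weights
  w <- w / sum(w)
  band <- gq$nodes >= growth_band[1] & gq$nodes <= growth_band[2]
  list(d = d, f = f, f_ci = f_ci, loglik = -fit$value,
       strong_fraction = f * sum(w[band]), n_variants = length(l),
       n_supra = n_supra, beta = beta)
}

#' Convert an annual growth rate to a per-division selective advantage
#'
#' Geometric compounding at one symmetric self-renewing division every
#' `division_interval` weeks:
#' `s_division = (1 + s_annual)^(interval / 52.18) - 1`.
#'
#' @param s_annual fractional growth per year (2 = 200\%).
#' @param division_interval weeks between symmetric divisions.
#' @export
annual_to_per_division <- function(s_annual, division_interval) {
  stopifnot(all(s_annual > -1), division_interval > 0)
  (1 + s_annual)^(division_interval / 52.18) - 1
}

#' @rdname annual_to_per_division
#' @param s_division per-division selective advantage.
#' @export
per_division_to_annual <- function(s_division, division_interval) {
  stopifnot(all(s_division > -1), division_interval > 0)
  (1 + s_division)^(52.18 / division_interval) - 1
}

#' Drift threshold and clone establishment time
#'
#' The minimal fitness a clone must exceed to outgrow neutral drift is
#' `s* = lambda / N`; a clone of fitness `s` is not established until
#' `t > 1/s` years.
#'
#' @param N population size (cells).
#' @param lambda symmetric division rate, per year.
#' @export
drift_threshold <- function(N, lambda) {
  stopifnot(N > 0, lambda > 0)
  lambda / N
}

#' @rdname drift_threshold
#' @param s annual fitness effect.
#' @export
establishment_time <- function(s) {
  stopifnot(all(s > 0))
  1 / s
}

#' Genome-wide per-base-pair mutation rate
#'
#' @param annual_burden mutations per year (genome-wide).
#' @param genome_bp diploid genome size in bp (default 5.46e9, twice the
#'   2.73 Gb mouse genome).
#' @export
per_bp_rate <- function(annual_burden, genome_bp = 5.46e9) {
  stopifnot(annual_burden >= 0, genome_bp > 0)
  annual_burden / genome_bp
}

#' Rescale a targeted-panel rate to the genome
#'
#' Naive ratio rescaling of a per-panel-bp rate to a genome-wide per-bp
#' rate (the panel rate is already per bp, so the value is unchanged; the
#' helper documents the conversion and returns the implied genome-wide
#' annual burden as an attribute).
#'
#' @param panel_rate mutation rate per bp per year on the panel.
#' @param panel_bp panel footprint (default 61,800 bp).
#' @param genome_bp diploid genome size.
#' @export
scale_panel_rate <- function(panel_rate, panel_bp = 61800,
                             genome_bp = 5.46e9) {
  stopifnot(panel_rate >= 0, panel_bp > 0, genome_bp > 0)
  structure(panel_rate, annual_genome_burden = panel_rate * genome_bp,
            panel_bp = panel_bp)
}
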
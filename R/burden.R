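#' Depth correction of per-colony mutation burdens
#'
#' Colonies sequenced to lower depth detect fewer of their mutations. Per
#' sample, an asymptotic regression `burden = a * (1 - exp(-k * depth))` is
#' fitted across colonies; each colony's corrected burden divides the
#' observed burden by its estimated detection sensitivity
#' `1 - exp(-k * depth)`.
#'
#' @param burden observed mutation counts per colony.
#' @param depth mean sequencing depth per colony.
#' @param sample sample (animal) id per colony; the fit is per sample.
#' @return data.frame with `burden`, `depth`, `sample`, `sensitivity`,
#'   `corrected`; attribute `fits` holds per-sample `(a, k)`.
#' @export
correct_burden_depth <- function(burden, depth, sample = NULL) {
  if (is.null(sample)) sample <- rep("s1", length(burden))
  stopifnot(length(burden) == length(depth), length(depth) == length(sample))
  out <- data.frame(burden = burden, depth = depth, sample = sample,
                    sensitivity = NA_real_, corrected = NA_real_)
  fits <- list()
  for (s in unique(sample)) {
    i <- sample == s
    if (sum(i) < 4) {
      warning(sprintf("sample %s has < 4 colonies; no depth correction", s))
      out$sensitivity[i] <- 1
      out$corrected[i] <- burden[i]
      fits[[s]] <- c(a = NA, k = NA)
      next
    }
    df <- data.frame(y = burden[i], x = depth[i])
    fit <- tryCatch(
      stats::nls(y ~ a * (1 - exp(-k * x)), data = df,
                 start = list(a = max(df$y) * 1.05, k = 0.2),
                 control = stats::nls.control(warnOnly = FALSE)),
      error = function(e) tryCatch(
        stats::nls(y ~ stats::SSasympOrig(x, Asym, lrc), data = df),
        error = function(e2) NULL))
    if (is.null(fit)) {
      warning(sprintf("asymptotic fit failed for sample %s; no correction", s))
      out$sensitivity[i] <- 1
      out$corrected[i] <- burden[i]
      fits[[s]] <- c(a = NA, k = NA)
      next
    }
    cf <- stats::coef(fit)
    a <- if ("a" %in% names(cf)) cf[["a"]] else cf[["Asym"]]
    k <- if ("k" %in% names(cf)) cf[["k"]] else exp(cf[["lrc"]])
    sens <- pmin(pmax(1 - exp(-k * depth[i]), 1e-6), 1)
    out$sensitivity[i] <- sens
    out$corrected[i] <- burden[i] / sens
    fits[[s]] <- c(a = a, k = k)
  }
  attr(out, "fits") <- fits
  out
}

#' Mutation accumulation rate with age (mixed model)
#'
#' Linear mixed-effect model `burden ~ age + (0 + age | animal)`: the fixed
#' slope is the population mutation accumulation rate (mutations per unit
#' age) with a per-animal random slope; the intercept estimates the burden
#' already present at age zero (mutations acquired before birth).
#'
#' @param burden per-colony (depth-corrected) mutation burdens.
#' @param age age per colony, in years unless noted.
#' @param animal animal id per colony.
#' @return list with `slope`, `intercept`, `slope_ci`, `intercept_ci`
#'   (95\% Wald), `model`, and `method` ("lmm" or "lm" fallback for a
#'   single animal).
#' @export
fit_burden_rate <- function(burden, age, animal) {
  stopifnot(length(burden) == length(age), length(age) == length(animal))
  if (length(unique(animal)) < 2) {
    warning("single animal: falling back to ordinary least squares")
    fit <- stats::lm(burden ~ age)
    ci <- stats::confint(fit)
    return(list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                slope_ci = ci["age", ], intercept_ci = ci["(Intercept)", ],
                model = fit, method = "lm"))
  }
  d <- data.frame(burden = burden, age = age, animal = factor(animal))
  fit <- lme4::lmer(burden ~ age + (0 + age | animal), data = d, REML = FALSE)
  b <- lme4::fixef(fit)
  ci <- stats::confint(fit, parm = "beta_", method = "Wald")
  list(slope = unname(b["age"]), intercept = unname(b["(Intercept)"]),
       slope_ci = ci["age", ], intercept_ci = ci["(Intercept)", ],
       model = fit, method = "lmm")
}

#' Extrapolate burden along the fitted age line
#'
#' @param fit result of [fit_burden_rate] (or a list with `slope` and
#'   `intercept`).
#' @param age age(s) at which to predict.
#' @return predicted burden(s).
#' @export
predict_burden <- function(fit, age) fit$intercept + fit$slope * age
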
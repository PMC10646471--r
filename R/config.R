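#' Run configuration for model fitting
#'
#' Collects prior settings, link choice, and MCMC settings.  Priors default
#' to the analysis priors: `alpha ~ half-normal(0, 1)`;
#' `beta, gamma, sigma ~ exponential(1)`;
#' `iota, zeta, eta, theta, xi, tau ~ normal(0, 1)`.  Imputation-regression
#' priors (per trait and sex stratum) are package defaults: intercept
#' `normal(1, 0.5)` for the unit-mean-scaled somatic traits and
#' `normal(0, 1)` for knowledge ability, slope `normal(0, 0.5)` on
#' standardised age, residual sd `exponential(1)`.
#'
#' @param chains number of MCMC chains (>= 2, for split-Rhat diagnostics).
#' @param warmup adaptation iterations discarded per chain.
#' @param iter kept iterations per chain.
#' @param seed integer seed governing all sampling randomness.
#' @param link Poisson rate link for the trap model: `"product"`
#'   (`lambda = alpha * phi * psi`, the default) or `"printed_exp"`
#'   (`lambda = exp(alpha * phi * psi)`, which cannot produce rates below 1
#'   and is retained only for comparison).
#' @param include_traits logical; include the Cobb-Douglas trait exponents
#'   (zeta, eta, theta) and the trait imputation submodel.  `FALSE` gives the
#'   age-only model used for the normalised age curves.
#' @param priors named list overriding individual prior settings; see
#'   `default_priors()`.
#' @return A list of class `forage_config`.
#' @export
forage_config <- function(chains = 4L, warmup = 1000L, iter = 1000L,
                          seed = 1L, link = c("product", "printed_exp"),
                          include_traits = TRUE, priors = list()) {
  link <- match.arg(link)
  p <- utils::modifyList(default_priors(), priors)
  stopifnot(chains >= 2L, warmup >= 1L, iter >= 1L)
  sc <- unlist(p)[grep("scale|rate", names(unlist(p)))]
  if (any(sc <= 0)) stop("all prior scales must be > 0", call. = FALSE)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 link = link, include_traits = include_traits, priors = p),
            class = "forage_config")
}

#' @rdname forage_config
#' @export
default_priors <- function() {
  list(
    alpha = list(dist = "half_normal", scale = 1),
    beta  = list(dist = "exponential", rate = 1),
    gamma = list(dist = "exponential", rate = 1),
    sigma = list(dist = "exponential", rate = 1),
    coef  = list(dist = "normal", scale = 1),   # iota, zeta, eta, theta, xi, tau
    imp_intercept_somatic = list(mean = 1, scale = 0.5),
    imp_intercept_knowledge = list(mean = 0, scale = 1),
    imp_slope = list(mean = 0, scale = 0.5),
    imp_sd = list(dist = "exponential", rate = 1))
}
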
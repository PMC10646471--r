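# The return model.  Individual productivity is
#   phi_i = exp(iota_i) * (1 - exp(-beta * a_i))^gamma * k_i^zeta * h_i^eta * g_i^theta
# and the trip factor is psi = d^xi * exp(t * tau) (shellfish) or d^xi (traps).
# Shellfish person-trip returns are lognormal(log(alpha * phi * psi), sigma);
# trap capture counts are Poisson with rate alpha * phi * psi under the
# default product link.  Knowledge, height and grip enter unit-mean scaled so
# the average individual contributes factor 1 and alpha is interpretable.

#' Saturating age component of individual productivity
#'
#' `(1 - exp(-beta * a))^gamma`: 0 at age 0, strictly increasing in age, and
#' saturating at 1, with `beta` the per-year rate and `gamma` a shape
#' exponent allowing a sigmoidal rise.
#'
#' @param a age in years (>= 0), vectorised.
#' @param beta per-year rate (> 0).
#' @param gamma shape exponent (> 0).
#' @return Values in `[0, 1)`.
#' @examples
#' age_component(10, beta = 0.1, gamma = 2)  # (1 - exp(-1))^2
#' @export
age_component <- function(a, beta, gamma) {
  if (any(a < 0)) stop("age must be >= 0", call. = FALSE)
  if (any(beta <= 0)) stop("beta must be > 0", call. = FALSE)
  if (any(gamma <= 0)) stop("gamma must be > 0", call. = FALSE)
  (-expm1(-beta * a))^gamma
}

# x^e with the production-function boundary convention: 0^positive = 0,
# 0^0 = 1, negative input or 0^negative is a domain error.
pow_trait <- function(x, e, name) {
  if (any(x < 0)) stop("trait '", name, "' must be >= 0", call. = FALSE)
  if (any(x == 0 & e < 0))
    stop("trait '", name, "' is 0 with a negative exponent", call. = FALSE)
  ifelse(x == 0 & e == 0, 1, x^e)
}

#' Individual production factor (Cobb-Douglas)
#'
#' `phi = exp(iota) * age_component(a) * k^zeta * h^eta * g^theta`.  The
#' traits are expected on their unit-mean scale (`k` already exponentiated
#' from the latent ability).  A zero trait with a positive exponent gives
#' `phi = 0`: without any knowledge, height or grip strength, foraging cannot
#' happen.
#'
#' @param a age in years.
#' @param beta,gamma age-component parameters.
#' @param iota individual log random effect (0 for a reference individual).
#' @param k,h,g positive scaled knowledge, height, grip (1 = population mean).
#' @param zeta,eta,theta Cobb-Douglas exponents.
#' @return Non-negative production factor, vectorised over individuals.
#' @export
phi <- function(a, beta, gamma, iota = 0, k = 1, h = 1, g = 1,
                zeta = 0, eta = 0, theta = 0) {
  exp(iota) * age_component(a, beta, gamma) *
    pow_trait(k, zeta, "knowledge") * pow_trait(h, eta, "height") *
    pow_trait(g, theta, "grip")
}

#' Trip factor for shellfish collection
#'
#' `psi = d^xi * exp(t * tau)` where `d` is trip duration scaled by the
#' sample mean and `t` the tide height centred at the sample mean, so the
#' average trip has `psi = 1`.
#'
#' @param d scaled duration (> 0).
#' @param t centred tide height (metres).
#' @param xi duration exponent.
#' @param tau tide coefficient.
#' @return Positive trip factor.
#' @export
psi_shellfish <- function(d, t, xi, tau) {
  if (any(d <= 0)) stop("duration must be > 0", call. = FALSE)
  d^xi * exp(t * tau)
}

#' Trap factor for snare exposure
#'
#' `psi = d^xi` with `d` the exposure in days scaled by the sample mean.
#'
#' @param d scaled exposure (> 0).
#' @param xi exposure exponent.
#' @return Positive trap factor.
#' @export
psi_trap <- function(d, xi) {
  if (any(d <= 0)) stop("exposure must be > 0", call. = FALSE)
  d^xi
}

#' Lognormal log-density of a shellfish return
#'
#' Log-density of `returns_kg ~ lognormal(log(mean_factor), sigma)` where
#' `mean_factor = alpha * phi * psi` is the median return.
#'
#' @param returns_kg observed return (> 0), vectorised.
#' @param mean_factor `alpha * phi * psi` (> 0).
#' @param sigma lognormal scale (> 0).
#' @return Log-density contribution(s).
#' @export
shellfish_logdensity <- function(returns_kg, mean_factor, sigma) {
  if (any(returns_kg <= 0)) stop("returns_kg must be > 0", call. = FALSE)
  if (any(mean_factor <= 0)) stop("mean_factor (alpha*phi*psi) must be > 0", call. = FALSE)
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  stats::dlnorm(returns_kg, meanlog = log(mean_factor), sdlog = sigma, log = TRUE)
}

#' Poisson log-density of a trap capture count
#'
#' Under the default `"product"` link the rate is
#' `lambda = alpha * phi * psi`, which can fall well below 1 as required by
#' sparse capture data.  The `"printed_exp"` link `lambda = exp(alpha*phi*psi)`
#' is retained for comparison; it cannot produce rates below 1 for
#' non-negative `alpha*phi*psi`.
#'
#' @param captures non-negative integer count(s).
#' @param rate_factor `alpha * phi * psi` (>= 0).
#' @param link `"product"` or `"printed_exp"`.
#' @return Log-density contribution(s).
#' @export
trap_logdensity <- function(captures, rate_factor,
                            link = c("product", "printed_exp")) {
  link <- match.arg(link)
  if (any(captures < 0) || any(captures != round(captures)))
    stop("captures must be non-negative integers", call. = FALSE)
  if (any(rate_factor < 0)) stop("rate_factor must be >= 0", call. = FALSE)
  lambda <- if (link == "product") rate_factor else exp(rate_factor)
  stats::dpois(captures, lambda, log = TRUE)
}

#' Trait-imputation log-density
#'
#' Each trait (scaled height, scaled grip, latent knowledge ability) is
#' modelled as normal around a sex-specific linear function of standardised
#' age.  Observed values contribute likelihood; missing values enter as
#' latent parameters whose density is this same term, so every individual
#' carries a trait value into the production function.
#'
#' @param values trait values (observed or current latent values).
#' @param zage standardised ages.
#' @param sex sex stratum of each individual (character).
#' @param coef named list per stratum, each `c(intercept, slope, sd)`.
#' @return Log-density contribution(s), one per individual.
#' @export
imputation_logdensity <- function(values, zage, sex, coef) {
  cf <- t(vapply(sex, function(s) {
    if (is.null(coef[[s]])) stop("no imputation coefficients for sex stratum '",
                                 s, "'", call. = FALSE)
    coef[[s]]
  }, numeric(3)))
  if (any(cf[, 3] <= 0)) stop("imputation sd must be > 0", call. = FALSE)
  stats::dnorm(values, cf[, 1] + cf[, 2] * zage, cf[, 3], log = TRUE)
}

# ---- model data preparation --------------------------------------------

#' Prepare model inputs for one resource
#'
#' Extracts the observations for `resource`, indexes the participating
#' individuals, applies the scaling conventions (duration and exposure scaled
#' by their sample mean; tide centred at its sample mean; height and grip
#' scaled by the mean of observed values; knowledge mapped through
#' `k = exp(kappa) / mean(exp(kappa_obs))`), and records the covariate
#' ranges used by the counterfactual reports.
#'
#' @param data a `forage_data` object.
#' @param resource `"shellfish"` or `"trap"`.
#' @param config a [forage_config()].
#' @param knowledge_prior optional data frame `individual_id`, `mean`, `sd`
#'   with per-individual ability posteriors from [fit_irt()]; when supplied,
#'   ability is a latent parameter for those individuals with this normal
#'   measurement-error likelihood attached.
#' @return A list of prepared model inputs (class `forage_model_data`).
#' @export
prepare_model_data <- function(data, resource = c("shellfish", "trap"),
                               config = forage_config(),
                               knowledge_prior = NULL) {
  resource <- match.arg(resource)
  validate_forage_data(data)
  obs <- if (resource == "shellfish") data$shellfish else data$traps
  # an empty table is allowed: the posterior is then the prior
  ids <- sort(unique(if (resource == "shellfish") obs$individual_id else obs$installer_id))
  ind <- data$individuals[match(ids, data$individuals$individual_id), ]
  n_ind <- nrow(ind)

  mean_or <- function(x, fallback)
    if (length(x) && any(!is.na(x))) mean(x, na.rm = TRUE) else fallback
  mean_h <- mean_or(ind$height, 1)
  mean_g <- mean_or(ind$grip, 1)
  K <- if (any(!is.na(ind$knowledge))) mean(exp(ind$knowledge[!is.na(ind$knowledge)]))
       else exp(0.5)  # E exp(N(0,1)) under the standardised-ability prior

  md <- list(
    resource = resource, link = config$link,
    include_traits = isTRUE(config$include_traits),
    ids = ids, n_ind = n_ind,
    age = ind$age,
    zage = as.numeric(scale(ind$age)),
    sex = ind$sex, strata = sort(unique(ind$sex)),
    h_obs = ind$height / mean_h, g_obs = ind$grip / mean_g,
    k_obs = ind$knowledge,
    mean_h = mean_h, mean_g = mean_g, K = K,
    mean_age = mean(ind$age), sd_age = stats::sd(ind$age))
  if (n_ind == 1) md$zage <- 0

  md$sex_idx <- match(md$sex, md$strata)
  ns <- length(md$strata)
  # row of the stacked imputation-coefficient matrix (traits x strata) that
  # applies to each individual, for height, grip, knowledge in turn
  md$imp_rows_all <- c(md$sex_idx, ns + md$sex_idx, 2L * ns + md$sex_idx)
  md$zage3 <- rep(md$zage, 3L)

  md$h_mis <- which(is.na(md$h_obs))
  md$g_mis <- which(is.na(md$g_obs))
  md$k_lat <- which(is.na(md$k_obs))
  if (!is.null(knowledge_prior)) {
    kp <- knowledge_prior[knowledge_prior$individual_id %in% ids, ]
    md$kp_idx <- match(kp$individual_id, ids)
    md$kp_mean <- kp$mean; md$kp_sd <- kp$sd
    md$k_lat <- sort(union(md$k_lat, md$kp_idx))
  }

  if (resource == "shellfish") {
    md$y <- obs$returns_kg
    md$logy <- log(obs$returns_kg)
    md$ind <- match(obs$individual_id, ids)
    md$mean_dur <- mean(obs$duration_min)
    md$mean_tide <- mean(obs$tide_height)
    md$d <- obs$duration_min / md$mean_dur
    md$t <- obs$tide_height - md$mean_tide
  } else {
    md$y <- obs$captures
    md$ind <- match(obs$installer_id, ids)
    md$mean_dur <- mean(obs$exposure_days)
    md$d <- obs$exposure_days / md$mean_dur
    md$t <- NULL
  }
  md$logd <- log(md$d)
  md$n <- length(md$y)
  md$ranges <- list(d = if (md$n) range(md$d),
                    t = if (!is.null(md$t) && md$n) range(md$t),
                    h = if (any(!is.na(md$h_obs))) range(md$h_obs, na.rm = TRUE),
                    g = if (any(!is.na(md$g_obs))) range(md$g_obs, na.rm = TRUE),
                    k = if (any(!is.na(md$k_obs))) range(exp(md$k_obs[!is.na(md$k_obs)]) / md$K))
  class(md) <- "forage_model_data"
  md
}

# ---- log-posterior -----------------------------------------------------

# fast unvalidated natural-scale log-posterior shared by the public wrapper
# and the sampler; returns -Inf outside the domain
logpost_natural <- function(md, th, priors) {
  if (!all(is.finite(c(th$alpha, th$beta, th$gamma))) ||
      th$alpha <= 0 || th$beta <= 0 || th$gamma <= 0)
    return(-Inf)
  lp <- 0
  if (md$include_traits) {
    h <- md$h_obs; g <- md$g_obs; kap <- md$k_obs
    if (length(md$h_mis)) h[md$h_mis] <- th$latent_height
    if (length(md$g_mis)) g[md$g_mis] <- th$latent_grip
    if (length(md$k_lat)) kap[md$k_lat] <- th$latent_knowledge
    if (any(h <= 0) || any(g <= 0)) return(-Inf)  # truncated-positive latents
    k <- exp(kap) / md$K
    logphi <- th$iota + th$gamma * log(-expm1(-th$beta * md$age)) +
      th$zeta * log(k) + th$eta * log(h) + th$theta * log(g)
    # imputation submodel: observed values contribute likelihood, latents
    # are parameters with the same conditional density; `imputation` is the
    # stacked coefficient matrix (traits x strata rows; intercept, slope, sd)
    imp <- th$imputation
    if (any(imp[, 3] <= 0)) return(-Inf)
    rows <- md$imp_rows_all
    lp <- lp + sum(stats::dnorm(c(h, g, kap),
                                imp[rows, 1] + imp[rows, 2] * md$zage3,
                                imp[rows, 3], log = TRUE))
    if (!is.null(md$kp_idx))
      lp <- lp + sum(stats::dnorm(md$kp_mean, kap[md$kp_idx], md$kp_sd,
                                  log = TRUE))
  } else {
    logphi <- th$iota + th$gamma * log(-expm1(-th$beta * md$age))
  }

  if (md$resource == "shellfish") {
    if (th$sigma <= 0) return(-Inf)
    mu <- log(th$alpha) + logphi[md$ind] + th$xi * md$logd + th$tau * md$t
    lp <- lp - sum(md$logy) - md$n * (log(th$sigma) + 0.5 * log(2 * pi)) -
      sum((md$logy - mu)^2) / (2 * th$sigma^2)
  } else {
    raw <- th$alpha * exp(logphi[md$ind] + th$xi * md$logd)
    lambda <- if (md$link == "product") raw else exp(raw)
    lp <- lp + sum(stats::dpois(md$y, lambda, log = TRUE))
  }

  # printed priors: alpha half-normal(0,1); beta, gamma, sigma exp(1);
  # iota and the exponents/coefficients normal(0,1)
  lp <- lp + stats::dnorm(th$alpha, 0, priors$alpha$scale, log = TRUE) + log(2)
  lp <- lp + stats::dexp(th$beta, priors$beta$rate, log = TRUE)
  lp <- lp + stats::dexp(th$gamma, priors$gamma$rate, log = TRUE)
  cs <- priors$coef$scale
  lp <- lp + sum(stats::dnorm(th$iota, 0, cs, log = TRUE))
  lp <- lp + stats::dnorm(th$xi, 0, cs, log = TRUE)
  if (md$resource == "shellfish") {
    lp <- lp + stats::dexp(th$sigma, priors$sigma$rate, log = TRUE)
    lp <- lp + stats::dnorm(th$tau, 0, cs, log = TRUE)
  }
  if (md$include_traits) {
    lp <- lp + sum(stats::dnorm(c(th$zeta, th$eta, th$theta), 0, cs, log = TRUE))
    imp <- th$imputation
    ns <- length(md$strata)
    ip_mean <- rep(c(priors$imp_intercept_somatic$mean,
                     priors$imp_intercept_somatic$mean,
                     priors$imp_intercept_knowledge$mean), each = ns)
    ip_scale <- rep(c(priors$imp_intercept_somatic$scale,
                      priors$imp_intercept_somatic$scale,
                      priors$imp_intercept_knowledge$scale), each = ns)
    lp <- lp + sum(stats::dnorm(imp[, 1], ip_mean, ip_scale, log = TRUE)) +
      sum(stats::dnorm(imp[, 2], priors$imp_slope$mean,
                       priors$imp_slope$scale, log = TRUE)) +
      sum(stats::dexp(imp[, 3], priors$imp_sd$rate, log = TRUE))
  }
  lp
}

# nested per-trait, per-sex imputation list -> stacked coefficient matrix in
# the row order logpost_natural expects (height, grip, knowledge x strata)
imputation_matrix <- function(imputation, strata) {
  do.call(rbind, lapply(c("height", "grip", "knowledge"), function(tr)
    do.call(rbind, lapply(strata, function(s) {
      c3 <- imputation[[tr]][[s]]
      if (is.null(c3)) stop("missing imputation coefficients for ", tr,
                            "/", s, call. = FALSE)
      as.numeric(c3)
    }))))
}

#' Total log-posterior of the return model
#'
#' Evaluates, at a full parameter configuration, the sum of the outcome
#' log-densities (lognormal returns or Poisson captures), the
#' trait-imputation terms, any knowledge measurement-error terms, and the
#' log-priors: `alpha ~ half-normal(0,1)`; `beta, gamma, sigma ~
#' exponential(1)`; `iota, zeta, eta, theta, xi, tau ~ normal(0,1)`, plus the
#' imputation-regression priors of [default_priors()].
#'
#' @param data a `forage_data` object, or a prepared `forage_model_data`.
#' @param params named list of natural-scale parameters: `alpha`, `beta`,
#'   `gamma`, `xi`, `iota` (vector over participating individuals, sorted by
#'   id), plus `sigma` and `tau` for shellfish, and — when traits are
#'   included — `zeta`, `eta`, `theta`, `imputation` (per-trait, per-sex
#'   `c(intercept, slope, sd)`) and `latent_height`/`latent_grip`/
#'   `latent_knowledge` vectors for the missing entries.
#' @param resource `"shellfish"` or `"trap"` (ignored when `data` is already
#'   prepared).
#' @param config a [forage_config()].
#' @param knowledge_prior see [prepare_model_data()].
#' @return Scalar log-posterior (finite inside the domain).
#' @export
total_logposterior <- function(data, params, resource = c("shellfish", "trap"),
                               config = forage_config(),
                               knowledge_prior = NULL) {
  md <- if (inherits(data, "forage_model_data")) data
        else prepare_model_data(data, match.arg(resource), config, knowledge_prior)
  check_par <- function(name, ok)
    if (!ok) stop("parameter domain violation: ", name, call. = FALSE)
  check_par("alpha", is.finite(params$alpha) && params$alpha > 0)
  check_par("beta", is.finite(params$beta) && params$beta > 0)
  check_par("gamma", is.finite(params$gamma) && params$gamma > 0)
  if (md$resource == "shellfish")
    check_par("sigma", is.finite(params$sigma) && params$sigma > 0)
  check_par("iota", length(params$iota) == md$n_ind && all(is.finite(params$iota)))
  if (md$include_traits) {
    check_par("latent_height", length(params$latent_height) == length(md$h_mis))
    check_par("latent_grip", length(params$latent_grip) == length(md$g_mis))
    check_par("latent_knowledge", length(params$latent_knowledge) == length(md$k_lat))
    if (is.list(params$imputation))
      params$imputation <- imputation_matrix(params$imputation, md$strata)
  }
  logpost_natural(md, params, config$priors)
}
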
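# Counterfactual post-processing of posterior draws: normalised age curves
# of the production factor phi, trait contrasts on the phi scale, max-min
# outcome-scale contrasts for trip covariates and traits, and posterior
# predictions.

draws_frame <- function(x) {
  if (inherits(x, "forage_fit")) x$draws
  else if (is.data.frame(x)) x
  else as.data.frame(x)
}

#' Normalised age curve of the production factor
#'
#' For each posterior draw, evaluates `phi` over an age grid with traits at
#' their reference (unit mean) values and no individual random effect, then
#' normalises by the maximum over the grid, giving the fraction of maximum
#' productivity attained at each age.  Summaries are central percentile bands
#' at the 30th, 60th and 89th levels.
#'
#' @param x a `forage_fit`, or a data frame of draws with columns `beta` and
#'   `gamma`.
#' @param age_grid ages (years) at which to evaluate the curve.
#' @param normalize `"max"` (grid maximum, the default) or `"asymptote"`
#'   (the infinite-age limit, 1); the two differ negligibly for saturating
#'   curves.
#' @param probs central band levels.
#' @return A list of class `forage_age_curve`: `age`, `draws` (draws x ages,
#'   normalised), `summary` (data frame with median and band columns).
#' @export
age_curve <- function(x, age_grid = seq(0, 40, by = 0.5),
                      normalize = c("max", "asymptote"),
                      probs = c(0.30, 0.60, 0.89)) {
  normalize <- match.arg(normalize)
  if (!length(age_grid)) stop("empty age grid", call. = FALSE)
  dr <- draws_frame(x)
  m <- t(vapply(seq_len(nrow(dr)), function(s) {
    v <- age_component(age_grid, dr$beta[s], dr$gamma[s])
    v / if (normalize == "max") max(v) else 1
  }, numeric(length(age_grid))))
  qs <- sort(c((1 - probs) / 2, 0.5, 1 - (1 - probs) / 2))
  sm <- data.frame(age = age_grid,
                   mean = colMeans(m),
                   t(apply(m, 2, stats::quantile, probs = qs)))
  names(sm)[-(1:2)] <- paste0("q", format(100 * qs, trim = TRUE))
  structure(list(age = age_grid, draws = m, summary = sm,
                 normalize = normalize),
            class = "forage_age_curve")
}

#' @export
print.forage_age_curve <- function(x, ...) {
  cat(sprintf("<forage_age_curve: %d draws over ages %.1f-%.1f (normalised by %s)>\n",
              nrow(x$draws), min(x$age), max(x$age), x$normalize))
  print(utils::head(round(x$summary, 3)))
  invisible(x)
}

trait_exponent <- function(trait) {
  switch(trait, knowledge = "zeta", height = "eta", grip = "theta",
         stop("unknown trait '", trait, "'", call. = FALSE))
}

# observed scaled range of a trait/covariate recorded at data preparation
stored_range <- function(fit, key) {
  r <- fit$md$ranges[[key]]
  if (is.null(r)) stop("no observed range available for '", key, "'",
                       call. = FALSE)
  r
}

#' Counterfactual trait contrast on the phi scale
#'
#' Per-draw difference `phi(high) - phi(low)` for hypothetical individuals
#' who are average in everything (unit traits, no random effect, age factor
#' at `age`) except the focal trait.  Defaults contrast the observed extreme
#' values of the (scaled) trait; `range = "percentile"` uses configurable
#' percentiles of a latent lognormal spread instead.
#'
#' @param x a `forage_fit` (required for default ranges) or a data frame of
#'   draws containing the exponent column.
#' @param trait `"knowledge"`, `"height"` or `"grip"`.
#' @param low,high scaled trait values to contrast (1 = population mean);
#'   default the observed min/max.
#' @param age age (years) at which the age factor is evaluated; `Inf` (the
#'   default) gives an age factor of 1.
#' @return A list of class `forage_contrast` with per-draw `draws`, the
#'   contrasted values, and `scale = "phi"`.
#' @export
trait_contrast <- function(x, trait = c("knowledge", "height", "grip"),
                           low = NULL, high = NULL, age = Inf) {
  trait <- match.arg(trait)
  dr <- draws_frame(x)
  expo <- trait_exponent(trait)
  if (is.null(dr[[expo]]))
    stop("trait '", trait, "' is not in the fitted model", call. = FALSE)
  if (is.null(low) || is.null(high)) {
    r <- stored_range(x, substr(trait, 1, 1))
    if (is.null(low)) low <- r[1]
    if (is.null(high)) high <- r[2]
  }
  ac <- if (is.infinite(age)) rep(1, nrow(dr))
        else age_component(age, dr$beta, dr$gamma)
  e <- dr[[expo]]
  cf <- ac * (pow_trait(high, e, trait) - pow_trait(low, e, trait))
  structure(list(trait = trait, low = low, high = high, draws = cf,
                 scale = "phi", units = "dimensionless"),
            class = "forage_contrast")
}

#' Counterfactual outcome-scale contrast for one predictor
#'
#' Difference in the model's expected outcome (kg of shellfish per
#' person-trip, including the lognormal mean correction `exp(sigma^2/2)`, or
#' expected captures per trap) between the observed maximum and minimum of
#' one predictor, with every other input held at its mean: unit traits and
#' trip factors, no random effect, age factor at the mean participant age.
#'
#' @param fit a `forage_fit`.
#' @param predictor one of `"duration"`, `"tide"` (shellfish only),
#'   `"exposure"` (traps only), `"height"`, `"grip"`, `"knowledge"`.
#' @return A list of class `forage_contrast` with `scale = "outcome"` and
#'   units `"kg"` or `"captures"`.
#' @export
outcome_contrast <- function(fit,
                             predictor = c("duration", "tide", "exposure",
                                           "height", "grip", "knowledge")) {
  stopifnot(inherits(fit, "forage_fit"))
  predictor <- match.arg(predictor)
  md <- fit$md
  dr <- fit$draws
  if (predictor == "tide" && md$resource != "shellfish")
    stop("predictor 'tide' is not part of the trap model", call. = FALSE)
  if (predictor == "exposure" && md$resource != "trap")
    stop("predictor 'exposure' is not part of the shellfish model", call. = FALSE)
  if (predictor == "duration" && md$resource != "shellfish")
    stop("use predictor 'exposure' for the trap model", call. = FALSE)

  ac <- age_component(md$mean_age, dr$beta, dr$gamma)
  expect_out <- function(d, t, k, h, g) {
    ph <- ac
    if (md$include_traits)
      ph <- ph * k^dr$zeta * h^dr$eta * g^dr$theta
    if (md$resource == "shellfish") {
      ps <- d^dr$xi * exp(t * dr$tau)
      dr$alpha * ph * ps * exp(dr$sigma^2 / 2)
    } else {
      raw <- dr$alpha * ph * d^dr$xi
      if (md$link == "product") raw else exp(raw)
    }
  }
  at <- list(d = 1, t = 0, k = 1, h = 1, g = 1)
  key <- switch(predictor, duration = "d", exposure = "d", tide = "t",
                knowledge = "k", height = "h", grip = "g")
  r <- stored_range(fit, key)
  hi <- at; hi[[key]] <- r[2]
  lo <- at; lo[[key]] <- r[1]
  cf <- expect_out(hi$d, hi$t, hi$k, hi$h, hi$g) -
        expect_out(lo$d, lo$t, lo$k, lo$h, lo$g)
  structure(list(trait = predictor, low = r[1], high = r[2], draws = cf,
                 scale = "outcome",
                 units = if (md$resource == "shellfish") "kg" else "captures"),
            class = "forage_contrast")
}

#' @export
print.forage_contrast <- function(x, ...) {
  q <- stats::quantile(x$draws, c(0.055, 0.5, 0.945))
  cat(sprintf("<forage_contrast: %s (%s scale, %s), low=%.3g high=%.3g>\n",
              x$trait, x$scale, x$units, x$low, x$high))
  cat(sprintf("  median %.3f [89%%: %.3f, %.3f], P(>0) = %.2f\n",
              q[2], q[1], q[3], mean(x$draws > 0)))
  invisible(x)
}

# per-draw production factor for every modelled individual, reconstructing
# latent trait values from the draws where they were imputed
phi_draws <- function(fit) {
  md <- fit$md
  dr <- fit$draws
  S <- nrow(dr)
  iota <- as.matrix(dr[paste0("iota[", md$ids, "]")])
  ac <- t(vapply(seq_len(S), function(s)
    age_component(md$age, dr$beta[s], dr$gamma[s]), numeric(md$n_ind)))
  ph <- exp(iota) * ac
  if (md$include_traits) {
    fill <- function(obs, lat_ids, prefix) {
      m <- matrix(obs, S, md$n_ind, byrow = TRUE)
      if (length(lat_ids))
        m[, lat_ids] <- as.matrix(dr[paste0(prefix, "[", md$ids[lat_ids], "]")])
      m
    }
    h <- fill(md$h_obs, md$h_mis, "lat_height")
    g <- fill(md$g_obs, md$g_mis, "lat_grip")
    kap <- fill(md$k_obs, md$k_lat, "kappa")
    k <- exp(kap) / md$K
    ph <- ph * k^dr$zeta * h^dr$eta * g^dr$theta
  }
  colnames(ph) <- md$ids
  ph
}

#' Posterior-predictive outcomes at the observed covariates
#'
#' For each (optionally thinned) posterior draw, simulates one outcome per
#' observed covariate row: lognormal returns for shellfish, Poisson capture
#' counts for traps.  Latent imputed traits are taken from their own
#' posterior draws.
#'
#' @param fit a `forage_fit`.
#' @param seed integer seed for the predictive simulation.
#' @param ndraws number of posterior draws to use (evenly thinned); default
#'   all.
#' @return A matrix (draws x observations) of simulated outcomes, with the
#'   per-observation expected value in `attr(, "expectation")`.
#' @export
posterior_predict_foraging <- function(fit, seed = 1, ndraws = NULL) {
  stopifnot(inherits(fit, "forage_fit"))
  md <- fit$md
  dr <- fit$draws
  S_all <- nrow(dr)
  use <- if (is.null(ndraws)) seq_len(S_all)
         else round(seq(1, S_all, length.out = min(ndraws, S_all)))
  ph <- phi_draws(fit)[use, , drop = FALSE]
  dr <- dr[use, , drop = FALSE]
  S <- length(use)
  psi <- if (md$resource == "shellfish")
    exp(outer(dr$xi, md$logd) + outer(dr$tau, md$t))
  else exp(outer(dr$xi, md$logd))
  mean_factor <- dr$alpha * ph[, md$ind, drop = FALSE] * psi
  set.seed(seed)
  if (md$resource == "shellfish") {
    out <- matrix(stats::rlnorm(S * md$n, log(mean_factor), dr$sigma),
                  S, md$n)
    expectation <- mean_factor * exp(dr$sigma^2 / 2)
  } else {
    lambda <- if (md$link == "product") mean_factor else exp(mean_factor)
    out <- matrix(stats::rpois(S * md$n, lambda), S, md$n)
    expectation <- lambda
  }
  attr(out, "expectation") <- expectation
  out
}

#' Expected shellfish catch for a counterfactual trip
#'
#' Posterior draws of the expected kg of unprocessed shellfish an average
#' forager (population-mean production factor) collects on a trip of the
#' given duration and tide height, including the lognormal mean correction.
#'
#' @param fit a shellfish `forage_fit`.
#' @param duration_min trip duration in minutes.
#' @param tide_height tide height (same units as the data); default the
#'   lowest observed tide.
#' @return A numeric vector of posterior draws (kg).
#' @export
expected_returns <- function(fit, duration_min = 180, tide_height = NULL) {
  stopifnot(inherits(fit, "forage_fit"))
  md <- fit$md
  if (md$resource != "shellfish")
    stop("expected_returns() applies to the shellfish model", call. = FALSE)
  if (is.null(tide_height))
    tide_height <- md$ranges$t[1] + md$mean_tide
  d <- duration_min / md$mean_dur
  t <- tide_height - md$mean_tide
  phi_bar <- rowMeans(phi_draws(fit))
  fit$draws$alpha * phi_bar * psi_shellfish(d, t, fit$draws$xi, fit$draws$tau) *
    exp(fit$draws$sigma^2 / 2)
}
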
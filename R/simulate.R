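# Synthetic-data generator.  Defaults encode the study design this package
# analyses: 39 foragers over 35 shellfish trips (156 person-trips), 24
# installers over 335 trap trips (724 traps, success fraction near 31/724),
# age-correlated traits, a ~80% / ~30% normalised age-10 productivity ratio
# for shellfish vs traps, and a "recovery" preset of 30 individuals x 500
# trips used for validation by simulation.

#' True generative parameters for the synthetic-data generator
#'
#' Returns the full set of known parameters from which synthetic datasets are
#' drawn: per-resource return-model parameters (`alpha`, `beta`, `gamma`,
#' Cobb-Douglas exponents `zeta`/`eta`/`theta` for knowledge/height/grip,
#' duration exponent `xi`, tide coefficient `tau`, lognormal sd `sigma`,
#' random-effect sd `sigma_iota`), sex-specific linear trait-growth curves,
#' trip-covariate distributions, age distributions, and trait missingness
#' fractions.
#'
#' Defaults emulate the study system: shellfish productivity reaches ~80% of
#' its maximum by age 10 while trap productivity reaches ~30%; height helps
#' and grip/knowledge slightly hinder shellfish collection; the trap scale is
#' calibrated so that roughly 31 of 724 traps succeed; an average ~3 h trip
#' at a strongly negative (low) tide yields more than 3 kg of shellfish.
#'
#' @return A list of class `true_parameters`.
#' @export
true_parameters <- function() {
  p <- list(
    shellfish = list(alpha = 2.5, beta = 0.16, gamma = 1.0,
                     zeta = -0.1, eta = 0.3, theta = -0.2,
                     xi = 0.5, tau = -0.8, sigma = 0.5, sigma_iota = 0.4),
    trap = list(alpha = 0.10, beta = 0.07, gamma = 2.0,
                zeta = -0.1, eta = 0.0, theta = 0.0,
                xi = 0.8, sigma = NA_real_, sigma_iota = 0.4),
    growth = list(
      height = list(female = c(intercept = 108, slope = 2.3, sd = 7),
                    male   = c(intercept = 110, slope = 2.4, sd = 7)),
      grip   = list(female = c(intercept = 4,   slope = 0.9, sd = 3.5),
                    male   = c(intercept = 4,   slope = 1.1, sd = 4)),
      knowledge = list(female = c(intercept = -1.6, slope = 0.10, sd = 0.6),
                       male   = c(intercept = -1.6, slope = 0.10, sd = 0.6))),
    ages = list(default   = c(min = 5, max = 40, shape1 = 1.5, shape2 = 3.5),
                shellfish = c(min = 8, max = 39, shape1 = 1.3, shape2 = 3.7),
                trap      = c(min = 7, max = 26, shape1 = 1.7, shape2 = 2.3)),
    trips = list(duration_meanlog = log(180), duration_sdlog = 0.3,
                 tide_mean = 1.0, tide_sd = 0.4,
                 exposure_meanlog = log(5), exposure_sdlog = 0.4),
    missing = c(height = 0.15, grip = 0.20, knowledge = 0.50))
  class(p) <- "true_parameters"
  p
}

validate_true_parameters <- function(params) {
  for (res in c("shellfish", "trap")) {
    q <- params[[res]]
    # alpha = 0 and sigma = 0 are permitted degenerate boundaries
    # (zero rates; noiseless lognormal); the shape parameters are not.
    nonneg <- c("alpha", if (res == "shellfish") "sigma")
    strict <- c("beta", "gamma", "sigma_iota")
    bad <- c(
      nonneg[!vapply(q[nonneg], function(v) is.finite(v) && v >= 0, logical(1))],
      strict[!vapply(q[strict], function(v) is.finite(v) && v > 0, logical(1))])
    if (length(bad))
      stop("invalid true parameters for ", res, ": ",
           paste(bad, collapse = ", "), " out of domain", call. = FALSE)
  }
  invisible(params)
}

draw_ages <- function(n, dist) {
  dist[["min"]] + (dist[["max"]] - dist[["min"]]) *
    stats::rbeta(n, dist[["shape1"]], dist[["shape2"]])
}

trait_curve <- function(trait, sex, age, growth) {
  cf <- t(vapply(sex, function(s) growth[[trait]][[s]], numeric(3)))
  cf[, 1] + cf[, 2] * age
}

#' Simulate a population of foragers with known latent traits
#'
#' Ages are drawn from a bounded beta-shaped distribution; height, grip and
#' latent knowledge ability follow sex-specific linear growth in age with
#' Gaussian noise, truncated positive for the somatic traits.  True values
#' are kept in `*_true` columns; the observed `height`/`grip`/`knowledge`
#' columns have a configurable fraction masked as missing.
#'
#' @param n number of individuals (>= 1).
#' @param seed integer seed.
#' @param params a [true_parameters()] list.
#' @param age_range one of `"default"`, `"shellfish"`, `"trap"`, selecting
#'   the configured age distribution.
#' @param sex_prob_female probability an individual is female.
#' @param missing named fractions of `height`, `grip`, `knowledge` set
#'   missing; defaults to `params$missing`.
#' @param id_prefix prefix for generated individual ids.
#' @return A data frame of individuals (canonical columns plus `*_true` and
#'   `iota_true`).
#' @export
simulate_individuals <- function(n, seed, params = true_parameters(),
                                 age_range = "default",
                                 sex_prob_female = 0.5,
                                 missing = params$missing,
                                 id_prefix = "ind") {
  stopifnot(n >= 1)
  validate_true_parameters(params)
  if (any(missing < 0 | missing > 1))
    stop("missingness fractions must lie in [0, 1]", call. = FALSE)
  set.seed(seed)
  age <- draw_ages(n, params$ages[[age_range]])
  sex <- ifelse(stats::runif(n) < sex_prob_female, "female", "male")
  draw_trait <- function(trait, lower = 0) {
    mu <- trait_curve(trait, sex, age, params$growth)
    sd <- vapply(sex, function(s) params$growth[[trait]][[s]][["sd"]], numeric(1))
    x <- stats::rnorm(n, mu, sd)
    if (is.finite(lower)) {                # truncate positive by redraw
      while (any(bad <- x <= lower)) x[bad] <- stats::rnorm(sum(bad), mu[bad], sd[bad])
    }
    x
  }
  height_true <- draw_trait("height")
  grip_true <- draw_trait("grip")
  knowledge_true <- draw_trait("knowledge", lower = -Inf)
  mask <- function(x, frac) { x[stats::runif(n) < frac] <- NA_real_; x }
  data.frame(
    individual_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    sex = sex, age = age,
    height = mask(height_true, missing[["height"]]),
    grip = mask(grip_true, missing[["grip"]]),
    knowledge = mask(knowledge_true, missing[["knowledge"]]),
    height_true = height_true, grip_true = grip_true,
    knowledge_true = knowledge_true,
    iota_true = stats::rnorm(n), # scaled by sigma_iota per resource at use
    stringsAsFactors = FALSE)
}

# individual production factor from TRUE traits, unit-mean scaling over the
# supplied population (mirrors the model's scaling convention)
true_phi <- function(ind, q, iota) {
  k <- exp(ind$knowledge_true); k <- k / mean(k)
  h <- ind$height_true / mean(ind$height_true)
  g <- ind$grip_true / mean(ind$grip_true)
  exp(iota) * age_component(ind$age, q$beta, q$gamma) *
    k^q$zeta * h^q$eta * g^q$theta
}

# allocate n_units units over n_groups groups, every group non-empty
alloc_groups <- function(n_units, n_groups) {
  stopifnot(n_units >= n_groups)
  g <- c(seq_len(n_groups), sample.int(n_groups, n_units - n_groups, replace = TRUE))
  sample(g)
}

#' Simulate shellfish person-trip returns
#'
#' Builds `n_trips` trips with lognormal durations and normal tide heights,
#' allocates `n_person_trips` participations (every individual and every trip
#' appears at least once, no individual twice on one trip), and draws returns
#' from `lognormal(log(alpha * phi_i * psi_f), sigma)` where
#' `psi = (d / mean d)^xi * exp((t - mean t) * tau)`.
#'
#' @param individuals output of [simulate_individuals()].
#' @param n_trips number of trips.
#' @param n_person_trips total person-trips.
#' @param params a [true_parameters()] list (component `shellfish` is used).
#' @param seed integer seed.
#' @return A data frame of shellfish observations (canonical columns plus
#'   `phi_true`, `psi_true`).
#' @export
simulate_shellfish <- function(individuals, n_trips = 35,
                               n_person_trips = 156,
                               params = true_parameters(), seed = 1) {
  validate_true_parameters(params)
  q <- params$shellfish
  n_ind <- nrow(individuals)
  stopifnot(n_person_trips >= n_ind, n_person_trips >= n_trips)
  set.seed(seed + 1L)
  duration <- stats::rlnorm(n_trips, params$trips$duration_meanlog,
                            params$trips$duration_sdlog)
  tide <- stats::rnorm(n_trips, params$trips$tide_mean, params$trips$tide_sd)

  trip <- alloc_groups(n_person_trips, n_trips)
  person <- c(sample(seq_len(n_ind)),
              sample.int(n_ind, n_person_trips - n_ind, replace = TRUE))
  # no individual twice on the same trip: reassign clashes to trips they miss
  repeat {
    dup <- duplicated(cbind(trip, person))
    if (!any(dup)) break
    for (i in which(dup)) {
      open <- setdiff(seq_len(n_trips),
                      trip[person == person[i] & !seq_along(trip) %in% i])
      trip[i] <- if (length(open)) open[sample.int(length(open), 1)] else
        sample.int(n_trips, 1)
    }
  }

  iota <- individuals$iota_true * q$sigma_iota
  phi <- true_phi(individuals, q, iota)
  d_sc <- duration / mean(duration)
  t_ct <- tide - mean(tide)
  psi <- d_sc[trip]^q$xi * exp(t_ct[trip] * q$tau)
  mu <- log(q$alpha * phi[person] * psi)
  returns <- if (q$sigma == 0) exp(mu) else stats::rlnorm(n_person_trips, mu, q$sigma)
  data.frame(
    individual_id = individuals$individual_id[person],
    trip_id = sprintf("trip%03d", trip),
    returns_kg = returns,
    duration_min = duration[trip],
    tide_height = tide[trip],
    phi_true = phi[person], psi_true = psi,
    stringsAsFactors = FALSE)
}

#' Simulate snare-trap capture counts
#'
#' Draws lognormal exposure durations (days) and Poisson capture counts with
#' rate `alpha * phi_i * (d / mean d)^xi` under the default product link
#' (`exp(alpha * phi * psi)` under `link = "printed_exp"`).
#'
#' @param individuals output of [simulate_individuals()].
#' @param n_traps number of traps.
#' @param n_trips number of trap-setting trips the traps are spread over.
#' @param params a [true_parameters()] list (component `trap` is used).
#' @param seed integer seed.
#' @param link Poisson rate link; see [forage_config()].
#' @return A data frame of trap observations (canonical columns plus
#'   `phi_true`, `psi_true`, `lambda_true`).
#' @export
simulate_traps <- function(individuals, n_traps = 724, n_trips = 335,
                           params = true_parameters(), seed = 1,
                           link = c("product", "printed_exp")) {
  validate_true_parameters(params)
  link <- match.arg(link)
  q <- params$trap
  n_ind <- nrow(individuals)
  stopifnot(n_traps >= n_ind, n_traps >= n_trips)
  set.seed(seed + 2L)
  installer <- c(sample(seq_len(n_ind)),
                 sample.int(n_ind, n_traps - n_ind, replace = TRUE))
  trip <- alloc_groups(n_traps, n_trips)
  exposure <- stats::rlnorm(n_traps, params$trips$exposure_meanlog,
                            params$trips$exposure_sdlog)
  iota <- individuals$iota_true * q$sigma_iota
  phi <- true_phi(individuals, q, iota)
  psi <- (exposure / mean(exposure))^q$xi
  raw <- q$alpha * phi[installer] * psi
  lambda <- if (link == "product") raw else exp(raw)
  data.frame(
    trap_id = sprintf("trap%04d", seq_len(n_traps)),
    installer_id = individuals$individual_id[installer],
    trip_id = sprintf("ttrip%03d", trip),
    exposure_days = exposure,
    captures = stats::rpois(n_traps, lambda),
    phi_true = phi[installer], psi_true = psi, lambda_true = lambda,
    stringsAsFactors = FALSE)
}

#' Simulate item parameters for the knowledge survey
#'
#' Item discriminations are lognormal(0, 0.4) and difficulties normal(0, 1),
#' labelled by survey component.  Defaults mirror the survey instrument: 50
#' knowledge questions and 27 organism-identification images (freelist items
#' can be added).
#'
#' @param n_question,n_image,n_freelist item counts per component.
#' @param seed integer seed.
#' @return A data frame with columns `item_id`, `component`,
#'   `discrimination`, `difficulty`.
#' @export
simulate_item_parameters <- function(n_question = 50, n_image = 27,
                                     n_freelist = 0, seed = 1) {
  set.seed(seed + 3L)
  n <- n_question + n_image + n_freelist
  data.frame(
    item_id = sprintf("item%03d", seq_len(n)),
    component = rep(c("question", "image", "freelist"),
                    c(n_question, n_image, n_freelist)),
    discrimination = stats::rlnorm(n, 0, 0.4),
    difficulty = stats::rnorm(n),
    stringsAsFactors = FALSE)
}

#' Simulate binary knowledge-survey responses from a 2PL model
#'
#' Each response is Bernoulli with probability
#' `logistic(discrimination * (ability - difficulty))`, using each
#' individual's true latent knowledge ability.
#'
#' @param individuals output of [simulate_individuals()]; only rows named in
#'   `respondents` are interviewed.
#' @param item_params output of [simulate_item_parameters()].
#' @param seed integer seed.
#' @param respondents individual ids to interview; defaults to individuals
#'   whose `knowledge` column is observed (the survey coverage).
#' @return A data frame of knowledge responses (canonical columns).
#' @export
simulate_knowledge_responses <- function(individuals, item_params, seed = 1,
                                         respondents = NULL) {
  if (is.null(respondents))
    respondents <- individuals$individual_id[!is.na(individuals$knowledge)]
  ii <- match(respondents, individuals$individual_id)
  if (anyNA(ii)) stop("unknown respondent id(s)", call. = FALSE)
  set.seed(seed + 4L)
  grid <- expand.grid(i = ii, j = seq_len(nrow(item_params)))
  p <- irt_response_prob(individuals$knowledge_true[grid$i],
                         item_params$discrimination[grid$j],
                         item_params$difficulty[grid$j])
  data.frame(
    individual_id = individuals$individual_id[grid$i],
    item_id = item_params$item_id[grid$j],
    component = item_params$component[grid$j],
    response = as.integer(stats::runif(nrow(grid)) < p),
    stringsAsFactors = FALSE)
}

#' Simulate a complete foraging dataset
#'
#' `preset = "table1"` reproduces the study design: 39 shellfish collectors
#' (72% of person-trips female) over 35 trips and 156 person-trips, and 24
#' male trap installers over 335 trips and 724 traps, plus knowledge-survey
#' responses for the surveyed individuals.  `preset = "recovery"` is the
#' validation design: 30 individuals performing 500 shellfish person-trips
#' (one per trip), with fully observed traits.
#'
#' @param preset `"table1"` or `"recovery"`.
#' @param seed integer seed.
#' @param params a [true_parameters()] list.
#' @return A validated `forage_data` object with the generating parameters
#'   attached as `attr(, "true_parameters")`.
#' @export
simulate_forage_data <- function(preset = c("table1", "recovery"), seed = 1,
                                 params = true_parameters()) {
  preset <- match.arg(preset)
  validate_true_parameters(params)
  if (preset == "table1") {
    ind_s <- simulate_individuals(39, seed, params, age_range = "shellfish",
                                  sex_prob_female = 0.72, id_prefix = "s")
    ind_t <- simulate_individuals(24, seed + 100L, params, age_range = "trap",
                                  sex_prob_female = 0, id_prefix = "t")
    sh <- simulate_shellfish(ind_s, 35, 156, params, seed)
    tr <- simulate_traps(ind_t, 724, 335, params, seed)
    ind <- rbind(ind_s, ind_t)
    items <- simulate_item_parameters(seed = seed)
    kn <- simulate_knowledge_responses(ind, items, seed)
  } else {
    # validation design: data are generated from the very model the recovery
    # harness fits (age-only), so trait exponents are switched off
    params$shellfish[c("zeta", "eta", "theta")] <- list(0, 0, 0)
    ind <- simulate_individuals(30, seed, params, age_range = "default",
                                sex_prob_female = 0.6,
                                missing = c(height = 0, grip = 0, knowledge = 0),
                                id_prefix = "r")
    sh <- simulate_shellfish(ind, 500, 500, params, seed)
    tr <- empty_traps()
    items <- simulate_item_parameters(seed = seed)
    kn <- empty_knowledge()
  }
  out <- forage_data(ind, sh, tr, kn)
  attr(out, "true_parameters") <- params
  attr(out, "item_parameters") <- items
  out
}
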
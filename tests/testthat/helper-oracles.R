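# Shared fixtures and independent oracles.  Oracles are written from the
# closed forms directly (dlnorm/dpois/dnorm/integrate), never through the
# package's own code paths.

# dense numerical-integration posterior mean of a 2PL ability with N(0,1)
# prior and fixed item parameters
grid_ability_mean <- function(r, a, b, lim = 8, n_grid = 4001) {
  kap <- seq(-lim, lim, length.out = n_grid)
  logpost <- vapply(kap, function(k) {
    p <- stats::plogis(a * (k - b))
    sum(stats::dbinom(r, 1, p, log = TRUE)) + stats::dnorm(k, log = TRUE)
  }, numeric(1))
  w <- exp(logpost - max(logpost))
  sum(kap * w) / sum(w)
}

# three-individual toy dataset exercising every model term, including
# missing entries for each trait
toy_forage_data <- function() {
  ind <- data.frame(
    individual_id = c("A", "B", "C"),
    sex = c("female", "female", "male"),
    age = c(10, 20, 30),
    height = c(120, 150, NA),
    grip = c(10, NA, 30),
    knowledge = c(0.5, NA, -0.3))
  sh <- data.frame(
    individual_id = c("A", "B", "A", "C", "B"),
    trip_id = c("t1", "t1", "t2", "t2", "t3"),
    returns_kg = c(1.5, 2.5, 3.0, 0.8, 4.2),
    duration_min = c(120, 120, 180, 180, 240),
    tide_height = c(0.8, 0.8, 1.2, 1.2, 1.0))
  tr <- data.frame(
    trap_id = c("x1", "x2"),
    installer_id = c("A", "C"),
    trip_id = c("tt1", "tt1"),
    exposure_days = c(3, 6),
    captures = c(0L, 1L))
  forage_data(ind, sh, tr)
}

toy_params_shellfish <- function() {
  imp <- function(f, m) list(female = f, male = m)
  list(alpha = 1.3, beta = 0.2, gamma = 1.5, sigma = 0.6,
       xi = 0.4, tau = -0.5,
       zeta = -0.15, eta = 0.25, theta = -0.1,
       iota = c(0.1, -0.2, 0.05),            # ids A, B, C
       imputation = list(
         height = imp(c(1.00, 0.10, 0.30), c(0.95, 0.05, 0.25)),
         grip = imp(c(1.05, 0.20, 0.35), c(0.90, 0.15, 0.40)),
         knowledge = imp(c(0.00, 0.30, 0.50), c(-0.10, 0.25, 0.45))),
       latent_height = 1.1,                  # C
       latent_grip = 0.9,                    # B
       latent_knowledge = 0.2)               # B
}

# memoised small fits shared across test files (kept deliberately short;
# assertions using them test structure and algebraic sign properties, not
# posterior accuracy)
.fit_cache <- new.env(parent = emptyenv())
small_shellfish_fit <- function() {
  if (is.null(.fit_cache$sh)) {
    d <- simulate_forage_data("table1", seed = 4)
    cfg <- forage_config(chains = 2L, warmup = 400L, iter = 400L,
                         include_traits = TRUE, seed = 4L)
    .fit_cache$sh <- suppressWarnings(fit_foraging(d, "shellfish", cfg))
  }
  .fit_cache$sh
}
small_trap_fit <- function() {
  if (is.null(.fit_cache$tr)) {
    d <- simulate_forage_data("table1", seed = 4)
    cfg <- forage_config(chains = 2L, warmup = 400L, iter = 400L,
                         include_traits = FALSE, seed = 4L)
    .fit_cache$tr <- suppressWarnings(fit_foraging(d, "trap", cfg))
  }
  .fit_cache$tr
}
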
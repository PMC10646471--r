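test_that("age component has the saturating form and boundaries", {
  expect_equal(age_component(0, 0.5, 2), 0)
  expect_equal(age_component(1e6, 0.1, 1), 1, tolerance = 1e-12)
  expect_equal(age_component(10, 0.1, 2), (1 - exp(-1))^2)
  expect_equal(age_component(10, 0.1, 2), 0.39958, tolerance = 1e-5)
  a <- seq(1, 60, by = 1)
  expect_true(all(diff(age_component(a, 0.07, 2.3)) > 0))
  expect_error(age_component(5, 0, 1), "beta")
  expect_error(age_component(5, 0.1, -2), "gamma")
  expect_error(age_component(-1, 0.1, 1), "age")
})

test_that("phi is a Cobb-Douglas with hard trait boundaries", {
  a <- c(5, 12, 33)
  expect_equal(phi(a, 0.2, 1.3), age_component(a, 0.2, 1.3))
  expect_equal(phi(10, 0.1, 1, k = 0, zeta = 0.5), 0)
  # age term 0.25, k = 2, zeta = 0.5 -> 0.25 * sqrt(2)
  beta <- -log(1 - 0.25) / 10   # age_component(10) = 0.25 with gamma = 1
  expect_equal(phi(10, beta, 1, k = 2, zeta = 0.5), 0.25 * sqrt(2))
  expect_equal(phi(10, beta, 1, k = 2, zeta = 0.5), 0.35355, tolerance = 1e-5)
  expect_error(phi(10, 0.1, 1, h = -1, eta = 0.3), "height")
  expect_error(phi(10, 0.1, 1, g = 0, theta = -0.2), "grip")
})

test_that("phi is monotone in each input according to its exponent sign", {
  set.seed(1)
  for (i in 1:25) {
    beta <- runif(1, 0.02, 0.4); gamma <- rexp(1); e <- rnorm(1)
    lo <- runif(1, 0.2, 1); hi <- lo + runif(1, 0.1, 2)
    f <- phi(15, beta, gamma, k = c(lo, hi), zeta = e)
    if (e > 0) expect_gt(f[2], f[1]) else if (e < 0) expect_lt(f[2], f[1])
    ages <- sort(runif(2, 1, 30))
    expect_gt(phi(ages[2], beta, gamma), phi(ages[1], beta, gamma))
  }
})

test_that("trip factors follow d^xi * exp(t tau)", {
  expect_equal(psi_shellfish(1, 0, xi = 0.7, tau = -0.4), 1)
  expect_equal(psi_shellfish(4, 0, xi = 0.5, tau = 0), 2)
  expect_equal(psi_shellfish(1, 0.5, xi = 1, tau = -1), exp(-0.5))
  expect_equal(psi_shellfish(1, 0.5, xi = 1, tau = -1), 0.60653, tolerance = 1e-5)
  expect_equal(psi_trap(1, xi = 0.3), 1)
  expect_equal(psi_trap(3, xi = 1), 3)
  expect_equal(psi_trap(5, xi = 0.7), 3.08517, tolerance = 1e-5)
  expect_error(psi_shellfish(0, 0, 1, 1), "duration")
  expect_error(psi_trap(-2, 1), "exposure")
})

test_that("shellfish log-density matches the lognormal oracle", {
  # at the median (returns = alpha phi psi) the kernel vanishes
  expect_equal(shellfish_logdensity(2.4, 2.4, 0.7),
               -log(2.4) - log(0.7 * sqrt(2 * pi)))
  # fixed toy against dlnorm directly
  expect_equal(shellfish_logdensity(2, 1, 1), dlnorm(2, 0, 1, log = TRUE))
  expect_equal(shellfish_logdensity(2, 1, 1), -1.8523122, tolerance = 1e-6)
  # flatness limit: density shrinks slowly as sigma grows
  s <- c(5, 20, 100)
  v <- shellfish_logdensity(2, 1, s)
  expect_true(all(diff(v) < 0))
  expect_gt(v[3], -10)
  expect_error(shellfish_logdensity(-1, 1, 1), "returns_kg")
  expect_error(shellfish_logdensity(2, 0, 1), "mean_factor")
})

test_that("trap log-density follows the configured Poisson link", {
  expect_equal(trap_logdensity(0L, 0.06), -0.06)
  expect_equal(trap_logdensity(1L, 1), -1)
  # printed exponential link forces rates >= 1
  expect_equal(trap_logdensity(0L, 0, link = "printed_exp"),
               dpois(0, 1, log = TRUE))
  rf <- seq(0, 3, by = 0.25)
  lam_printed <- exp(rf)
  expect_true(all(lam_printed >= 1))
  # while the product link reaches the sparse-capture regime
  expect_true(all(rf * 0.05 < 1))
  expect_error(trap_logdensity(-1L, 1), "captures")
})

test_that("imputation log-density is the sex-specific normal regression", {
  coef <- list(female = c(1, 0.2, 0.3), male = c(0.9, 0.1, 0.4))
  v <- imputation_logdensity(c(1.1, 0.8), zage = c(0.5, -1),
                             sex = c("female", "male"), coef = coef)
  expect_equal(v, c(dnorm(1.1, 1 + 0.2 * 0.5, 0.3, log = TRUE),
                    dnorm(0.8, 0.9 - 0.1, 0.4, log = TRUE)))
  # shrinking the residual sd pins values to the regression line
  on_line <- function(s) imputation_logdensity(1.1, 0.5, "female",
                                               list(female = c(1, 0.2, s)))
  off_line <- function(s) imputation_logdensity(1.4, 0.5, "female",
                                                list(female = c(1, 0.2, s)))
  expect_gt(on_line(1e-4), on_line(0.1))
  expect_lt(off_line(1e-4), -1e4)
  expect_error(imputation_logdensity(1, 0, "female",
                                     list(female = c(1, 0, -1))), "sd")
  expect_error(imputation_logdensity(1, 0, "other",
                                     list(female = c(1, 0, 1))), "stratum")
})

test_that("total log-posterior equals the term-by-term oracle", {
  d <- toy_forage_data()
  th <- toy_params_shellfish()
  cfg <- forage_config(include_traits = TRUE)
  got <- total_logposterior(d, th, "shellfish", cfg)

  # ---- independent oracle, assembled from closed forms only ----
  ids <- c("A", "B", "C")
  age <- c(10, 20, 30); sex <- c("female", "female", "male")
  zage <- (age - mean(age)) / sd(age)
  h <- c(120, 150, NA) / mean(c(120, 150)); h[3] <- th$latent_height
  g <- c(10, NA, 30) / mean(c(10, 30)); g[2] <- th$latent_grip
  kap <- c(0.5, NA, -0.3); kap[2] <- th$latent_knowledge
  K <- mean(exp(c(0.5, -0.3)))
  k <- exp(kap) / K
  phi_i <- exp(th$iota) * (1 - exp(-th$beta * age))^th$gamma *
    k^th$zeta * h^th$eta * g^th$theta
  dur <- c(120, 120, 180, 180, 240); tide <- c(0.8, 0.8, 1.2, 1.2, 1.0)
  dsc <- dur / mean(dur); tc <- tide - mean(tide)
  psi_f <- dsc^th$xi * exp(tc * th$tau)
  who <- c(1, 2, 1, 3, 2)
  y <- c(1.5, 2.5, 3.0, 0.8, 4.2)
  ll <- sum(dlnorm(y, log(th$alpha * phi_i[who] * psi_f), th$sigma, log = TRUE))
  imp_ll <- 0
  for (tr in c("height", "grip", "knowledge")) {
    vals <- switch(tr, height = h, grip = g, knowledge = kap)
    cf <- th$imputation[[tr]]
    for (i in 1:3) {
      c3 <- cf[[sex[i]]]
      imp_ll <- imp_ll + dnorm(vals[i], c3[1] + c3[2] * zage[i], c3[3], log = TRUE)
    }
  }
  pri <- dnorm(th$alpha, 0, 1, log = TRUE) + log(2) +
    dexp(th$beta, 1, log = TRUE) + dexp(th$gamma, 1, log = TRUE) +
    dexp(th$sigma, 1, log = TRUE) +
    sum(dnorm(c(th$iota, th$xi, th$tau, th$zeta, th$eta, th$theta),
              0, 1, log = TRUE))
  for (tr in c("height", "grip", "knowledge")) {
    im <- if (tr == "knowledge") c(0, 1) else c(1, 0.5)
    for (s in c("female", "male")) {
      c3 <- th$imputation[[tr]][[s]]
      pri <- pri + dnorm(c3[1], im[1], im[2], log = TRUE) +
        dnorm(c3[2], 0, 0.5, log = TRUE) + dexp(c3[3], 1, log = TRUE)
    }
  }
  expect_lt(abs(got - (ll + imp_ll + pri)), 1e-8)
})

test_that("total log-posterior reduces to the log-prior on empty data", {
  d0 <- forage_data(empty_individuals())
  th <- list(alpha = 0.5, beta = 0.3, gamma = 1, sigma = 0.5,
             xi = 0.2, tau = -0.1, iota = numeric(0))
  cfg <- forage_config(include_traits = FALSE)
  oracle <- dnorm(0.5, 0, 1, log = TRUE) + log(2) +
    dexp(0.3, 1, log = TRUE) + dexp(1, 1, log = TRUE) +
    dexp(0.5, 1, log = TRUE) +
    dnorm(0.2, 0, 1, log = TRUE) + dnorm(-0.1, 0, 1, log = TRUE)
  expect_equal(total_logposterior(d0, th, "shellfish", cfg), oracle)
})

test_that("parameter domain violations are reported by name", {
  d <- toy_forage_data()
  th <- toy_params_shellfish()
  cfg <- forage_config(include_traits = TRUE)
  th_bad <- th; th_bad$beta <- -1
  expect_error(total_logposterior(d, th_bad, "shellfish", cfg), "beta")
  th_bad <- th; th_bad$sigma <- 0
  expect_error(total_logposterior(d, th_bad, "shellfish", cfg), "sigma")
  th_bad <- th; th_bad$iota <- c(0, 0)
  expect_error(total_logposterior(d, th_bad, "shellfish", cfg), "iota")
})

test_that("rescaling alpha against the random effects only moves the prior", {
  d <- toy_forage_data()
  th <- toy_params_shellfish()
  cfg <- forage_config(include_traits = TRUE)
  cc <- 1.7
  th2 <- th
  th2$alpha <- th$alpha * cc
  th2$iota <- th$iota - log(cc)   # every phi_i * alpha unchanged
  delta <- total_logposterior(d, th2, "shellfish", cfg) -
    total_logposterior(d, th, "shellfish", cfg)
  prior_delta <- dnorm(th2$alpha, 0, 1, log = TRUE) -
    dnorm(th$alpha, 0, 1, log = TRUE) +
    sum(dnorm(th2$iota, 0, 1, log = TRUE)) -
    sum(dnorm(th$iota, 0, 1, log = TRUE))
  expect_equal(delta, prior_delta, tolerance = 1e-10)
})

test_that("widening a prior lowers its density at a fixed interior point", {
  # normal: scale up -> lower density at a point inside one sd
  expect_lt(dnorm(0.3, 0, 2, log = TRUE), dnorm(0.3, 0, 1, log = TRUE))
  # exponential: smaller rate (wider) -> lower density near zero
  expect_lt(dexp(0.2, 0.5, log = TRUE), dexp(0.2, 1, log = TRUE))
  d <- toy_forage_data()
  th <- toy_params_shellfish()
  wide <- forage_config(include_traits = TRUE,
                        priors = list(coef = list(dist = "normal", scale = 3)))
  tight <- forage_config(include_traits = TRUE)
  expect_lt(total_logposterior(d, th, "shellfish", wide),
            total_logposterior(d, th, "shellfish", tight))
})
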
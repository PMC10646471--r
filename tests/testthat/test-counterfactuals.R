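fake_fit <- function(draws, resource = "shellfish", include_traits = FALSE,
                     ranges = list(d = c(0.5, 2), t = c(-0.6, 0.8)),
                     mean_age = 1e6, link = "product") {
  structure(list(draws = draws,
                 md = list(resource = resource,
                           include_traits = include_traits,
                           ranges = ranges, mean_age = mean_age,
                           link = link)),
            class = "forage_fit")
}

test_that("normalised age curves match direct evaluation", {
  d1 <- data.frame(alpha = 2, beta = 0.1, gamma = 1)
  ac <- age_curve(d1, age_grid = seq(0, 100, by = 0.5))
  v10 <- ac$draws[1, ac$age == 10]
  expect_equal(v10, (1 - exp(-1)) / (1 - exp(-10)))
  expect_equal(v10, 0.632, tolerance = 1e-3)
  # gamma -> 0: flat curve at 1 for all positive ages
  ac0 <- age_curve(data.frame(beta = 0.1, gamma = 1e-9),
                   age_grid = seq(1, 40, by = 1))
  expect_true(all(abs(ac0$draws - 1) < 1e-6))
  expect_error(age_curve(d1, age_grid = numeric()), "empty")
})

test_that("normalised age curves are invariant to the overall scale alpha", {
  dr <- data.frame(alpha = c(1, 10, 100), beta = 0.2, gamma = 1.4)
  ac <- age_curve(dr, age_grid = seq(0, 40, by = 2))
  expect_equal(ac$draws[1, ], ac$draws[2, ])
  expect_equal(ac$draws[1, ], ac$draws[3, ])
})

test_that("curves rise and saturate when normalised by the asymptote", {
  dr <- data.frame(beta = 0.16, gamma = 1)
  ac <- age_curve(dr, age_grid = seq(0, 40, 0.5), normalize = "asymptote")
  expect_true(all(diff(ac$draws[1, ]) > 0))
  expect_lt(max(ac$draws), 1)
  # for saturating curves the two normalisations differ negligibly
  acm <- age_curve(dr, age_grid = seq(0, 40, 0.5), normalize = "max")
  expect_equal(ac$draws[1, ac$age == 10], acm$draws[1, acm$age == 10],
               tolerance = 0.005)
})

test_that("trait contrasts evaluate the Cobb-Douglas difference", {
  dr <- data.frame(zeta = c(0, 0), eta = c(0.5, -0.2), theta = c(1, 2),
                   beta = 0.1, gamma = 1)
  # zero exponent -> exactly zero contrast in every draw
  ck <- trait_contrast(dr, "knowledge", low = 0.3, high = 2.5)
  expect_equal(ck$draws, c(0, 0))
  # eta = 0.5, height 0.5 vs 2 -> sqrt(2) - sqrt(0.5)
  ch <- trait_contrast(dr, "height", low = 0.5, high = 2)
  expect_equal(ch$draws[1], sqrt(2) - sqrt(0.5))
  expect_equal(ch$draws[1], 0.70711, tolerance = 1e-5)
  # contrast sign equals exponent sign, draw by draw
  set.seed(2)
  dr2 <- data.frame(eta = rnorm(200), beta = 0.1, gamma = 1)
  cc <- trait_contrast(dr2, "height", low = 0.4, high = 1.9)
  expect_true(all(sign(cc$draws) == sign(dr2$eta)))
  # finite age discounts the contrast by the age component
  ca <- trait_contrast(dr, "height", low = 0.5, high = 2, age = 10)
  expect_equal(ca$draws[1], (1 - exp(-1)) * (sqrt(2) - sqrt(0.5)))
  expect_error(trait_contrast(dr[, c("beta", "gamma")], "height", 0.5, 2),
               "not in the fitted model")
})

test_that("outcome contrasts respect ranges, units and monotonicity", {
  dr <- data.frame(alpha = 2, beta = 0.3, gamma = 1, xi = 1,
                   tau = c(-0.8, -0.2), sigma = 1e-9)
  # degenerate predictor range -> zero contrast
  f0 <- fake_fit(dr, ranges = list(d = c(1, 1), t = c(-0.5, 0.5)))
  expect_equal(outcome_contrast(f0, "duration")$draws, c(0, 0))
  # tau < 0 in every draw -> max-min tide contrast negative in every draw
  f1 <- fake_fit(dr)
  ct <- outcome_contrast(f1, "tide")
  expect_true(all(ct$draws < 0))
  expect_equal(ct$units, "kg")
  # xi = 1, sigma ~ 0, duration doubling -> one extra reference catch
  f2 <- fake_fit(dr, ranges = list(d = c(1, 2), t = c(-0.5, 0.5)))
  cd <- outcome_contrast(f2, "duration")
  expect_equal(cd$draws, dr$alpha * rep(1, 2), tolerance = 1e-6)
  # tide is not a trap predictor
  ftr <- fake_fit(data.frame(alpha = 0.1, beta = 0.1, gamma = 1, xi = 0.8),
                  resource = "trap", ranges = list(d = c(0.5, 3)))
  expect_error(outcome_contrast(ftr, "tide"), "not part of the trap model")
  expect_error(outcome_contrast(f1, "exposure"), "not part of the shellfish")
  ce <- outcome_contrast(ftr, "exposure")
  expect_equal(ce$units, "captures")
  expect_true(all(ce$draws > 0))
})

test_that("posterior predictions use the lognormal mean and collapse as sigma -> 0", {
  fit <- small_shellfish_fit()
  pp <- posterior_predict_foraging(fit, seed = 1)
  ex <- attr(pp, "expectation")
  expect_equal(dim(pp), c(nrow(fit$draws), fit$md$n))
  # empirical mean over simulated outcomes matches the stored expectation
  expect_equal(mean(pp), mean(ex), tolerance = 0.03)
  expect_true(all(pp > 0))

  # degenerate noise: predictions equal the median surface
  fit0 <- fit
  fit0$draws$sigma[] <- 1e-12
  pp0 <- posterior_predict_foraging(fit0, seed = 1, ndraws = 50)
  ex0 <- attr(pp0, "expectation")
  expect_equal(unname(as.vector(pp0)), unname(as.vector(ex0)),
               tolerance = 1e-6)
})

test_that("trap posterior predictions reproduce the observed sparse successes", {
  fit <- small_trap_fit()
  pp <- posterior_predict_foraging(fit, seed = 2, ndraws = 200)
  pred_frac <- mean(pp > 0)
  obs_frac <- mean(fit$md$y > 0)
  expect_lt(abs(pred_frac - obs_frac), 0.03)
})

test_that("expected counterfactual catch responds to tide and duration", {
  fit <- small_shellfish_fit()
  low_tide <- expected_returns(fit, duration_min = 180)
  mean_tide <- expected_returns(fit, duration_min = 180,
                                tide_height = fit$md$mean_tide)
  # posterior tau is overwhelmingly negative here: low tide must help
  expect_gt(median(low_tide), median(mean_tide))
  longer <- expected_returns(fit, duration_min = 360,
                             tide_height = fit$md$mean_tide)
  expect_gt(median(longer), median(mean_tide))
  expect_error(expected_returns(small_trap_fit()), "shellfish")
})
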
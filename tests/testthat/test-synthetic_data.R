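test_that("generation is deterministic under a fixed seed", {
  d1 <- simulate_forage_data("table1", seed = 11)
  d2 <- simulate_forage_data("table1", seed = 11)
  expect_identical(d1$individuals, d2$individuals)
  expect_identical(d1$shellfish, d2$shellfish)
  expect_identical(d1$traps, d2$traps)
  expect_identical(d1$knowledge, d2$knowledge)
  d3 <- simulate_forage_data("table1", seed = 12)
  expect_false(identical(d1$shellfish$returns_kg, d3$shellfish$returns_kg))
})

test_that("zero trait noise puts traits exactly on the growth curve", {
  p <- true_parameters()
  for (tr in c("height", "grip", "knowledge"))
    for (s in c("female", "male")) p$growth[[tr]][[s]]["sd"] <- 0
  ind <- simulate_individuals(25, seed = 5, params = p,
                              missing = c(height = 0, grip = 0, knowledge = 0))
  for (s in c("female", "male")) {
    w <- ind$sex == s
    cf <- p$growth$height[[s]]
    expect_equal(ind$height[w], cf[["intercept"]] + cf[["slope"]] * ind$age[w])
  }
})

test_that("traits are strongly age-correlated at the default noise level", {
  ind <- simulate_individuals(30, seed = 8,
                              missing = c(height = 0, grip = 0, knowledge = 0))
  expect_gt(cor(ind$age, ind$height), 0.5)
  expect_gt(cor(ind$age, ind$grip), 0.5)
  expect_gt(cor(ind$age, ind$knowledge), 0.3)
})

test_that("invalid generator parameters error before sampling", {
  p <- true_parameters()
  p$shellfish$beta <- -0.1
  expect_error(simulate_individuals(5, 1, p), "out of domain")
  p <- true_parameters()
  p$trap$gamma <- 0
  expect_error(simulate_forage_data("table1", 1, params = p), "out of domain")
})

test_that("the sigma -> 0 limit gives noiseless lognormal returns", {
  p <- true_parameters()
  p$shellfish$sigma <- 0
  ind <- simulate_individuals(10, seed = 2, params = p,
                              missing = c(height = 0, grip = 0, knowledge = 0))
  sh <- simulate_shellfish(ind, 12, 40, p, seed = 2)
  expect_equal(sh$returns_kg,
               p$shellfish$alpha * sh$phi_true * sh$psi_true)
})

test_that("tau = 0 removes the tide-returns association", {
  p <- true_parameters()
  p$shellfish$tau <- 0
  ind <- simulate_individuals(50, seed = 6, params = p,
                              missing = c(height = 0, grip = 0, knowledge = 0))
  sh <- simulate_shellfish(ind, 600, 3000, p, seed = 6)
  expect_lt(abs(cor(log(sh$returns_kg), sh$tide_height)), 0.06)
})

test_that("mean returns match the closed-form lognormal mean", {
  p <- true_parameters()
  ind <- simulate_individuals(50, seed = 7, params = p,
                              missing = c(height = 0, grip = 0, knowledge = 0))
  sh <- simulate_shellfish(ind, 800, 6000, p, seed = 7)
  closed <- p$shellfish$alpha * mean(sh$phi_true * sh$psi_true) *
    exp(p$shellfish$sigma^2 / 2)
  expect_equal(mean(sh$returns_kg), closed, tolerance = 0.05)
})

test_that("alpha = 0 yields all-zero captures and low rates match the study", {
  p <- true_parameters()
  p$trap$alpha <- 0
  ind <- simulate_individuals(10, seed = 3, params = p, age_range = "trap")
  tr <- simulate_traps(ind, 100, 40, p, seed = 3)
  expect_true(all(tr$captures == 0))

  # at defaults the success fraction is of the order 31/724
  fr <- vapply(1:3, function(s)
    mean(simulate_forage_data("table1", seed = s)$traps$captures > 0),
    numeric(1))
  expect_lt(abs(mean(fr) - 31 / 724), 0.02)
})

test_that("expected captures are linear in exposure when xi = 1", {
  p <- true_parameters()
  set.seed(99)
  lam0 <- 0.05 * runif(4000, 0.5, 2)  # alpha * phi at heterogeneous traps
  d <- runif(4000, 1, 9)
  y1 <- rpois(4000, lam0 * psi_trap(d, xi = 1))
  y2 <- rpois(4000, lam0 * psi_trap(2 * d, xi = 1))
  expect_equal(sum(y2) / sum(y1), 2, tolerance = 0.15)
})

test_that("knowledge responses follow the 2PL structure", {
  ind <- simulate_individuals(60, seed = 4,
                              missing = c(height = 0, grip = 0, knowledge = 0))
  items <- simulate_item_parameters(n_question = 20, n_image = 10, seed = 4)
  # an impossibly easy item is always answered correctly
  items$difficulty[1] <- -50
  resp <- simulate_knowledge_responses(ind, items, seed = 4,
                                       respondents = ind$individual_id)
  expect_true(all(resp$response[resp$item_id == items$item_id[1]] == 1))
  # zero discrimination -> coin flips
  items0 <- items; items0$discrimination[] <- 0
  resp0 <- simulate_knowledge_responses(ind, items0, seed = 5,
                                        respondents = ind$individual_id)
  expect_equal(mean(resp0$response), 0.5, tolerance = 0.03)
  # proportion correct increases with true ability
  pc <- tapply(resp$response, resp$individual_id, mean)
  truth <- ind$knowledge_true[match(names(pc), ind$individual_id)]
  expect_gt(cor(pc, truth, method = "spearman"), 0.7)
})

test_that("generated datasets pass schema validation verbatim", {
  expect_invisible(validate_forage_data(simulate_forage_data("table1", seed = 21)))
  expect_invisible(validate_forage_data(simulate_forage_data("recovery", seed = 21)))
})
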
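# Two-parameter logistic (2PL) item response model for the ecological
# knowledge survey.  A single latent ability dimension is shared across the
# three survey components (questions, picture identification, freelist);
# component-level means on the item parameters acknowledge the instrument
# parts without inventing multidimensionality.

#' 2PL response probability
#'
#' `P(correct) = logistic(discrimination * (ability - difficulty))`,
#' strictly increasing in ability when discrimination is positive and equal
#' to 0.5 at `ability == difficulty`.
#'
#' @param ability latent ability (dimensionless), vectorised.
#' @param discrimination item discrimination.
#' @param difficulty item difficulty.
#' @return Probability in (0, 1).
#' @export
irt_response_prob <- function(ability, discrimination, difficulty) {
  stats::plogis(discrimination * (ability - difficulty))
}

# bernoulli log-likelihood on the logit scale, numerically stable:
# log(plogis(eta)) = -log1p(exp(-eta)); log(1 - plogis(eta)) = -log1p(exp(eta))
bern_loglik <- function(eta, r) {
  -sum(ifelse(r == 1, log1p(exp(-eta)), log1p(exp(eta))))
}

#' Fit the knowledge IRT model
#'
#' Samples the joint posterior of item parameters and latent abilities with
#' an adaptive Metropolis-within-Gibbs sampler.  Priors: ability
#' `normal(0, 1)`; item log-discrimination `normal(mu_a[component], 0.5)`
#' with `mu_a ~ normal(0, 0.25)` (so discriminations are lognormal,
#' sign-identified positive); difficulty `normal(mu_b[component], 1)` with
#' `mu_b ~ normal(0, 0.5)`.  Abilities are standardised (mean 0, sd 1 across
#' individuals) within each posterior draw, which fixes the latent scale.
#' Items with all-0 or all-1 responses are flagged in the result and retained
#' (their parameters revert toward the component prior).
#'
#' @param responses data frame of binary responses with columns
#'   `individual_id`, `item_id`, `component`, `response`.
#' @param chains,warmup,iter,seed MCMC settings (chains >= 2).
#' @param item_params optional data frame (`item_id`, `discrimination`,
#'   `difficulty`) fixing the item parameters; only abilities are sampled and
#'   they are not re-standardised (the fixed items identify the scale).
#' @return An object of class `irt_fit`: `ability` (data frame
#'   `individual_id`, `mean`, `sd`), `ability_draws` (draws x individuals),
#'   `items` (posterior summaries or the fixed values), `draws_array` for
#'   diagnostics, and `degenerate_items`.
#' @export
fit_irt <- function(responses, chains = 2L, warmup = 1000L, iter = 1000L,
                    seed = 1L, item_params = NULL) {
  stopifnot(all(responses$response %in% 0:1))
  persons <- sort(unique(responses$individual_id))
  items <- sort(unique(responses$item_id))
  n <- length(persons); J <- length(items)
  if (n < 2L || J < 2L)
    stop("need at least 2 individuals and 2 items", call. = FALSE)
  ii <- match(responses$individual_id, persons)
  jj <- match(responses$item_id, items)
  comp <- tapply(as.character(responses$component), jj, function(z) z[1])
  comp <- as.character(comp[as.character(seq_len(J))])
  comp[is.na(comp)] <- "question"
  comps <- sort(unique(comp))
  cidx <- match(comp, comps)

  by_person <- lapply(seq_len(n), function(i) {
    w <- which(ii == i); list(j = jj[w], r = responses$response[w])
  })
  by_item <- lapply(seq_len(J), function(j) {
    w <- which(jj == j); list(i = ii[w], r = responses$response[w])
  })
  rate <- vapply(by_item, function(b) mean(b$r), numeric(1))
  degenerate <- items[rate %in% c(0, 1)]
  if (length(degenerate))
    message(length(degenerate),
            " degenerate item(s) (all-0 or all-1 responses) retained with informative priors")

  fixed <- !is.null(item_params)
  if (fixed) {
    mi <- match(items, item_params$item_id)
    if (anyNA(mi)) stop("item_params must cover all items", call. = FALSE)
    a_fix <- item_params$discrimination[mi]
    b_fix <- item_params$difficulty[mi]
  }

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    kap <- stats::rnorm(n, 0, 0.2)
    la <- stats::rnorm(J, 0, 0.1)     # log discrimination
    b <- stats::rnorm(J, 0, 0.2)      # difficulty
    mu_a <- numeric(length(comps)); mu_b <- numeric(length(comps))
    if (fixed) { a <- a_fix; b <- b_fix } else a <- exp(la)

    person_ll <- function(i, kap_i)
      bern_loglik(a[by_person[[i]]$j] * (kap_i - b[by_person[[i]]$j]),
                  by_person[[i]]$r)
    item_ll <- function(j, a_j, b_j)
      bern_loglik(a_j * (kap[by_item[[j]]$i] - b_j), by_item[[j]]$r)

    n_par <- n + if (fixed) 0L else 2L * J + 2L * length(comps)
    lstep <- rep(log(0.5), n_par)
    keep <- matrix(NA_real_, iter, n_par)
    acc <- numeric(n_par)
    nb <- 0L
    total <- warmup + iter
    for (it in seq_len(total)) {
      # abilities
      for (i in seq_len(n)) {
        prop <- kap[i] + exp(lstep[i]) * stats::rnorm(1)
        dl <- person_ll(i, prop) - person_ll(i, kap[i]) +
          stats::dnorm(prop, 0, 1, log = TRUE) -
          stats::dnorm(kap[i], 0, 1, log = TRUE)
        if (dl > log(stats::runif(1))) { kap[i] <- prop; acc[i] <- acc[i] + 1 }
      }
      if (!fixed) {
        for (j in seq_len(J)) {
          pj <- n + j
          prop <- la[j] + exp(lstep[pj]) * stats::rnorm(1)
          dl <- item_ll(j, exp(prop), b[j]) - item_ll(j, a[j], b[j]) +
            stats::dnorm(prop, mu_a[cidx[j]], 0.5, log = TRUE) -
            stats::dnorm(la[j], mu_a[cidx[j]], 0.5, log = TRUE)
          if (dl > log(stats::runif(1))) {
            la[j] <- prop; a[j] <- exp(prop); acc[pj] <- acc[pj] + 1
          }
          pj <- n + J + j
          prop <- b[j] + exp(lstep[pj]) * stats::rnorm(1)
          dl <- item_ll(j, a[j], prop) - item_ll(j, a[j], b[j]) +
            stats::dnorm(prop, mu_b[cidx[j]], 1, log = TRUE) -
            stats::dnorm(b[j], mu_b[cidx[j]], 1, log = TRUE)
          if (dl > log(stats::runif(1))) { b[j] <- prop; acc[pj] <- acc[pj] + 1 }
        }
        for (cc in seq_along(comps)) {
          pj <- n + 2L * J + cc
          prop <- mu_a[cc] + exp(lstep[pj]) * stats::rnorm(1)
          dl <- sum(stats::dnorm(la[cidx == cc], prop, 0.5, log = TRUE)) -
            sum(stats::dnorm(la[cidx == cc], mu_a[cc], 0.5, log = TRUE)) +
            stats::dnorm(prop, 0, 0.25, log = TRUE) -
            stats::dnorm(mu_a[cc], 0, 0.25, log = TRUE)
          if (dl > log(stats::runif(1))) { mu_a[cc] <- prop; acc[pj] <- acc[pj] + 1 }
          pj <- n + 2L * J + length(comps) + cc
          prop <- mu_b[cc] + exp(lstep[pj]) * stats::rnorm(1)
          dl <- sum(stats::dnorm(b[cidx == cc], prop, 1, log = TRUE)) -
            sum(stats::dnorm(b[cidx == cc], mu_b[cc], 1, log = TRUE)) +
            stats::dnorm(prop, 0, 0.5, log = TRUE) -
            stats::dnorm(mu_b[cc], 0, 0.5, log = TRUE)
          if (dl > log(stats::runif(1))) { mu_b[cc] <- prop; acc[pj] <- acc[pj] + 1 }
        }
      }
      nb <- nb + 1L
      if (it <= warmup && nb == 50L) {
        delta <- min(0.1, 1 / sqrt(it / 50))
        lstep <- lstep + ifelse(acc / 50 > 0.44, delta, -delta)
        acc[] <- 0; nb <- 0L
      }
      if (it > warmup)
        keep[it - warmup, ] <- if (fixed) kap
          else c(kap, la, b, mu_a, mu_b)
    }
    keep
  }

  draws <- lapply(seq_len(chains), function(ch)
    run_chain((seed %% 1000000L) * 1000L + ch))
  par_names <- c(paste0("kappa[", persons, "]"),
                 if (!fixed) c(paste0("log_a[", items, "]"),
                               paste0("b[", items, "]"),
                               paste0("mu_a[", comps, "]"),
                               paste0("mu_b[", comps, "]")))
  a3 <- array(NA_real_, c(iter, chains, length(par_names)),
              dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(chains)) a3[, ch, ] <- draws[[ch]]

  kd <- do.call(rbind, lapply(draws, function(m) m[, seq_len(n), drop = FALSE]))
  if (!fixed) {
    # identify the scale: standardise abilities within each draw
    kd <- t(apply(kd, 1, function(z) (z - mean(z)) / stats::sd(z)))
  }
  colnames(kd) <- persons
  ability <- data.frame(individual_id = persons,
                        mean = colMeans(kd),
                        sd = apply(kd, 2, stats::sd),
                        stringsAsFactors = FALSE)
  item_summary <- if (fixed) {
    data.frame(item_id = items, component = comp, discrimination = a_fix,
               difficulty = b_fix, stringsAsFactors = FALSE)
  } else {
    ad <- do.call(rbind, lapply(draws, function(m)
      m[, n + seq_len(J), drop = FALSE]))
    bd <- do.call(rbind, lapply(draws, function(m)
      m[, n + J + seq_len(J), drop = FALSE]))
    data.frame(item_id = items, component = comp,
               discrimination = colMeans(exp(ad)),
               difficulty = colMeans(bd), stringsAsFactors = FALSE)
  }
  structure(list(ability = ability, ability_draws = kd, items = item_summary,
                 draws_array = a3, degenerate_items = degenerate,
                 chains = chains, iter = iter, seed = seed, fixed = fixed),
            class = "irt_fit")
}

#' @export
print.irt_fit <- function(x, ...) {
  cat(sprintf("<irt_fit: %d individuals, %d items%s, %d chains x %d draws>\n",
              nrow(x$ability), nrow(x$items),
              if (x$fixed) " (fixed)" else "", x$chains, x$iter))
  invisible(x)
}

#' Extract per-individual ability posteriors for the foraging model
#'
#' Returns the data frame expected by `fit_foraging(knowledge_prior = ...)`
#' in the two-stage analysis: each interviewed individual's posterior mean
#' and sd of standardised ability, used downstream as a normal
#' measurement-error likelihood on latent knowledge.
#'
#' @param fit an `irt_fit`.
#' @return Data frame `individual_id`, `mean`, `sd`.
#' @export
knowledge_prior_from_irt <- function(fit) {
  stopifnot(inherits(fit, "irt_fit"))
  fit$ability
}
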
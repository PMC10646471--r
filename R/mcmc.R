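# Adaptive Metropolis-within-Gibbs sampler.  One univariate random-walk
# update per parameter per sweep, with per-parameter proposal scales adapted
# in batches of 50 toward 44% acceptance during warmup and frozen afterwards
# (so the kept draws target the exact posterior).  Optional "shift" moves
# propose a joint translation u[add] + eps, u[sub] - eps, used to traverse
# the scale ridge between log(alpha) and the individual random effects.
amwg_sample <- function(logf, init, warmup, iter, shift_moves = list(),
                        group_moves = list(), step0 = 0.2, seed = 1L) {
  set.seed(seed)
  p <- length(init)
  u <- init
  lstep <- rep(log(step0), p)
  lstep_s <- rep(log(step0), length(shift_moves))
  lstep_g <- rep(log(step0), length(group_moves))
  lp <- logf(u)
  if (!is.finite(lp))
    stop("initial point has non-finite log-posterior", call. = FALSE)
  keep <- matrix(NA_real_, iter, p)
  acc <- numeric(p); acc_s <- numeric(length(shift_moves))
  acc_g <- numeric(length(group_moves))
  n_batch <- 0L
  total <- warmup + iter
  for (it in seq_len(total)) {
    z <- stats::rnorm(p)
    lu <- log(stats::runif(p))
    for (j in seq_len(p)) {
      prop <- u
      prop[j] <- u[j] + exp(lstep[j]) * z[j]
      lpp <- logf(prop)
      if (lpp - lp > lu[j]) {
        u <- prop; lp <- lpp; acc[j] <- acc[j] + 1
      }
    }
    for (m in seq_along(shift_moves)) {
      mv <- shift_moves[[m]]
      eps <- exp(lstep_s[m]) * stats::rnorm(1)
      prop <- u
      if (length(mv$add)) prop[mv$add] <- prop[mv$add] + eps
      if (length(mv$sub)) prop[mv$sub] <- prop[mv$sub] - eps
      lpp <- logf(prop)
      if (lpp - lp > log(stats::runif(1))) {
        u <- prop; lp <- lpp; acc_s[m] <- acc_s[m] + 1
      }
    }
    # symmetric Jacobian-1 reparameterisation moves (e.g. move log beta and
    # compensate every random effect so each phi_i is unchanged)
    for (m in seq_along(group_moves)) {
      eps <- exp(lstep_g[m]) * stats::rnorm(1)
      prop <- group_moves[[m]](u, eps)
      if (anyNA(prop) || any(is.infinite(prop))) next  # numeric overflow: reject
      lpp <- logf(prop)
      if (lpp - lp > log(stats::runif(1))) {
        u <- prop; lp <- lpp; acc_g[m] <- acc_g[m] + 1
      }
    }
    n_batch <- n_batch + 1L
    if (it <= warmup && n_batch == 25L) {
      delta <- min(0.15, 1 / sqrt(it / 25))
      lstep <- lstep + ifelse(acc / 25 > 0.44, delta, -delta)
      if (length(shift_moves))
        lstep_s <- lstep_s + ifelse(acc_s / 25 > 0.44, delta, -delta)
      if (length(group_moves))
        lstep_g <- lstep_g + ifelse(acc_g / 25 > 0.44, delta, -delta)
      acc[] <- 0; acc_s[] <- 0; acc_g[] <- 0; n_batch <- 0L
    }
    if (it == warmup) { acc[] <- 0; acc_s[] <- 0; acc_g[] <- 0 }
    if (it > warmup) keep[it - warmup, ] <- u
  }
  list(draws = keep, accept = acc / iter, step = exp(lstep), last_lp = lp)
}

# ---- convergence diagnostics -------------------------------------------

# split chains in half along iterations; x is an iterations x chains matrix
split_chains <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[seq.int(n - h + 1L, n), , drop = FALSE])
}

# split potential-scale-reduction (Gelman-Rubin) for one parameter
split_rhat <- function(x) {
  x <- split_chains(as.matrix(x))
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (W == 0) return(if (B == 0) 1 else Inf)
  varplus <- (n - 1) / n * W + B / n
  sqrt(varplus / W)
}

# split-chain effective sample size with Geyer initial-monotone truncation
ess_mcmc <- function(x) {
  x <- split_chains(as.matrix(x))
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  s2 <- apply(x, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  varplus <- (n - 1) / n * W + if (m > 1) B / n else 0
  if (varplus == 0) return(NA_real_)
  max_lag <- n - 2L
  acov <- vapply(seq_len(m), function(j)
    stats::acf(x[, j], lag.max = max_lag, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1],
    numeric(max_lag + 1L))
  rho <- 1 - (W - rowMeans(acov)[-1]) / varplus
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  npair <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(npair)) {
    pk <- rho[2 * k - 1] + rho[2 * k]
    if (pk < 0) break
    pk <- min(pk, prev)
    tau <- tau + 2 * pk
    prev <- pk
  }
  min(m * n / tau, m * n * log10(m * n))
}

#' Convergence diagnostics for posterior draws
#'
#' Computes the split potential-scale-reduction statistic (split-Rhat) and
#' the effective sample size for every sampled parameter.  Parameters with
#' Rhat above 1.01 are flagged `"warn"`, above 1.05 `"fail"`.
#'
#' @param x a `forage_fit`/`irt_fit` object, or a 3-d array of draws with
#'   dimensions (iterations, chains, parameters).
#' @return A data.frame of class `forage_diagnostics` with columns
#'   `parameter`, `rhat`, `ess`, `flag`.
#' @export
diagnose <- function(x) {
  a <- if (is.array(x) && length(dim(x)) == 3L) x
       else if (!is.null(x$draws_array)) x$draws_array
       else stop("diagnose() needs a fit object or (iter, chain, parameter) array",
                 call. = FALSE)
  if (dim(a)[2] < 2L)
    stop("diagnostics require at least 2 chains", call. = FALSE)
  pars <- dimnames(a)[[3]]
  if (is.null(pars)) pars <- paste0("par", seq_len(dim(a)[3]))
  out <- data.frame(
    parameter = pars,
    rhat = vapply(seq_len(dim(a)[3]), function(k) split_rhat(a[, , k]), numeric(1)),
    ess = vapply(seq_len(dim(a)[3]), function(k) ess_mcmc(a[, , k]), numeric(1)),
    stringsAsFactors = FALSE)
  out$flag <- ifelse(!is.finite(out$rhat) | out$rhat > 1.05, "fail",
                     ifelse(out$rhat > 1.01, "warn", "ok"))
  class(out) <- c("forage_diagnostics", "data.frame")
  out
}
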
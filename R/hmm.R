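# 3-state Gaussian hidden Markov model on step speed and absolute turning
# angle, fitted by EM (Baum-Welch) with k-means-seeded restarts and decoded
# by Viterbi. States are labelled rest / forage / commute by their speed and
# angle means. Written directly against the bivariate-independent-Gaussian
# observation model used in the analysis.

#' Observation series for behavioural-state inference
#'
#' Pairs each interior sub-sampled fix with the speed of the step starting
#' there and the absolute relative turning angle at it.
#'
#' @param sub a `subsampled_flight` (see [subsample()]).
#' @return data.frame with `time`, `speed` (m/s), `angle` (degrees, >= 0)
#'   and `lon`, `lat` of the fix.
#' @export
hmm_observations <- function(sub) {
  m <- length(sub$time)
  if (m < 4) stop("hmm_observations: too few sub-sampled fixes")
  i <- 2:(m - 1)
  data.frame(time = sub$time[i], speed = sub$speed[i],
             angle = abs(sub$theta), lon = sub$lon[i], lat = sub$lat[i])
}

# log emission densities: n x K matrix
ghmm_logdens <- function(X, mu, sigma) {
  K <- nrow(mu)
  sapply(seq_len(K), function(s)
    stats::dnorm(X[, 1], mu[s, 1], sigma[s, 1], log = TRUE) +
    stats::dnorm(X[, 2], mu[s, 2], sigma[s, 2], log = TRUE))
}

# scaled forward-backward; returns loglik, gamma (n x K), xi-sums (K x K)
ghmm_estep <- function(logd, trans, delta) {
  n <- nrow(logd); K <- ncol(logd)
  d <- exp(logd - apply(logd, 1, max))
  dmax <- apply(logd, 1, max)
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  cscale <- numeric(n)
  a <- delta * d[1, ]
  cscale[1] <- sum(a)
  alpha[1, ] <- a / cscale[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% trans) * d[t, ]
    cscale[t] <- sum(a)
    alpha[t, ] <- a / cscale[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1)
    beta[t, ] <- (trans %*% (d[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  for (t in 1:(n - 1)) {
    x <- (alpha[t, ] %o% (d[t + 1, ] * beta[t + 1, ])) * trans / cscale[t + 1]
    xi <- xi + x
  }
  list(loglik = sum(log(cscale)) + sum(dmax), gamma = gamma, xi = xi)
}

ghmm_em_once <- function(X, mu, sigma, trans, delta, max_iter, tol, sd_floor) {
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logd <- ghmm_logdens(X, mu, sigma)
    es <- ghmm_estep(logd, trans, delta)
    g <- es$gamma
    w <- colSums(g)
    for (s in seq_len(ncol(g))) {
      mu[s, ] <- colSums(X * g[, s]) / w[s]
      sigma[s, ] <- pmax(sqrt(colSums((X - rep(mu[s, ], each = nrow(X)))^2 *
                                        g[, s]) / w[s]), sd_floor)
    }
    trans <- es$xi / rowSums(es$xi)
    delta <- g[1, ]
    delta <- delta / sum(delta)
    if (is.finite(es$loglik) && abs(es$loglik - ll_old) <
        tol * (1 + abs(es$loglik))) {
      converged <- TRUE
      ll_old <- es$loglik
      break
    }
    ll_old <- es$loglik
  }
  list(mu = mu, sigma = sigma, trans = trans, delta = delta,
       loglik = ll_old, converged = converged, iter = it)
}

#' Fit a Gaussian hidden Markov model to speed and turning angle
#'
#' EM (Baum-Welch) fit of a K-state HMM with independent Gaussian emissions
#' on step speed (m/s) and absolute relative turning angle (degrees). Each
#' restart is initialized from a k-means partition of the observations; the
#' restart with the highest log-likelihood wins. The fit is deterministic
#' given `seed`.
#'
#' @param obs data.frame with columns `speed` and `angle` (e.g. from
#'   [hmm_observations()]), or a two-column matrix.
#' @param n_states number of states, default 3.
#' @param seed integer seed for the restart stream.
#' @param n_restarts EM restarts, default 10.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param sd_floor lower bound on emission SDs, guarding degenerate
#'   zero-variance states (e.g. exactly-zero speeds at fine intervals).
#' @return object of class `state_model`: list with `mu` (K x 2 means:
#'   speed, angle), `sigma` (K x 2 SDs), `trans`, `delta`, `loglik`,
#'   `n_states`, `converged`, `seed`.
#' @export
fit_hmm <- function(obs, n_states = 3, seed = 1, n_restarts = 10,
                    max_iter = 200, tol = 1e-8, sd_floor = 1e-3) {
  X <- as.matrix(as.data.frame(obs)[, c("speed", "angle")])
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("fit_hmm: non-finite speed/angle values")
  n <- nrow(X)
  if (n < 10 * n_states)
    stop("fit_hmm: need at least ", 10 * n_states, " observations, have ", n)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  degenerate <- any(apply(X, 2, stats::sd) < sd_floor)
  if (degenerate)
    warning("fit_hmm: near-constant observation series; SD floor applied")
  Xs <- scale(X)
  Xs[, !is.finite(colSums(Xs))] <- 0
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(Xs, centers = n_states, nstart = 1),
                   error = function(e) NULL)
    cl <- if (is.null(km)) sample.int(n_states, n, replace = TRUE) else
      km$cluster
    mu <- t(sapply(seq_len(n_states), function(s)
      colMeans(X[cl == s, , drop = FALSE])))
    sigma <- t(sapply(seq_len(n_states), function(s)
      pmax(apply(X[cl == s, , drop = FALSE], 2, stats::sd), sd_floor)))
    sigma[!is.finite(sigma)] <- sd_floor
    mu <- mu + stats::rnorm(length(mu), 0, 1e-6)  # break exact restarts apart
    trans <- matrix(0.05 / (n_states - 1), n_states, n_states)
    diag(trans) <- 0.95
    delta <- rep(1 / n_states, n_states)
    fit <- tryCatch(
      ghmm_em_once(X, mu, sigma, trans, delta, max_iter, tol, sd_floor),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik) &&
        (is.null(best) || fit$loglik > best$loglik)) best <- fit
  }
  if (is.null(best))
    stop("fit_hmm: all ", n_restarts, " EM restarts failed (n = ", n,
         ", speed range ", paste(signif(range(X[, 1]), 3), collapse = "-"),
         ")")
  structure(list(n_states = n_states, mu = best$mu, sigma = best$sigma,
                 trans = best$trans, delta = best$delta,
                 loglik = best$loglik, converged = best$converged,
                 seed = seed, degenerate = degenerate),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  lab <- tryCatch(suppressWarnings(label_states(x)),
                  error = function(e) rep("?", x$n_states))
  cat(sprintf("<state_model> %d states, logLik %.1f%s\n", x$n_states,
              x$loglik, if (x$converged) "" else " (not converged)"))
  for (s in seq_len(x$n_states))
    cat(sprintf("  %s: speed %.2f +/- %.2f m/s, |angle| %.1f +/- %.1f deg\n",
                lab[s], x$mu[s, 1], x$sigma[s, 1], x$mu[s, 2], x$sigma[s, 2]))
  invisible(x)
}

#' Semantic labels for fitted states
#'
#' Labels the fitted states by their emission means: lowest mean speed is
#' `rest`, highest is `commute`, the remaining state is `forage`. A warning
#' is emitted when the forage state does not also have the largest mean
#' turning angle (the expected area-restricted-search signature), or when
#' tied speeds force the tie to be broken by angle (lower angle means
#' commute).
#'
#' @param model a `state_model`.
#' @return character vector of length `n_states` giving the label of each
#'   state index.
#' @export
label_states <- function(model) {
  stopifnot(inherits(model, "state_model"))
  if (model$n_states != 3)
    stop("label_states: semantic labels are defined for 3-state models")
  sp <- model$mu[, 1]; an <- model$mu[, 2]
  if (anyDuplicated(sp)) {
    warning("label_states: tied mean speeds; tie broken by turning angle ",
            "(lower angle -> commute)")
    ord <- order(sp, -an)  # among tied speeds the lower angle ranks faster
  } else {
    ord <- order(sp)
  }
  labels <- character(3)
  labels[ord[1]] <- "rest"
  labels[ord[3]] <- "commute"
  labels[ord[2]] <- "forage"
  if (an[labels == "forage"] < max(an))
    warning("label_states: forage state does not have the largest mean ",
            "turning angle")
  labels
}

#' Decode the most likely state sequence
#'
#' Global (Viterbi) decoding by default; per-point posterior argmax as an
#' alternative.
#'
#' @param model a `state_model`.
#' @param obs observation data.frame/matrix with `speed`, `angle`.
#' @param method `"viterbi"` or `"posterior"`.
#' @return integer vector of state indices (1..K).
#' @export
decode_states <- function(model, obs, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  X <- as.matrix(as.data.frame(obs)[, c("speed", "angle")])
  logd <- ghmm_logdens(X, model$mu, model$sigma)
  n <- nrow(logd); K <- ncol(logd)
  lt <- log(model$trans)
  if (method == "posterior") {
    es <- ghmm_estep(logd, model$trans, model$delta)
    return(max.col(es$gamma))
  }
  v <- matrix(-Inf, n, K)
  bp <- matrix(0L, n, K)
  v[1, ] <- log(model$delta) + logd[1, ]
  for (t in 2:n) {
    for (s in seq_len(K)) {
      cand <- v[t - 1, ] + lt[, s]
      bp[t, s] <- which.max(cand)
      v[t, s] <- cand[bp[t, s]] + logd[t, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (t in (n - 1):1) path[t] <- bp[t + 1, path[t + 1]]
  path
}
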
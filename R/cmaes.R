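#' Covariance matrix adaptation evolution strategy (CMA-ES)
#'
#' Minimises a black-box cost over a real vector with the canonical CMA-ES:
#' a multivariate normal search distribution whose mean, covariance (rank-1
#' plus rank-mu updates) and global step size (cumulative step-size
#' adaptation) are adapted from the ranked population of each generation.
#' The run is fully determined by `seed`.
#'
#' @param cost_fn function mapping a numeric vector of length `length(x0)`
#'   to a scalar cost; may return `Inf`/`NA` for infeasible points.
#' @param x0 initial mean.
#' @param sigma0 per-parameter initial scales (sets the initial diagonal
#'   covariance; the global step size starts at 1).
#' @param popsize candidates per generation.
#' @param max_evals evaluation budget.
#' @param seed integer RNG seed; identical seeds give bit-identical runs.
#' @param stagnation_gens,stagnation_tol stop when the relative improvement
#'   of the best cost over this many generations falls below the tolerance.
#' @return List with `x` (best point), `cost`, `evaluations`, `generations`,
#'   `converged` (stopped by stagnation rather than budget), and `seed`.
#' @export
cma_es_minimize <- function(cost_fn, x0, sigma0, popsize = 70,
                            max_evals = 8000, seed = 1,
                            stagnation_gens = 20, stagnation_tol = 1e-8) {
  n <- length(x0)
  if (popsize < 4) stop("popsize must be at least 4")
  if (!all(is.finite(x0))) stop("non-finite initial point")
  if (length(sigma0) == 1) sigma0 <- rep(sigma0, n)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  lambda <- popsize
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cs <- (mueff + 2) / (n + mueff + 5)
  ds <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  m <- as.numeric(x0)
  sigma <- 1
  C <- diag(sigma0^2)
  pc <- ps <- numeric(n)
  eig <- eigen(C, symmetric = TRUE)
  B <- eig$vectors
  D <- sqrt(pmax(eig$values, 1e-30))

  best_x <- m
  best_cost <- Inf
  evals <- 0L
  gen <- 0L
  gen_best <- numeric(0)
  converged <- FALSE

  while (evals < max_evals) {
    gen <- gen + 1L
    lam <- min(lambda, max_evals - evals)
    if (lam < 2) break
    Z <- matrix(rnorm(n * lam), n, lam)
    Y <- B %*% (D * Z)                       # N(0, C) samples
    X <- m + sigma * Y
    costs <- apply(X, 2, cost_fn)
    evals <- evals + as.integer(lam)
    bad <- !is.finite(costs)
    if (all(bad))
      stop("cost function non-finite over an entire generation (",
           lam, " candidates at sigma = ", signif(sigma, 4), ")")
    costs[bad] <- max(costs[!bad]) + seq_len(sum(bad))
    ord <- order(costs)
    if (costs[ord[1]] < best_cost) {
      best_cost <- costs[ord[1]]
      best_x <- X[, ord[1]]
    }
    gen_best <- c(gen_best, best_cost)

    sel <- ord[seq_len(min(mu, lam))]
    wsel <- w[seq_along(sel)] / sum(w[seq_along(sel)])
    ymean <- Y[, sel, drop = FALSE] %*% wsel
    m <- m + sigma * as.numeric(ymean)

    Cinv_half_y <- B %*% ((t(B) %*% ymean) / D)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinv_half_y)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * gen)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc +
      hsig * sqrt(cc * (2 - cc) * mueff) * as.numeric(ymean)
    rank_mu <- matrix(0, n, n)
    for (i in seq_along(sel))
      rank_mu <- rank_mu + wsel[i] * tcrossprod(Y[, sel[i]])
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * rank_mu
    sigma <- sigma * exp((cs / ds) * (sqrt(sum(ps^2)) / chiN - 1))

    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    B <- eig$vectors
    D <- sqrt(pmax(eig$values, 1e-30))

    if (length(gen_best) > stagnation_gens) {
      prev <- gen_best[length(gen_best) - stagnation_gens]
      rel <- (prev - best_cost) / max(abs(best_cost), 1e-12)
      if (is.finite(rel) && rel < stagnation_tol) {
        converged <- TRUE
        break
      }
    }
  }

  list(x = best_x, cost = best_cost, evaluations = evals,
       generations = gen, converged = converged, seed = seed)
}
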
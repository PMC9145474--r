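#' Gaussian-process Bayesian optimization over a bounded search space
#'
#' Black-box maximizer used for hyperparameter tuning: a Latin-hypercube
#' initial design, then a Gaussian-process surrogate (squared-exponential
#' kernel on the unit cube, fixed length-scale, small nugget for the
#' cross-validation noise) with expected-improvement acquisition maximized
#' over a fresh random candidate cloud at each iteration. Integer and
#' log-scaled dimensions are handled by transformation, so e.g. a penalty
#' searched over 1e-4..1e1 moves on log10 scale.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to maximize.
#' @param space named list; each element `list(lower=, upper=, integer=,
#'   log=)` (the last two optional, default FALSE).
#' @param n_init number of Latin-hypercube initial evaluations.
#' @param n_iter number of expected-improvement iterations after the design.
#' @param n_candidates size of the random candidate cloud per iteration.
#' @return list with `best_params` (named list), `best_value`, and `history`
#'   (data.frame of evaluated parameters and objective values).
#' @export
bayes_optimize <- function(objective, space, n_init = 10, n_iter = 30,
                           n_candidates = 512) {
  d <- length(space)
  stopifnot(d >= 1L, n_init >= 1L, n_iter >= 0L)
  nms <- names(space)

  from_unit <- function(u) {
    # u: matrix (m x d) in [0,1]^d -> list of named parameter lists
    lapply(seq_len(nrow(u)), function(i) {
      p <- lapply(seq_len(d), function(j) {
        sp <- space[[j]]
        lo <- sp$lower; hi <- sp$upper
        v <- if (isTRUE(sp$log)) {
          10^(log10(lo) + u[i, j] * (log10(hi) - log10(lo)))
        } else {
          lo + u[i, j] * (hi - lo)
        }
        if (isTRUE(sp$integer)) as.integer(round(v)) else v
      })
      names(p) <- nms
      p
    })
  }

  U <- as.matrix(lhs::randomLHS(n_init, d))
  params <- from_unit(U)
  y <- vapply(params, objective, numeric(1L))

  sqdist <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * tcrossprod(A, B), 0)
  }
  lengthscale <- 0.25
  nugget <- 1e-4

  for (it in seq_len(n_iter)) {
    ys <- (y - mean(y)) / max(sd(y), 1e-8)
    K <- exp(-0.5 * sqdist(U, U) / lengthscale^2) + diag(nugget, nrow(U))
    L <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-6, nrow(U))))
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    cand <- matrix(runif(n_candidates * d), ncol = d)
    Ks <- exp(-0.5 * sqdist(cand, U) / lengthscale^2)
    mu <- as.vector(Ks %*% alpha)
    v <- forwardsolve(t(L), t(Ks))
    s2 <- pmax(1 + nugget - colSums(v^2), 1e-12)
    s <- sqrt(s2)
    ybest <- max(ys)
    z <- (mu - ybest - 0.01) / s
    ei <- s * (z * pnorm(z) + dnorm(z))
    pick <- which.max(ei)
    U <- rbind(U, cand[pick, , drop = FALSE])
    new_par <- from_unit(cand[pick, , drop = FALSE])[[1L]]
    params[[length(params) + 1L]] <- new_par
    y <- c(y, objective(new_par))
  }

  best <- which.max(y)
  hist <- as.data.frame(do.call(rbind, lapply(params, function(p) {
    unlist(lapply(p, as.numeric))
  })))
  names(hist) <- nms
  hist$objective <- y
  list(best_params = params[[best]], best_value = y[best], history = hist)
}
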
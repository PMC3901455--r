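## Zero-truncated binomial mixture model for the pan-matrix spectrum.
##
## Let x_j in {1..G} be the number of genomes containing family j, and
## y_g the number of families with x_j = g. The model is
##     f(x) = sum_k pi_k * Binom(x; G, rho_k),
## truncated at zero: families present in no sampled genome are
## unobservable, which is exactly what allows the unseen count y_0, and
## with it the population pangenome size, to be predicted.

# run expr with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# truncated log-likelihood of spectrum weights w at support g (subset 1..G)
.binomix_loglik <- function(g, w, G, pi, rho) {
  D <- vapply(seq_along(rho),
              function(k) stats::dbinom(g, G, rho[k]), numeric(length(g)))
  D <- matrix(D, nrow = length(g))
  p0 <- sum(pi * (1 - rho)^G)
  mix <- as.vector(D %*% pi)
  if (any(mix <= 0) || p0 >= 1) return(-Inf)
  sum(w * log(mix)) - sum(w) * log(1 - p0)
}

# one EM run from a given start; spectrum given as support g, weights w
.binomix_em <- function(g, w, G, pi, rho, tol, max_iter) {
  S <- sum(w)
  K <- length(pi)
  ll <- .binomix_loglik(g, w, G, pi, rho)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    D <- matrix(vapply(seq_len(K),
                       function(k) stats::dbinom(g, G, rho[k]),
                       numeric(length(g))), nrow = length(g))
    num <- sweep(D, 2L, pi, "*")
    rs <- rowSums(num)
    resp <- num / rs                           # responsibilities, observed g
    p0k <- pi * (1 - rho)^G
    p0 <- sum(p0k)
    z <- S * p0k / (1 - p0)                    # expected unseen per component
    nk <- colSums(w * resp) + z
    pi_new <- nk / sum(nk)
    rho_new <- colSums(w * resp * g) / (G * nk)
    rho_new[!is.finite(rho_new)] <- rho[!is.finite(rho_new)]
    rho_new <- pmin(pmax(rho_new, 0), 1)
    ll_new <- .binomix_loglik(g, w, G, pi_new, rho_new)
    if (is.finite(ll) && is.finite(ll_new) && ll_new < ll - 1e-6)
      stop("EM log-likelihood decreased; this indicates a numerical problem")
    pi <- pi_new; rho <- rho_new
    trace <- c(trace, ll_new)
    if (is.finite(ll) && is.finite(ll_new) && abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  list(pi = pi, rho = rho, loglik = ll, converged = converged,
       n_iter = iter, trace = trace)
}

#' Fit a zero-truncated binomial mixture to a family spectrum
#'
#' Fits, by EM, the K-component binomial mixture
#' f(x) = sum_k pi_k Binom(x; G, rho_k) to the observed family frequency
#' spectrum y_1..y_G, truncated at x = 0 (families absent from every
#' sampled genome cannot be observed). The rho_k are the selection
#' probabilities: a family of a component with rho_k = 0.1 is present, on
#' average, in 1 out of 10 genomes. The E-step also imputes the expected
#' number of unseen families per component, which is what corrects the
#' M-step for the truncation. The best of \code{restarts} seeded random
#' initializations is returned; each run stops when the log-likelihood
#' changes by less than \code{tol} or after \code{max_iter} iterations.
#'
#' @param y spectrum: integer vector of length G where \code{y[g]} counts
#'   families present in exactly g genomes, or a \code{"panmat"}.
#' @param K number of mixture components.
#' @param restarts number of random EM initializations.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter iteration cap per restart.
#' @param seed optional integer seed; the caller's RNG stream is restored
#'   afterwards.
#'
#' @return An object of class \code{"binomix"}: list with \code{K},
#'   \code{pi}, \code{rho}, \code{loglik}, \code{G}, \code{S} (observed
#'   families), \code{y}, \code{bic}, \code{converged}, \code{n_iter} and
#'   the per-iteration log-likelihood \code{trace} of the winning run.
#'
#' @examples
#' y <- c(3, 2)          # G = 2 genomes: 3 ORFans, 2 core-ish families
#' fit <- binomix_fit(y, K = 1, seed = 1)
#' coef(fit)
#'
#' @export
binomix_fit <- function(y, K, restarts = 10L, tol = 1e-8,
                        max_iter = 1000L, seed = NULL) {
  if (inherits(y, "panmat")) y <- spectrum_summary(y)$y
  y <- as.numeric(y)
  if (any(y < 0) || any(y != round(y))) stop("spectrum counts must be non-negative integers")
  G <- length(y)
  S <- sum(y)
  if (S < 1) stop("empty spectrum: no observed families")
  if (K < 1) stop("K must be >= 1")
  g <- which(y > 0)
  w <- y[g]
  if (K > length(g))
    warning("K exceeds the number of distinct observed frequencies; ",
            "some components may collapse (pi -> 0)")
  with_seed(seed, {
    best <- NULL
    # rho spread at quantiles of x/G, jittered; pi uniform
    base_q <- stats::quantile(rep(g, w) / G,
                              probs = seq(0.05, 0.95, length.out = K),
                              names = FALSE, type = 7)
    for (r in seq_len(restarts)) {
      jit <- if (r == 1L) 0 else stats::runif(K, -0.1, 0.1)
      rho0 <- pmin(pmax(base_q + jit, 1e-3), 1)
      pi0 <- rep(1 / K, K)
      run <- .binomix_em(g, w, G, pi0, rho0, tol, max_iter)
      if (is.null(best) || run$loglik > best$loglik) best <- run
    }
    structure(list(
      K = as.integer(K), pi = best$pi, rho = best$rho,
      loglik = best$loglik, G = G, S = S, y = y,
      bic = -2 * best$loglik + (2 * K - 1) * log(S),
      converged = best$converged, n_iter = best$n_iter,
      trace = best$trace
    ), class = "binomix")
  })
}

#' Fit binomial mixtures over a range of K and select by BIC
#'
#' Fits the zero-truncated binomial mixture for every K in \code{K_range}
#' and selects the model with the smallest Bayesian Information Criterion,
#' BIC = -2 logLik + (2K - 1) log(S), where S is the number of observed
#' families; ties go to the smaller K.
#'
#' @param y spectrum vector or \code{"panmat"} (see
#'   \code{\link{binomix_fit}}).
#' @param K_range integer vector of candidate component counts.
#' @param ... passed to \code{\link{binomix_fit}}.
#' @param seed optional integer seed shared by all fits.
#'
#' @return The winning \code{"binomix"} fit, with the full BIC table
#'   attached as \code{$bic_table} (\code{data.frame(K, loglik, BIC)}) and
#'   all fits as \code{$fits}.
#'
#' @export
binomix <- function(y, K_range = 1:5, seed = NULL, ...) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) == 0L) stop("K_range is empty")
  fits <- lapply(K_range, function(k) binomix_fit(y, K = k, seed = seed, ...))
  bics <- vapply(fits, `[[`, numeric(1L), "bic")
  best <- which.min(bics)           # which.min takes the first (smallest K) tie
  fit <- fits[[best]]
  fit$bic_table <- data.frame(K = K_range,
                              loglik = vapply(fits, `[[`, numeric(1L), "loglik"),
                              BIC = bics)
  fit$fits <- fits
  fit
}

#' @export
print.binomix <- function(x, digits = 4L, ...) {
  cat("Zero-truncated binomial mixture (K =", x$K, "components)\n")
  cat("  genomes G =", x$G, "; observed families S =", x$S, "\n")
  cat("  logLik =", format(x$loglik, digits = 7), "; BIC =",
      format(x$bic, digits = 7),
      if (!x$converged) "(not converged)" else "", "\n")
  m <- rbind(pi = round(x$pi, digits), rho = round(x$rho, digits))
  colnames(m) <- paste0("comp", seq_len(x$K))
  print(m)
  invisible(x)
}

#' @exportS3Method stats::coef
coef.binomix <- function(object, ...) {
  list(pi = object$pi, rho = object$rho)
}

#' @exportS3Method stats::logLik
logLik.binomix <- function(object, ...) {
  structure(object$loglik, df = 2 * object$K - 1, nobs = object$S,
            class = "logLik")
}

#' Expected spectrum under a fitted mixture
#'
#' @param object a \code{"binomix"} fit.
#' @param ... unused.
#' @return Expected counts E(y_g) for g = 1..G under the zero-truncated
#'   fitted model, scaled to S observed families.
#' @export
fitted.binomix <- function(object, ...) {
  G <- object$G
  gg <- seq_len(G)
  D <- vapply(seq_len(object$K),
              function(k) stats::dbinom(gg, G, object$rho[k]), numeric(G))
  p0 <- sum(object$pi * (1 - object$rho)^G)
  stats::setNames(as.vector(matrix(D, nrow = G) %*% object$pi) /
                    (1 - p0) * object$S, gg)
}

#' @exportS3Method base::summary
summary.binomix <- function(object, ...) {
  print(object)
  est <- pangenome_size(object)
  print(est)
  if (!is.null(object$bic_table)) {
    cat("BIC over candidate K:\n")
    print(object$bic_table, row.names = FALSE)
  }
  invisible(object)
}

#' Population pangenome and core size from a mixture fit
#'
#' From a fitted zero-truncated binomial mixture, the probability that a
#' pangenome family is missed by all G sampled genomes is
#' p0 = sum_k pi_k (1 - rho_k)^G. The population pangenome size is then
#' estimated as N = S / (1 - p0), the predicted number of families not yet
#' seen as y0 = N p0 (so N = S + y0), and the population core -- families
#' expected to be present in every one of G genomes -- as
#' N sum_k pi_k rho_k^G.
#'
#' @param fit a \code{"binomix"} fit.
#'
#' @return An object of class \code{"pangenome_estimate"}: list with
#'   \code{p0}, \code{N_hat}, \code{y0_hat}, \code{core_hat}, \code{S},
#'   \code{G}.
#'
#' @export
pangenome_size <- function(fit) {
  stopifnot(inherits(fit, "binomix"))
  p0 <- sum(fit$pi * (1 - fit$rho)^fit$G)
  if (p0 >= 1 - 1e-12)
    stop("estimated zero-class probability is ~1; pangenome size is unidentifiable")
  N <- fit$S / (1 - p0)
  structure(list(p0 = p0, N_hat = N, y0_hat = N * p0,
                 core_hat = N * sum(fit$pi * fit$rho^fit$G),
                 S = fit$S, G = fit$G),
            class = "pangenome_estimate")
}

#' @export
print.pangenome_estimate <- function(x, ...) {
  cat("Population pangenome estimate:\n")
  cat(sprintf("  observed families S        = %d\n", as.integer(x$S)))
  cat(sprintf("  predicted unseen y0        = %.1f\n", x$y0_hat))
  cat(sprintf("  pangenome size N           = %.1f\n", x$N_hat))
  cat(sprintf("  population core            = %.1f\n", x$core_hat))
  cat(sprintf("  sample coverage S/N        = %.3f\n", x$S / x$N_hat))
  invisible(x)
}

#' Expected overlap between m genomes
#'
#' The expected number of families in one genome is E1 = N sum_k rho_k
#' pi_k, and the expected number found simultaneously in m independent
#' genomes is N sum_k rho_k^m pi_k; their ratio, in which the pangenome
#' size N cancels, is the expected overlap. For a single component it
#' reduces to rho^(m-1).
#'
#' @param fit a \code{"binomix"} fit.
#' @param m number of genomes, >= 2.
#'
#' @return The expected overlap, a number in \code{(0, 1]}.
#'
#' @export
expected_overlap <- function(fit, m = 2L) {
  stopifnot(inherits(fit, "binomix"), m >= 2)
  sum(fit$pi * fit$rho^m) / sum(fit$pi * fit$rho)
}

#' Bagging interval for the pangenome size estimate
#'
#' Resamples the G genomes (rows of the pan-matrix) with replacement B
#' times; each replicate rebuilds the spectrum from the resampled rows
#' (families absent from every sampled row drop out), refits the mixture at
#' a fixed K and records the pangenome size estimate. The empirical 5% and
#' 95% quantiles of the replicates give a 90% uncertainty interval.
#'
#' @param pm a \code{"panmat"}.
#' @param K number of mixture components for every refit.
#' @param B number of bootstrap replicates.
#' @param seed integer seed; results are reproducible given the seed.
#' @param restarts EM restarts per replicate (fewer than the default fit,
#'   for speed).
#'
#' @return A list with \code{N_hat} (vector of replicate estimates),
#'   \code{quantiles} (named 5%/95%), and \code{n_failed}.
#'
#' @export
bag_estimate <- function(pm, K, B = 100L, seed = NULL, restarts = 3L) {
  stopifnot(B >= 2)
  G <- nrow(pm)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, B)
    N_hat <- rep(NA_real_, B)
    for (b in seq_len(B)) {
      rows <- sample.int(G, G, replace = TRUE)
      sub <- as_panmat(unclass(pm)[rows, , drop = FALSE])
      res <- tryCatch({
        fit <- binomix_fit(sub, K = K, restarts = restarts, seed = seeds[b])
        pangenome_size(fit)$N_hat
      }, error = function(e) NA_real_)
      N_hat[b] <- res
    }
    failed <- sum(is.na(N_hat))
    if (failed > 0L)
      warning("bag_estimate: ", failed, " replicate(s) failed and were excluded")
    ok <- N_hat[!is.na(N_hat)]
    list(N_hat = ok,
         quantiles = stats::quantile(ok, c(0.05, 0.95), names = TRUE),
         n_failed = failed)
  })
}
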
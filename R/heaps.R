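## Heaps law analysis of pangenome openness.
##
## Arrange the G genomes in some order and let n_g be the number of new
## families contributed by genome g relative to the previous g - 1. The
## Heaps law states E(n_g) = beta * g^(-alpha). An alpha below 1 means the
## number of new families decays too slowly for the pangenome to be
## bounded: the population is open.

#' New-family counts along a genome ordering
#'
#' For a given ordering of the genomes, counts the number of families first
#' seen in each genome: n_g is the number of families present in the genome
#' at position g and absent from all earlier positions. The counts over all
#' positions (including n_1, the first genome's family count) sum to the
#' sample pangenome size M.
#'
#' @param pm a \code{"panmat"}.
#' @param order integer permutation of \code{1:G} (row order).
#'
#' @return Integer vector n_1..n_G.
#'
#' @export
new_family_counts <- function(pm, order = seq_len(nrow(pm))) {
  G <- nrow(pm)
  if (length(order) != G || !setequal(order, seq_len(G)))
    stop("'order' must be a permutation of 1:", G)
  p <- (unclass(pm)[order, , drop = FALSE] > 0) * 1
  first <- max.col(t(p), ties.method = "first")  # first genome per family
  tabulate(first, nbins = G)
}

#' Least-squares Heaps fit on pooled (g, n_g) points
#'
#' The fitting core behind \code{\link{fit_heaps}}: minimizes
#' sum (n_g - beta g^(-alpha))^2 over beta > 0, alpha > 0 by bounded
#' quasi-Newton on (log beta, log alpha), initialized at alpha = 1 and
#' beta = mean(n) at the smallest g. Exposed so that new-family curves
#' obtained elsewhere (or simulated) can be fitted directly.
#'
#' @param g genome positions (all >= 2).
#' @param n new-family counts, same length as \code{g}.
#'
#' @return List with \code{alpha}, \code{beta} and \code{residual_ss}.
#'
#' @export
heaps_fit_points <- function(g, n) {
  stopifnot(length(g) == length(n), all(g >= 2))
  obj <- function(par) {
    beta <- exp(par[1L]); alpha <- exp(par[2L])
    sum((n - beta * g^(-alpha))^2)
  }
  beta0 <- max(mean(n[g == min(g)]), 1e-8)
  opt <- stats::optim(c(log(beta0), log(1)), obj, method = "L-BFGS-B",
                      lower = c(-20, -20), upper = c(50, 5),
                      control = list(factr = 10))
  list(alpha = exp(opt$par[2L]), beta = exp(opt$par[1L]),
       residual_ss = opt$value)
}

#' Fit the Heaps law by permutation
#'
#' Estimates the Heaps law E(n_g) = beta g^(-alpha) from a pan-matrix by
#' repeatedly permuting the genome order, counting the new families n_g for
#' g = 2..G after each re-ordering, and fitting (alpha, beta) by least
#' squares on the pooled points of all permutations. The first genome
#' (g = 1) is excluded from the fit: the law describes new families
#' relative to previous genomes, and n_1 is simply the first genome's size
#' (its permutation mean is kept for extrapolation). An alpha below 1 calls
#' the pangenome open.
#'
#' @param pm a \code{"panmat"} with at least 3 genomes.
#' @param n_perm number of random genome orderings.
#' @param seed optional integer seed; given the seed the fit is
#'   deterministic.
#'
#' @return An object of class \code{"heaps"}: list with \code{alpha},
#'   \code{beta}, \code{open} (alpha < 1), \code{degenerate}, \code{n_perm},
#'   \code{points} (data.frame g, n pooled over permutations),
#'   \code{first_genome_mean} and \code{residual_ss}.
#'
#' @export
fit_heaps <- function(pm, n_perm = 100L, seed = NULL) {
  G <- nrow(pm)
  if (G < 3L) stop("need at least 3 genomes for a Heaps fit")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  with_seed(seed, {
    pts_g <- integer(0); pts_n <- integer(0)
    n1 <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      ng <- new_family_counts(pm, sample.int(G))
      n1[p] <- ng[1L]
      pts_g <- c(pts_g, 2:G)
      pts_n <- c(pts_n, ng[2:G])
    }
    if (all(pts_n == 0)) {
      warning("all genomes contribute zero new families; Heaps fit is degenerate")
      return(structure(list(alpha = NaN, beta = NaN, open = FALSE,
                            degenerate = TRUE, n_perm = n_perm,
                            points = data.frame(g = pts_g, n = pts_n),
                            first_genome_mean = mean(n1),
                            residual_ss = 0),
                       class = "heaps"))
    }
    ls <- heaps_fit_points(pts_g, pts_n)
    structure(list(alpha = ls$alpha, beta = ls$beta,
                   open = ls$alpha < 1, degenerate = FALSE,
                   n_perm = n_perm,
                   points = data.frame(g = pts_g, n = pts_n),
                   first_genome_mean = mean(n1),
                   residual_ss = ls$residual_ss),
              class = "heaps")
  })
}

#' @export
print.heaps <- function(x, ...) {
  cat("Heaps law fit over", x$n_perm, "genome permutations\n")
  if (x$degenerate) {
    cat("  degenerate: no new families beyond the first genome\n")
  } else {
    cat(sprintf("  alpha = %.4f, beta = %.2f\n", x$alpha, x$beta))
    cat("  pangenome:", if (x$open) "OPEN (alpha < 1)" else
      "CLOSED (alpha >= 1)", "\n")
  }
  invisible(x)
}

#' @exportS3Method stats::coef
coef.heaps <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}

#' Predicted new-family counts
#'
#' @param object a \code{"heaps"} fit.
#' @param g genome positions.
#' @param ... unused.
#' @return Expected n_g = beta g^(-alpha).
#' @export
predict.heaps <- function(object, g = 2:10, ...) {
  if (object$degenerate) return(rep(0, length(g)))
  object$beta * g^(-object$alpha)
}

#' Extrapolate the cumulative family count
#'
#' Expected cumulative number of distinct families after sequencing
#' \code{G_target} genomes: the mean first-genome size plus the Heaps law
#' contributions beta sum_{g=2..G_target} g^(-alpha). The sum is evaluated
#' directly up to 10^6 terms; beyond that a midpoint integral approximation
#' of the tail is used (relative error well below 0.1%).
#'
#' @param fit a non-degenerate \code{"heaps"} fit.
#' @param G_target number of genomes, >= 1.
#' @param first_genome_mean expected family count of a single genome;
#'   defaults to the permutation mean recorded in the fit.
#'
#' @return Expected cumulative family count.
#'
#' @export
extrapolate_heaps <- function(fit, G_target,
                              first_genome_mean = fit$first_genome_mean) {
  stopifnot(inherits(fit, "heaps"))
  if (G_target < 1) stop("G_target must be >= 1")
  if (fit$degenerate) stop("cannot extrapolate a degenerate Heaps fit")
  if (G_target == 1) return(first_genome_mean)
  a <- fit$alpha; b <- fit$beta
  direct_to <- min(G_target, 1e6)
  s <- sum((2:direct_to)^(-a))
  if (G_target > 1e6) {
    lo <- 1e6 + 1
    if (abs(1 - a) > 1e-12) {
      s <- s + ((G_target + 0.5)^(1 - a) - (lo - 0.5)^(1 - a)) / (1 - a)
    } else {
      s <- s + log((G_target + 0.5) / (lo - 0.5))
    }
  }
  first_genome_mean + b * s
}

#' Closed-population pangenome size
#'
#' When alpha exceeds 1 the Heaps series converges and the population
#' pangenome is finite; its size is the mean first-genome count plus
#' beta (zeta(alpha) - 1), with zeta the Riemann zeta function. For
#' alpha <= 1 the series diverges and the population is open (unbounded),
#' signalled by an infinite return value.
#'
#' @param fit a \code{"heaps"} fit.
#' @param first_genome_mean expected single-genome family count; defaults
#'   to the value recorded in the fit.
#'
#' @return The finite population size for alpha > 1, or \code{Inf} for an
#'   open population (alpha <= 1 or a degenerate fit with some families).
#'
#' @export
closed_population_size <- function(fit,
                                   first_genome_mean = fit$first_genome_mean) {
  stopifnot(inherits(fit, "heaps"))
  if (fit$degenerate) return(first_genome_mean)
  if (!is.finite(fit$alpha) || fit$alpha <= 1) return(Inf)
  first_genome_mean + fit$beta * (pracma::zeta(fit$alpha) - 1)
}
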
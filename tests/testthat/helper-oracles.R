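# Independent oracles and fixture builders used across the suite.

# --- literal recursive overlap elimination -------------------------------
# A deliberately naive re-statement of the elimination rule: find every
# pair of overlapping hits by double loop, and while any exists, drop the
# involved hit with the largest iEvalue (ties: shorter alignment, larger
# ali_from, lexicographically larger accession), then recurse.
oracle_resolve <- function(h) {
  n <- nrow(h)
  if (n >= 2L) {
    involved <- rep(FALSE, n)
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (h$ali_from[i] <= h$ali_to[j] && h$ali_from[j] <= h$ali_to[i])
          involved[i] <- involved[j] <- TRUE
      }
    }
    if (any(involved)) {
      idx <- which(involved)
      worse_than <- function(a, b) {
        if (h$ievalue[a] != h$ievalue[b]) return(h$ievalue[a] > h$ievalue[b])
        la <- h$ali_to[a] - h$ali_from[a]
        lb <- h$ali_to[b] - h$ali_from[b]
        if (la != lb) return(la < lb)
        if (h$ali_from[a] != h$ali_from[b])
          return(h$ali_from[a] > h$ali_from[b])
        h$accession[a] > h$accession[b]
      }
      worst <- idx[1L]
      for (i in idx[-1L]) if (worse_than(i, worst)) worst <- i
      return(oracle_resolve(h[-worst, , drop = FALSE]))
    }
  }
  h <- h[order(h$ali_from, h$ali_to), , drop = FALSE]
  rownames(h) <- NULL
  h
}

random_hitset <- function(n, positions = 1:60) {
  from <- sample(positions, n, replace = TRUE)
  len <- sample(1:30, n, replace = TRUE)
  data.frame(query = "p1",
             accession = sample(sprintf("PF%05d.%d", 1:4, 1), n,
                                replace = TRUE),
             # coarse iEvalue grid so that ties actually occur
             ievalue = sample(c(1e-20, 1e-10, 1e-5), n, replace = TRUE),
             score = 50, ali_from = from, ali_to = from + len - 1L,
             env_from = from, env_to = from + len - 1L,
             stringsAsFactors = FALSE)
}

# --- grid-search maximization of the truncated likelihood ----------------
trunc_loglik <- function(g, w, G, pi, rho) {
  p0 <- sum(pi * (1 - rho)^G)
  mix <- sapply(g, function(x) sum(pi * dbinom(x, G, rho)))
  sum(w * log(mix)) - sum(w) * log(1 - p0)
}

grid_oracle_k1 <- function(y, n_grid = 200L) {
  G <- length(y)
  g <- which(y > 0); w <- y[g]
  rhos <- seq(1 / n_grid, 1, length.out = n_grid)
  ll <- vapply(rhos, function(r) trunc_loglik(g, w, G, 1, r), numeric(1L))
  list(rho = rhos[which.max(ll)], loglik = max(ll))
}

grid_oracle_k2 <- function(y, n_rho = 100L, n_pi = 49L) {
  G <- length(y)
  g <- which(y > 0); w <- y[g]
  rhos <- seq(1 / n_rho, 1, length.out = n_rho)
  pis <- seq(0.02, 0.98, length.out = n_pi)
  d <- sapply(rhos, function(r) dbinom(g, G, r))       # |g| x n_rho
  d <- matrix(d, nrow = length(g))
  z <- (1 - rhos)^G
  best <- -Inf
  for (p in pis) {
    p0 <- outer(p * z, (1 - p) * z, "+")
    llw <- matrix(0, n_rho, n_rho)
    for (i in seq_along(g)) {
      mix <- outer(p * d[i, ], (1 - p) * d[i, ], "+")
      llw <- llw + w[i] * log(mix)
    }
    llw <- llw - sum(w) * log(1 - p0)
    best <- max(best, max(llw, na.rm = TRUE))
  }
  best
}

# --- misc ----------------------------------------------------------------
# small presence pan-matrix with given rows
pm_from_rows <- function(...) {
  as_panmat(rbind(...))
}

# a two-protein domtblout fixture written to a temp file
write_domtbl_fixture <- function(lines, path = tempfile(fileext = ".txt")) {
  writeLines(lines, path)
  path
}

domtbl_line <- function(acc, query, iev, from, to, score = 55.0) {
  paste(sub("\\..*$", "", acc), acc, "200", query, "-", "250",
        format(iev / 10, digits = 3), "60.1", "0.1", "1", "1",
        format(iev / 100, digits = 3), format(iev, digits = 3),
        format(score, nsmall = 1), "0.1", "1", to - from + 1, from, to,
        max(1, from - 2), to + 2, "0.95", "some description text")
}
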
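# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive (enumeration, O(M^3) loops) and
# shares no code with the package internals it checks.

# Minimum-cost assignment by exhaustive search over all K! permutations.
brute_force_assignment <- function(cost) {
  K <- nrow(cost)
  perms <- gtools_permutations(K)
  best <- Inf
  best_perm <- NULL
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    tot <- sum(cost[cbind(seq_len(K), p)])
    if (tot < best - 1e-12) {
      best <- tot
      best_perm <- p
    }
  }
  list(cost = best, permutation = best_perm)
}

# all permutations of 1..n as rows (recursive, no package dependency)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Naive O(M^3) agglomeration with the Lance-Williams Ward update applied to
# the supplied dissimilarity matrix as-is ("ward.D" convention). Returns the
# merge heights and, at each step, the set of leaves in the newly merged
# cluster.
naive_ward <- function(D) {
  M <- nrow(D)
  active <- as.list(seq_len(M))
  sizes <- rep(1L, M)
  d <- D
  heights <- numeric(M - 1L)
  merged_sets <- vector("list", M - 1L)
  alive <- rep(TRUE, length(active))
  for (step in seq_len(M - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L
    idx <- which(alive)
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        i <- idx[b]; j <- idx[a]  # i < j scan order; ties keep first found
        if (d[i, j] < best - 1e-12) { best <- d[i, j]; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    ni <- sizes[bi]; nj <- sizes[bj]
    new_set <- sort(c(active[[bi]], active[[bj]]))
    merged_sets[[step]] <- new_set
    # Lance-Williams Ward update against every other alive cluster
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      nk <- sizes[k]
      dn <- ((ni + nk) * d[bi, k] + (nj + nk) * d[bj, k] - nk * best) /
        (ni + nj + nk)
      d[bi, k] <- dn; d[k, bi] <- dn
    }
    sizes[bi] <- ni + nj
    active[[bi]] <- new_set
    alive[bj] <- FALSE
    d[bj, ] <- Inf; d[, bj] <- Inf
  }
  list(heights = heights, merged_sets = merged_sets)
}

# leaf sets merged at each step of an hclust tree
hclust_merged_sets <- function(tree) {
  M <- length(tree$height) + 1L
  sets <- vector("list", M - 1L)
  for (i in seq_len(M - 1L)) {
    m <- tree$merge[i, ]
    leaves <- c()
    for (x in m) {
      leaves <- c(leaves, if (x < 0) -x else sets[[x]])
    }
    sets[[i]] <- sort(leaves)
  }
  sets
}

# log of the normalizer of the subjective HMM joint by exhaustive path
# enumeration (tiny T only), with session restarts from pitil.
logz_enumerate <- function(logB, Ptil, pitil, lengths) {
  total <- 0
  t0 <- 0L
  for (L in lengths) {
    K <- ncol(logB)
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
    z <- 0
    for (i in seq_len(nrow(paths))) {
      p <- paths[i, ]
      lp <- log(pitil[p[1L]]) + logB[t0 + 1L, p[1L]]
      if (L > 1L) for (t in 2:L) {
        lp <- lp + log(Ptil[p[t - 1L], p[t]]) + logB[t0 + t, p[t]]
      }
      z <- z + exp(lp)
    }
    total <- total + log(z)
    t0 <- t0 + L
  }
  total
}

# posterior state marginals (gamma) and summed transition counts by
# enumeration, for the same subjective distribution
fb_enumerate <- function(logB, Ptil, pitil, lengths) {
  K <- ncol(logB)
  T_total <- sum(lengths)
  gamma <- matrix(0, T_total, K)
  xisum <- matrix(0, K, K)
  t0 <- 0L
  for (L in lengths) {
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), L)))
    w <- numeric(nrow(paths))
    for (i in seq_len(nrow(paths))) {
      p <- paths[i, ]
      lp <- log(pitil[p[1L]]) + logB[t0 + 1L, p[1L]]
      if (L > 1L) for (t in 2:L) {
        lp <- lp + log(Ptil[p[t - 1L], p[t]]) + logB[t0 + t, p[t]]
      }
      w[i] <- exp(lp)
    }
    w <- w / sum(w)
    for (i in seq_len(nrow(paths))) {
      p <- paths[i, ]
      for (t in seq_len(L)) gamma[t0 + t, p[t]] <- gamma[t0 + t, p[t]] + w[i]
      if (L > 1L) for (t in 2:L) {
        xisum[p[t - 1L], p[t]] <- xisum[p[t - 1L], p[t]] + w[i]
      }
    }
    t0 <- t0 + L
  }
  list(gamma = gamma, xisum = xisum)
}

# small sessioned series with reproducible content
toy_ts <- function(T_per = 60, sessions = 2, P = 3, seed = 1) {
  withr::with_seed(seed, {
    sessioned_ts(matrix(rnorm(T_per * sessions * P), ncol = P),
                 lengths = rep(T_per, sessions))
  })
}

# a hard state series (T x K indicator rows) from a path vector
hard_series <- function(path, K = max(path)) path_indicator(path, K)

# build an hmm_ensemble object directly from a list of Gamma matrices /
# covariance lists / free energies, bypassing fitting (for unit tests of
# ensemble-consuming code)
fake_ensemble <- function(gammas, fes = seq_along(gammas),
                          C_lists = NULL, base_seed = 0L) {
  K <- ncol(gammas[[1L]])
  fits <- lapply(seq_along(gammas), function(i) {
    structure(list(K = K, Gamma = gammas[[i]],
                   C = if (is.null(C_lists)) rep(list(diag(2)), K) else C_lists[[i]],
                   free_energy_trace = c(fes[i] + 1, fes[i]),
                   seed = base_seed + i - 1L, converged = TRUE),
              class = "hmm_fit")
  })
  structure(list(fits = fits, R = length(fits), base_seed = base_seed),
            class = "hmm_ensemble")
}
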
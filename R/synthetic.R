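#' Sticky transition matrix for simulation
#'
#' Diagonal entries equal `stay_prob`; the remaining mass is spread
#' uniformly over the other states, optionally perturbed by a seeded
#' Dirichlet jitter (rows always renormalized to sum to one).
#'
#' @param K number of states.
#' @param stay_prob self-transition probability, in (0, 1].
#' @param seed integer seed (used only when `jitter > 0`).
#' @param jitter nonnegative scalar; 0 (default) gives the exact uniform
#'   off-diagonal split.
#' @return K x K stochastic matrix.
#' @export
make_transition_matrix <- function(K, stay_prob, seed = 0L, jitter = 0) {
  if (stay_prob <= 0 || stay_prob > 1) stop("stay_prob must be in (0, 1]")
  if (K == 1L) return(matrix(1, 1L, 1L))
  off <- (1 - stay_prob) / (K - 1)
  A <- matrix(off, K, K)
  diag(A) <- stay_prob
  if (jitter > 0) {
    noise <- withr::with_seed(as.integer(seed),
                              matrix(rexp(K * K), K, K))
    A <- A * (1 + jitter * (noise - 1))
    A <- A / rowSums(A)
  }
  A
}

#' State covariance matrices with a separation dial
#'
#' All states share one random base covariance; each state's matrix is
#' obtained by rotating the base eigenbasis (a Cayley-transform orthogonal
#' rotation whose angle scales with `separation`) and reweighting the
#' spectrum by a factor `exp(separation * z)` with seeded standard-normal
#' `z`. The result is rescaled to unit variances, so states differ only in
#' their correlation structure -- like FC states with standardized inputs.
#' `separation = 0` returns K identical matrices; larger values give states
#' that are easier to tell apart, and hence an easier inference problem.
#'
#' @param K number of states.
#' @param P number of channels (`>= 2`).
#' @param separation nonnegative difficulty dial.
#' @param seed integer seed.
#' @param base optional P x P SPD matrix to perturb instead of a random
#'   base; passing one of a previous call's outputs builds a hierarchy of
#'   states (well-separated groups with small within-group separation),
#'   which is how inference problems with several competing, near-tied
#'   solutions are constructed.
#' @return List of K symmetric positive-definite P x P matrices with unit
#'   diagonals.
#' @export
make_state_covariances <- function(K, P, separation, seed = 0L, base = NULL) {
  if (P < 2L) stop("P must be >= 2")
  if (separation < 0) stop("separation must be >= 0")
  withr::with_seed(as.integer(seed), {
    if (is.null(base)) {
      A <- matrix(rnorm(P * P), P, P)
      base <- crossprod(A) / P + diag(P)
    } else {
      base <- as.matrix(base)
      stopifnot(nrow(base) == P, ncol(base) == P)
    }
    eg <- eigen(base, symmetric = TRUE)
    lapply(seq_len(K), function(k) {
      B <- matrix(rnorm(P * P, sd = 0.4), P, P)
      skew <- separation * (B - t(B)) / 2
      Q <- solve(diag(P) + skew, diag(P) - skew)  # Cayley: orthogonal
      w <- exp(separation * rnorm(P, sd = 0.4))
      V <- Q %*% eg$vectors
      S <- V %*% (t(V) * (eg$values * w))
      stats::cov2cor((S + t(S)) / 2)
    })
  })
}

#' Simulate sessioned Markov-switching Gaussian data
#'
#' The forward model of the FC-state HMM: a hidden sticky Markov chain over
#' K states, restarted from the initial distribution at the first time
#' point of every session (emulating recording discontinuities), emitting
#' zero-mean multivariate Gaussian observations with the active state's
#' covariance. The `separation` dial controls how distinguishable the state
#' covariances are, and thereby how variable repeated inference runs on the
#' simulated data will be.
#'
#' @param K number of states.
#' @param P number of channels.
#' @param session_lengths integer vector of session lengths (each `>= 2`).
#' @param stay_prob self-transition probability (default 0.95).
#' @param separation covariance separation dial (default 2; see
#'   [make_state_covariances()]).
#' @param seed integer seed; the simulation is fully determined by it.
#' @param initial length-K initial distribution (default uniform).
#' @param jitter transition-matrix jitter passed to
#'   [make_transition_matrix()].
#' @param covariances optional list of K SPD matrices overriding the
#'   generated state covariances (e.g. a hierarchy built with
#'   [make_state_covariances()] and its `base` argument).
#' @return List with `ts` (a [sessioned_ts()]) and `truth` (class
#'   `fc_ground_truth`): `true_transition`, `true_initial`,
#'   `true_covariances`, `true_path`, `separation`.
#' @export
#' @examples
#' sim <- simulate_fc(K = 3, P = 4, session_lengths = c(200, 200), seed = 7)
#' table(sim$truth$true_path)
simulate_fc <- function(K, P, session_lengths, stay_prob = 0.95,
                        separation = 2, seed = 0L, initial = NULL,
                        jitter = 0, covariances = NULL) {
  stopifnot(K >= 1L, all(session_lengths >= 2L))
  if (is.null(initial)) initial <- rep(1 / K, K)
  stopifnot(length(initial) == K, abs(sum(initial) - 1) < 1e-8)
  A <- make_transition_matrix(K, stay_prob, seed = seed, jitter = jitter)
  covs <- if (is.null(covariances)) {
    make_state_covariances(K, P, separation, seed = seed)
  } else {
    stopifnot(length(covariances) == K)
    covariances
  }
  chols <- lapply(covs, chol)
  T_total <- sum(session_lengths)
  withr::with_seed(as.integer(seed), {
    path <- integer(T_total)
    t0 <- 0L
    for (L in session_lengths) {
      path[t0 + 1L] <- sample.int(K, 1L, prob = initial)
      for (t in seq_len(L - 1L)) {
        path[t0 + t + 1L] <- sample.int(K, 1L, prob = A[path[t0 + t], ])
      }
      t0 <- t0 + L
    }
    X <- matrix(0, T_total, P)
    for (k in seq_len(K)) {
      idx <- which(path == k)
      if (length(idx) > 0L) {
        X[idx, ] <- matrix(rnorm(length(idx) * P), length(idx), P) %*% chols[[k]]
      }
    }
  })
  truth <- structure(
    list(true_transition = A, true_initial = initial,
         true_covariances = covs, true_path = path,
         separation = separation),
    class = "fc_ground_truth")
  list(ts = sessioned_ts(X, lengths = session_lengths), truth = truth)
}

#' One-hot indicator series of a hard state path
#'
#' @param path integer state path with values in `1..K`.
#' @param K number of states (default `max(path)`).
#' @return T x K 0/1 matrix with rows summing to 1.
#' @export
path_indicator <- function(path, K = max(path)) {
  ind <- matrix(0, length(path), K)
  ind[cbind(seq_along(path), path)] <- 1
  ind
}
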
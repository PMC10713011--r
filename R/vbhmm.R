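#' Priors for the variational Gaussian HMM
#'
#' The observation model is a zero-mean Gaussian with a full state covariance
#' (a functional-connectivity pattern), so the only observation prior is a
#' Wishart over the state precision. Transition-matrix rows and the initial
#' distribution carry Dirichlet priors; the diagonal of the transition prior
#' gets extra concentration (`dirichlet_diag`) to favor temporally sticky
#' states, as is standard for FC-state models.
#'
#' @param P number of channels.
#' @param dirichlet_diag prior Dirichlet count on self-transitions (default 10).
#' @param dirichlet_off baseline Dirichlet count for off-diagonal transitions
#'   and for the initial distribution (default 1).
#' @param wishart_nu0 prior Wishart degrees of freedom; must exceed `P - 1`
#'   (default `P + 2`, weakly informative).
#' @param wishart_scale0 P x P symmetric positive-definite prior scale (the
#'   inverse of the Wishart scale over precisions). Default: diagonal of the
#'   empirical covariance of the data the fit is given.
#' @return An object of class `hmm_priors`.
#' @export
hmm_priors <- function(P, dirichlet_diag = 10, dirichlet_off = 1,
                       wishart_nu0 = P + 2, wishart_scale0 = diag(P)) {
  stopifnot(dirichlet_diag > 0, dirichlet_off > 0, wishart_nu0 > P - 1)
  wishart_scale0 <- as.matrix(wishart_scale0)
  stopifnot(nrow(wishart_scale0) == P, ncol(wishart_scale0) == P)
  if (max(abs(wishart_scale0 - t(wishart_scale0))) > 1e-10)
    stop("wishart_scale0 must be symmetric")
  if (inherits(try(chol(wishart_scale0), silent = TRUE), "try-error"))
    stop("wishart_scale0 must be positive definite")
  structure(list(P = P, dirichlet_diag = dirichlet_diag,
                 dirichlet_off = dirichlet_off, wishart_nu0 = wishart_nu0,
                 wishart_scale0 = wishart_scale0),
            class = "hmm_priors")
}

.default_priors <- function(ts, ...) {
  P <- n_channels(ts)
  hmm_priors(P, wishart_scale0 = diag(apply(ts$data, 2L, stats::var), P), ...)
}

.prior_trans <- function(priors, K) {
  A <- matrix(priors$dirichlet_off, K, K)
  diag(A) <- priors$dirichlet_diag
  A
}

#' Random initial state responsibilities
#'
#' Each row is drawn from a symmetric Dirichlet(1) over the K states and sums
#' to one. This random starting point is the (only) source of run-to-run
#' stochasticity in the inference, whose consequences the ensemble procedures
#' address.
#'
#' @param ts a [sessioned_ts()].
#' @param K number of states (`>= 1`).
#' @param seed integer seed; the draw is fully determined by it.
#' @return T x K matrix of responsibilities.
#' @export
init_responsibilities <- function(ts, K, seed) {
  if (K < 1L) stop("K must be >= 1")
  T_total <- n_timepoints(ts)
  if (K == 1L) return(matrix(1, T_total, 1L))
  withr::with_seed(as.integer(seed), {
    g <- matrix(rexp(T_total * K), T_total, K)
    g / rowSums(g)
  })
}

# Expected transition pseudo-counts and initial counts implied by a fixed
# responsibility matrix, treating consecutive rows as independent (used only
# to seed the first M-step).
.init_counts_from_gamma <- function(ts, gamma) {
  K <- ncol(gamma)
  xisum <- matrix(0, K, K)
  init_counts <- numeric(K)
  for (s in seq_len(n_sessions(ts))) {
    rows <- ts$starts[s]:ts$ends[s]
    g <- gamma[rows, , drop = FALSE]
    L <- nrow(g)
    xisum <- xisum + crossprod(g[-L, , drop = FALSE], g[-1L, , drop = FALSE])
    init_counts <- init_counts + g[1L, ]
  }
  list(xisum = xisum, init_counts = init_counts)
}

#' Variational M-step
#'
#' Conjugate updates given responsibilities: Dirichlet counts are prior plus
#' expected counts; each state's Wishart scale is the prior scale plus the
#' responsibility-weighted scatter `sum_t gamma_tk x_t x_t'` (zero-mean model,
#' so there is no mean update) and `nu_k = nu0 + sum_t gamma_tk`. The expected
#' state covariance is reported as the inverse of the expected precision,
#' `C_k = scale_k / nu_k`.
#'
#' @param ts a [sessioned_ts()].
#' @param gamma T x K responsibilities.
#' @param xisum K x K expected transition counts.
#' @param init_counts length-K expected initial-state counts.
#' @param priors an [hmm_priors()].
#' @return A list of posterior parameters (class `hmm_posteriors`).
#' @export
m_step <- function(ts, gamma, xisum, init_counts, priors) {
  K <- ncol(gamma)
  P <- n_channels(ts)
  X <- ts$data
  N <- colSums(gamma)
  low <- which(N < 10 * P)
  if (length(low) > 0L) {
    warning("near-empty state(s) ", paste(low, collapse = ", "),
            ": total responsibility < 10 * P; posterior stays prior-dominated")
  }
  scale <- vector("list", K)
  C <- vector("list", K)
  nu <- priors$wishart_nu0 + N
  for (k in seq_len(K)) {
    Sk <- priors$wishart_scale0 + crossprod(X * gamma[, k], X)
    Sk <- (Sk + t(Sk)) / 2
    scale[[k]] <- Sk
    C[[k]] <- Sk / nu[k]
  }
  structure(
    list(K = K,
         trans_posterior = .prior_trans(priors, K) + xisum,
         init_posterior = priors$dirichlet_off + init_counts,
         nu = nu, scale = scale, C = C),
    class = "hmm_posteriors")
}

# Variational expectations used by the E-step: exp(E[log theta]),
# exp(E[log eta]), E[Lambda_k] and E[log det Lambda_k] under the Wishart
# posterior over precisions (scale parameterized as the inverse of the
# standard Wishart scale: E[Lambda] = nu * scale^{-1}).
.expectations <- function(post) {
  K <- post$K
  A <- post$trans_posterior
  Ptil <- exp(digamma(A) - digamma(rowSums(A)))
  if (K == 1L) Ptil <- matrix(1, 1L, 1L)
  a0 <- post$init_posterior
  pitil <- if (K == 1L) 1 else exp(digamma(a0) - digamma(sum(a0)))
  P <- nrow(post$scale[[1L]])
  ELambda <- vector("list", K)
  Elogdet <- numeric(K)
  for (k in seq_len(K)) {
    R <- chol(post$scale[[k]])
    inv <- chol2inv(R)
    ELambda[[k]] <- post$nu[k] * inv
    Elogdet[k] <- sum(digamma((post$nu[k] + 1 - seq_len(P)) / 2)) +
      P * log(2) - 2 * sum(log(diag(R)))
  }
  list(Ptil = Ptil, pitil = pitil, ELambda = ELambda, Elogdet = Elogdet)
}

# T x K matrix of E[log N(x_t | 0, Lambda_k^{-1})]
.log_obs <- function(ts, exps) {
  X <- ts$data
  P <- ncol(X)
  K <- length(exps$ELambda)
  logB <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    quad <- rowSums((X %*% exps$ELambda[[k]]) * X)
    logB[, k] <- 0.5 * exps$Elogdet[k] - 0.5 * quad - P / 2 * log(2 * pi)
  }
  logB
}

#' Variational E-step
#'
#' Runs the scaled forward-backward recursion independently on every session,
#' under the variational expectations of the model parameters. The first time
#' point of each session is modeled with the initial distribution, not the
#' transition matrix, and expected transition counts exclude cross-session
#' steps.
#'
#' @param ts a [sessioned_ts()].
#' @param post an `hmm_posteriors` object from [m_step()].
#' @return A list with `gamma` (T x K, rows sum to 1), `xisum` (K x K),
#'   `init_counts` (K), and `logz` (sum of log scaling constants).
#' @export
e_step <- function(ts, post) {
  exps <- .expectations(post)
  logB <- .log_obs(ts, exps)
  fb_sessions(logB, exps$Ptil, exps$pitil, ts$starts, ts$ends)
}

.lmvgamma <- function(a, P) {
  P * (P - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(P)) / 2))
}

# KL(Dirichlet(a) || Dirichlet(b)) for count vectors a, b
.kl_dirichlet <- function(a, b) {
  a0 <- sum(a); b0 <- sum(b)
  lgamma(a0) - sum(lgamma(a)) - lgamma(b0) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(a0)))
}

# KL between Wishart posteriors over precisions, parameterized by degrees of
# freedom nu and inverse scale S (so E[Lambda] = nu * S^{-1}).
.kl_wishart <- function(nu1, S1, nu0, S0) {
  P <- nrow(S1)
  R1 <- chol(S1)
  ldet1 <- 2 * sum(log(diag(R1)))
  ldet0 <- 2 * sum(log(diag(chol(S0))))
  Elogdet <- sum(digamma((nu1 + 1 - seq_len(P)) / 2)) + P * log(2) - ldet1
  lz1 <- nu1 * P / 2 * log(2) - nu1 / 2 * ldet1 + .lmvgamma(nu1 / 2, P)
  lz0 <- nu0 * P / 2 * log(2) - nu0 / 2 * ldet0 + .lmvgamma(nu0 / 2, P)
  (nu1 - nu0) / 2 * Elogdet - nu1 * P / 2 +
    nu1 / 2 * sum(S0 * chol2inv(R1)) - lz1 + lz0
}

# KL(q || prior) summed over all parameter blocks
.param_kl <- function(post, priors) {
  K <- post$K
  A0 <- .prior_trans(priors, K)
  kl <- .kl_dirichlet(post$init_posterior, rep(priors$dirichlet_off, K))
  for (k in seq_len(K)) {
    kl <- kl + .kl_dirichlet(post$trans_posterior[k, ], A0[k, ]) +
      .kl_wishart(post$nu[k], post$scale[[k]],
                  priors$wishart_nu0, priors$wishart_scale0)
  }
  kl
}

#' Variational free energy
#'
#' The negative evidence lower bound: minus the log normalizer of the
#' forward-backward recursion under the variational parameter expectations,
#' plus the KL divergence of every parameter posterior from its prior
#' (transition-matrix rows, initial distribution, and each state's Wishart).
#' Equivalently, negative expected data log-likelihood minus state-path
#' entropy plus the parameter KL terms. Lower is better; the best-ranked
#' procedure ranks runs by this quantity.
#'
#' @param ts a [sessioned_ts()].
#' @param post an `hmm_posteriors` object.
#' @param priors the [hmm_priors()] the posteriors were fit under.
#' @return A scalar free energy.
#' @export
free_energy <- function(ts, post, priors) {
  es <- e_step(ts, post)
  -es$logz + .param_kl(post, priors)
}

#' Fit a variational Gaussian HMM
#'
#' Alternates conjugate M-steps and forward-backward E-steps from a seeded
#' random responsibility initialization until the relative change in free
#' energy drops below `tol` or `max_iter` is reached. The fit is fully
#' determined by `(data, K, priors, seed, max_iter, tol)`.
#'
#' @param ts a [sessioned_ts()]; standardize it first for FC-state analysis.
#' @param K number of states.
#' @param priors an [hmm_priors()]; default is weakly informative with the
#'   prior Wishart scale set to the diagonal of the empirical covariance.
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum number of variational cycles (default 500).
#' @param tol relative free-energy change declaring convergence (default 1e-5).
#' @return An object of class `hmm_fit` with elements `K`, `Gamma` (T x K
#'   state time series), `Xi` (K x K expected transition counts),
#'   `trans_posterior`, `init_posterior`, `nu`, `scale`, `C` (K expected
#'   covariances), `free_energy_trace`, `seed`, `converged`, `priors`.
#' @export
#' @examples
#' sim <- simulate_fc(K = 2, P = 3, session_lengths = c(150, 150),
#'                    stay_prob = 0.9, separation = 2, seed = 1)
#' fit <- fit_hmm(standardize(sim$ts), K = 2, seed = 1)
#' fit$converged
fit_hmm <- function(ts, K, priors = NULL, seed = 0L, max_iter = 500L,
                    tol = 1e-5) {
  stopifnot(inherits(ts, "sessioned_ts"), K >= 1L)
  K <- as.integer(K)
  P <- n_channels(ts)
  T_total <- n_timepoints(ts)
  if (T_total < 10 * K * P) {
    warning("only ", T_total, " time points for K=", K, ", P=", P,
            "; at least ", 10 * K * P, " recommended")
  }
  if (is.null(priors)) priors <- .default_priors(ts)

  gamma <- init_responsibilities(ts, K, seed)
  cnt <- .init_counts_from_gamma(ts, gamma)
  xisum <- cnt$xisum
  init_counts <- cnt$init_counts

  trace <- numeric(0)
  converged <- FALSE
  post <- NULL
  f_old <- Inf
  for (it in seq_len(max_iter)) {
    post <- withCallingHandlers(
      m_step(ts, gamma, xisum, init_counts, priors),
      warning = function(w) {
        if (it > 1L && grepl("near-empty", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    es <- e_step(ts, post)
    gamma <- es$gamma
    xisum <- es$xisum
    init_counts <- es$init_counts
    f <- -es$logz + .param_kl(post, priors)
    if (!is.finite(f)) stop("free energy diverged at iteration ", it)
    trace <- c(trace, f)
    if (it > 1L && f > f_old + 1e-6 * max(1, abs(f_old))) {
      stop("free energy increased at iteration ", it,
           " (", f_old, " -> ", f, "): implementation fault")
    }
    if (it > 1L && abs(f - f_old) <= tol * abs(f_old)) converged <- TRUE
    f_old <- f
    if (converged) break
  }
  structure(
    list(K = K, Gamma = gamma, Xi = xisum, init_counts = init_counts,
         trans_posterior = post$trans_posterior,
         init_posterior = post$init_posterior,
         nu = post$nu, scale = post$scale, C = post$C,
         free_energy_trace = trace, seed = as.integer(seed),
         converged = converged, priors = priors),
    class = "hmm_fit")
}

#' Final free energy of a fit
#' @param fit an `hmm_fit`.
#' @return Last value of the free-energy trace.
#' @export
final_free_energy <- function(fit) {
  tail_i <- length(fit$free_energy_trace)
  fit$free_energy_trace[tail_i]
}

#' Expected transition matrix of a fit
#' @param fit an `hmm_fit` (or `hmm_posteriors`).
#' @return K x K stochastic matrix (posterior Dirichlet means; rows sum to 1).
#' @export
expected_transitions <- function(fit) {
  A <- fit$trans_posterior
  A / rowSums(A)
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf(
    "hmm_fit: K=%d states, T=%d, free energy %.2f (%s, %d iterations, seed %d)\n",
    x$K, nrow(x$Gamma), final_free_energy(x),
    if (x$converged) "converged" else "max_iter reached",
    length(x$free_energy_trace), x$seed))
  invisible(x)
}
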
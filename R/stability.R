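#' All pairwise between-run similarities of an ensemble
#'
#' One aligned similarity score per unordered pair of runs, `R(R-1)/2` in
#' total. The histogram of these scores describes how variable the
#' inference is on a given dataset.
#'
#' @param ensemble an `hmm_ensemble` with `R >= 2`.
#' @return Numeric vector of length `choose(R, 2)` with values in [0, 1],
#'   ordered as the column pairs of [utils::combn()].
#' @export
pairwise_similarities <- function(ensemble) {
  R <- length(ensemble$fits)
  if (R < 2L) stop("need at least 2 runs, got ", R)
  pairs <- combn(R, 2L)
  apply(pairs, 2L, function(ij) {
    run_similarity(ensemble$fits[[ij[1L]]]$Gamma, ensemble$fits[[ij[2L]]]$Gamma)
  })
}

#' Free-energy-sorted similarity matrix
#'
#' The run-by-run matrix of aligned similarities with runs ordered by
#' ascending final free energy, so the best-ranked run comes first. A block
#' of high similarity in the top-left corner indicates that the
#' lowest-free-energy runs agree on one solution.
#'
#' @param ensemble an `hmm_ensemble` with `R >= 2`.
#' @return List with `matrix` (R x R, symmetric, unit diagonal, rows in
#'   free-energy order) and `order` (run indices sorted by free energy).
#' @export
fe_sorted_similarity_matrix <- function(ensemble) {
  R <- length(ensemble$fits)
  if (R < 2L) stop("need at least 2 runs, got ", R)
  ord <- order(ensemble_free_energies(ensemble))
  sims <- pairwise_similarities(ensemble)
  m <- diag(1, R)
  m[t(combn(R, 2L))] <- sims
  m[t(combn(R, 2L))[, 2:1, drop = FALSE]] <- sims
  list(matrix = m[ord, ord, drop = FALSE], order = ord)
}

# Deterministic seed schedule for the repetition protocol: every
# (R, repetition) cell gets a fresh, non-overlapping block of run seeds.
.protocol_seeds <- function(base_seed, R_grid, n_repetitions) {
  offsets <- cumsum(c(0L, rep(R_grid, each = n_repetitions)))
  matrix(as.integer(base_seed) + offsets[-length(offsets)],
         nrow = n_repetitions, ncol = length(R_grid))
}

#' Repetition-based stability protocol
#'
#' For each ensemble size `R` in `R_grid` and each of `n_repetitions`
#' repetitions, fits a fresh seeded ensemble and extracts the requested
#' method's output state series: the selected run's state time series for
#' best-ranked selection (`"br"`), the cluster state series for the
#' hierarchical-clustered model (`"hc"`), or a single run for `"plain"`.
#' Between-repetition similarities (all `choose(n_repetitions, 2)` pairs,
#' scored with the same aligned-overlap similarity) summarize how stable
#' the method is at that `R`. Asking for several methods at once evaluates
#' them on the same underlying ensembles, which is both cheaper and a
#' paired comparison.
#'
#' @param ts a [sessioned_ts()].
#' @param K number of states.
#' @param method one or more of `"br"`, `"hc"`, `"plain"`.
#' @param R_grid integer vector of ensemble sizes.
#' @param n_repetitions repetitions per grid point (default 8).
#' @param base_seed integer; all run seeds derive from it.
#' @param priors,workers,... passed to [run_ensemble()].
#' @param K_c clusters for the `"hc"` method (default K).
#' @return A `stability_report` (or a named list of them when several
#'   methods are requested): list with `method`, `R_grid`, `n_repetitions`,
#'   `similarities` (list, one numeric vector per R), and `summaries`
#'   (data.frame with columns `R`, `min`, `mean`, `max`, `sd`).
#' @export
repetition_stability <- function(ts, K, method = c("br", "hc"), R_grid,
                                 n_repetitions = 8L, base_seed = 0L,
                                 priors = NULL, workers = 1L, K_c = NULL, ...) {
  method <- match.arg(method, c("br", "hc", "plain"), several.ok = TRUE)
  stopifnot(all(R_grid >= 1L), n_repetitions >= 2L)
  if (is.null(priors)) priors <- .default_priors(ts)
  seeds <- .protocol_seeds(base_seed, R_grid, n_repetitions)
  out <- lapply(method, function(m) {
    list(method = m, similarities = vector("list", length(R_grid)))
  })
  names(out) <- method
  for (iR in seq_along(R_grid)) {
    R <- R_grid[iR]
    series <- lapply(method, function(m) vector("list", n_repetitions))
    names(series) <- method
    for (rep_i in seq_len(n_repetitions)) {
      ens <- tryCatch(
        run_ensemble(ts, K, priors = priors, R = R,
                     base_seed = seeds[rep_i, iR], workers = workers, ...),
        error = function(e) {
          stop("ensemble failed at R=", R, ", repetition ", rep_i,
               " (base seed ", seeds[rep_i, iR], "): ", conditionMessage(e))
        })
      for (m in method) {
        series[[m]][[rep_i]] <- switch(
          m,
          br = select_best(ens)$Gamma,
          hc = hc_hmm(ens, K_c = if (is.null(K_c)) K else K_c)$S,
          plain = ens$fits[[1L]]$Gamma)
      }
    }
    pairs <- combn(n_repetitions, 2L)
    for (m in method) {
      out[[m]]$similarities[[iR]] <- apply(pairs, 2L, function(ij) {
        run_similarity(series[[m]][[ij[1L]]], series[[m]][[ij[2L]]])
      })
    }
  }
  reports <- lapply(out, function(o) {
    summaries <- data.frame(
      R = R_grid,
      min = vapply(o$similarities, min, numeric(1L)),
      mean = vapply(o$similarities, mean, numeric(1L)),
      max = vapply(o$similarities, max, numeric(1L)),
      sd = vapply(o$similarities, sd, numeric(1L)))
    structure(list(method = o$method, R_grid = R_grid,
                   n_repetitions = as.integer(n_repetitions),
                   similarities = o$similarities, summaries = summaries),
              class = "stability_report")
  })
  if (length(reports) == 1L) reports[[1L]] else reports
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report (%s): %d repetitions per R\n",
              x$method, x$n_repetitions))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Hard state path of a state time series
#'
#' Per-row argmax with ties broken by the lowest state index.
#'
#' @param gamma T x K state probabilities.
#' @return Integer vector of length T with values in `1..K`.
#' @export
hard_path <- function(gamma) {
  max.col(as.matrix(gamma), ties.method = "first")
}

#' Per-state dynamic metrics
#'
#' Fractional occupancy is the column mean of the (soft) state time series.
#' Lifetimes and the switching rate are computed on the hard (argmax) path,
#' per session: a visit never spans a recording discontinuity, and the
#' switching rate divides the number of hard-state changes by the number of
#' modeled transitions, `T - n_sessions`.
#'
#' @param gamma T x K state time series (rows sum to 1).
#' @param lengths session lengths summing to T (default: one session).
#' @return Object of class `state_metrics`: list with `fractional_occupancy`
#'   (length K, sums to 1), `mean_lifetime` (length K, in time points; NA for
#'   a state the hard path never visits), `switching_rate` (scalar), and
#'   `hard_path`.
#' @export
state_metrics <- function(gamma, lengths = nrow(gamma)) {
  gamma <- as.matrix(gamma)
  K <- ncol(gamma)
  T_total <- nrow(gamma)
  stopifnot(sum(lengths) == T_total)
  path <- hard_path(gamma)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  lifetimes <- vector("list", K)
  changes <- 0L
  for (s in seq_along(lengths)) {
    p <- path[starts[s]:ends[s]]
    rl <- rle(p)
    changes <- changes + length(rl$lengths) - 1L
    for (k in unique(rl$values)) {
      lifetimes[[k]] <- c(lifetimes[[k]], rl$lengths[rl$values == k])
    }
  }
  structure(
    list(fractional_occupancy = colMeans(gamma),
         mean_lifetime = vapply(lifetimes, function(v) {
           if (is.null(v)) NA_real_ else mean(v)
         }, numeric(1L)),
         switching_rate = changes / (T_total - length(lengths)),
         hard_path = path),
    class = "state_metrics")
}

#' @export
print.state_metrics <- function(x, ...) {
  d <- data.frame(state = seq_along(x$fractional_occupancy),
                  fractional_occupancy = round(x$fractional_occupancy, 4),
                  mean_lifetime = round(x$mean_lifetime, 2))
  print(d, row.names = FALSE)
  cat(sprintf("switching rate: %.4f changes per modeled transition\n",
              x$switching_rate))
  invisible(x)
}

#' Spatial correspondence between two sets of state covariances
#'
#' Pearson correlation between the vectorized upper triangles (diagonal
#' included) of paired covariance matrices, one value per aligned state
#' pair. Correlation is scale-invariant, so this compares FC patterns, not
#' magnitudes.
#'
#' @param C_list_a,C_list_b lists of K P x P covariance matrices.
#' @param pairing integer vector: state k of `C_list_a` pairs with state
#'   `pairing[k]` of `C_list_b` (default identity).
#' @return Numeric vector of K correlations.
#' @export
spatial_correspondence <- function(C_list_a, C_list_b,
                                   pairing = seq_along(C_list_a)) {
  stopifnot(length(C_list_a) == length(C_list_b),
            length(pairing) == length(C_list_a))
  vapply(seq_along(C_list_a), function(k) {
    A <- C_list_a[[k]]
    B <- C_list_b[[pairing[k]]]
    if (!all(dim(A) == dim(B))) stop("covariance shapes differ for pair ", k)
    ut <- upper.tri(A, diag = TRUE)
    cor(A[ut], B[ut])
  }, numeric(1L))
}
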
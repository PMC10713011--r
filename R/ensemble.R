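#' Run an ensemble of seeded HMM fits
#'
#' Runs the variational inference `R` times from different random
#' initializations. Run `r` uses seed `base_seed + r - 1`, so any
#' sub-ensemble is reproducible without storing the others, and the result is
#' identical for any worker count.
#'
#' @param ts a [sessioned_ts()].
#' @param K number of states.
#' @param priors an [hmm_priors()] or NULL for defaults.
#' @param R number of runs (`>= 1`).
#' @param base_seed integer; run seeds are `base_seed + 0:(R-1)`.
#' @param workers number of parallel workers (forked; numerics unchanged).
#' @param ... passed to [fit_hmm()] (`max_iter`, `tol`).
#' @return Object of class `hmm_ensemble`: list with `fits`, `R`, `base_seed`.
#' @export
run_ensemble <- function(ts, K, priors = NULL, R, base_seed = 0L,
                         workers = 1L, ...) {
  stopifnot(R >= 1L)
  if (is.null(priors)) priors <- .default_priors(ts)
  seeds <- as.integer(base_seed) + seq_len(R) - 1L
  one <- function(seed) {
    tryCatch(fit_hmm(ts, K, priors = priors, seed = seed, ...),
             error = function(e) {
               stop("fit with seed ", seed, " failed: ", conditionMessage(e))
             })
  }
  fits <- if (workers > 1L) {
    parallel::mclapply(seeds, one, mc.cores = workers)
  } else {
    lapply(seeds, one)
  }
  errs <- vapply(fits, inherits, logical(1L), "try-error")
  if (any(errs)) stop(fits[[which(errs)[1L]]])
  structure(list(fits = fits, R = R, base_seed = as.integer(base_seed)),
            class = "hmm_ensemble")
}

#' Final free energies of an ensemble
#' @param ensemble an `hmm_ensemble`.
#' @return Numeric vector of length R.
#' @export
ensemble_free_energies <- function(ensemble) {
  vapply(ensemble$fits, final_free_energy, numeric(1L))
}

#' Best-ranked selection
#'
#' Selects the run with the lowest final free energy among the ensemble's
#' runs (ties broken by lowest run index). Non-converged runs remain
#' eligible, with a warning.
#'
#' @param ensemble an `hmm_ensemble`.
#' @return The selected `hmm_fit`.
#' @export
select_best <- function(ensemble) {
  if (length(ensemble$fits) < 1L) stop("empty ensemble")
  fe <- ensemble_free_energies(ensemble)
  best <- which.min(fe)
  fit <- ensemble$fits[[best]]
  if (!fit$converged) {
    warning("selected run (seed ", fit$seed, ") stopped at max_iter without ",
            "meeting the convergence tolerance")
  }
  fit
}

#' @export
print.hmm_ensemble <- function(x, ...) {
  fe <- ensemble_free_energies(x)
  cat(sprintf("hmm_ensemble: R=%d runs (seeds %d..%d), free energy [%.2f, %.2f]\n",
              x$R, x$base_seed, x$base_seed + x$R - 1L, min(fe), max(fe)))
  invisible(x)
}
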
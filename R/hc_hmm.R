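#' Stack the state time series of an ensemble
#'
#' Concatenates the K state-probability columns of every run into one
#' T x M matrix with M = R x K columns, keeping the (run, state) provenance
#' of each column.
#'
#' @param ensemble an `hmm_ensemble`.
#' @return Object of class `state_stack`: list with `Y` (T x M), `source`
#'   (data.frame with columns `run`, `state`), `M`.
#' @export
stack_states <- function(ensemble) {
  Ts <- vapply(ensemble$fits, function(f) nrow(f$Gamma), integer(1L))
  if (length(unique(Ts)) != 1L) stop("fits have inconsistent T: ",
                                     paste(unique(Ts), collapse = ", "))
  Y <- do.call(cbind, lapply(ensemble$fits, function(f) f$Gamma))
  Ks <- vapply(ensemble$fits, function(f) f$K, integer(1L))
  source <- data.frame(run = rep(seq_along(Ks), Ks),
                       state = unlist(lapply(Ks, seq_len)))
  structure(list(Y = Y, source = source, M = ncol(Y)), class = "state_stack")
}

#' Pearson similarity and distance between stacked state time series
#'
#' `P` holds the Pearson correlation between every pair of stacked state
#' time series; the clustering distance is `D = 1 - P`. A state that never
#' activates (constant column) carries no temporal signature: its
#' correlation with every other state is set to 0 (distance 1), with a
#' warning, instead of failing the whole ensemble.
#'
#' @param stack a `state_stack`.
#' @return Object of class `state_similarity`: list with `P` and `D`
#'   (both M x M; `P` has unit diagonal, `D` zero diagonal).
#' @export
state_similarity <- function(stack) {
  Y <- stack$Y
  sds <- apply(Y, 2L, sd)
  flat <- sds == 0
  P <- suppressWarnings(cor(Y))
  if (any(flat)) {
    warning(sum(flat), " constant state time series (states that never ",
            "activate); their correlations are set to 0")
    P[flat, ] <- 0
    P[, flat] <- 0
  }
  diag(P) <- 1
  dimnames(P) <- NULL
  D <- 1 - P
  diag(D) <- 0
  structure(list(P = P, D = D), class = "state_similarity")
}

#' Ward clustering of stacked states
#'
#' Agglomerative clustering applied to the precomputed distance `D = 1 - P`
#' with Ward's linkage (the Lance-Williams Ward update applied directly to
#' the supplied dissimilarities), cut to exactly `K_c` clusters.
#'
#' @param sim a `state_similarity`.
#' @param K_c number of clusters, `1 <= K_c <= M`.
#' @return List with `assignment` (cluster label in `1..K_c` per stacked
#'   state, numbered by first appearance), `merge_table` (data.frame with
#'   columns `a`, `b`, `height`, `size`: negative entries in `a`/`b` are
#'   singleton leaves, positive ones earlier merge rows), and the `hclust`
#'   object `tree`.
#' @export
ward_cluster <- function(sim, K_c) {
  M <- nrow(sim$D)
  if (K_c < 1L || K_c > M) stop("K_c must be in [1, ", M, "], got ", K_c)
  tree <- hclust(as.dist(sim$D), method = "ward.D")
  sizes <- integer(M - 1L)
  for (i in seq_len(M - 1L)) {
    m <- tree$merge[i, ]
    sizes[i] <- sum(ifelse(m < 0, 1L, sizes[pmax(m, 0L)]))
  }
  merge_table <- data.frame(a = tree$merge[, 1L], b = tree$merge[, 2L],
                            height = tree$height, size = sizes)
  assignment <- cutree(tree, k = K_c)
  list(assignment = as.integer(assignment), merge_table = merge_table,
       tree = tree)
}

#' Fractional occupancy of a state time series column
#'
#' The average activation probability of the state over the whole dataset.
#'
#' @param y numeric vector with values in [0, 1].
#' @return Scalar in [0, 1].
#' @export
fractional_occupancy <- function(y) {
  if (any(y < -1e-12 | y > 1 + 1e-12)) stop("probabilities must lie in [0, 1]")
  mean(y)
}

#' Cluster state time series
#'
#' Each cluster's raw series is the mean of its member state time series;
#' the rows of the resulting T x K_c matrix are then rescaled to sum to one
#' at every time point, so cluster series remain interpretable as state
#' probabilities.
#'
#' @param stack a `state_stack`.
#' @param assignment cluster label per stacked state.
#' @return T x K_c matrix `S` with rows summing to 1.
#' @export
cluster_series <- function(stack, assignment) {
  K_c <- max(assignment)
  counts <- tabulate(assignment, K_c)
  if (any(counts == 0L)) stop("empty cluster: ", which(counts == 0L)[1L])
  S <- sapply(seq_len(K_c), function(i) {
    rowMeans(stack$Y[, assignment == i, drop = FALSE])
  })
  rs <- rowSums(S)
  if (any(rs <= 0)) stop("zero total probability at time point ",
                         which(rs <= 0)[1L])
  S / rs
}

#' Cluster covariance matrices
#'
#' Each cluster's covariance is the fractional-occupancy-weighted average of
#' its member states' covariance matrices, normalized by the total weight so
#' it is a convex combination (and hence symmetric positive definite when
#' the members are).
#'
#' @param assignment cluster label per stacked state.
#' @param C_list list of covariance matrices, one per stacked state.
#' @param beta fractional occupancy per stacked state (nonnegative weights).
#' @return List of K_c covariance matrices.
#' @export
cluster_covariances <- function(assignment, C_list, beta) {
  K_c <- max(assignment)
  lapply(seq_len(K_c), function(i) {
    members <- which(assignment == i)
    w <- beta[members]
    if (sum(w) <= 0) stop("cluster ", i, " has zero total occupancy")
    Q <- Reduce(`+`, Map(function(Cj, wj) wj * Cj, C_list[members], w))
    Q / sum(w)
  })
}

#' Hierarchical-clustered HMM
#'
#' Pools the R x K state time series of an ensemble of HMM runs: computes
#' pairwise Pearson correlations, clusters the states with Ward's linkage on
#' the distance 1 - correlation, and aggregates each cluster into one
#' cluster state (time series by within-cluster averaging plus row
#' rescaling; covariance by occupancy-weighted averaging). Because clusters
#' collect states that recur across runs, the aggregated series are more
#' stable across repetitions of the whole procedure than any single run.
#'
#' @param ensemble an `hmm_ensemble` (R >= 2 recommended).
#' @param K_c number of clusters; defaults to the runs' K.
#' @return Object of class `hc_hmm`: list with `assignment`, `merge_table`,
#'   `S` (T x K_c cluster state series), `Q` (K_c covariance matrices),
#'   `beta` (occupancy per stacked state), `cluster_sizes`, `source`,
#'   `K_c`, and the `state_similarity` object `sim`.
#' @export
#' @examples
#' sim <- simulate_fc(K = 2, P = 3, session_lengths = c(150, 150),
#'                    stay_prob = 0.9, separation = 2, seed = 1)
#' ens <- run_ensemble(standardize(sim$ts), K = 2, R = 3, base_seed = 1)
#' model <- hc_hmm(ens)
#' model$cluster_sizes
hc_hmm <- function(ensemble, K_c = NULL) {
  if (is.null(K_c)) K_c <- ensemble$fits[[1L]]$K
  stack <- stack_states(ensemble)
  sim <- state_similarity(stack)
  cl <- ward_cluster(sim, K_c)
  beta <- apply(stack$Y, 2L, fractional_occupancy)
  C_list <- do.call(c, lapply(ensemble$fits, function(f) f$C))
  structure(
    list(assignment = cl$assignment, merge_table = cl$merge_table,
         S = cluster_series(stack, cl$assignment),
         Q = cluster_covariances(cl$assignment, C_list, beta),
         beta = beta,
         cluster_sizes = tabulate(cl$assignment, K_c),
         source = stack$source, K_c = K_c, sim = sim),
    class = "hc_hmm")
}

#' @export
print.hc_hmm <- function(x, ...) {
  cat(sprintf("hc_hmm: %d stacked states -> %d clusters (sizes %s)\n",
              length(x$assignment), x$K_c,
              paste(x$cluster_sizes, collapse = ", ")))
  invisible(x)
}
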
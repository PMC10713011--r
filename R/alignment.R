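#' Overlap between two sets of state time series
#'
#' Entry (a, b) is the summed joint probability that state `a` of the first
#' run and state `b` of the second run are simultaneously active,
#' `sum_t Y1[t, a] * Y2[t, b]`, treating the two runs as conditionally
#' independent given the data.
#'
#' @param Y1,Y2 T x K state time series (rows sum to 1).
#' @return K x K nonnegative matrix; the total sum is at most T.
#' @export
overlap_matrix <- function(Y1, Y2) {
  Y1 <- as.matrix(Y1); Y2 <- as.matrix(Y2)
  if (!all(dim(Y1) == dim(Y2))) {
    stop("state series shapes differ: ", nrow(Y1), "x", ncol(Y1), " vs ",
         nrow(Y2), "x", ncol(Y2))
  }
  crossprod(Y1, Y2)
}

#' Align the states of two runs and score their similarity
#'
#' States are paired with the Hungarian algorithm so that the total overlap of
#' paired states is maximal (equivalently, the cost `T - sum_k overlap[k,
#' perm(k)]` is minimal). The similarity is `1 - cost / max_cost` with
#' `max_cost = T`, i.e. the summed joint probability of aligned states per
#' time point; it lies in [0, 1] and equals 1 when the two runs produce
#' identical state time series up to relabeling.
#'
#' @param Y1,Y2 T x K state time series (rows sum to 1).
#' @param max_K guard against accidental misuse with huge K (default 64).
#' @return An object of class `state_alignment`: list with `permutation`
#'   (state k of run 1 pairs with `permutation[k]` of run 2), `overlap`,
#'   `cost`, `max_cost`, `similarity`.
#' @export
#' @examples
#' Y <- diag(3)[c(1, 1, 2, 3), ]
#' align_states(Y, Y)$similarity  # 1
align_states <- function(Y1, Y2, max_K = 64L) {
  ov <- overlap_matrix(Y1, Y2)
  K <- ncol(ov)
  if (K > max_K) stop("K = ", K, " exceeds the guard max_K = ", max_K)
  T_total <- nrow(as.matrix(Y1))
  perm <- if (K == 1L) 1L else as.integer(clue::solve_LSAP(ov, maximum = TRUE))
  matched <- sum(ov[cbind(seq_len(K), perm)])
  cost <- T_total - matched
  structure(
    list(permutation = perm, overlap = ov, cost = cost,
         max_cost = T_total, similarity = 1 - cost / T_total),
    class = "state_alignment")
}

#' @export
print.state_alignment <- function(x, ...) {
  cat(sprintf("state_alignment: K=%d, similarity %.4f (cost %.2f / max %.2f)\n",
              length(x$permutation), x$similarity, x$cost, x$max_cost))
  cat("pairing:", paste(seq_along(x$permutation), x$permutation, sep = "->",
                        collapse = " "), "\n")
  invisible(x)
}

#' Between-run similarity score
#'
#' Convenience wrapper returning just the aligned similarity of
#' [align_states()].
#'
#' @inheritParams align_states
#' @return Scalar in [0, 1].
#' @export
run_similarity <- function(Y1, Y2) align_states(Y1, Y2)$similarity
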
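#' Sessioned multichannel time series
#'
#' Container for a concatenated data matrix (time points x channels) together
#' with the session structure: recordings from several sessions and subjects
#' are stacked row-wise, and the session boundaries mark discontinuities in
#' time. The boundaries matter for inference: the first time point after a
#' discontinuity is modeled with the initial state distribution rather than
#' the transition matrix.
#'
#' @param data numeric matrix, `T_total` time points by `P >= 2` channels.
#' @param lengths integer vector of session lengths (each `>= 2`), summing to
#'   `nrow(data)`.
#' @param subjects optional integer subject label per session; defaults to one
#'   subject per session.
#'
#' @return An object of class `sessioned_ts`: a list with elements `data`,
#'   `lengths`, `subjects`, and derived 1-based inclusive `starts`/`ends`.
#' @export
#' @examples
#' x <- matrix(rnorm(30), 10, 3)
#' ts <- sessioned_ts(x, lengths = c(4, 6))
#' n_sessions(ts)
sessioned_ts <- function(data, lengths = nrow(data), subjects = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 2L) stop("need at least 2 channels, got ", ncol(data))
  if (!all(is.finite(data))) stop("data contains non-finite values")
  lengths <- as.integer(lengths)
  if (any(lengths < 2L)) stop("every session must have length >= 2")
  if (sum(lengths) != nrow(data)) {
    stop("session lengths sum to ", sum(lengths), " but the matrix has ",
         nrow(data), " rows")
  }
  if (is.null(subjects)) subjects <- seq_along(lengths)
  subjects <- as.integer(subjects)
  if (length(subjects) != length(lengths)) {
    stop("one subject label per session required")
  }
  ends <- cumsum(lengths)
  structure(
    list(data = data, lengths = lengths, subjects = subjects,
         starts = ends - lengths + 1L, ends = ends),
    class = "sessioned_ts"
  )
}

#' @rdname sessioned_ts
#' @param x a `sessioned_ts` object.
#' @export
n_sessions <- function(x) length(x$lengths)

#' @rdname sessioned_ts
#' @export
n_timepoints <- function(x) nrow(x$data)

#' @rdname sessioned_ts
#' @export
n_channels <- function(x) ncol(x$data)

#' @export
print.sessioned_ts <- function(x, ...) {
  cat(sprintf(
    "sessioned_ts: %d time points x %d channels, %d session(s), %d subject(s)\n",
    n_timepoints(x), n_channels(x), n_sessions(x), length(unique(x$subjects))))
  invisible(x)
}

# sniff the delimiter of a delimited text file from its first line
.sniff_sep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl(",", line, fixed = TRUE)) "," else if (grepl("\t", line, fixed = TRUE)) "\t" else ""
}

.read_matrix <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    m <- readRDS(path)
    if (!is.matrix(m)) m <- as.matrix(m)
    return(m)
  }
  m <- as.matrix(read.table(path, sep = .sniff_sep(path), header = FALSE))
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  m
}

#' Load a sessioned time series from disk
#'
#' Reads a data matrix (delimited text with no header, one row per time point;
#' or an `.rds` array container) and a session-index file holding one session
#' length per line, optionally `length,subject`.
#'
#' @param matrix_path path to the data matrix.
#' @param session_index_path path to the session-index text file.
#' @return A validated [sessioned_ts()].
#' @export
load_timeseries <- function(matrix_path, session_index_path) {
  m <- .read_matrix(matrix_path)
  idx <- read.table(session_index_path, sep = .sniff_sep(session_index_path),
                    header = FALSE)
  lengths <- as.integer(idx[[1L]])
  subjects <- if (ncol(idx) >= 2L) as.integer(idx[[2L]]) else NULL
  sessioned_ts(m, lengths = lengths, subjects = subjects)
}

#' Write the session index of a sessioned time series
#'
#' @param ts a [sessioned_ts()].
#' @param path output path.
#' @export
write_session_index <- function(ts, path) {
  write.table(data.frame(length = ts$lengths, subject = ts$subjects),
              path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a data matrix as headerless CSV
#'
#' @param m numeric matrix.
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Standardize a sessioned time series
#'
#' Z-scores every channel within every session (mean 0, sd 1 per session and
#' channel). Standardizing per session removes session-level offsets and scale
#' differences before a group-level fit on the concatenated data.
#'
#' @param ts a [sessioned_ts()].
#' @return A `sessioned_ts` with standardized data.
#' @export
standardize <- function(ts) {
  stopifnot(inherits(ts, "sessioned_ts"))
  out <- ts$data
  for (s in seq_len(n_sessions(ts))) {
    rows <- ts$starts[s]:ts$ends[s]
    block <- ts$data[rows, , drop = FALSE]
    sds <- apply(block, 2L, sd)
    if (any(sds == 0)) {
      stop("zero-variance channel ", which(sds == 0)[1L], " in session ", s)
    }
    out[rows, ] <- scale(block)
  }
  sessioned_ts(out, lengths = ts$lengths, subjects = ts$subjects)
}

#' Write / read a state time series
#'
#' State time series are stored as CSV with one column per state
#' (`state_1 ... state_K`) and one row per time point; values are posterior
#' activation probabilities.
#'
#' @param gamma T x K matrix of state probabilities.
#' @param path output path.
#' @export
write_state_series <- function(gamma, path) {
  gamma <- as.matrix(gamma)
  if (ncol(gamma) < 1L) stop("state series must have at least one state")
  colnames(gamma) <- paste0("state_", seq_len(ncol(gamma)))
  write.table(gamma, path, sep = ",", row.names = FALSE, col.names = TRUE,
              qmethod = "double")
  invisible(path)
}

#' @rdname write_state_series
#' @export
read_state_series <- function(path) {
  m <- as.matrix(read.table(path, sep = ",", header = TRUE))
  dimnames(m) <- NULL
  m
}

#' Write / read a list of state covariance matrices
#'
#' Stored as one long-format CSV with columns `state,row,col,value`, so each
#' state's matrix is labeled and the file stays plain text.
#'
#' @param covs list of square numeric matrices (one per state).
#' @param path output path.
#' @export
write_covariances <- function(covs, path) {
  if (length(covs) < 1L) stop("need at least one covariance matrix")
  P <- nrow(covs[[1L]])
  rows <- lapply(seq_along(covs), function(k) {
    m <- covs[[k]]
    stopifnot(nrow(m) == P, ncol(m) == P)
    data.frame(state = k, row = rep(seq_len(P), P),
               col = rep(seq_len(P), each = P), value = as.vector(m))
  })
  write.table(do.call(rbind, rows), path, sep = ",", row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_covariances
#' @export
read_covariances <- function(path) {
  d <- read.table(path, sep = ",", header = TRUE)
  P <- max(d$row)
  lapply(sort(unique(d$state)), function(k) {
    dk <- d[d$state == k, ]
    m <- matrix(0, P, P)
    m[cbind(dk$row, dk$col)] <- dk$value
    m
  })
}

#' Write a structured report as JSON
#'
#' @param report a list (e.g. a stability report).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
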
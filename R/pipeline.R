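#' Stack a multistatic tensor into a signal map
#'
#' Flattens the (transmitter, receiver, time) tensor into a 2D map with one
#' row per antenna pair, transmitter-major: row `n` (1-based) holds the
#' trace of `tx = (n-1) %/% n_rx + 1`, `rx = (n-1) %% n_rx + 1`. The
#' mapping is bijective; [unstack_signals()] inverts it.
#'
#' @param tensor `n_antennas x n_antennas x n_steps` array.
#' @return `(n_antennas^2) x n_steps` matrix.
#' @export
stack_signals <- function(tensor) {
  d <- dim(tensor)
  if (length(d) != 3 || d[1] != d[2])
    stop(sprintf("expected an n x n x n_steps tensor, got %s",
                 paste(d, collapse = " x ")), call. = FALSE)
  na <- d[1]
  out <- matrix(0, na * na, d[3])
  for (tx in seq_len(na))
    out[(tx - 1) * na + seq_len(na), ] <- tensor[tx, , ]
  out
}

#' @rdname stack_signals
#' @param map Stacked `(n^2) x n_steps` matrix.
#' @export
unstack_signals <- function(map) {
  na <- sqrt(nrow(map))
  if (na != round(na))
    stop("row count is not a perfect square", call. = FALSE)
  na <- as.integer(na)
  tens <- array(0, dim = c(na, na, ncol(map)))
  for (tx in seq_len(na))
    tens[tx, , ] <- map[(tx - 1) * na + seq_len(na), ]
  tens
}

#' Downsample signal columns
#'
#' Keeps every `rate`-th column starting at column 1 (pure decimation, no
#' anti-alias filter); `method = "average"` instead averages each block of
#' `rate` consecutive columns.
#'
#' @param map Numeric matrix.
#' @param rate Positive integer; `ncol(map)` must be divisible by it.
#' @param method `"decimate"` (default) or `"average"`.
#' @return Matrix with `ncol(map) / rate` columns.
#' @export
downsample_columns <- function(map, rate, method = c("decimate", "average")) {
  method <- match.arg(method)
  rate <- as.integer(rate)
  if (rate < 1) stop("rate must be >= 1", call. = FALSE)
  if (ncol(map) %% rate != 0)
    stop(sprintf("column count %d not divisible by rate %d", ncol(map), rate),
         call. = FALSE)
  if (rate == 1) return(map)
  if (method == "decimate") {
    map[, seq(1, ncol(map), by = rate), drop = FALSE]
  } else {
    k <- ncol(map) / rate
    out <- matrix(0, nrow(map), k)
    for (q in seq_len(k))
      out[, q] <- rowMeans(map[, (q - 1) * rate + seq_len(rate), drop = FALSE])
    out
  }
}

#' Append zero padding columns
#'
#' @param map Numeric matrix.
#' @param n_cols Number of all-zero trailing columns to append (>= 0).
#' @return Padded matrix; existing values untouched.
#' @export
pad_columns <- function(map, n_cols) {
  if (n_cols < 0) stop("n_cols must be >= 0", call. = FALSE)
  if (n_cols == 0) return(map)
  cbind(map, matrix(0, nrow(map), n_cols))
}

#' Per-row min-max normalization
#'
#' Maps each row affinely onto \[0, 1\]:
#' `X'_n = (X_n - min(X_n)) / (max(X_n) - min(X_n))`. Rows that are constant
#' before normalization (where the formula is 0/0) map to all zeros.
#'
#' @param map Numeric matrix with finite values.
#' @return Matrix of the same shape, class `input_map`.
#' @export
minmax_normalize <- function(map) {
  if (!all(is.finite(map)))
    stop("non-finite values in signal map", call. = FALSE)
  lo <- apply(map, 1, min)
  hi <- apply(map, 1, max)
  rng <- hi - lo
  out <- (map - lo) / ifelse(rng > 0, rng, 1)
  out[rng == 0, ] <- 0
  class(out) <- c("input_map", class(out))
  out
}

#' Preprocess a signal tensor into a network input
#'
#' Composition of the preprocessing chain: stack the tensor into an
#' `n^2 x n_steps` map, decimate columns, append zero padding, then
#' normalize each row onto \[0, 1\]. At the default acquisition settings the
#' shape chain is 16x16x5000 -> 256x5000 -> 256x250 -> 256x256.
#'
#' @param tensor Signal tensor (`n x n x n_steps`).
#' @param rate Decimation rate (default 20).
#' @param pad Zero-padding columns (default 6).
#' @param method Downsampling method, see [downsample_columns()].
#' @return Normalized `input_map` matrix.
#' @export
preprocess_signals <- function(tensor, rate = 20, pad = 6,
                               method = "decimate") {
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("preprocess stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  m <- stage("stack", stack_signals(tensor))
  m <- stage("downsample", downsample_columns(m, rate, method))
  m <- stage("pad", pad_columns(m, pad))
  stage("normalize", minmax_normalize(m))
}
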
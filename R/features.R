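#' Extract statistical features from an accelerometer window
#'
#' Summarizes one window of tri-axial accelerometer samples into the fixed
#' 12-dimensional feature vector used by the activity classifier: mean,
#' population variance and zero-crossing rate for each axis and for the
#' magnitude `sqrt(ax^2 + ay^2 + az^2)`. The zero-crossing rate counts sign
#' changes of the mean-removed signal divided by the window duration, a
#' cheap proxy for gait periodicity.
#'
#' @param window Data frame with numeric columns `ax`, `ay`, `az`
#'   (accelerometer, g units), uniformly sampled.
#' @param sample_rate_hz Sampling rate of the window, Hz.
#' @param window_start Optional timestamp carried through to the output.
#' @return A one-row tibble with columns `<axis>_mean`, `<axis>_var`,
#'   `<axis>_zcr` for axis in `ax, ay, az, mag`, plus `window_start` and
#'   `window_length_s`.
#' @examples
#' w <- data.frame(ax = c(1, 2, 3), ay = 0, az = 1)
#' extract_features(w, sample_rate_hz = 20)
#' @export
extract_features <- function(window, sample_rate_hz = 20,
                             window_start = NA) {
  if (is.null(window) || nrow(window) == 0L) {
    abort("`window` must contain at least one sample.")
  }
  if (!all(c("ax", "ay", "az") %in% names(window))) {
    abort("`window` must have columns ax, ay, az.")
  }
  stopifnot_scalar_number(
    sample_rate_hz, "sample_rate_hz",
    min = 0, strict = TRUE
  )
  sig <- cbind(
    ax = window$ax, ay = window$ay, az = window$az,
    mag = sqrt(window$ax^2 + window$ay^2 + window$az^2)
  )
  out <- signal_features(sig, nrow(sig) / sample_rate_hz)
  as_tibble(as.list(out)) %>%
    mutate(
      window_start = window_start,
      window_length_s = nrow(sig) / sample_rate_hz
    )
}

# mean / population variance / zcr for a (samples x signals) matrix,
# returned as a named vector in canonical feature order.
signal_features <- function(sig, dur_s) {
  m <- colMeans(sig)
  v <- colMeans(sig^2) - m^2
  v <- pmax(v, 0) # guard tiny negative rounding
  zcr <- vapply(seq_len(ncol(sig)), function(j) {
    zero_crossings(sig[, j] - m[j]) / dur_s
  }, numeric(1))
  names <- as.vector(vapply(colnames(sig), function(b) {
    paste0(b, c("_mean", "_var", "_zcr"))
  }, character(3)))
  setNames(as.vector(rbind(m, v, zcr)), names)
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) > 1) sum(diff(s) != 0) else 0L
}

feature_cols <- function() {
  as.vector(vapply(c("ax", "ay", "az", "mag"), function(b) {
    paste0(b, c("_mean", "_var", "_zcr"))
  }, character(3)))
}

#' Extract features over a sensor stream in fixed windows
#'
#' Splits a fixed-rate sensor stream into consecutive non-overlapping
#' windows and extracts one feature vector per window. A trailing partial
#' window is dropped. Vectorized: suitable for day-long 1 Hz streams.
#'
#' @param stream Tibble with `timestamp`, `ax`, `ay`, `az` (other columns
#'   ignored).
#' @param window_s Window length in seconds.
#' @param sample_rate_hz Stream sampling rate, Hz.
#' @return Tibble of feature rows with `window_start` set to the first
#'   timestamp in each window.
#' @export
window_features <- function(stream, window_s = 10, sample_rate_hz = 1) {
  per <- max(1L, as.integer(round(window_s * sample_rate_hz)))
  n_win <- nrow(stream) %/% per
  if (n_win == 0L) {
    return(tibble())
  }
  n_use <- n_win * per
  sig <- list(
    ax = stream$ax[seq_len(n_use)],
    ay = stream$ay[seq_len(n_use)],
    az = stream$az[seq_len(n_use)]
  )
  sig$mag <- sqrt(sig$ax^2 + sig$ay^2 + sig$az^2)
  dur_s <- per / sample_rate_hz
  cols <- list()
  for (axis in names(sig)) {
    m <- matrix(sig[[axis]], nrow = per)
    mu <- colMeans(m)
    v <- pmax(colMeans(m^2) - mu^2, 0)
    zcr <- vapply(seq_len(n_win), function(j) {
      zero_crossings(m[, j] - mu[j]) / dur_s
    }, numeric(1))
    cols[[paste0(axis, "_mean")]] <- mu
    cols[[paste0(axis, "_var")]] <- v
    cols[[paste0(axis, "_zcr")]] <- zcr
  }
  as_tibble(cols) %>%
    mutate(
      window_start = stream$timestamp[seq(1L, n_use, by = per)],
      window_length_s = dur_s
    ) %>%
    select(all_of(feature_cols()), "window_start", "window_length_s")
}
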
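# Internal helpers shared across modules.

# Classed error so callers can catch pipeline failures specifically.
pg_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pligraph_error")))
}

#' Wrap phase angles into (-pi, pi]
#'
#' Maps arbitrary phase values onto the principal branch. The wrapped
#' difference of two instantaneous phases is what the sign operator of the
#' phase lag index acts on; the sign of an unwrapped difference is
#' meaningless for PLI.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector with every element in `(-pi, pi]`.
#' @export
wrap_phase <- function(x) {
  -(((-x + pi) %% (2 * pi)) - pi)
}

# Linear-phase FIR applied with zero net phase shift: single-pass FFT
# convolution with the group delay removed, odd-reflection padding at both
# ends to suppress edge transients. `b` must be odd-length (type I FIR).
fir_zerophase <- function(x, b) {
  nb <- length(b)
  if (nb %% 2L != 1L) pg_stop("FIR kernel must have odd length", "pg_filter_error")
  d <- (nb - 1L) %/% 2L
  n <- length(x)
  pad <- min(d, n - 1L)
  xp <- if (pad > 0L) {
    c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  } else {
    x
  }
  L <- length(xp) + nb - 1L
  nfft <- stats::nextn(L, 2L)
  Y <- stats::fft(c(xp, numeric(nfft - length(xp)))) *
    stats::fft(c(b, numeric(nfft - nb)))
  y <- Re(stats::fft(Y, inverse = TRUE)) / nfft
  y[(pad + d + 1L):(pad + d + n)]
}

# Matrix version: rows are channels. One shared kernel FFT, one mvfft per
# direction; this is what keeps whole-cohort filtering tractable.
fir_zerophase_mat <- function(X, b) {
  nb <- length(b)
  if (nb %% 2L != 1L) pg_stop("FIR kernel must have odd length", "pg_filter_error")
  d <- (nb - 1L) %/% 2L
  n <- ncol(X)
  pad <- min(d, n - 1L)
  idx_head <- if (pad > 0L) (pad + 1L):2L else integer(0)
  idx_tail <- if (pad > 0L) (n - 1L):(n - pad) else integer(0)
  XP <- cbind(2 * X[, 1L] - X[, idx_head, drop = FALSE], X,
              2 * X[, n] - X[, idx_tail, drop = FALSE])
  L <- ncol(XP) + nb - 1L
  nfft <- stats::nextn(L, 2L)
  Bf <- stats::fft(c(b, numeric(nfft - nb)))
  XF <- stats::mvfft(rbind(t(XP), matrix(0, nfft - ncol(XP), nrow(XP))))
  YF <- XF * Bf
  Yt <- Re(stats::mvfft(YF, inverse = TRUE)) / nfft
  t(Yt[(pad + d + 1L):(pad + d + n), , drop = FALSE])
}

# Analytic signal by the frequency-domain method (rows = channels).
analytic_signal_mat <- function(X) {
  n <- ncol(X)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2L:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) %/% 2L)] <- 2
  }
  XF <- stats::mvfft(t(X))
  t(stats::mvfft(XF * h, inverse = TRUE)) / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
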
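# Internal helpers shared across modules.

# largest seed handed to set.seed(); keeps derived seeds in 32-bit range
.IMAX <- 2147483646L

# cos(2 * theta) with theta in degrees of orientation
cos2d <- function(theta) cospi(theta / 90)

mod180 <- function(x) x %% 180

# absolute angular difference between two orientations, in [0, 90]
ang_diff <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}

# DFT sample frequencies (cycles per unit) for n samples spaced d apart
fft_freq <- function(n, d) {
  k <- c(seq.int(0L, floor(n / 2)), seq.int(-(ceiling(n / 2) - 1L), -1L))
  k / (n * d)
}

# Deterministic stream of child seeds. Drawing with replacement guarantees
# that the first k seeds do not depend on n, so e.g. adding subjects to a
# scenario never perturbs the data of existing subjects.
draw_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.IMAX, n, replace = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
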
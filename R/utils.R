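# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream. A `NULL` seed evaluates the code unseeded.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministic fan-out so each pipeline stage (and each session within a
#' stage) consumes an independent, reproducible substream. Result is kept
#' strictly below 2^31 - 1.
#'
#' @param seed Master integer seed.
#' @param ... Stage labels (characters or integers) hashed into the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(paste(p, collapse = ""))) else as.numeric(p)
  }))
  h <- as.numeric(seed) %% 2147483629
  for (p in parts) h <- (h * 48271 + p * 7919 + 1) %% 2147483629
  as.integer(h + 1)
}

# Column standard deviations of a matrix (denominator n - 1).
col_sds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m * m) - mu * mu, 0) * n / (n - 1))
}

# Running (moving) mean over the rows of a matrix, full windows only.
# Returns list(values = matrix of nrow = n - w + 1, centers = integer row
# indices of window centers in the original matrix).
running_mean <- function(m, w) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (w > n) stop("window longer than series")
  if (w == 1) return(list(values = m, centers = seq_len(n)))
  cs <- apply(m, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, ncol = ncol(m))
  # sum over the window ending at row k is cs[k] - cs[k - w]
  cs0 <- rbind(matrix(0, 1, ncol(cs)), cs)
  sums <- cs0[(w + 1):(n + 1), , drop = FALSE] - cs0[1:(n - w + 1), , drop = FALSE]
  centers <- seq_len(n - w + 1) + floor((w - 1) / 2)
  list(values = sums / w, centers = centers)
}

# Raised-cosine plateau of length n samples with ramps of r samples at each
# end; values in [0, 1], exactly 1 on the plateau.
smooth_plateau <- function(n, r) {
  if (n <= 0) return(numeric(0))
  r <- min(r, floor(n / 2))
  g <- rep(1, n)
  if (r > 0) {
    up <- 0.5 * (1 - cos(pi * seq_len(r) / (r + 1)))
    g[seq_len(r)] <- up
    g[n + 1 - seq_len(r)] <- up
  }
  g
}

# 1/f^a coloured Gaussian noise via spectral shaping; sd scaled to `sd`.
colored_noise <- function(n, fs, exponent = 1, sd = 1) {
  if (n <= 1 || sd == 0) return(numeric(n))
  m <- stats::nextn(n, c(2, 3))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- seq(0, m - 1) * fs / m
  f <- pmin(f, fs - f)           # two-sided frequency magnitude
  shape <- ifelse(f < 1, 1, 1 / f^(exponent / 2)) # flatten below 1 Hz
  shape[1] <- 0                  # remove DC
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / stats::sd(x) * sd
}

#' Wrap angles to (-pi, pi]
#'
#' @param phi Numeric angles, radians.
#' @return Angles wrapped to the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  # map -pi to +pi so phases lie in (-pi, pi]
  out[out <= -pi] <- pi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
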
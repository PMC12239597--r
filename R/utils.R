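# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a global seed
#'
#' Deterministic seed splitting so every randomized stage of a pipeline run
#' receives its own reproducible stream. The derived seed stays below
#' 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer global seed.
#' @param stage character stage name (hashed into the derived seed).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1L, "render")
#' derive_seed(1L, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 7919 + h) %% 2147483629 + 1)
}

# parameter error with a consistent class so tests can target it
abort_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("gearbelt_param_error", "error")))
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_param(name, " must be a finite numeric scalar")
  lo_ok <- if (allow_zero_lower) x >= lower else x > lower
  if (!lo_ok || x > upper)
    abort_param(name, " out of range: ", format(x))
  invisible(x)
}

# map angle differences into (-pi, pi]; exactly pi resolves toward +pi
wrap_to_pi <- function(d) pi - ((pi - d) %% (2 * pi))

# circular mean of angles (radians)
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# centered moving average; edges use symmetrically shrunk windows so the
# output has the same length and no phase shift
moving_average <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n < 3L) return(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

# von Mises sampler (Best & Fisher 1979); kappa = 0 falls back to uniform
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out + mu
}
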
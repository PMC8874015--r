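#' Generate reference signals with known dynamics
#'
#' Fixture generator for the dynamical regimes the network constructions
#' are meant to distinguish: a pure sinusoid, the logistic map (periodic or
#' chaotic depending on r), the Lorenz and Roessler flows (fixed-step RK4,
#' standard chaotic parameters by default), white Gaussian noise, spectral
#' 1/f pink noise, and an AR(1) process. Flows and maps discard a 1000-step
#' transient by default so output starts near the attractor. Stochastic
#' kinds require a seed; identical spec + seed gives bit-identical output.
#'
#' Defaults: logistic `r = 4`, `x0 = 0.3`; Lorenz `sigma = 10`, `rho = 28`,
#' `beta = 8/3`, `dt = 0.01`; Roessler `a = 0.2`, `b = 0.2`, `c = 5.7`,
#' `dt = 0.05`; AR(1) `phi = 0.8`, unit innovations.
#'
#' @param kind one of `"sine"`, `"logistic"`, `"lorenz"`, `"rossler"`,
#'   `"white"`, `"pink"`, `"ar1"`.
#' @param n number of samples (>= 2).
#' @param period sine period T in samples (`x_t = sin(2*pi*t/T)`).
#' @param r,x0 logistic-map rate (in (0, 4]) and initial value (in (0, 1)).
#' @param params named list overriding ODE / AR parameters (see defaults).
#' @param dt integration step for the flows.
#' @param sd innovation standard deviation for the noise kinds.
#' @param seed integer seed, mandatory for `"white"`, `"pink"`, `"ar1"`.
#' @param burn_in transient steps discarded for flows and maps.
#' @return tibble with a `time` column (1..n) and channel `x` (plus `y`,
#'   `z` for the 3-channel flows).
#' @examples
#' generate_signal("logistic", n = 100, r = 4, x0 = 0.3)
#' generate_signal("white", n = 100, seed = 7)
#' @export
generate_signal <- function(kind = c("sine", "logistic", "lorenz",
                                     "rossler", "white", "pink", "ar1"),
                            n, period = 16, r = 4, x0 = 0.3,
                            params = list(), dt = NULL, sd = 1,
                            seed = NULL, burn_in = 1000L) {
  kind <- match.arg(kind)
  n <- check_count(n, "n", min = 2L)
  stochastic <- kind %in% c("white", "pink", "ar1")
  if (stochastic && is.null(seed)) {
    stop("`seed` is mandatory for stochastic kind '", kind, "'",
         call. = FALSE)
  }
  burn <- if (kind %in% c("logistic", "lorenz", "rossler")) {
    check_count(burn_in, "burn_in", min = 0L)
  } else 0L

  out <- switch(kind,
    sine = {
      tibble::tibble(time = seq_len(n), x = sin(2 * pi * seq_len(n) / period))
    },
    logistic = {
      if (r <= 0 || r > 4) stop("`r` must be in (0, 4]", call. = FALSE)
      if (x0 <= 0 || x0 >= 1) stop("`x0` must be in (0, 1)", call. = FALSE)
      x <- numeric(n + burn)
      x[1] <- x0
      for (i in seq_len(n + burn - 1L)) x[i + 1L] <- r * x[i] * (1 - x[i])
      tibble::tibble(time = seq_len(n), x = x[burn + seq_len(n)])
    },
    lorenz = {
      p <- utils::modifyList(list(sigma = 10, rho = 28, beta = 8 / 3,
                                  init = c(1, 1, 1)), params)
      f <- function(s) c(p$sigma * (s[2] - s[1]),
                         s[1] * (p$rho - s[3]) - s[2],
                         s[1] * s[2] - p$beta * s[3])
      rk4_flow(f, p$init, n, dt %||% 0.01, burn)
    },
    rossler = {
      p <- utils::modifyList(list(a = 0.2, b = 0.2, c = 5.7,
                                  init = c(1, 1, 0)), params)
      f <- function(s) c(-s[2] - s[3],
                         s[1] + p$a * s[2],
                         p$b + s[3] * (s[1] - p$c))
      rk4_flow(f, p$init, n, dt %||% 0.05, burn)
    },
    white = withr::with_seed(seed, {
      tibble::tibble(time = seq_len(n), x = stats::rnorm(n, sd = sd))
    }),
    pink = withr::with_seed(seed, {
      tibble::tibble(time = seq_len(n), x = pink_noise(n, sd = sd))
    }),
    ar1 = withr::with_seed(seed, {
      phi <- utils::modifyList(list(phi = 0.8), params)$phi
      if (abs(phi) >= 1) stop("`phi` must satisfy |phi| < 1", call. = FALSE)
      x <- numeric(n)
      x[1] <- stats::rnorm(1, sd = sd / sqrt(1 - phi^2)) # stationary start
      for (i in seq_len(n - 1L)) {
        x[i + 1L] <- phi * x[i] + stats::rnorm(1, sd = sd)
      }
      tibble::tibble(time = seq_len(n), x = x)
    }))
  out
}

# Fixed-step 4th-order Runge-Kutta; reproducibility over accuracy at
# fixture scale.
rk4_flow <- function(f, init, n, dt, burn) {
  s <- as.numeric(init)
  keep <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n + burn)) {
    k1 <- f(s)
    k2 <- f(s + dt / 2 * k1)
    k3 <- f(s + dt / 2 * k2)
    k4 <- f(s + dt * k3)
    s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (i > burn) keep[i - burn, ] <- s
  }
  tibble::tibble(time = seq_len(n), x = keep[, 1L], y = keep[, 2L],
                 z = keep[, 3L])
}

# Spectral synthesis: white spectrum shaped by 1/sqrt(f), inverse FFT.
pink_noise <- function(n, sd = 1) {
  m <- n %/% 2L
  freqs <- seq_len(m)
  mag <- 1 / sqrt(freqs)
  phase <- stats::runif(m, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(length.out = n)
  full[2:(m + 1L)] <- spec
  if (n %% 2L == 0L) full[m + 1L] <- complex(real = mag[m] * cos(phase[m]))
  full[seq.int(n, m + 2L)] <- Conj(spec[seq_len(n - m - 1L)])
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd / stats::sd(x)
}
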
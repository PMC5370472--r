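#' Stochastic gradient descent settings
#'
#' The gain sequence is \code{gamma(k) = a / (A + k + 1)^tau} for
#' \code{k = 0 .. iterations - 1} — the standard decaying-gain law of
#' adaptive stochastic gradient optimizers, with the deterministic schedule
#' driven by the printed constants.
#'
#' @param A gain offset (default 50).
#' @param tau decay exponent in (0.5, 1] (default 0.602).
#' @param a gain numerator (default 2000).
#' @param iterations iteration count (default 1000).
#' @param seed RNG seed applied by the registration drivers before the
#'   optimization loop (the stochasticity lives in the metric's sampling).
#' @export
asgdSettings <- function(A = 50, tau = 0.602, a = 2000, iterations = 1000,
                         seed = 1) {
  stopifnot(A > 0, tau > 0.5, tau <= 1, a > 0, iterations >= 1)
  list(A = A, tau = tau, a = a, iterations = as.integer(iterations),
       seed = seed)
}

#' Minimize a cost by stochastic gradient descent with decaying gain
#'
#' Iterates \code{mu_{k+1} = mu_k - gamma(k) * grad(mu_k) / scales^2} with
#' \code{gamma(k) = a / (A + k + 1)^tau}. The cost callable may be
#' stochastic (e.g. re-drawing metric samples every evaluation); determinism
#' then comes from seeding the RNG before the loop.
#'
#' @param cost function(mu, k) returning \code{list(E = scalar, gradient =
#'   numeric like mu)}.
#' @param mu0 initial parameter vector.
#' @param settings \code{\link{asgdSettings}}.
#' @param scales optional per-parameter scale; gradients are divided by
#'   \code{scales^2} (used to balance affine matrix vs translation
#'   parameters).
#' @param tailAverage fraction of final iterations whose iterates are
#'   averaged into the returned parameters (0, the default, returns the
#'   last iterate). Averaging the tail suppresses the stationary wander
#'   a stochastic cost induces at non-vanishing gain.
#' @return list with \code{mu} (final parameters) and \code{trace}
#'   (per-iteration energy values, length \code{iterations}).
#' @export
asgdMinimize <- function(cost, mu0, settings = asgdSettings(),
                         scales = NULL, tailAverage = 0) {
  mu <- as.numeric(mu0)
  if (is.null(scales)) scales <- rep(1, length(mu))
  trace <- numeric(settings$iterations)
  nTail <- floor(settings$iterations * tailAverage)
  tailFrom <- settings$iterations - nTail   # 0-based first averaged iterate
  acc <- NULL
  for (k in seq_len(settings$iterations) - 1L) {
    res <- cost(mu, k)
    g <- as.numeric(res$gradient)
    if (any(!is.finite(g)))
      stop("non-finite gradient at iteration ", k)
    trace[k + 1] <- res$E
    gamma <- settings$a / (settings$A + k + 1)^settings$tau
    mu <- mu - gamma * g / scales^2
    if (nTail > 0 && k + 1 >= tailFrom)
      acc <- if (is.null(acc)) mu else acc + mu
  }
  if (nTail > 0) mu <- acc / (settings$iterations - tailFrom + 1)
  list(mu = mu, trace = trace)
}
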
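#' Bayesian posterior over population prevalence
#'
#' Given that k of n subjects reached within-subject significance at level
#' alpha, infers the population prevalence gamma of subjects carrying a
#' detectable effect. Each tested subject is significant with probability
#' `theta(gamma) = alpha + gamma * (1 - alpha)` (truly, at rate gamma, or
#' falsely, at rate alpha; sensitivity within carriers is treated as 1, so
#' the estimand is the prevalence of detectable effects). The likelihood is
#' `Binomial(k; n, theta)` with a uniform prior on gamma, evaluated on a
#' regular grid and normalized by the trapezoid rule.
#'
#' @param k Number of significant subjects.
#' @param n Number of tested subjects.
#' @param alpha Within-subject significance level (default 0.05).
#' @param grid_step Grid resolution on `[0, 1]` (default 1e-4).
#' @return A `prevalence_posterior`: list with `gamma` (grid), `density`,
#'   `map`, `hdi` (95%), `k`, `n`, `alpha`.
#' @export
prevalence_posterior <- function(k, n, alpha = 0.05, grid_step = 1e-4) {
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  gamma <- seq(0, 1, by = grid_step)
  theta <- alpha + gamma * (1 - alpha)
  logd <- stats::dbinom(k, n, theta, log = TRUE)
  d <- exp(logd - max(logd))
  z <- trapz(gamma, d)
  d <- d / z
  post <- structure(
    list(gamma = gamma, density = d, map = NA_real_, hdi = c(NA, NA),
         k = as.integer(k), n = as.integer(n), alpha = alpha,
         grid_step = grid_step),
    class = "prevalence_posterior"
  )
  post$map <- map_estimate(post)
  post$hdi <- hdi(post, 0.95)
  post
}

trapz <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Maximum a posteriori prevalence estimate
#'
#' Under the uniform prior the posterior mode has the closed form
#' `clamp((k/n - alpha) / (1 - alpha), 0, 1)`; the grid argmax is checked
#' against it and the closed form is returned.
#'
#' @param post A [prevalence_posterior()].
#' @return MAP estimate in `[0, 1]`.
#' @export
map_estimate <- function(post) {
  stopifnot(inherits(post, "prevalence_posterior"))
  closed <- min(max((post$k / post$n - post$alpha) / (1 - post$alpha), 0), 1)
  grid_map <- post$gamma[which.max(post$density)]
  if (abs(grid_map - closed) > post$grid_step + 1e-12) {
    warning("grid argmax deviates from the closed-form mode by more than ",
            "one grid step")
  }
  closed
}

#' Highest posterior density interval
#'
#' Shortest interval containing at least `mass` of the posterior, found by
#' descending a density water level on the grid. Boundary-touching
#' intervals are allowed (e.g. lo = 0 when the mode sits at 0).
#'
#' @param post A [prevalence_posterior()].
#' @param mass Posterior mass of the interval (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
hdi <- function(post, mass = 0.95) {
  stopifnot(inherits(post, "prevalence_posterior"))
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  g <- post$gamma
  d <- post$density
  ord <- order(d, decreasing = TRUE)
  # regular grid: each point carries grid_step of mass (half at the edges)
  w <- rep(post$grid_step, length(g))
  w[c(1, length(g))] <- post$grid_step / 2
  cum <- cumsum(d[ord] * w[ord])
  k_need <- which(cum >= mass)[1]
  if (is.na(k_need)) k_need <- length(g)
  sel <- sort(ord[seq_len(k_need)])
  c(g[sel[1]], g[sel[length(sel)]])
}

#' @export
print.prevalence_posterior <- function(x, ...) {
  cat("<prevalence_posterior> k =", x$k, "of n =", x$n,
      "significant at alpha =", x$alpha, "\n")
  cat(sprintf("  MAP = %.2f, 95%% HDI = [%.2f, %.2f]\n",
              x$map, x$hdi[1], x$hdi[2]))
  invisible(x)
}

#' @export
plot.prevalence_posterior <- function(x, ...) {
  plot(x$gamma, x$density, type = "l",
       xlab = expression(gamma), ylab = "posterior density", ...)
  graphics::abline(v = x$map, lty = 2)
  graphics::abline(v = x$hdi, lty = 3)
  invisible(x)
}
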
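#' Parameters of the analytic decision-depth model
#'
#' Bundles the scalar world of the closed-form cost-benefit model: an organism
#' perceives `n` distinct stimuli, information accrues with decision depth at
#' rate `r`, a single productive decision takes `tau` experiences to learn, and
#' the organism lives for `lifespan` learning experiences. The constant that
#' scales the number of realizable sequences is folded into `tau`, which is why
#' `tau` is real-valued rather than integer.
#'
#' @param n Number of distinct perceivable stimuli (integer, `>= 2`).
#' @param r Information-distribution rate, in `(0, 1)`. Small `r` concentrates
#'   information in the most recent stimulus; `r` close to 1 spreads it deep
#'   into the past.
#' @param tau Experiences needed to learn one productive decision (`> 0`).
#' @param lifespan Lifetime measured in learning experiences (integer, `>= 0`);
#'   the symbol `T` in the model equations.
#'
#' @return An object of class `"analytic_params"`: a list with components
#'   `n`, `r`, `tau`, `lifespan`.
#' @examples
#' p <- analytic_params(n = 12, r = 0.5, tau = 10, lifespan = 10000)
#' lifetime_utility(p, depth = 1)
#' @export
analytic_params <- function(n, r, tau, lifespan) {
  if (!is.numeric(n) || length(n) != 1L || n < 2 || n != floor(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("`tau` must be a positive number", call. = FALSE)
  }
  if (!is.numeric(lifespan) || length(lifespan) != 1L || lifespan < 0 ||
      lifespan != floor(lifespan)) {
    stop("`lifespan` must be a single non-negative integer", call. = FALSE)
  }
  structure(list(n = as.numeric(n), r = r, tau = tau,
                 lifespan = as.numeric(lifespan)),
            class = "analytic_params")
}

#' @export
print.analytic_params <- function(x, ...) {
  cat("Analytic decision-depth parameters\n")
  cat(sprintf("  n (stimuli):        %g\n", x$n))
  cat(sprintf("  r (info rate):      %g\n", x$r))
  cat(sprintf("  tau (learn cost):   %g\n", x$tau))
  cat(sprintf("  lifespan T (steps): %g\n", x$lifespan))
  invisible(x)
}

as_analytic_params <- function(params) {
  if (inherits(params, "analytic_params")) return(params)
  if (is.list(params) && all(c("n", "r", "tau", "lifespan") %in% names(params))) {
    return(analytic_params(params$n, params$r, params$tau, params$lifespan))
  }
  stop("`params` must be an `analytic_params` object", call. = FALSE)
}

check_depth <- function(depth, allow_zero = FALSE) {
  lo <- if (allow_zero) 0 else 1
  if (!is.numeric(depth) || length(depth) != 1L || depth < lo ||
      depth != floor(depth)) {
    stop(sprintf("`depth` must be a single integer >= %d", lo), call. = FALSE)
  }
  as.numeric(depth)
}

#' Fraction of histories that support a productive decision
#'
#' `f(l) = 1 - r^l`: the fraction of length-`depth` stimulus histories in the
#' environment that contain enough information to choose the productive
#' response. It is 0 at depth 0, increases monotonically with depth, and
#' approaches 1; the rate `r` controls how quickly additional depth pays off.
#'
#' @param depth Decision depth `l` (integer, `>= 0`).
#' @param r Information-distribution rate in `(0, 1)`.
#' @return A number in `[0, 1)`.
#' @examples
#' fraction_informative(1, r = 0.5) # 0.5
#' fraction_informative(2, r = 0.5) # 0.75
#' @export
fraction_informative <- function(depth, r) {
  depth <- check_depth(depth, allow_zero = TRUE)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("`r` must lie strictly between 0 and 1", call. = FALSE)
  }
  1 - r^depth
}

#' Number of distinct stimulus sequences of a given depth
#'
#' With sequences formed by drawing from `n` stimuli with replacement there are
#' `n^depth` distinct histories of length `depth`. The value is computed by
#' exact integer multiplication; the full decimal expansion is attached as
#' attribute `"digits"` so that counts beyond the range where doubles are exact
#' (above 2^53) can still be inspected exactly.
#'
#' @param n Alphabet size (integer, `>= 1`).
#' @param depth Sequence length `l` (integer, `>= 1`).
#' @return The count `n^depth` as a number, with the exact decimal expansion in
#'   attribute `"digits"`.
#' @examples
#' num_sequences(12, 2)  # 144
#' attr(num_sequences(10000, 8), "digits")
#' @export
num_sequences <- function(n, depth) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  depth <- check_depth(depth)
  digits <- big_power(as.integer(n), as.integer(depth))
  value <- n^depth
  structure(value, digits = digits)
}

# exact n^k in decimal, as a digit string; little big-integer in base 1e4
big_power <- function(n, k) {
  base <- 10000L
  chunks <- integer(0)
  m <- n
  while (m > 0L) {
    chunks <- c(chunks, m %% base)
    m <- m %/% base
  }
  acc <- 1L  # little-endian chunk vector
  for (i in seq_len(k)) {
    prod <- numeric(length(acc) + length(chunks))
    for (j in seq_along(acc)) {
      idx <- j:(j + length(chunks) - 1L)
      prod[idx] <- prod[idx] + acc[j] * chunks
    }
    carry <- 0
    for (j in seq_along(prod)) {
      v <- prod[j] + carry
      prod[j] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) {
      prod <- c(prod, carry %% base)
      carry <- carry %/% base
    }
    while (length(prod) > 1L && prod[length(prod)] == 0) {
      prod <- prod[-length(prod)]
    }
    acc <- prod
  }
  hi <- length(acc)
  paste0(format(acc[hi], scientific = FALSE),
         paste(sprintf("%04d", rev(acc[-hi])), collapse = ""))
}

#' Probability of a productive decision after t experiences
#'
#' The per-step probability `u(l, t)` that the decision taken at time `t` is
#' productive, for an organism of decision depth `l` starting with no innate
#' knowledge (`u(l, 0) = 0`). Each experience closes a fraction
#' `1 / (tau * N(l))` of the remaining gap to the ceiling `f(l)`, where
#' `N(l) = n^l` is the number of situations to be learned:
#'
#' \deqn{u(l, t+1) = u(l, t) + \frac{1}{\tau N(l)}\,[f(l) - u(l, t)]}
#'
#' `productive_prob_recurrence()` iterates this update `t` times and serves as
#' the brute-force reference; `productive_prob_closed()` evaluates the solved
#' form \eqn{u(l,t) = f(l)[1 - (1 - 1/(\tau N(l)))^t]} using a numerically
#' stable `log1p`/`expm1` formulation.
#'
#' @param params An [analytic_params()] object.
#' @param depth Decision depth `l` (integer, `>= 1`).
#' @param t Number of learning experiences so far (integer, `>= 0`).
#' @return A probability in `[0, 1]`, bounded above by `fraction_informative()`.
#' @examples
#' p <- analytic_params(12, 0.5, 10, 10000)
#' productive_prob_closed(p, depth = 1, t = 1000)
#' productive_prob_recurrence(p, depth = 1, t = 1000)
#' @export
productive_prob_recurrence <- function(params, depth, t) {
  params <- as_analytic_params(params)
  depth <- check_depth(depth)
  if (!is.numeric(t) || length(t) != 1L || t < 0 || t != floor(t)) {
    stop("`t` must be a single non-negative integer", call. = FALSE)
  }
  f <- fraction_informative(depth, params$r)
  rate <- 1 / (params$tau * params$n^depth)
  u <- 0
  for (i in seq_len(t)) {
    u <- u + rate * (f - u)
  }
  u
}

#' @rdname productive_prob_recurrence
#' @export
productive_prob_closed <- function(params, depth, t) {
  params <- as_analytic_params(params)
  depth <- check_depth(depth)
  if (!is.numeric(t) || any(t < 0) || any(t != floor(t))) {
    stop("`t` must be non-negative integer(s)", call. = FALSE)
  }
  f <- fraction_informative(depth, params$r)
  rate <- 1 / (params$tau * params$n^depth)
  # 1 - (1 - rate)^t without cancellation for tiny rate, large t
  f * (-expm1(t * log1p(-rate)))
}

#' Expected lifetime number of productive decisions
#'
#' The fitness proxy \eqn{U(l, T) = \sum_{t=0}^{T-1} u(l, t)}, evaluated in
#' closed form:
#' \deqn{U(l,T) = f(l)\left[T - \tau N(l)\left(1 - \left(1 -
#'   \frac{1}{\tau N(l)}\right)^T\right)\right]}
#' Larger depth raises the ceiling `f(l)` but inflates the number of
#' situations `N(l) = n^l` that must be learned, so utility trades benefit
#' against learning cost.
#'
#' @inheritParams productive_prob_recurrence
#' @return A non-negative number, at most `lifespan`.
#' @examples
#' p <- analytic_params(20, 0.5, 10, 10000)
#' lifetime_utility(p, 1) > lifetime_utility(p, 2)
#' @export
lifetime_utility <- function(params, depth) {
  params <- as_analytic_params(params)
  depth <- check_depth(depth)
  f <- fraction_informative(depth, params$r)
  tn <- params$tau * params$n^depth
  f * (params$lifespan - tn * (-expm1(params$lifespan * log1p(-1 / tn))))
}

#' Utility across decision depths
#'
#' Evaluates [lifetime_utility()] on a range of depths, returning a small
#' classed table that can be printed or plotted (utility against depth, one of
#' the standard views of the model).
#'
#' @inheritParams productive_prob_recurrence
#' @param depths Integer vector of decision depths (default `1:4`).
#' @return An object of class `"utility_surface"`: a data.frame with columns
#'   `depth` and `utility`, plus the parameters as attribute `"params"`.
#' @examples
#' utility_surface(analytic_params(12, 0.5, 10, 10000))
#' @export
utility_surface <- function(params, depths = 1:4) {
  params <- as_analytic_params(params)
  depths <- vapply(depths, check_depth, numeric(1))
  util <- vapply(depths, function(l) lifetime_utility(params, l), numeric(1))
  structure(data.frame(depth = depths, utility = util),
            params = params, class = c("utility_surface", "data.frame"))
}

#' @export
print.utility_surface <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Lifetime utility U(l, T): n = %g, r = %g, tau = %g, T = %g\n",
              p$n, p$r, p$tau, p$lifespan))
  print.data.frame(x, row.names = FALSE, ...)
  best <- x$depth[which.max(x$utility)]
  cat(sprintf("optimal depth: %d\n", as.integer(best)))
  invisible(x)
}

#' @export
plot.utility_surface <- function(x, ...) {
  p <- attr(x, "params")
  graphics::plot(x$depth, x$utility, type = "b", pch = 16,
                 xlab = "decision depth l",
                 ylab = "expected productive decisions U(l, T)",
                 main = sprintf("n = %g, T = %g", p$n, p$lifespan), ...)
  invisible(x)
}

#' Optimal decision depth
#'
#' The depth in `1..depth_max` maximizing [lifetime_utility()]. Exact ties are
#' broken toward the smaller depth: at equal utility the shallower (cheaper)
#' representation is preferred.
#'
#' @inheritParams productive_prob_recurrence
#' @param depth_max Largest depth considered (integer, `>= 1`).
#' @return A single integer depth.
#' @examples
#' optimal_depth(analytic_params(500, 0.5, 10, 10000), depth_max = 4) # 1
#' @export
optimal_depth <- function(params, depth_max = 4) {
  params <- as_analytic_params(params)
  depth_max <- check_depth(depth_max)
  util <- vapply(seq_len(depth_max), function(l) lifetime_utility(params, l),
                 numeric(1))
  as.integer(which.max(util))  # which.max returns the first (smallest) maximum
}

#' Smallest alphabet size at which shallow beats deep
#'
#' Scans integer alphabet sizes `n = 2, 3, ...` and returns the first `n` at
#' which the shallower depth `depth_a` achieves at least the lifetime utility
#' of the deeper `depth_b`. Below the returned boundary the deeper
#' representation is favored; at and above it the combinatorial learning cost
#' of depth `depth_b` outweighs its information benefit.
#'
#' @param r Information-distribution rate in `(0, 1)`.
#' @param tau Experiences per learned decision (`> 0`).
#' @param lifespan Lifetime in learning experiences.
#' @param depth_a,depth_b The two depths compared; `depth_a < depth_b`.
#' @param n_max Upper end of the scan (default 1000).
#' @return The boundary alphabet size as an integer, or `NA_integer_` (with a
#'   warning) if no `n <= n_max` satisfies the condition. Invalid parameters
#'   signal an error instead.
#' @examples
#' depth_boundary_n(r = 0.5, tau = 10, lifespan = 10000) # 20
#' @export
depth_boundary_n <- function(r, tau, lifespan, depth_a = 1, depth_b = 2,
                             n_max = 1000) {
  depth_a <- check_depth(depth_a)
  depth_b <- check_depth(depth_b)
  if (depth_a >= depth_b) {
    stop("`depth_a` must be strictly smaller than `depth_b`", call. = FALSE)
  }
  if (!is.numeric(n_max) || length(n_max) != 1L || n_max < 2) {
    stop("`n_max` must be an integer >= 2", call. = FALSE)
  }
  for (n in 2:n_max) {
    p <- analytic_params(n, r, tau, lifespan)
    if (lifetime_utility(p, depth_a) >= lifetime_utility(p, depth_b)) {
      return(as.integer(n))
    }
  }
  warning(sprintf("no boundary found for n <= %d", as.integer(n_max)),
          call. = FALSE)
  NA_integer_
}

#' Utility and optimal depth over a parameter grid
#'
#' Evaluates the analytic model over the cross product of alphabet sizes and
#' lifespans, one row per (n, T, depth) combination — a long-format table
#' suitable for re-plotting utility curves and optimal-depth maps.
#'
#' @param n Integer vector of alphabet sizes.
#' @param lifespan Integer vector of lifetimes.
#' @param r,tau Model constants (defaults 0.5 and 10).
#' @param depths Depths to evaluate (default `1:4`).
#' @return A data.frame with columns `n`, `lifespan`, `r`, `tau`, `depth`,
#'   `utility`, `optimal_depth`.
#' @examples
#' head(utility_grid(n = c(5, 12, 20), lifespan = 10000))
#' @export
utility_grid <- function(n, lifespan, r = 0.5, tau = 10, depths = 1:4) {
  rows <- expand.grid(n = n, lifespan = lifespan, KEEP.OUT.ATTRS = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    p <- analytic_params(rows$n[i], r, tau, rows$lifespan[i])
    util <- vapply(depths, function(l) lifetime_utility(p, l), numeric(1))
    data.frame(n = rows$n[i], lifespan = rows$lifespan[i], r = r, tau = tau,
               depth = depths, utility = util,
               optimal_depth = depths[which.max(util)])
  }))
  rownames(out) <- NULL
  out
}
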
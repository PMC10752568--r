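strategy_code <- function(strategy) {
  switch(strategy$type, trace = 0L, depth = 1L, flexible = 2L)
}

#' Run a learning simulation
#'
#' Executes the time-stepped learning loop: at every step a sequence is drawn
#' from the environment, represented according to the strategy, a behavior is
#' chosen by the softmax rule, reinforcement is delivered (+5 for go on a
#' rewarding sequence, -4 for go on a non-rewarding one, 0 for no-go), and
#' associative strengths are updated by the normalized delta rule. Every
#' `measure_every` steps the simulation is frozen and the agent's performance
#' on a fixed test set is recorded without touching the weights.
#'
#' Each replicate re-draws its own environment stream and frozen test set from
#' seeds derived from `seed`. The derived streams depend only on `seed` and
#' the replicate index — not on the strategy — so different strategies run
#' against identical stimulus streams (paired comparisons).
#'
#' Test performance is measured with the weights frozen, by default as the
#' expected fraction of correct responses under the softmax rule (see
#' [measure_performance()]); `test_rule = "greedy"` scores the deterministic
#' argmax response instead.
#'
#' @param env A [seq_environment()].
#' @param strategy A [strategy_trace()], [strategy_depth()] or
#'   [strategy_flexible()] configuration.
#' @param steps Number of learning time-steps per replicate.
#' @param replicates Number of independent replicates (default 20).
#' @param measure_every Measurement interval in steps (default 100).
#' @param test_instantiations Instantiations per template in the frozen test
#'   set (default 10).
#' @param seed Integer master seed.
#' @param alpha Learning rate (default `0.1`).
#' @param beta Softmax sharpness (default 1).
#' @param test_rule `"expected"` (default) or `"greedy"`.
#' @param engine `"cpp"` (compiled, default) or `"R"` (pure-R reference
#'   implementation; identical results, far slower).
#' @param return_memory Keep the final [associative_memory()] of the last
#'   replicate (default `FALSE`).
#' @return An object of class `"performance_curve"`: checkpoints, a
#'   checkpoint-by-replicate performance matrix, its replicate mean, and the
#'   run configuration.
#' @examples
#' env <- build_positional_env("last", n_stimuli = 10, n_templates = 4)
#' run_simulation(env, strategy_depth(1), steps = 500, replicates = 2, seed = 1)
#' @export
run_simulation <- function(env, strategy, steps, replicates = 20,
                           measure_every = 100, test_instantiations = 10,
                           seed = 1, alpha = DEFAULT_ALPHA,
                           beta = DEFAULT_BETA,
                           test_rule = c("expected", "greedy"),
                           engine = c("cpp", "R"), return_memory = FALSE) {
  stopifnot(inherits(env, "seq_env"), inherits(strategy, "strategy_config"))
  test_rule <- match.arg(test_rule)
  engine <- match.arg(engine)
  if (!is.numeric(steps) || length(steps) != 1L || steps < 1) {
    stop("`steps` must be a positive integer", call. = FALSE)
  }
  if (measure_every < 1 || steps < measure_every) {
    stop("`steps` must be at least `measure_every` (>= 1)", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (strategy$type %in% c("depth", "flexible") &&
      strategy$depth > env$seq_length) {
    stop("strategy depth exceeds the environment's sequence length",
         call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  env_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  test_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  agent_seeds <- sample.int(.Machine$integer.max - 1L, replicates)

  checkpoints <- seq(measure_every, floor(steps / measure_every) * measure_every,
                     by = measure_every)
  perf <- matrix(NA_real_, nrow = length(checkpoints), ncol = replicates)
  memory <- NULL
  for (i in seq_len(replicates)) {
    set.seed(test_seeds[i])
    ts <- test_set(env, test_instantiations)
    set.seed(env_seeds[i])
    stream <- env_stream(env, steps)
    set.seed(agent_seeds[i])
    res <- if (engine == "cpp") {
      engine_run_cpp(env, stream, ts, strategy, alpha, beta, measure_every,
                     test_rule, keep_memory = return_memory && i == replicates)
    } else {
      engine_run_r(env, stream, ts, strategy, alpha, beta, measure_every,
                   test_rule, keep_memory = return_memory && i == replicates)
    }
    perf[, i] <- res$performance
    if (!is.null(res$memory)) memory <- res$memory
  }
  structure(list(checkpoints = checkpoints, performance = perf,
                 mean = rowMeans(perf), strategy = strategy$label,
                 environment = env$name, steps = steps,
                 measure_every = measure_every, replicates = replicates,
                 seed = seed, alpha = alpha, beta = beta,
                 test_rule = test_rule, memory = memory),
            class = "performance_curve")
}

engine_run_cpp <- function(env, stream, ts, strategy, alpha, beta,
                           measure_every, test_rule, keep_memory = FALSE) {
  res <- run_engine_cpp(
    stream$seq, stream$rewarding, ts$seq, ts$rewarding,
    length(env$alphabet), strategy_code(strategy),
    if (strategy$type == "trace") 0L else as.integer(strategy$depth),
    if (strategy$type == "trace") strategy$theta else 0.5,
    if (strategy$type == "trace" && strategy$merge == "recent") 1L else 0L,
    alpha, beta, as.integer(measure_every),
    if (test_rule == "greedy") 1L else 0L
  )
  out <- list(performance = res$performance, memory = NULL)
  if (keep_memory) {
    mem <- associative_memory(alpha = alpha, beta = beta)
    for (j in seq_along(res$keys)) {
      key <- subseq_key(env$alphabet[res$keys[[j]]])
      assign(key, c(res$go[j], res$nogo[j]), envir = mem$weights)
    }
    out$memory <- mem
  }
  out
}

# Pure-R reference engine: the same loop, built from the exported module
# functions. Consumes the RNG identically to the compiled engine (one uniform
# per training step), so both give identical curves from identical streams.
engine_run_r <- function(env, stream, ts, strategy, alpha, beta,
                         measure_every, test_rule, keep_memory = FALSE) {
  memory <- associative_memory(alpha = alpha, beta = beta)
  steps <- nrow(stream$seq)
  n_checks <- floor(steps / measure_every)
  performance <- numeric(n_checks)
  check <- 0L
  for (t in seq_len(steps)) {
    seq_labels <- env$alphabet[stream$seq[t, ]]
    p <- represent(strategy, seq_labels)
    b <- decide(memory, p)
    r <- reinforcement(b, stream$rewarding[t])
    learn(memory, p, b, r)
    if (t %% measure_every == 0L) {
      check <- check + 1L
      performance[check] <- measure_performance(memory, ts, strategy,
                                                rule = test_rule)
    }
  }
  list(performance = performance,
       memory = if (keep_memory) memory else NULL)
}

#' Measure frozen-test performance
#'
#' Scores an agent on a frozen test set without changing any associative
#' strength. Under the default `"expected"` rule each item contributes the
#' probability that the softmax response is correct (go on rewarding, no-go on
#' non-rewarding), so the measure reflects the agent's graded knowledge and a
#' naive agent scores exactly 0.5 on any half-rewarding test set. Under the
#' `"greedy"` rule each item contributes 1 if the deterministic argmax
#' response (ties resolved to no-go) is correct, 0 otherwise.
#'
#' @param memory An [associative_memory()].
#' @param ts A [test_set()].
#' @param strategy The representation strategy used to perceive each test
#'   sequence.
#' @param rule `"expected"` (default) or `"greedy"`.
#' @return The fraction correct, in `[0, 1]`.
#' @export
measure_performance <- function(memory, ts, strategy,
                                rule = c("expected", "greedy")) {
  stopifnot(inherits(memory, "assoc_memory"), inherits(ts, "seq_test_set"))
  rule <- match.arg(rule)
  if (nrow(ts$seq) == 0L) stop("the test set is empty", call. = FALSE)
  total <- 0
  for (j in seq_len(nrow(ts$seq))) {
    p <- represent(strategy, ts$alphabet[ts$seq[j, ]])
    v_go <- behavior_value(memory, p, "go")
    v_nogo <- behavior_value(memory, p, "no-go")
    total <- total + if (rule == "expected") {
      p_go <- stats::plogis(memory$beta * (v_go - v_nogo))
      if (ts$rewarding[j]) p_go else 1 - p_go
    } else {
      correct_go <- v_go > v_nogo
      if (ts$rewarding[j] == correct_go) 1 else 0
    }
  }
  total / nrow(ts$seq)
}

#' First checkpoint at which a performance level is reached
#'
#' @param curve A `"performance_curve"` from [run_simulation()].
#' @param level Performance level in `(0, 1]`.
#' @return The earliest checkpoint (time-step) whose replicate-mean
#'   performance is at least `level`, or `NA` if the curve never reaches it.
#' @export
trials_to_reach <- function(curve, level) {
  stopifnot(inherits(curve, "performance_curve"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level > 1) {
    stop("`level` must lie in (0, 1]", call. = FALSE)
  }
  idx <- which(curve$mean >= level)
  if (!length(idx)) return(NA_real_)
  curve$checkpoints[idx[1]]
}

#' @export
print.performance_curve <- function(x, ...) {
  cat(sprintf("<performance_curve> %s in %s\n", x$strategy, x$environment))
  cat(sprintf("  %d steps, %d replicate(s), measured every %d steps (%s rule)\n",
              x$steps, x$replicates, x$measure_every, x$test_rule))
  k <- length(x$checkpoints)
  show <- unique(round(seq(1, k, length.out = min(6, k))))
  cat("  mean performance:\n")
  for (i in show) {
    cat(sprintf("    step %7d: %.3f\n", x$checkpoints[i], x$mean[i]))
  }
  invisible(x)
}

#' @export
plot.performance_curve <- function(x, add = FALSE, col = "black", ...) {
  if (!add) {
    graphics::plot(NA, xlim = range(x$checkpoints), ylim = c(0, 1),
                   xlab = "time-steps", ylab = "fraction correct",
                   main = sprintf("%s in %s", x$strategy, x$environment), ...)
    graphics::abline(h = 0.5, lty = 3, col = "grey")
  }
  if (ncol(x$performance) > 1L) {
    graphics::matlines(x$checkpoints, x$performance,
                       col = grDevices::adjustcolor(col, alpha.f = 0.2),
                       lty = 1)
  }
  graphics::lines(x$checkpoints, x$mean, col = col, lwd = 2)
  invisible(x)
}

#' @export
as.data.frame.performance_curve <- function(x, ...) {
  data.frame(environment = x$environment, strategy = x$strategy,
             replicate = rep(seq_len(x$replicates),
                             each = length(x$checkpoints)),
             step = rep(x$checkpoints, x$replicates),
             performance = as.vector(x$performance),
             stringsAsFactors = FALSE)
}

#' Run several representation strategies on one environment
#'
#' Runs [run_simulation()] for each strategy with the same master seed, so all
#' strategies face identical stimulus streams and test sets, and collects the
#' resulting curves for comparison.
#'
#' @inheritParams run_simulation
#' @param strategies A list of strategy configurations (at least two).
#' @return An object of class `"strategy_comparison"`: a list with `curves`
#'   (named list of performance curves) and the run settings. Use
#'   `as.data.frame()` for the long-format table, [curve_milestones()] for
#'   summaries, and `plot()` for the curve figure.
#' @examples
#' env <- build_positional_env("last", n_stimuli = 10, n_templates = 4)
#' cmp <- compare_strategies(env, list(strategy_depth(1), strategy_trace()),
#'                           steps = 500, replicates = 2, seed = 1)
#' curve_milestones(cmp)
#' @export
compare_strategies <- function(env, strategies, steps, replicates = 20,
                               measure_every = 100, test_instantiations = 10,
                               seed = 1, alpha = DEFAULT_ALPHA,
                               beta = DEFAULT_BETA,
                               test_rule = c("expected", "greedy"),
                               engine = c("cpp", "R")) {
  if (!is.list(strategies) || length(strategies) < 2L) {
    stop("provide at least two strategy configurations", call. = FALSE)
  }
  test_rule <- match.arg(test_rule)
  engine <- match.arg(engine)
  curves <- lapply(strategies, function(s) {
    run_simulation(env, s, steps = steps, replicates = replicates,
                   measure_every = measure_every,
                   test_instantiations = test_instantiations, seed = seed,
                   alpha = alpha, beta = beta, test_rule = test_rule,
                   engine = engine)
  })
  names(curves) <- vapply(strategies, `[[`, character(1), "label")
  structure(list(curves = curves, environment = env$name, steps = steps,
                 replicates = replicates, seed = seed),
            class = "strategy_comparison")
}

#' @export
as.data.frame.strategy_comparison <- function(x, ...) {
  out <- do.call(rbind, lapply(x$curves, as.data.frame))
  rownames(out) <- NULL
  out
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat(sprintf("<strategy_comparison> %s\n", x$environment))
  cat(sprintf("  %d steps, %d replicates, strategies: %s\n", x$steps,
              x$replicates, paste(names(x$curves), collapse = ", ")))
  print(curve_milestones(x))
  invisible(x)
}

#' @export
plot.strategy_comparison <- function(x, level = NULL, ...) {
  cols <- grDevices::hcl.colors(max(3L, length(x$curves)), "Dark 3")
  first <- x$curves[[1]]
  graphics::plot(NA, xlim = range(first$checkpoints), ylim = c(0, 1),
                 xlab = "time-steps", ylab = "fraction correct",
                 main = x$environment, ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey")
  if (!is.null(level)) graphics::abline(h = level, lty = 2, col = "grey40")
  for (i in seq_along(x$curves)) {
    graphics::lines(x$curves[[i]]$checkpoints, x$curves[[i]]$mean,
                    col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = names(x$curves), col =
                     cols[seq_along(x$curves)], lwd = 2, bty = "n")
  invisible(x)
}
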
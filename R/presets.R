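#' Canonical simulation settings
#'
#' Pre-configured environment/strategy/step combinations for the package's
#' standard experiments:
#'
#' * `graded20`, `graded500` — Depth-1..4 learners in graded-depth worlds of
#'   20 and 500 stimuli: how the combinatorial cost of depth scales with
#'   alphabet size.
#' * `position-last`, `position-uniform`, `position-first` — Trace vs
#'   Depth-1..4 in 66-stimulus worlds where information sits in the last
#'   position only, uniformly over all positions, or in the first position
#'   only.
#' * `order-p0`, `order-p25`, `order-p50`, `order-p75`, `order-p100` —
#'   Trace, Depth-4 and Flexible-4 in order-sensitive worlds with
#'   sequential-information fraction p = 0, 0.25, 0.5, 0.75, 1.
#'
#' Step counts are package defaults chosen so the qualitative outcome of each
#' setting is visible (fast strategies near their plateau, slow ones clearly
#' separated); they can be overridden.
#'
#' @param name Preset name (see above).
#' @return `figure_preset()` returns a list with `env`, `strategies` and
#'   `steps`; `run_figure_preset()` runs it and returns the
#'   `"strategy_comparison"`.
#' @examples
#' figure_preset("position-last")$env
#' @export
figure_preset <- function(name) {
  name <- match.arg(name, c("graded20", "graded500", "position-last",
                            "position-uniform", "position-first",
                            paste0("order-p", c(0, 25, 50, 75, 100))))
  depth_set <- lapply(1:4, strategy_depth)
  trace_depths <- c(list(strategy_trace()), depth_set)
  order_set <- list(strategy_trace(), strategy_depth(4), strategy_flexible(4))
  order_preset <- function(p) {
    list(env = build_order_env(p), strategies = order_set, steps = 300000)
  }
  switch(name,
    graded20 = list(env = build_graded_depth_env(20), strategies = depth_set,
                    steps = 20000),
    graded500 = list(env = build_graded_depth_env(500),
                     strategies = depth_set, steps = 300000),
    `position-last` = list(env = build_positional_env("last"),
                           strategies = trace_depths, steps = 10000),
    `position-uniform` = list(env = build_positional_env("uniform"),
                              strategies = trace_depths, steps = 10000),
    `position-first` = list(env = build_positional_env("first"),
                            strategies = trace_depths, steps = 10000),
    `order-p0` = order_preset(0),
    `order-p25` = order_preset(0.25),
    `order-p50` = order_preset(0.5),
    `order-p75` = order_preset(0.75),
    `order-p100` = order_preset(1)
  )
}

#' @rdname figure_preset
#' @inheritParams compare_strategies
#' @param steps Optional override of the preset's step count.
#' @export
run_figure_preset <- function(name, seed = 1, replicates = 20, steps = NULL,
                              ...) {
  preset <- figure_preset(name)
  compare_strategies(preset$env, preset$strategies,
                     steps = steps %||% preset$steps, replicates = replicates,
                     seed = seed, ...)
}
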
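#' Percepts: sets of perception elements
#'
#' A percept is the agent's internal representation of a just-experienced
#' stimulus sequence: a set of *perception elements*, each a pair of a
#' subsequence (an ordered run of stimulus ids) and an intensity. Percepts are
#' stored as named numeric vectors — names are subsequence keys (stimulus ids
#' joined by spaces, so `"A B"` and `"B A"` are distinct), values are
#' intensities. Duplicate subsequences are merged.
#'
#' @param intensities Named numeric vector of intensities keyed by
#'   subsequence.
#' @return An object of class `"percept"`.
#' @seealso [represent_trace()], [represent_depth()], [represent_flexible()]
#' @export
percept <- function(intensities) {
  if (is.null(names(intensities)) || any(!nzchar(names(intensities)))) {
    stop("percept elements must be named by their subsequence", call. = FALSE)
  }
  if (any(intensities <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  if (anyDuplicated(names(intensities))) {
    intensities <- tapply(intensities, names(intensities), sum)
    intensities <- stats::setNames(as.numeric(intensities), names(intensities))
  }
  structure(intensities, class = "percept")
}

#' @export
print.percept <- function(x, ...) {
  cat(sprintf("<percept> %d element(s)\n", length(x)))
  for (i in seq_along(x)) {
    cat(sprintf("  (%s)  x = %g\n", names(x)[i], unclass(x)[i]))
  }
  invisible(x)
}

subseq_key <- function(symbols) paste(symbols, collapse = " ")

check_sequence <- function(sequence) {
  if (length(sequence) < 1L) stop("the stimulus sequence is empty", call. = FALSE)
  as.character(sequence)
}

#' Trace-memory representation
#'
#' Represents a sequence the way a decaying stimulus trace would: every
#' stimulus is present as a single-element subsequence whose intensity decays
#' geometrically with the time elapsed since it occurred — the most recent
#' stimulus has intensity 1, the one before it `theta`, then `theta^2`, and so
#' on. Order is carried only implicitly, through intensity. If the same
#' stimulus occurs more than once its traces are merged, by default by summing
#' intensities (trace accumulation); alternatively only the most recent
#' occurrence can be kept.
#'
#' @param sequence Character vector of stimulus ids, oldest first.
#' @param theta Trace decay rate in `(0, 1)` (default 0.5).
#' @param merge How to merge repeated stimuli: `"sum"` (default) or
#'   `"recent"`.
#' @return A [percept()].
#' @examples
#' represent_trace(c("D", "C", "B", "A"), theta = 0.5)
#' represent_trace(c("A", "A"), theta = 0.5)  # merged: intensity 1.5
#' @export
represent_trace <- function(sequence, theta = 0.5, merge = c("sum", "recent")) {
  sequence <- check_sequence(sequence)
  merge <- match.arg(merge)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("`theta` must lie strictly between 0 and 1", call. = FALSE)
  }
  L <- length(sequence)
  x <- theta^(L - seq_len(L))
  if (merge == "recent" && anyDuplicated(sequence)) {
    keep <- !duplicated(sequence, fromLast = TRUE)  # most recent = largest x
    sequence <- sequence[keep]
    x <- x[keep]
  }
  percept(stats::setNames(x, sequence))
}

#' Fixed-depth sequence representation
#'
#' Represents the last `depth` stimuli as one ordered, indivisible unit: the
#' percept holds a single element whose subsequence is the entire length-
#' `depth` tail of the sequence, at intensity 1. Two sequences that differ
#' anywhere within the window are entirely distinct situations for the
#' learner.
#'
#' @param sequence Character vector of stimulus ids, oldest first.
#' @param depth Window length `l`; at most `length(sequence)`.
#' @return A [percept()] with exactly one element.
#' @examples
#' represent_depth(c("D", "C", "B", "A"), depth = 2)  # ("B A", 1)
#' @export
represent_depth <- function(sequence, depth) {
  sequence <- check_sequence(sequence)
  depth <- check_depth(depth)
  L <- length(sequence)
  if (depth > L) {
    stop("`depth` exceeds the sequence length", call. = FALSE)
  }
  tail_seq <- sequence[(L - depth + 1L):L]
  percept(stats::setNames(1, subseq_key(tail_seq)))
}

#' Flexible-sequence representation
#'
#' Represents every contiguous subsequence of the last `depth` stimuli as its
#' own perception element at intensity 1: all single stimuli, all adjacent
#' pairs, and so on up to the full window. For a window of `l` distinct
#' stimuli this yields `l(l+1)/2` elements (10 for `l = 4`). The flexibility
#' to respond to any sub-chunk lets the learner pick out informative
#' subsequences wherever they sit and ignore the rest.
#'
#' @param sequence Character vector of stimulus ids, oldest first.
#' @param depth Window length `l`; at most `length(sequence)`.
#' @return A [percept()].
#' @examples
#' represent_flexible(c("D", "C", "B", "A"), depth = 4)  # 10 elements
#' represent_flexible(c("A", "B"), depth = 2)            # (A B), (A), (B)
#' @export
represent_flexible <- function(sequence, depth) {
  sequence <- check_sequence(sequence)
  depth <- check_depth(depth)
  L <- length(sequence)
  if (depth > L) {
    stop("`depth` exceeds the sequence length", call. = FALSE)
  }
  window <- sequence[(L - depth + 1L):L]
  keys <- character(0)
  for (len in seq_len(depth)) {
    for (start in seq_len(depth - len + 1L)) {
      keys <- c(keys, subseq_key(window[start:(start + len - 1L)]))
    }
  }
  percept(stats::setNames(rep(1, length(keys)), keys))
}

#' Representation strategy configurations
#'
#' Small constructors bundling a representation type with its parameters, for
#' use with [run_simulation()] and [compare_strategies()]. `strategy_trace()`
#' is the decaying-trace memory, `strategy_depth()` the fixed-depth ordered
#' window, and `strategy_flexible()` the all-contiguous-subsequences
#' representation.
#'
#' @param theta Trace decay rate in `(0, 1)`.
#' @param merge Trace merge rule for repeated stimuli (see
#'   [represent_trace()]).
#' @param depth Window length for the depth and flexible strategies.
#' @param label Optional display label.
#' @return An object of class `"strategy_config"`.
#' @examples
#' strategy_trace()
#' strategy_depth(2)
#' strategy_flexible(4)
#' @export
strategy_trace <- function(theta = 0.5, merge = c("sum", "recent"),
                           label = NULL) {
  merge <- match.arg(merge)
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stop("`theta` must lie strictly between 0 and 1", call. = FALSE)
  }
  structure(list(type = "trace", theta = theta, merge = merge,
                 label = label %||% "Trace"),
            class = "strategy_config")
}

#' @rdname strategy_trace
#' @export
strategy_depth <- function(depth, label = NULL) {
  depth <- check_depth(depth)
  structure(list(type = "depth", depth = depth,
                 label = label %||% sprintf("Depth-%d", depth)),
            class = "strategy_config")
}

#' @rdname strategy_trace
#' @export
strategy_flexible <- function(depth, label = NULL) {
  depth <- check_depth(depth)
  structure(list(type = "flexible", depth = depth,
                 label = label %||% sprintf("Flexible-%d", depth)),
            class = "strategy_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.strategy_config <- function(x, ...) {
  cat(sprintf("<strategy_config> %s\n", x$label))
  invisible(x)
}

#' Apply a representation strategy to a stimulus sequence
#'
#' @param strategy A [strategy_trace()], [strategy_depth()] or
#'   [strategy_flexible()] configuration.
#' @param sequence Character vector of stimulus ids, oldest first.
#' @return A [percept()].
#' @examples
#' represent(strategy_depth(2), c("D", "C", "B", "A"))
#' @export
represent <- function(strategy, sequence) {
  stopifnot(inherits(strategy, "strategy_config"))
  switch(strategy$type,
         trace = represent_trace(sequence, strategy$theta, strategy$merge),
         depth = represent_depth(sequence, strategy$depth),
         flexible = represent_flexible(sequence, strategy$depth),
         stop("unknown strategy type"))
}
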
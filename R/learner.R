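# Default learning rate. Calibrated so that roughly ten reinforced exposures
# to a single discrimination carry its expected test accuracy from chance to
# ~88% (matching a learning cost of about ten experiences per productive
# decision); see the methods vignette for the calibration.
DEFAULT_ALPHA <- 0.05
DEFAULT_BETA <- 1

#' Associative go/no-go memory
#'
#' The agent's memory maps (subsequence, behavior) pairs to associative
#' strengths. Unseen pairs read as exactly 0 — the agent starts with no innate
#' knowledge. Strengths are updated by error correction ([learn()]) and drive
#' response selection ([decide()]). The store is a mutable hashed environment,
#' so `learn()` updates it in place.
#'
#' @param alpha Learning rate in `(0, 1]`.
#' @param beta Response-selection sharpness (`> 0`); larger values make the
#'   softmax choice rule more deterministic.
#' @return An object of class `"assoc_memory"`.
#' @examples
#' mem <- associative_memory()
#' p <- represent_depth(c("B", "A"), 1)
#' behavior_value(mem, p, "go")  # 0: no innate knowledge
#' @export
associative_memory <- function(alpha = DEFAULT_ALPHA, beta = DEFAULT_BETA) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0) {
    stop("`beta` must be positive", call. = FALSE)
  }
  structure(list(weights = new.env(parent = emptyenv(), hash = TRUE),
                 alpha = alpha, beta = beta),
            class = "assoc_memory")
}

#' @export
print.assoc_memory <- function(x, ...) {
  cat(sprintf("<assoc_memory> %d known subsequence(s), alpha = %g, beta = %g\n",
              length(ls(x$weights)), x$alpha, x$beta))
  invisible(x)
}

behavior_index <- function(behavior) {
  i <- match(match.arg(behavior, c("go", "no-go")), c("go", "no-go"))
  i
}

# strengths for one subsequence key: c(go, nogo); 0 where never updated
key_strengths <- function(memory, key) {
  get0(key, envir = memory$weights, ifnotfound = c(0, 0))
}

#' Summed associative support for a behavior
#'
#' The value of a behavior given a percept: the sum over perception elements
#' of the element's associative strength for that behavior, weighted by the
#' element's intensity. A fresh memory values every behavior at 0.
#'
#' @param memory An [associative_memory()].
#' @param percept A [percept()].
#' @param behavior `"go"` or `"no-go"`.
#' @return A real number.
#' @export
behavior_value <- function(memory, percept, behavior = c("go", "no-go")) {
  stopifnot(inherits(memory, "assoc_memory"), inherits(percept, "percept"))
  if (length(percept) == 0L) stop("the percept is empty", call. = FALSE)
  i <- behavior_index(behavior)
  keys <- names(percept)
  total <- 0
  for (j in seq_along(keys)) {
    total <- total + key_strengths(memory, keys[j])[i] * percept[[j]]
  }
  total
}

#' Choose a behavior in response to a percept
#'
#' In the default stochastic mode the agent responds "go" with softmax
#' probability `exp(beta * v_go) / (exp(beta * v_go) + exp(beta * v_nogo))`,
#' which guarantees exploration early in learning. In greedy mode (used for
#' frozen-test measurement) the higher-valued behavior is chosen
#' deterministically, with exact ties resolved to "no-go" — withholding is
#' the cost-free default.
#'
#' @inheritParams behavior_value
#' @param greedy Logical; pick the argmax instead of sampling.
#' @return `"go"` or `"no-go"`.
#' @export
decide <- function(memory, percept, greedy = FALSE) {
  v_go <- behavior_value(memory, percept, "go")
  v_nogo <- behavior_value(memory, percept, "no-go")
  if (greedy) {
    return(if (v_go > v_nogo) "go" else "no-go")
  }
  p_go <- stats::plogis(memory$beta * (v_go - v_nogo))
  if (stats::runif(1) < p_go) "go" else "no-go"
}

#' The reinforcement schedule of the go/no-go task
#'
#' Responding ("go") to a rewarding sequence earns the highest reinforcement
#' (+5); responding to a non-rewarding sequence costs -4 (the price of acting
#' without payoff); withholding ("no-go") earns 0 regardless of the sequence.
#'
#' @param behavior `"go"` or `"no-go"`.
#' @param rewarding Logical: is the current sequence rewarding?
#' @return The reinforcement value: 5, -4 or 0.
#' @examples
#' reinforcement("go", TRUE)    # 5
#' reinforcement("go", FALSE)   # -4
#' reinforcement("no-go", TRUE) # 0
#' @export
reinforcement <- function(behavior, rewarding) {
  if (behavior_index(behavior) == 2L) return(0)
  if (isTRUE(rewarding)) 5 else -4
}

#' Error-correction update of associative strengths
#'
#' Updates the memory from one experience by a normalized delta rule
#' (Widrow-Hoff / Rescorla-Wagner form). The prediction error is
#' `delta = reinforcement - behavior_value(memory, percept, behavior)`; each
#' element `(K, x)` of the percept then has its strength for the *chosen*
#' behavior incremented by `alpha * x * delta / sum(x)^2`. With this
#' normalization one experience moves the percept's value toward the
#' reinforcement by the fraction `alpha * sum(x^2) / sum(x)^2`: a learner
#' whose perception is concentrated in a single element moves by the full
#' `alpha`, while one that spreads perception over many elements learns
#' proportionally more slowly — representing more gets paid for in learning
#' speed. Strengths for the unchosen behavior are untouched, and since
#' "no-go" always earns 0 from a value that starts at 0, no-go strengths
#' never move from 0.
#'
#' @inheritParams behavior_value
#' @param reinforcement The received reinforcement value.
#' @return The memory, invisibly (it is modified in place).
#' @examples
#' mem <- associative_memory(alpha = 0.1)
#' p <- percept(c(A = 1))
#' learn(mem, p, "go", 5)
#' behavior_value(mem, p, "go")  # 0.5
#' @export
learn <- function(memory, percept, behavior, reinforcement) {
  stopifnot(inherits(memory, "assoc_memory"), inherits(percept, "percept"))
  i <- behavior_index(behavior)
  delta <- reinforcement - behavior_value(memory, percept, behavior)
  if (delta == 0) return(invisible(memory))
  norm <- sum(unclass(percept))^2
  keys <- names(percept)
  step <- memory$alpha * delta / norm
  for (j in seq_along(keys)) {
    w <- key_strengths(memory, keys[j])
    w[i] <- w[i] + step * percept[[j]]
    assign(keys[j], w, envir = memory$weights)
  }
  invisible(memory)
}

#' Snapshot of an associative memory
#'
#' @param memory An [associative_memory()].
#' @return A data.frame with columns `subsequence`, `go`, `nogo`, sorted by
#'   subsequence key.
#' @export
memory_snapshot <- function(memory) {
  stopifnot(inherits(memory, "assoc_memory"))
  keys <- sort(ls(memory$weights))
  go <- numeric(length(keys))
  nogo <- numeric(length(keys))
  for (j in seq_along(keys)) {
    w <- key_strengths(memory, keys[j])
    go[j] <- w[1]
    nogo[j] <- w[2]
  }
  data.frame(subsequence = keys, go = go, nogo = nogo,
             stringsAsFactors = FALSE)
}

#' Serialize an associative memory to and from JSON
#'
#' @param memory An [associative_memory()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `memory_to_json()` returns the JSON string; `memory_from_json()`
#'   an [associative_memory()].
#' @export
memory_to_json <- function(memory, path = NULL) {
  snap <- memory_snapshot(memory)
  doc <- list(alpha = memory$alpha, beta = memory$beta, weights = snap)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname memory_to_json
#' @param json A JSON string or file path produced by `memory_to_json()`.
#' @export
memory_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  mem <- associative_memory(alpha = as.numeric(doc$alpha), beta = as.numeric(doc$beta))
  w <- doc$weights
  for (j in seq_len(nrow(w))) {
    assign(w$subsequence[j], c(w$go[j], w$nogo[j]), envir = mem$weights)
  }
  mem
}
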
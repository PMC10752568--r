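#' Template-sequence environments
#'
#' An environment is an alphabet of stimuli — some *informative* (their
#' identity carries reward information), some *noise* — together with a set of
#' length-`L` template sequences. Each template fixes some positions to
#' concrete informative stimuli and leaves the rest as noise wildcards; each
#' template is labelled rewarding or not, and exactly half of the templates are
#' rewarding. Concrete stimulus sequences are drawn by picking a template
#' uniformly at random and filling every wildcard with a noise stimulus chosen
#' uniformly at random (with replacement).
#'
#' `seq_environment()` is the low-level constructor; most users will call one
#' of [build_positional_env()], [build_graded_depth_env()] or
#' [build_order_env()].
#'
#' @param alphabet Character vector of unique stimulus identifiers.
#' @param kind Character vector, same length as `alphabet`, each entry
#'   `"informative"` or `"noise"`.
#' @param templates Integer matrix, one row per template and one column per
#'   sequence position; entries index into `alphabet`, `NA` marks a noise
#'   wildcard.
#' @param rewarding Logical vector, one entry per template; exactly half must
#'   be `TRUE`.
#' @param wildcard_pool Character vector of stimulus ids from which wildcard
#'   positions are filled; defaults to the noise stimuli. Environments in
#'   which some informative stimuli also occur intermixed with the noise can
#'   include them here.
#' @param name Optional label for printing.
#'
#' @return An object of class `"seq_env"`.
#' @seealso [sample_sequence()], [test_set()], [env_to_json()]
#' @export
seq_environment <- function(alphabet, kind, templates, rewarding,
                            wildcard_pool = NULL, name = "environment") {
  if (anyDuplicated(alphabet)) {
    stop("stimulus identifiers must be unique", call. = FALSE)
  }
  if (length(kind) != length(alphabet) ||
      !all(kind %in% c("informative", "noise"))) {
    stop("`kind` must mark each alphabet entry 'informative' or 'noise'",
         call. = FALSE)
  }
  templates <- as.matrix(templates)
  storage.mode(templates) <- "integer"
  if (nrow(templates) < 1L) stop("at least one template is required", call. = FALSE)
  idx <- templates[!is.na(templates)]
  if (length(idx) && (min(idx) < 1L || max(idx) > length(alphabet))) {
    stop("template entries must index into the alphabet", call. = FALSE)
  }
  rewarding <- as.logical(rewarding)
  if (length(rewarding) != nrow(templates) || anyNA(rewarding)) {
    stop("`rewarding` must be one logical per template", call. = FALSE)
  }
  if (sum(rewarding) * 2L != nrow(templates)) {
    stop("exactly half of the templates must be rewarding", call. = FALSE)
  }
  if (is.null(wildcard_pool)) {
    pool <- which(kind == "noise")
  } else {
    pool <- match(wildcard_pool, alphabet)
    if (anyNA(pool)) {
      stop("`wildcard_pool` contains ids not in the alphabet", call. = FALSE)
    }
  }
  if (any(is.na(templates)) && !length(pool)) {
    stop("templates contain wildcards but the wildcard pool is empty",
         call. = FALSE)
  }
  structure(list(alphabet = alphabet, kind = kind, templates = templates,
                 rewarding = rewarding, seq_length = ncol(templates),
                 wildcard_pool = as.integer(pool), name = name),
            class = "seq_env")
}

template_pattern <- function(env, i) {
  row <- env$templates[i, ]
  paste(ifelse(is.na(row), "*", env$alphabet[row]), collapse = " ")
}

#' @export
print.seq_env <- function(x, n = 8, ...) {
  cat(sprintf("<seq_env> %s\n", x$name))
  cat(sprintf("  %d stimuli (%d informative, %d noise), sequence length %d\n",
              length(x$alphabet), sum(x$kind == "informative"),
              sum(x$kind == "noise"), x$seq_length))
  k <- nrow(x$templates)
  cat(sprintf("  %d templates (%d rewarding); '*' = noise wildcard\n",
              k, sum(x$rewarding)))
  for (i in seq_len(min(n, k))) {
    cat(sprintf("    %-24s %s\n", template_pattern(x, i),
                if (x$rewarding[i]) "[+]" else "[-]"))
  }
  if (k > n) cat(sprintf("    ... and %d more\n", k - n))
  invisible(x)
}

# Largest-remainder (Hamilton) rounding of `total * fractions` to integers.
# Deterministic: remainder ties go to the earlier entry.
allocate_counts <- function(total, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("proportions must sum to 1", call. = FALSE)
  }
  if (any(fractions < 0)) stop("proportions must be non-negative", call. = FALSE)
  raw <- total * fractions
  base <- floor(raw + 1e-12)
  short <- total - sum(base)
  if (short > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

# Split per-group counts into rewarding halves such that the overall total is
# exactly half rewarding; groups with odd counts alternate ceil/floor.
split_rewarding <- function(counts) {
  rew <- counts %/% 2L
  odd <- which(counts %% 2L == 1L)
  if (length(odd)) {
    up <- odd[seq_along(odd) %% 2L == 1L]
    rew[up] <- rew[up] + 1L
  }
  if (sum(rew) * 2L != sum(counts)) {
    stop("cannot split an odd total of templates half/half", call. = FALSE)
  }
  rew
}

#' Environments varying the temporal position of information
#'
#' Builds a world in which every template carries exactly one concrete
#' informative stimulus whose identity determines the reward label (one symbol
#' marks rewarding templates, another non-rewarding ones), placed according to
#' a distribution over temporal positions. The canonical settings put all
#' information in the last position, spread it uniformly over all positions,
#' or put it all in the first position.
#'
#' @param informative_positions Either a keyword (`"last"`, `"uniform"`,
#'   `"first"`) or a numeric probability vector over positions `1..seq_length`.
#' @param n_stimuli Total alphabet size, informative plus noise (default 66).
#' @param n_templates Number of templates (even, default 32).
#' @param seq_length Template length (default 4).
#' @return A [seq_environment()] object.
#' @examples
#' build_positional_env("last")
#' build_positional_env(c(0, 0, 0.5, 0.5), n_templates = 16)
#' @export
build_positional_env <- function(informative_positions = "uniform",
                                 n_stimuli = 66, n_templates = 32,
                                 seq_length = 4) {
  if (n_templates %% 2L != 0L || n_templates < 2L) {
    stop("`n_templates` must be a positive even number", call. = FALSE)
  }
  if (is.character(informative_positions)) {
    informative_positions <- switch(
      match.arg(informative_positions, c("last", "uniform", "first")),
      last = c(rep(0, seq_length - 1L), 1),
      uniform = rep(1 / seq_length, seq_length),
      first = c(1, rep(0, seq_length - 1L))
    )
  }
  if (length(informative_positions) != seq_length) {
    stop("`informative_positions` must have one entry per position",
         call. = FALSE)
  }
  if (n_stimuli < 3L) stop("`n_stimuli` must leave room for noise", call. = FALSE)
  counts <- allocate_counts(n_templates, informative_positions)
  rew_counts <- split_rewarding(counts)
  alphabet <- c("R", "Q", sprintf("n%02d", seq_len(n_stimuli - 2L)))
  kind <- c("informative", "informative", rep("noise", n_stimuli - 2L))
  templates <- matrix(NA_integer_, nrow = n_templates, ncol = seq_length)
  rewarding <- logical(n_templates)
  row <- 1L
  for (pos in seq_len(seq_length)) {
    for (j in seq_len(counts[pos])) {
      rewarding[row] <- j <= rew_counts[pos]
      templates[row, pos] <- if (rewarding[row]) 1L else 2L
      row <- row + 1L
    }
  }
  dist_label <- paste(signif(informative_positions, 3), collapse = "/")
  seq_environment(alphabet, kind, templates, rewarding,
                  name = sprintf("positional (%s), %d stimuli", dist_label,
                                 n_stimuli))
}

#' Environments with geometrically graded information depth
#'
#' Builds a world in which each template's single informative position sits at
#' recency `k` (the k-th position from the end; all later positions are noise
#' wildcards), with the proportion of templates at recency `k = 1..4`
#' defaulting to (1/2, 1/4, 1/8, 1/8): information decays geometrically with
#' ratio 0.5 per step into the past, truncated and renormalized at the
#' sequence length. Each template carries its own informative stimulus
#' identity, so the number of stimulus-response situations to be learned
#' scales with the number of templates and, for deeper representations, with
#' the noise alphabet. Half of the templates at every recency level are
#' rewarding.
#'
#' @param n_stimuli Total alphabet size (e.g. 20 or 500).
#' @param depth_fractions Proportions of templates whose information sits at
#'   recency 1..`seq_length`; must sum to 1.
#' @param n_templates Number of templates (default 16, giving 8/4/2/2 per
#'   recency level under the default fractions).
#' @param seq_length Template length (default 4).
#' @return A [seq_environment()] object.
#' @examples
#' build_graded_depth_env(500)
#' @export
build_graded_depth_env <- function(n_stimuli,
                                   depth_fractions = c(1/2, 1/4, 1/8, 1/8),
                                   n_templates = 16, seq_length = 4) {
  if (length(depth_fractions) != seq_length) {
    stop("`depth_fractions` must have one entry per recency level",
         call. = FALSE)
  }
  if (n_templates %% 2L != 0L || n_templates < 2L) {
    stop("`n_templates` must be a positive even number", call. = FALSE)
  }
  if (n_stimuli <= n_templates) {
    stop("`n_stimuli` must exceed `n_templates` to leave noise stimuli",
         call. = FALSE)
  }
  counts <- allocate_counts(n_templates, depth_fractions)
  rew_counts <- split_rewarding(counts)
  alphabet <- c(sprintf("i%02d", seq_len(n_templates)),
                sprintf("n%03d", seq_len(n_stimuli - n_templates)))
  kind <- c(rep("informative", n_templates),
            rep("noise", n_stimuli - n_templates))
  templates <- matrix(NA_integer_, nrow = n_templates, ncol = seq_length)
  rewarding <- logical(n_templates)
  row <- 1L
  for (k in seq_len(seq_length)) {
    pos <- seq_length - k + 1L
    for (j in seq_len(counts[k])) {
      rewarding[row] <- j <= rew_counts[k]
      templates[row, pos] <- row  # identity unique to this template
      row <- row + 1L
    }
  }
  seq_environment(alphabet, kind, templates, rewarding,
                  name = sprintf("graded depth, %d stimuli", n_stimuli))
}

#' Environments with order-sensitive sequential information
#'
#' Builds a world in which a fraction `p` of the informative templates carry
#' the ordered bigram (A, B) — rewarding — or (B, A) — non-rewarding — placed
#' at each of the start offsets where the bigram fits, with noise wildcards
#' elsewhere; only the order of A and B distinguishes reward. The remaining
#' `1 - p` of the informative templates carry a single concrete stimulus
#' (a distinct identity per template) whose identity determines the label,
#' spread over all temporal positions. Whenever bigram templates are present,
#' filler templates expose A alone (rewarding) and B alone (non-rewarding) at
#' several temporal positions, so that neither the first nor the last element
#' alone — nor the bare presence of A or B — identifies the bigram or its
#' order. Exactly half of all templates are rewarding.
#'
#' The alphabet is fixed at `n_stimuli` regardless of `p`: A, B, one identity
#' per potential single-stimulus template, and the remainder noise. Keeping
#' the noise pool constant across `p` makes learning speeds comparable between
#' panels.
#'
#' @param p Fraction of sequential (bigram) information, in `[0, 1]`.
#' @param n_stimuli Total alphabet size (default 66).
#' @param n_templates Number of informative templates (default 48; with the
#'   default alphabet this leaves 16 noise stimuli).
#' @param n_ab_alone Number of A/B-alone filler templates added whenever
#'   bigram templates are present (even, default 20: each of A and B appears
#'   alone, in a fixed concrete noise context, cycling over the last three
#'   temporal positions).
#' @param seq_length Template length (default 4).
#' @return A [seq_environment()] object.
#' @examples
#' build_order_env(0)
#' build_order_env(1)
#' @export
build_order_env <- function(p, n_stimuli = 66, n_templates = 48,
                            n_ab_alone = 20, seq_length = 4) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("`p` must be a single number in [0, 1]", call. = FALSE)
  }
  if (n_templates %% 2L != 0L) {
    stop("`n_templates` must be even", call. = FALSE)
  }
  if (n_ab_alone %% 2L != 0L || n_ab_alone < 0L) {
    stop("`n_ab_alone` must be an even non-negative number", call. = FALSE)
  }
  n_noise <- n_stimuli - 2L - n_templates
  if (n_noise < 1L) {
    stop("`n_stimuli` must exceed `n_templates` + 2 to leave noise stimuli",
         call. = FALSE)
  }
  n_pairs <- round(p * n_templates / 2)      # (A,B)/(B,A) pairs
  n_bigram <- 2L * n_pairs
  n_single <- n_templates - n_bigram
  A <- 1L; B <- 2L
  alphabet <- c("A", "B", sprintf("s%02d", seq_len(n_templates)),
                sprintf("n%02d", seq_len(n_noise)))
  kind <- c(rep("informative", 2L + n_templates), rep("noise", n_noise))

  rows <- list(); rew <- logical(0)
  n_offsets <- seq_length - 1L
  offset_counts <- allocate_counts(n_pairs, rep(1 / n_offsets, n_offsets))
  for (sign in c("AB", "BA")) {
    for (off in seq_len(n_offsets)) {
      for (j in seq_len(offset_counts[off])) {
        tpl <- rep(NA_integer_, seq_length)
        tpl[off] <- if (sign == "AB") A else B
        tpl[off + 1L] <- if (sign == "AB") B else A
        rows[[length(rows) + 1L]] <- tpl
        rew <- c(rew, sign == "AB")
      }
    }
  }
  if (n_single > 0L) {
    pos_counts <- allocate_counts(n_single, rep(1 / seq_length, seq_length))
    rew_counts <- split_rewarding(pos_counts)
    id <- 0L
    for (pos in seq_len(seq_length)) {
      for (j in seq_len(pos_counts[pos])) {
        id <- id + 1L
        tpl <- rep(NA_integer_, seq_length)
        tpl[pos] <- 2L + id
        rows[[length(rows) + 1L]] <- tpl
        rew <- c(rew, j <= rew_counts[pos])
      }
    }
  }
  if (n_bigram > 0L && n_ab_alone > 0L) {
    # A and B also occur alone, embedded in fixed noise contexts, at several
    # temporal positions, so that no single stimulus (first, last, or any
    # other position) identifies the bigram or its order on its own. The
    # contexts are concrete (not wildcards), so these templates are ordinary
    # learnable situations for every representation; the context symbols are
    # drawn from the noise alphabet and so carry almost no information of
    # their own (they mostly occur as random fills).
    noise_ids <- which(kind == "noise")
    positions <- rep(seq(seq_length, 2L), length.out = n_ab_alone %/% 2L)
    ctx <- 0L
    for (sym in c(A, B)) {
      for (pos in positions) {
        tpl <- integer(seq_length)
        for (q in seq_len(seq_length)) {
          if (q == pos) {
            tpl[q] <- sym
          } else {
            tpl[q] <- noise_ids[ctx %% length(noise_ids) + 1L]
            ctx <- ctx + 1L
          }
        }
        rows[[length(rows) + 1L]] <- tpl
        rew <- c(rew, sym == A)
      }
    }
  }
  templates <- do.call(rbind, rows)
  # A and B are also encountered intermixed with the noise: wildcard
  # positions may be filled with them, blurring simple intensity cues.
  pool <- if (n_bigram > 0L) c("A", "B", alphabet[kind == "noise"]) else NULL
  seq_environment(alphabet, kind, templates, rew, wildcard_pool = pool,
                  name = sprintf("order-sensitive, p = %g, %d stimuli", p,
                                 n_stimuli))
}

#' Draw one stimulus sequence from an environment
#'
#' Picks a template uniformly at random and fills each noise wildcard with a
#' noise stimulus drawn uniformly with replacement; concrete positions are
#' copied verbatim.
#'
#' @param env A [seq_environment()] object.
#' @return A list with `sequence` (character vector of stimulus ids),
#'   `rewarding` (logical) and `template` (the template row index).
#' @examples
#' set.seed(1)
#' sample_sequence(build_positional_env("last"))
#' @export
sample_sequence <- function(env) {
  stopifnot(inherits(env, "seq_env"))
  i <- sample.int(nrow(env$templates), 1L)
  row <- env$templates[i, ]
  wild <- is.na(row)
  if (any(wild)) {
    pool <- env$wildcard_pool
    row[wild] <- pool[sample.int(length(pool), sum(wild), replace = TRUE)]
  }
  list(sequence = env$alphabet[row], rewarding = env$rewarding[i], template = i)
}

# Vectorized stimulus stream for the simulation engine: `steps` draws as an
# integer matrix of alphabet indices plus reward labels. Consumes the R RNG
# (template picks first, then all wildcard fills).
env_stream <- function(env, steps) {
  idx <- sample.int(nrow(env$templates), steps, replace = TRUE)
  seqs <- env$templates[idx, , drop = FALSE]
  wild <- is.na(seqs)
  if (any(wild)) {
    pool <- env$wildcard_pool
    seqs[wild] <- pool[sample.int(length(pool), sum(wild), replace = TRUE)]
  }
  list(seq = seqs, rewarding = env$rewarding[idx], template = idx)
}

#' Build a frozen test set
#'
#' Instantiates every template a fixed number of times with independently
#' drawn noise, producing the fixed list of test sequences on which
#' performance is measured throughout a run. Generate it once per run (under
#' a known seed) and reuse it at every measurement point.
#'
#' @param env A [seq_environment()] object.
#' @param instantiations_per_template How many concrete sequences to draw per
#'   template (default 10).
#' @return An object of class `"seq_test_set"`: a list with `seq` (integer
#'   matrix of alphabet indices, one row per item), `rewarding` (logical),
#'   `template` (row indices) and `alphabet`.
#' @examples
#' set.seed(1)
#' ts <- test_set(build_positional_env("last"), 5)
#' nrow(ts$seq)
#' @export
test_set <- function(env, instantiations_per_template = 10) {
  stopifnot(inherits(env, "seq_env"))
  m <- instantiations_per_template
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != floor(m)) {
    stop("`instantiations_per_template` must be a positive integer",
         call. = FALSE)
  }
  idx <- rep(seq_len(nrow(env$templates)), each = m)
  seqs <- env$templates[idx, , drop = FALSE]
  wild <- is.na(seqs)
  if (any(wild)) {
    pool <- env$wildcard_pool
    seqs[wild] <- pool[sample.int(length(pool), sum(wild), replace = TRUE)]
  }
  structure(list(seq = seqs, rewarding = env$rewarding[idx], template = idx,
                 alphabet = env$alphabet),
            class = "seq_test_set")
}

#' @export
print.seq_test_set <- function(x, ...) {
  cat(sprintf("<seq_test_set> %d items (%d rewarding), length %d\n",
              nrow(x$seq), sum(x$rewarding), ncol(x$seq)))
  invisible(x)
}

#' Serialize an environment to and from JSON
#'
#' Archives the exact world — alphabet, stimulus kinds, templates with
#' wildcards, reward labels — as a JSON document so that results can be stored
#' alongside the environment that produced them.
#'
#' @param env A [seq_environment()] object.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `env_to_json()` returns the JSON string (invisibly when written to
#'   a file); `env_from_json()` returns the reconstructed `seq_env`.
#' @examples
#' json <- env_to_json(build_positional_env("last"))
#' env_from_json(json)$name
#' @export
env_to_json <- function(env, path = NULL) {
  stopifnot(inherits(env, "seq_env"))
  tpl <- apply(env$templates, 1L, function(row) {
    ifelse(is.na(row), "*", env$alphabet[row])
  })
  doc <- list(name = env$name, seq_length = env$seq_length,
              alphabet = env$alphabet, kind = env$kind,
              templates = t(tpl), rewarding = env$rewarding,
              wildcard_pool = env$alphabet[env$wildcard_pool])
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname env_to_json
#' @param json A JSON string or path to a JSON file produced by `env_to_json()`.
#' @export
env_from_json <- function(json) {
  doc <- jsonlite::fromJSON(json)
  tpl <- as.matrix(doc$templates)
  templates <- matrix(match(tpl, doc$alphabet), nrow = nrow(tpl))
  seq_environment(doc$alphabet, doc$kind, templates, doc$rewarding,
                  wildcard_pool = doc$wildcard_pool, name = doc$name)
}
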
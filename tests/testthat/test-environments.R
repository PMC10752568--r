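test_that("every generated world is exactly half rewarding", {
  envs <- list(
    build_positional_env("last"), build_positional_env("uniform"),
    build_positional_env("first"), build_positional_env(c(0, 0, 0.3, 0.7)),
    build_graded_depth_env(20), build_graded_depth_env(500),
    build_graded_depth_env(66, n_templates = 30),
    build_order_env(0), build_order_env(0.25), build_order_env(0.5),
    build_order_env(0.75), build_order_env(1),
    build_order_env(0.5, n_templates = 24)
  )
  for (env in envs) {
    expect_identical(sum(env$rewarding) * 2L, nrow(env$templates))
  }
})

test_that("positional environments place information where asked", {
  last <- build_positional_env("last", n_templates = 32)
  concrete <- !is.na(last$templates)
  expect_true(all(concrete[, 4]))
  expect_true(all(!concrete[, 1:3]))
  expect_identical(nrow(last$templates), 32L)
  expect_identical(sum(last$rewarding), 16L)

  first <- build_positional_env("first", n_templates = 32)
  expect_true(all(!is.na(first$templates[, 1])))
  expect_true(all(is.na(first$templates[, 2:4])))

  unif <- build_positional_env("uniform", n_templates = 32)
  per_pos <- as.integer(colSums(!is.na(unif$templates)))
  expect_identical(per_pos, c(8L, 8L, 8L, 8L))
  # the informative symbol's identity encodes the label
  for (i in seq_len(nrow(unif$templates))) {
    sym <- unif$alphabet[unif$templates[i, !is.na(unif$templates[i, ])]]
    expect_identical(unif$rewarding[i], sym == "R")
  }
  expect_identical(length(unif$alphabet), 66L)
  expect_error(build_positional_env("last", n_templates = 7), "even")
})

test_that("graded-depth worlds allocate templates geometrically by recency", {
  env <- build_graded_depth_env(500, n_templates = 16)
  expect_identical(length(env$alphabet), 500L)
  expect_identical(sum(env$kind == "informative"), 16L)
  # single informative position at recency k, all wildcards elsewhere
  recency <- apply(env$templates, 1, function(row) {
    pos <- which(!is.na(row))
    expect_length(pos, 1)
    length(row) - pos + 1L
  })
  expect_identical(as.integer(table(factor(recency, levels = 1:4))),
                   c(8L, 4L, 2L, 2L))
  # half rewarding at every recency level
  for (k in 1:4) {
    expect_identical(sum(env$rewarding[recency == k]) * 2L,
                     sum(recency == k))
  }
  # degenerate fractions reduce to the last-position world
  lastish <- build_graded_depth_env(66, depth_fractions = c(1, 0, 0, 0),
                                    n_templates = 16)
  expect_true(all(!is.na(lastish$templates[, 4])))
  expect_true(all(is.na(lastish$templates[, 1:3])))
  expect_error(build_graded_depth_env(66, depth_fractions = c(0.5, 0.5, 0.1, 0)),
               "sum to 1")
})

test_that("order worlds split information between bigrams and singles", {
  # p = 0: singles only, no A/B templates at all
  p0 <- build_order_env(0)
  expect_identical(nrow(p0$templates), 48L)
  has_ab <- apply(p0$templates, 1, function(row) any(row %in% 1:2))
  expect_false(any(has_ab))

  # worked allocation: p = 0.5 with 24 informative templates gives
  # 12 bigram templates (6 per order, 2 per offset) and 12 singles
  p5 <- build_order_env(0.5, n_templates = 24)
  is_bigram <- apply(p5$templates, 1, function(row) {
    sum(row %in% 1:2, na.rm = TRUE) == 2
  })
  expect_identical(sum(is_bigram), 12L)
  bigrams <- p5$templates[is_bigram, , drop = FALSE]
  offsets <- apply(bigrams, 1, function(row) min(which(row %in% 1:2)))
  ab <- apply(bigrams, 1, function(row) {
    row[min(which(row %in% 1:2))] == 1
  })
  expect_identical(as.integer(table(offsets[ab])), c(2L, 2L, 2L))
  expect_identical(as.integer(table(offsets[!ab])), c(2L, 2L, 2L))
  # (A,B) rewarding, (B,A) not
  expect_true(all(p5$rewarding[is_bigram][ab]))
  expect_false(any(p5$rewarding[is_bigram][!ab]))
  singles <- p5$templates[!is_bigram & seq_len(nrow(p5$templates)) <= 24, ,
                          drop = FALSE]
  expect_identical(nrow(singles), 12L)

  # p = 1: every informative template is a bigram
  p1 <- build_order_env(1)
  n_info <- 48L
  expect_identical(sum(apply(p1$templates[seq_len(n_info), ], 1,
                             function(row) sum(row %in% 1:2, na.rm = TRUE))),
                   96L)
  # A and B are part of the wildcard pool ("intermixed with other stimuli")
  expect_true(all(c(1L, 2L) %in% p1$wildcard_pool))
  expect_error(build_order_env(1.2), "in \\[0, 1\\]")
})

test_that("no single temporal position separates reward in order worlds", {
  for (p in c(0.25, 0.5, 1)) {
    env <- build_order_env(p)
    for (pos in seq_len(env$seq_length)) {
      sym <- env$templates[, pos]
      # a position-pos rule must classify wildcard templates too; wildcards
      # occur in both classes, so no rule is perfect
      wild <- is.na(sym)
      perfect <- !any(wild) || length(unique(env$rewarding[wild])) == 1L
      if (perfect) {
        # concrete symbols must then also map 1:1 onto labels
        for (s in unique(sym[!wild])) {
          perfect <- perfect &&
            length(unique(env$rewarding[!wild & sym == s])) == 1L
        }
      }
      expect_false(perfect)
    }
  }
})

test_that("sampling instantiates templates with uniform wildcard fills", {
  env <- build_positional_env("uniform", n_stimuli = 10, n_templates = 8)
  set.seed(42)
  draw <- sample_sequence(env)
  expect_length(draw$sequence, 4)
  expect_true(all(draw$sequence %in% env$alphabet))
  tpl <- env$templates[draw$template, ]
  concrete <- !is.na(tpl)
  expect_identical(draw$sequence[concrete], env$alphabet[tpl[concrete]])
  expect_true(all(draw$sequence[!concrete] %in%
                    env$alphabet[env$kind == "noise"]))
  expect_identical(draw$rewarding, env$rewarding[draw$template])

  # a wildcard-free environment reproduces its templates verbatim
  tpl <- matrix(c(1L, 2L, 1L, 2L, 2L, 1L, 2L, 1L), nrow = 2, byrow = TRUE)
  fixed <- seq_environment(c("a", "b", "z"), c("informative", "informative",
                                               "noise"),
                           tpl, c(TRUE, FALSE))
  set.seed(1)
  for (i in 1:5) {
    d <- sample_sequence(fixed)
    expect_identical(d$sequence, fixed$alphabet[tpl[d$template, ]])
  }
})

test_that("templates are drawn uniformly", {
  env <- build_positional_env("uniform", n_templates = 32)
  set.seed(7)
  idx <- vapply(1:10000, function(i) sample_sequence(env)$template, integer(1))
  counts <- table(factor(idx, levels = seq_len(32)))
  expected <- 10000 / 32
  se <- sqrt(10000 * (1 / 32) * (31 / 32))
  expect_true(all(abs(counts - expected) <= 3 * se))
})

test_that("frozen test sets are complete, balanced and seed-stable", {
  env <- build_positional_env("uniform", n_templates = 32)
  set.seed(11)
  ts <- test_set(env, 10)
  expect_identical(nrow(ts$seq), 320L)
  expect_identical(sum(ts$rewarding), 160L)
  expect_identical(as.integer(table(ts$template)), rep(10L, 32L))
  set.seed(11)
  ts2 <- test_set(env, 10)
  expect_identical(ts, ts2)
  set.seed(12)
  ts3 <- test_set(env, 10)
  expect_false(identical(ts$seq, ts3$seq))
  expect_error(test_set(env, 0), "positive integer")
})

test_that("environments survive a JSON round trip", {
  for (env in list(build_graded_depth_env(20), build_order_env(0.5))) {
    path <- tempfile(fileext = ".json")
    env_to_json(env, path)
    back <- env_from_json(path)
    expect_identical(back$alphabet, env$alphabet)
    expect_identical(back$kind, env$kind)
    expect_identical(back$rewarding, env$rewarding)
    expect_identical(back$templates, env$templates)
    expect_identical(back$wildcard_pool, env$wildcard_pool)
    unlink(path)
  }
})

test_that("environment construction enforces its invariants", {
  tpl <- matrix(c(1L, NA, NA, 2L), nrow = 2)
  expect_error(seq_environment(c("a", "a"), c("informative", "informative"),
                               tpl, c(TRUE, FALSE)), "unique")
  expect_error(seq_environment(c("a", "b"), c("informative", "informative"),
                               tpl, c(TRUE, TRUE)), "half")
  expect_error(seq_environment(c("a", "b"), c("informative", "informative"),
                               tpl, c(TRUE, FALSE)), "wildcard pool is empty")
  expect_error(seq_environment(c("a", "b"), c("informative", "x"),
                               tpl, c(TRUE, FALSE)), "informative")
})
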
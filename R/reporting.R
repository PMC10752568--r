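#' Milestone summary of a strategy comparison
#'
#' Per-strategy summary of a [compare_strategies()] result: mean performance
#' at selected checkpoints, the final mean performance, and the first
#' checkpoint at which the replicate-mean curve reaches the milestone level
#' (0.75 by default).
#'
#' @param x A `"strategy_comparison"` object.
#' @param level Milestone performance level (default 0.75).
#' @param at Optional vector of time-steps at which to report mean
#'   performance (defaults to the last checkpoint only).
#' @return A data.frame with one row per strategy.
#' @export
curve_milestones <- function(x, level = 0.75, at = NULL) {
  stopifnot(inherits(x, "strategy_comparison"))
  rows <- lapply(names(x$curves), function(label) {
    curve <- x$curves[[label]]
    out <- data.frame(environment = curve$environment, strategy = label,
                      final = curve$mean[length(curve$mean)],
                      trials_to_level = trials_to_reach(curve, level),
                      stringsAsFactors = FALSE)
    for (s in at) {
      idx <- which(curve$checkpoints >= s)[1]
      out[[sprintf("at_%d", as.integer(s))]] <-
        if (is.na(idx)) NA_real_ else curve$mean[idx]
    }
    out
  })
  out <- do.call(rbind, rows)
  attr(out, "level") <- level
  out
}

#' Write a comparison table to CSV
#'
#' Writes the long-format curve table (columns `environment`, `strategy`,
#' `replicate`, `step`, `performance`) of one or more comparisons.
#'
#' @param x A `"strategy_comparison"`, or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(x, path) {
  if (inherits(x, "strategy_comparison")) x <- list(x)
  tab <- do.call(rbind, lapply(x, as.data.frame))
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

required_curve_columns <- c("environment", "strategy", "replicate", "step",
                            "performance")

read_curve_table <- function(csv) {
  if (!file.exists(csv)) stop(sprintf("input CSV not found: %s", csv),
                              call. = FALSE)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  missing <- setdiff(required_curve_columns, names(tab))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", csv,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(tab) == 0L) stop(sprintf("%s: table is empty", csv), call. = FALSE)
  tab
}

#' Render learning-curve figures and a milestone summary from CSV
#'
#' Reads a long-format curve table (as written by [write_comparison_csv()]),
#' draws one learning-curve panel per environment (replicate-mean performance
#' per strategy), and writes a machine-readable JSON summary of milestones
#' (performance at the final checkpoint and trials to the milestone level,
#' per strategy per environment). Output is a pure function of the input
#' table: rendering the same CSV twice gives identical summaries.
#'
#' @param csv Path to the input CSV.
#' @param out_prefix Path prefix for outputs; panel `i` is written to
#'   `<out_prefix>-<environment>.png` (or `.svg`) and the summary to
#'   `<out_prefix>-summary.json`.
#' @param level Milestone level (default 0.75).
#' @param format `"png"` or `"svg"`.
#' @return Invisibly, the summary as a data.frame.
#' @export
render_figure <- function(csv, out_prefix, level = 0.75,
                          format = c("png", "svg")) {
  format <- match.arg(format)
  tab <- read_curve_table(csv)
  summaries <- list()
  for (envname in unique(tab$environment)) {
    sub <- tab[tab$environment == envname, , drop = FALSE]
    agg <- stats::aggregate(performance ~ strategy + step, data = sub,
                            FUN = mean)
    strategies <- unique(sub$strategy)  # keep the table's strategy order
    slug <- gsub("[^A-Za-z0-9]+", "_", envname)
    file <- sprintf("%s-%s.%s", out_prefix, slug, format)
    if (format == "png") {
      grDevices::png(file, width = 900, height = 600)
    } else {
      grDevices::svg(file, width = 9, height = 6)
    }
    cols <- grDevices::hcl.colors(max(3L, length(strategies)), "Dark 3")
    graphics::plot(NA, xlim = range(agg$step), ylim = c(0, 1),
                   xlab = "time-steps", ylab = "fraction correct",
                   main = envname)
    graphics::abline(h = 0.5, lty = 3, col = "grey")
    graphics::abline(h = level, lty = 2, col = "grey40")
    for (i in seq_along(strategies)) {
      a <- agg[agg$strategy == strategies[i], , drop = FALSE]
      a <- a[order(a$step), , drop = FALSE]
      graphics::lines(a$step, a$performance, col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright", legend = strategies,
                     col = cols[seq_along(strategies)], lwd = 2, bty = "n")
    grDevices::dev.off()

    for (i in seq_along(strategies)) {
      a <- agg[agg$strategy == strategies[i], , drop = FALSE]
      a <- a[order(a$step), , drop = FALSE]
      reached <- which(a$performance >= level)
      summaries[[length(summaries) + 1L]] <- data.frame(
        environment = envname, strategy = strategies[i],
        final = a$performance[nrow(a)],
        trials_to_level = if (length(reached)) a$step[reached[1]] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, summaries)
  jsonlite::write_json(list(level = level, milestones = summary),
                       sprintf("%s-summary.json", out_prefix),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(summary)
}
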
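# Push-phase detection by force threshold.
#
# A push is a maximal run of samples whose total force stays at or above
# the threshold (30 N by default). Short below-threshold dips are merged
# (sensor chatter), and short surviving runs are discarded. The first two
# and the last detected push of a run are transitional (start-up from
# standstill, final release) and are excluded from analysis.

#' Total (resultant) handrim force
#'
#' Elementwise `sqrt(fx^2 + fy^2 + fz^2)`.
#'
#' @param ts A [wheel_ts()] object (or any data frame with `fx`, `fy`, `fz`).
#' @return Non-negative numeric vector.
#' @export
total_force <- function(ts) {
  sqrt(ts$fx^2 + ts$fy^2 + ts$fz^2)
}

new_push_set <- function(df, n_detected, excluded, audit = character()) {
  new_tibble(df, n_detected = n_detected, excluded = excluded,
             audit = audit, class = "pushrim_pushes")
}

#' Detect push phases in a total-force series
#'
#' Finds maximal runs with `ftot >= threshold`; below-threshold gaps
#' shorter than `min_gap` are merged into a single push, and merged runs
#' shorter than `min_push` are discarded. Transitional-push exclusion is a
#' separate step ([exclude_transitional()]), so `n_analyzed` is `NA` here.
#'
#' @param ftot Non-negative total-force series (N).
#' @param fs Sampling rate in Hz.
#' @param threshold Detection threshold in newtons (default 30).
#' @param min_push Minimum push duration in seconds (default 0.10).
#' @param min_gap Maximum mergeable gap in seconds (default 0.05).
#'
#' @return A `pushrim_pushes` tibble: columns `push`, `start_index`,
#'   `end_index` (1-based, inclusive), `analyzed` (all `FALSE` until
#'   exclusion); attributes `n_detected`, `excluded`.
#' @export
detect_pushes <- function(ftot, fs, threshold = 30, min_push = 0.10,
                          min_gap = 0.05) {
  check_number(fs, "fs", min = 1e-6)
  above <- ftot >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1) {
    # merge runs separated by a below-threshold gap shorter than min_gap
    gap <- runs$start[-1] - runs$end[-nrow(runs)] - 1L
    keep_sep <- gap >= min_gap * fs
    grp <- cumsum(c(TRUE, keep_sep))
    runs <- runs |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
      select("start", "end")
  }
  if (nrow(runs) > 0) {
    dur <- (runs$end - runs$start + 1L) / fs
    runs <- runs[dur >= min_push, , drop = FALSE]
  }
  df <- tibble(
    push = seq_len(nrow(runs)),
    start_index = as.integer(runs$start),
    end_index = as.integer(runs$end),
    analyzed = FALSE
  )
  new_push_set(df, n_detected = nrow(df), excluded = FALSE)
}

#' Number of detected / analyzed pushes
#'
#' @param pushes A `pushrim_pushes` tibble.
#' @return Integer count.
#' @export
n_detected <- function(pushes) attr(pushes, "n_detected")

#' @rdname n_detected
#' @export
n_analyzed <- function(pushes) {
  if (!isTRUE(attr(pushes, "excluded"))) return(NA_integer_)
  sum(pushes$analyzed)
}

#' Exclude transitional pushes
#'
#' Marks the first two and the last detected push as transitional
#' (acceleration from standstill and final release) and the remainder as
#' analyzed. At least 4 detected pushes are required, otherwise no
#' analyzable push remains.
#'
#' @param pushes A `pushrim_pushes` tibble from [detect_pushes()].
#' @return The same tibble with `analyzed` set and `n_analyzed` defined.
#' @export
exclude_transitional <- function(pushes) {
  nd <- nrow(pushes)
  if (nd < 4) {
    abort_pushrim(
      sprintf("only %d push(es) detected; need >= 4 so at least one survives transitional exclusion", nd),
      class = "insufficient_pushes"
    )
  }
  pushes$analyzed <- seq_len(nd) >= 3L & seq_len(nd) <= nd - 1L
  attr(pushes, "excluded") <- TRUE
  pushes
}

#' Apply manual review edits to a push set
#'
#' Reproducible counterpart of a manual segmentation check: a list of
#' directives, each `list(action =, ...)` with actions
#' `"remove"` (`push = detection index`), `"add"` (`start_index`,
#' `end_index`) or `"adjust"` (`push`, plus new `start_index` and/or
#' `end_index`). After each directive the push set is re-sorted, checked
#' for overlaps, renumbered, and (if transitional exclusion had been
#' applied) re-excluded. Every directive is appended to the audit log
#' (`segmentation_audit()`).
#'
#' @param pushes A `pushrim_pushes` tibble.
#' @param edits List of directives; an empty list returns the input
#'   unchanged.
#' @return The edited `pushrim_pushes` tibble.
#' @export
review_segmentation <- function(pushes, edits = list()) {
  if (length(edits) == 0) return(pushes)
  audit <- attr(pushes, "audit") %||% character()
  was_excluded <- isTRUE(attr(pushes, "excluded"))
  df <- as_tibble(pushes)
  for (e in edits) {
    action <- check_choice(e$action %||% "", "action", c("remove", "add", "adjust"))
    if (action == "remove") {
      i <- e$push
      if (is.null(i) || !i %in% df$push) {
        abort_pushrim("remove directive names an unknown push", class = "value")
      }
      df <- df[df$push != i, , drop = FALSE]
      audit <- c(audit, sprintf("remove push %d", i))
    } else if (action == "add") {
      s <- e$start_index; en <- e$end_index
      if (is.null(s) || is.null(en) || s > en || s < 1) {
        abort_pushrim("add directive needs valid start_index <= end_index", class = "value")
      }
      df <- bind_rows(df, tibble(push = NA_integer_, start_index = as.integer(s),
                                 end_index = as.integer(en), analyzed = FALSE))
      audit <- c(audit, sprintf("add push [%d, %d]", s, en))
    } else {
      i <- e$push
      if (is.null(i) || !i %in% df$push) {
        abort_pushrim("adjust directive names an unknown push", class = "value")
      }
      row <- which(df$push == i)
      s <- e$start_index %||% df$start_index[row]
      en <- e$end_index %||% df$end_index[row]
      if (s > en || s < 1) {
        abort_pushrim("adjust directive produces an invalid interval", class = "value")
      }
      df$start_index[row] <- as.integer(s)
      df$end_index[row] <- as.integer(en)
      audit <- c(audit, sprintf("adjust push %d to [%d, %d]", i, s, en))
    }
  }
  df <- arrange(df, .data$start_index)
  if (nrow(df) > 1) {
    overlap <- df$start_index[-1] <= df$end_index[-nrow(df)]
    if (any(overlap)) {
      abort_pushrim("edits produce overlapping pushes", class = "overlap")
    }
  }
  df$push <- seq_len(nrow(df))
  df$analyzed <- FALSE
  out <- new_push_set(df, n_detected = nrow(df), excluded = FALSE, audit = audit)
  if (was_excluded) out <- exclude_transitional(out)
  out
}

#' Audit log of segmentation edits
#'
#' @param pushes A `pushrim_pushes` tibble.
#' @return Character vector, one entry per applied directive.
#' @export
segmentation_audit <- function(pushes) attr(pushes, "audit") %||% character()

#' @export
print.pushrim_pushes <- function(x, ...) {
  na <- n_analyzed(x)
  cat(sprintf("<push set: %d detected, %s analyzed>\n", n_detected(x),
              if (is.na(na)) "exclusion not applied" else na))
  NextMethod()
}
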
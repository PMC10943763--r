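courtship_elements <- c("orientation", "tapping", "singing", "attempted_copulation")
all_labels <- c(courtship_elements, "copulation", "none")

#' Build an ethogram from a certified label sequence
#'
#' An ethogram is the per-frame behavior label time series plus an
#' observation window. Three window conventions are supported: the full
#' recording, the span from the beginning to copulation onset (the usual
#' convention for mated males), or a fixed duration in seconds (used to
#' compare groups over equal spans; the duration is data-derived and so a
#' parameter, never a constant).
#'
#' @param labels Character vector of certified labels
#'   (orientation/tapping/singing/attempted_copulation/copulation/none).
#' @param fps Frames per second.
#' @param window `"full"`, `"to_copulation"`, or `"seconds"`.
#' @param window_seconds Window length when `window = "seconds"`.
#' @return A `fly_ethogram` object.
#' @export
ethogram <- function(labels, fps, window = c("full", "to_copulation", "seconds"),
                     window_seconds = NULL) {
  window <- match.arg(window)
  stopifnot(fps > 0, length(labels) > 0)
  bad <- setdiff(unique(labels), all_labels)
  if (length(bad) > 0) stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  n <- length(labels)
  end <- n
  if (window == "to_copulation") {
    onset <- match("copulation", labels)
    if (!is.na(onset)) end <- onset - 1L
  } else if (window == "seconds") {
    if (is.null(window_seconds)) stop("window_seconds required", call. = FALSE)
    end <- min(n, round(window_seconds * fps))
  }
  if (end < 1) stop("observation window is empty", call. = FALSE)
  structure(list(labels = labels, fps = fps, window = c(1L, as.integer(end)),
                 window_kind = window),
            class = "fly_ethogram")
}

window_labels <- function(e) e$labels[e$window[1]:e$window[2]]

#' Total courtship time
#'
#' Seconds spent in any of the four courtship elements (orientation,
#' tapping, singing, attempted copulation) inside the observation window;
#' copulation itself and `none` are excluded.
#'
#' @param e A `fly_ethogram`.
#' @return Seconds (numeric scalar).
#' @export
total_courtship_time <- function(e) {
  stopifnot(inherits(e, "fly_ethogram"))
  sum(window_labels(e) %in% courtship_elements) / e$fps
}

#' Proportion of each behavioral element
#'
#' Frames of each element divided by the observation-window length in
#' frames.
#'
#' @param e A `fly_ethogram`.
#' @return Tibble: `element`, `frames`, `proportion` (one row per label
#'   including copulation and none; the four courtship proportions sum to
#'   at most 1).
#' @export
element_proportions <- function(e) {
  stopifnot(inherits(e, "fly_ethogram"))
  lab <- window_labels(e)
  counts <- table(factor(lab, levels = all_labels))
  tibble::tibble(
    element = names(counts),
    frames = as.integer(counts),
    proportion = as.numeric(counts) / length(lab)
  )
}

#' Behavioral transition matrix
#'
#' Counts changes from element A to element B (A != B; self-transitions are
#' not changes) over the certified label sequence in the window, and
#' row-normalizes: P(A -> B) = changes A -> B / all changes out of A. By
#' default a `none` stretch breaks the chain (A, none, B is not a change
#' A -> B); set `bridge_none = TRUE` to bridge across gaps.
#'
#' @param e A `fly_ethogram`.
#' @param bridge_none Bridge transitions across `none` stretches.
#' @param include_copulation Keep copulation as a (terminal) state.
#' @return A `transition_matrix` list: `elements`, `counts`,
#'   `probabilities` (rows with no outgoing change are NA and flagged in
#'   `undefined_rows`).
#' @export
transition_matrix <- function(e, bridge_none = FALSE, include_copulation = TRUE) {
  stopifnot(inherits(e, "fly_ethogram"))
  lab <- window_labels(e)
  states <- c(courtship_elements, if (include_copulation) "copulation")
  seqs <- if (bridge_none) list(lab[lab != "none"]) else {
    split(lab, cumsum(lab == "none"))
  }
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(from = states, to = states))
  for (s in seqs) {
    s <- s[s != "none"]
    s <- s[s %in% states]
    if (length(s) < 2) next
    r <- rle(s)$values
    if (length(r) < 2) next
    for (i in seq_len(length(r) - 1)) {
      counts[r[i], r[i + 1]] <- counts[r[i], r[i + 1]] + 1L
    }
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, NA_real_, rs)
  structure(list(elements = states, counts = counts, probabilities = probs,
                 undefined_rows = names(rs)[rs == 0]),
            class = "transition_matrix")
}

#' Machine-readable courtship pattern summary
#'
#' Bundles element proportions and the transition matrix into one list that
#' serializes losslessly to JSON; the companion [autoplot.courtship_summary()]
#' draws the pattern diagram (nodes sized by proportion, arrows weighted by
#' transition probability).
#'
#' @param proportions Tibble from [element_proportions()].
#' @param tm A `transition_matrix`.
#' @return A `courtship_summary` list.
#' @export
courtship_pattern_summary <- function(proportions, tm) {
  structure(list(
    proportions = stats::setNames(as.list(proportions$proportion), proportions$element),
    transition_counts = apply(tm$counts, 1, as.list, simplify = FALSE),
    transition_probabilities = apply(tm$probabilities, 1, as.list, simplify = FALSE),
    elements = tm$elements
  ), class = "courtship_summary")
}

#' Write / read a courtship summary as JSON
#' @param x A `courtship_summary`.
#' @param path Output path.
#' @return `path`, invisibly (write); a `courtship_summary` (read).
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE), class = "courtship_summary")
}

#' @exportS3Method generics::tidy
tidy.fly_ethogram <- function(x, ...) {
  tibble::tibble(
    frame = seq_along(x$labels) - 1L,
    time_s = (seq_along(x$labels) - 1L) / x$fps,
    label = x$labels,
    in_window = seq_along(x$labels) >= x$window[1] & seq_along(x$labels) <= x$window[2]
  )
}

#' @exportS3Method generics::glance
glance.fly_ethogram <- function(x, ...) {
  onset <- match("copulation", x$labels)
  tibble::tibble(
    n_frames = length(x$labels),
    fps = x$fps,
    window_frames = x$window[2] - x$window[1] + 1L,
    total_courtship_s = total_courtship_time(x),
    courtship_index = total_courtship_time(x) * x$fps / (x$window[2] - x$window[1] + 1L),
    copulated = !is.na(onset),
    copulation_onset_s = if (is.na(onset)) NA_real_ else (onset - 1) / x$fps
  )
}

#' @exportS3Method generics::tidy
tidy.transition_matrix <- function(x, ...) {
  df <- as.data.frame.table(x$counts, stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "n")
  df$probability <- as.vector(x$probabilities)
  tibble::as_tibble(df)
}

#' @exportS3Method ggplot2::autoplot
autoplot.fly_ethogram <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = 1, fill = .data$label)) +
    ggplot2::geom_tile(height = 1) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "element",
                  title = "Courtship ethogram") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.transition_matrix <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$to, y = .data$from, fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(is.na(.data$probability), "",
                                                   sprintf("%.2f", .data$probability))),
                       size = 3) +
    ggplot2::labs(title = "Behavioral transitions", x = "to", y = "from") +
    ggplot2::theme_minimal()
}

#' Courtship pattern diagram
#'
#' Nodes (one per element, laid out on a circle) are sized by the element's
#' time proportion and arrows weighted by transition probability.
#'
#' @param object A `courtship_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.courtship_summary <- function(object, ...) {
  el <- unlist(object$elements)
  k <- length(el)
  th <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
  nodes <- tibble::tibble(
    element = el, x = cos(th), y = sin(th),
    proportion = vapply(el, function(e) {
      p <- object$proportions[[e]]
      if (is.null(p)) 0 else as.numeric(p)
    }, numeric(1))
  )
  edges <- tidy_summary_edges(object, nodes)
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
                   linewidth = .data$probability),
      arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt")), color = "grey40"
    )
  }
  p +
    ggplot2::geom_point(ggplot2::aes(size = .data$proportion), color = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$element), vjust = -1.6, size = 3) +
    ggplot2::scale_size_area(max_size = 18) +
    ggplot2::coord_equal(xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Courtship pattern")
}

tidy_summary_edges <- function(object, nodes) {
  out <- list()
  for (from in names(object$transition_probabilities)) {
    row <- object$transition_probabilities[[from]]
    for (to in names(row)) {
      pr <- row[[to]]
      if (is.null(pr) || is.na(pr) || pr <= 0 || from == to) next
      a <- nodes[nodes$element == from, ]; b <- nodes[nodes$element == to, ]
      if (nrow(a) == 0 || nrow(b) == 0) next
      shrink <- 0.12
      dx <- b$x - a$x; dy <- b$y - a$y
      out[[length(out) + 1]] <- tibble::tibble(
        from = from, to = to, probability = as.numeric(pr),
        x0 = a$x + shrink * dx, y0 = a$y + shrink * dy,
        x1 = b$x - shrink * dx, y1 = b$y - shrink * dy
      )
    }
  }
  if (length(out) == 0) {
    tibble::tibble(from = character(0), to = character(0), probability = numeric(0),
                   x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0))
  } else {
    dplyr::bind_rows(out)
  }
}
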
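#' Tidiers and plots for anonymization results
#'
#' `tidy()` on a `p4_anonymization` returns one row per partition
#' (scheme, size, suppression); on a `p4_report` one row per pipeline
#' stage; on an `anon_result` one row per equivalence class.  `glance()`
#' returns a one-row summary.  `autoplot()` on a `p4_report` draws the
#' per-step time consumption; on a `fidelity_summary` the per-attribute
#' fidelity.
#'
#' @param x The object.
#' @param ... Unused.
#' @name p4-tidiers
NULL

scheme_label <- function(s) {
  if (is.null(s)) NA_character_ else paste(s, collapse = ",")
}

#' @rdname p4-tidiers
#' @export
tidy.p4_anonymization <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    partition = seq_len(r$partitions),
    scheme = vapply(r$per_partition_schemes, scheme_label, character(1))
  )
}

#' @rdname p4-tidiers
#' @export
glance.p4_anonymization <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n = r$n,
    partitions = r$partitions,
    mode = r$mode,
    fidelity = r$fidelity,
    suppressed = unname(r$suppressed_counts[["finalization"]]),
    harmonized_scheme = scheme_label(r$harmonized_scheme),
    total_seconds = sum(r$step_durations)
  )
}

#' @rdname p4-tidiers
#' @export
tidy.p4_report <- function(x, ...) {
  tibble::tibble(
    stage = names(x$step_durations),
    seconds = unname(x$step_durations),
    suppressed = unname(x$suppressed_counts[names(x$step_durations)])
  )
}

#' @rdname p4-tidiers
#' @export
glance.p4_report <- function(x, ...) {
  tibble::tibble(
    n = x$n, partitions = x$partitions, mode = x$mode,
    fidelity = x$fidelity,
    suppressed = unname(x$suppressed_counts[["finalization"]]),
    total_seconds = sum(x$step_durations)
  )
}

#' @rdname p4-tidiers
#' @export
tidy.anon_result <- function(x, ...) {
  if (is.null(x$classes)) return(tibble::tibble())
  dplyr::select(x$classes, dplyr::any_of(c("key", "size")))
}

#' @rdname p4-tidiers
#' @export
glance.anon_result <- function(x, ...) {
  tibble::tibble(
    n = x$n, mode = x$mode,
    scheme = scheme_label(x$scheme),
    suppressed = length(x$suppressed_row_ids),
    fidelity = x$fidelity
  )
}

#' @rdname p4-tidiers
#' @export
autoplot.p4_report <- function(x, ...) {
  d <- tidy(x)
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot2::ggplot(d, ggplot2::aes(x = "run", y = .data$seconds,
                                  fill = .data$stage)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "seconds", fill = "step",
      title = sprintf("Per-step time, %d partition(s), %s mode (fidelity %.3f)",
                      x$partitions, x$mode, x$fidelity)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname p4-tidiers
#' @export
autoplot.p4_anonymization <- function(x, ...) autoplot(x$report, ...)

#' @rdname p4-tidiers
#' @export
autoplot.fidelity_summary <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$attribute, y = .data$mean_fidelity)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "mean fidelity",
                  title = sprintf("Domain-coverage fidelity (overall %.3f)",
                                  x$mean_fidelity)) +
    ggplot2::theme_minimal()
}
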
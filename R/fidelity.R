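#' Domain-coverage data fidelity
#'
#' Utility is measured as the degree to which output values still pin down
#' the domain of the original input values.  A cell generalized to a value
#' covering `c` of the `D` leaves of its hierarchy has fidelity
#' `1 - (c - 1)/(D - 1)` (for `D > 1`; single-leaf domains have fidelity
#' 1): an untouched leaf scores 1, the suppression symbol `"*"`, which
#' covers the whole domain, scores 0.  Record fidelity is the mean over
#' the record's quasi-identifier cells, with fully suppressed records
#' scoring 0; dataset fidelity is the mean over records.  The same metric
#' serves as the lattice-search objective and as the reported utility.
#'
#' @param h A [build_hierarchy()] object.
#' @param value Character vector of values valid at `level`.
#' @param level Generalization level the values live at.
#' @return `cell_fidelity()`: numeric vector in `[0, 1]`.
#' @examples
#' h <- generate_hierarchy(4, 2)
#' cell_fidelity(h, "v1", 0)
#' cell_fidelity(h, "*", h$L)
#' @export
cell_fidelity <- function(h, value, level) {
  stopifnot(inherits(h, "gen_hierarchy"))
  if (h$n_leaves == 1L) return(rep(1, length(value)))
  covered <- leaves_covered(h, value, level)
  1 - (covered - 1) / (h$n_leaves - 1)
}

## Fidelity of output labels whose level is unknown (local recoding mixes
## levels).  A label's coverage is the number of distinct leaves whose
## hierarchy row contains it at any level; "*" outside the hierarchy is the
## suppression symbol and scores 0.
label_fidelity_map <- function(h) {
  labels <- sort_c(as.vector(h$levels))
  D <- h$n_leaves
  covered <- vapply(labels, function(v) {
    sum(apply(h$levels == v, 1L, any))
  }, numeric(1))
  f <- if (D == 1L) rep(1, length(labels)) else 1 - (covered - 1) / (D - 1)
  map <- setNames(f, labels)
  if (!.p4_star %in% names(map)) map[[.p4_star]] <- 0
  map
}

#' Fidelity of a generalized dataset
#'
#' @param data A generalized output dataset (tibble).
#' @param config The [anon_config()] whose hierarchies the output was
#'   generalized against.
#' @return A `fidelity_summary`: `record_count`, `mean_fidelity`, and
#'   `per_attribute_mean` (named, quasi-identifiers only).
#' @rdname cell_fidelity
#' @export
dataset_fidelity <- function(data, config) {
  stopifnot(inherits(config, "anon_config"))
  qis <- config$quasi_identifiers
  n <- nrow(data)
  if (n == 0L) {
    return(structure(
      list(record_count = 0L, mean_fidelity = NA_real_,
           per_attribute_mean = setNames(rep(NA_real_, length(qis)), qis)),
      class = "fidelity_summary"
    ))
  }
  cellf <- matrix(0, nrow = n, ncol = length(qis),
                  dimnames = list(NULL, qis))
  for (a in qis) {
    map <- label_fidelity_map(config$hierarchies[[a]])
    x <- data[[a]]
    unknown <- setdiff(unique(x), names(map))
    if (length(unknown) > 0L) {
      abort_p4(sprintf("attribute '%s': output value '%s' not found in its hierarchy",
                       a, unknown[[1L]]),
               "p4_error_unknown_value")
    }
    cellf[, a] <- unname(map[x])
  }
  ## fully suppressed records score 0 on every cell by construction ("*")
  recf <- rowMeans(cellf)
  structure(
    list(
      record_count = n,
      mean_fidelity = mean(recf),
      per_attribute_mean = colMeans(cellf)
    ),
    class = "fidelity_summary"
  )
}

#' @export
print.fidelity_summary <- function(x, ...) {
  cat(sprintf("<fidelity_summary: %d records, mean fidelity %.4f>\n",
              x$record_count, x$mean_fidelity))
  invisible(x)
}

#' @export
tidy.fidelity_summary <- function(x, ...) {
  tibble::tibble(attribute = names(x$per_attribute_mean),
                 mean_fidelity = unname(x$per_attribute_mean))
}

#' @export
glance.fidelity_summary <- function(x, ...) {
  tibble::tibble(record_count = x$record_count, mean_fidelity = x$mean_fidelity)
}

#' Pool per-partition fidelity summaries
#'
#' The record-weighted mean of per-partition fidelities, which is
#' identical to computing [dataset_fidelity()] on the concatenated output.
#'
#' @param parts List of `fidelity_summary` objects.
#' @return A number in `[0, 1]`.
#' @rdname cell_fidelity
#' @export
pooled_fidelity <- function(parts) {
  if (length(parts) == 0L) abort_p4("no partitions to pool", "p4_error_fidelity")
  n <- vapply(parts, function(p) as.numeric(p$record_count), numeric(1))
  f <- vapply(parts, function(p) p$mean_fidelity, numeric(1))
  keep <- n > 0
  if (!any(keep)) abort_p4("pooled fidelity over zero records", "p4_error_fidelity")
  sum(n[keep] * f[keep]) / sum(n[keep])
}

#' Relative utility reduction against a baseline
#'
#' `100 * (baseline - value) / baseline`, in percent.  Gains show up as
#' negative reductions.
#'
#' @param baseline Baseline fidelity, must be positive.
#' @param value Observed fidelity.
#' @return Percentage reduction.
#' @export
relative_reduction <- function(baseline, value) {
  if (any(baseline <= 0)) {
    abort_p4("`baseline` must be positive", "p4_error_fidelity")
  }
  100 * (baseline - value) / baseline
}
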
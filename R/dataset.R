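#' Read and write datasets
#'
#' Datasets are delimited text files with a header row.  Every cell is
#' read as text: numeric attributes are handled through interval
#' hierarchies, so no cell value is ever coerced.  Empty strings are
#' ordinary values (they must appear in the hierarchy like any other
#' leaf); there is no implicit missing-value handling.  Row ids are
#' assigned in file order into the `.row_id` column and stay stable
#' through every transformation, so callers can always restore the
#' original record order.
#'
#' @param path File path.
#' @param config An [anon_config()]; supplies the CSV dialect and the
#'   attribute names the header must contain.
#' @return `load_dataset()`: a tibble of character columns plus `.row_id`.
#' @export
load_dataset <- function(path, config) {
  stopifnot(inherits(config, "anon_config"))
  if (!file.exists(path)) {
    abort_p4(sprintf("dataset file '%s' does not exist", path), "p4_error_io")
  }
  d <- readr::read_delim(
    path,
    delim = config$csv_delimiter,
    quote = config$csv_quote,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    progress = FALSE,
    show_col_types = FALSE
  )
  probs <- readr::problems(d)
  if (nrow(probs) > 0L) {
    abort_p4(sprintf("'%s' line %d: %s", path, probs$row[[1L]] + 1L,
                     probs$expected[[1L]]),
             "p4_error_io")
  }
  expected <- attribute_roles(config)$name
  missing <- setdiff(expected, names(d))
  if (length(missing) > 0L) {
    abort_p4(sprintf("'%s': configured attribute '%s' missing from header",
                     path, missing[[1L]]),
             "p4_error_io")
  }
  d <- d[expected]
  d$.row_id <- seq_len(nrow(d))
  d
}

#' @rdname load_dataset
#' @param data A dataset tibble.
#' @param keep_row_ids Emit the `.row_id` column so consumers can restore
#'   the original record order.
#' @return `write_dataset()`: `path`, invisibly.
#' @export
write_dataset <- function(data, path, config, keep_row_ids = FALSE) {
  stopifnot(inherits(config, "anon_config"))
  if (!keep_row_ids) data <- data[setdiff(names(data), ".row_id")]
  readr::write_delim(data, path, delim = config$csv_delimiter, na = "")
  invisible(path)
}

ensure_row_ids <- function(data) {
  if (!".row_id" %in% names(data)) data$.row_id <- seq_len(nrow(data))
  data
}

#' Reference distribution of the sensitive attributes
#'
#' The relative frequencies of each sensitive attribute's values in the
#' scoped data.  These are the reference distributions `q` that
#' t-closeness, delta-disclosure and beta-likeness compare each
#' equivalence class against.  During partition-parallel anonymization,
#' each partition is anonymized against its own (`scope = "partition"`)
#' distribution, while compliance checking and final verification use the
#' distribution of the complete input (`scope = "global"`).
#'
#' @param data A dataset tibble.
#' @param config An [anon_config()].
#' @param scope `"global"` or `"partition"`; a label recording what the
#'   distribution describes.
#' @return A `reference_stats` object: `n` (record count), `dist` (named
#'   list of named probability vectors, one per sensitive attribute) and
#'   `scope`.
#' @export
reference_stats <- function(data, config, scope = c("global", "partition")) {
  stopifnot(inherits(config, "anon_config"))
  scope <- match.arg(scope)
  n <- nrow(data)
  dist <- lapply(setNames(nm = config$sensitive), function(a) {
    x <- data[[a]]
    lev <- sort_c(x)
    tab <- tabulate(match(x, lev), nbins = length(lev))
    setNames(tab / n, lev)
  })
  structure(list(n = n, dist = dist, scope = scope), class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats: n=%d, scope=%s>\n", x$n, x$scope))
  for (a in names(x$dist)) {
    cat(" ", a, ":", paste(sprintf("%s=%.3g", names(x$dist[[a]]), x$dist[[a]]),
                           collapse = ", "), "\n")
  }
  invisible(x)
}

## ---------------------------------------------------------------------------
## Engine context: per-dataset precomputation shared by every lattice node.
## For each quasi-identifier we cache the leaf index of every record, the
## leaf-by-level matrix of generalized labels, and the matching matrix of
## per-cell fidelities, so evaluating a node costs one subscript per cell.

build_ctx <- function(data, config) {
  qis <- config$quasi_identifiers
  data <- ensure_row_ids(data)
  n <- nrow(data)
  leaf_idx <- list()
  gen <- list()
  fid <- list()
  for (a in qis) {
    h <- config$hierarchies[[a]]
    idx <- match(data[[a]], h$levels[, 1L])
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[[1L]]
      abort_p4(
        sprintf("attribute '%s', row id %s: value '%s' is not a leaf of its hierarchy",
                a, data$.row_id[[bad]], data[[a]][[bad]]),
        "p4_error_unknown_value"
      )
    }
    leaf_idx[[a]] <- idx
    gen[[a]] <- h$levels
    D <- h$n_leaves
    fm <- matrix(1, nrow = D, ncol = h$L + 1L)
    if (D > 1L) {
      for (j in seq_len(h$L + 1L)) {
        col <- h$levels[, j]
        covered <- as.vector(table(col)[col])
        fm[, j] <- 1 - (covered - 1) / (D - 1)
      }
    }
    fid[[a]] <- fm
  }
  list(data = data, n = n, qis = qis, leaf_idx = leaf_idx, gen = gen,
       fid = fid, config = config)
}

## Generalized quasi-identifier columns of every record under `scheme`.
ctx_gen_cols <- function(ctx, scheme) {
  lapply(setNames(nm = ctx$qis), function(a) {
    ctx$gen[[a]][ctx$leaf_idx[[a]], scheme[[a]] + 1L]
  })
}

## Per-record fidelity (mean over quasi-identifier cells) under `scheme`.
ctx_record_fid <- function(ctx, scheme) {
  acc <- numeric(ctx$n)
  for (a in ctx$qis) {
    acc <- acc + ctx$fid[[a]][ctx$leaf_idx[[a]], scheme[[a]] + 1L]
  }
  acc / length(ctx$qis)
}

#' Group records into equivalence classes
#'
#' Applies a generalization scheme to the quasi-identifiers and groups
#' records with identical generalized tuples.  Classes partition the row
#' ids and are returned in lexicographic (codepoint) key order.
#'
#' @param data A dataset tibble.
#' @param config An [anon_config()].
#' @param scheme Generalization scheme: integer vector of levels, one per
#'   quasi-identifier (named or in configuration order).
#' @return A tibble with one row per class: the generalized
#'   quasi-identifier columns, `key` (the tuple joined for display),
#'   `size`, `row_ids` (list of integer vectors) and `counts` (list of
#'   named count vectors per sensitive attribute).
#' @examples
#' syn <- generate_dataset(20, qi_domains = c(4, 4), seed = 1)
#' cfg <- anon_config(syn$quasi_identifiers, syn$hierarchies,
#'                    sensitive = syn$sensitive)
#' group_into_classes(syn$data, cfg, c(1, 0))
#' @export
group_into_classes <- function(data, config, scheme) {
  stopifnot(inherits(config, "anon_config"))
  data <- ensure_row_ids(data)
  scheme <- normalize_scheme(scheme, config)
  if (nrow(data) == 0L) {
    out <- tibble::as_tibble(setNames(
      rep(list(character(0)), length(config$quasi_identifiers)),
      config$quasi_identifiers
    ))
    out$key <- character(0)
    out$size <- integer(0)
    out$row_ids <- list()
    out$counts <- list()
    return(out)
  }
  ctx <- build_ctx(data, config)
  cols <- ctx_gen_cols(ctx, scheme)
  key <- do.call(paste, c(unname(cols), list(sep = .p4_sep)))
  kf <- factor(key, levels = sort_c(key))
  idx <- split(seq_len(ctx$n), kf)
  keys <- names(idx)
  parts <- strsplit(keys, .p4_sep, fixed = TRUE)
  km <- do.call(rbind, parts)
  out <- tibble::as_tibble(setNames(
    lapply(seq_along(ctx$qis), function(j) km[, j]), ctx$qis
  ))
  out$key <- gsub(.p4_sep, "|", keys, fixed = TRUE)
  out$size <- unname(lengths(idx))
  out$row_ids <- unname(lapply(idx, function(i) data$.row_id[i]))
  out$counts <- unname(lapply(idx, function(i) {
    lapply(setNames(nm = config$sensitive), function(a) {
      x <- data[[a]][i]
      lev <- sort_c(x)
      setNames(tabulate(match(x, lev), nbins = length(lev)), lev)
    })
  }))
  out
}

normalize_scheme <- function(scheme, config) {
  qis <- config$quasi_identifiers
  if (!is.null(names(scheme))) {
    if (!setequal(names(scheme), qis)) {
      abort_p4("scheme names must match the quasi-identifiers", "p4_error_scheme")
    }
    scheme <- scheme[qis]
  } else if (length(scheme) != length(qis)) {
    abort_p4(sprintf("scheme has length %d, expected %d (one level per quasi-identifier)",
                     length(scheme), length(qis)),
             "p4_error_scheme")
  }
  scheme <- setNames(as.integer(scheme), qis)
  for (a in qis) {
    L <- config$hierarchies[[a]]$L
    if (is.na(scheme[[a]]) || scheme[[a]] < 0L || scheme[[a]] > L) {
      abort_p4(sprintf("level %s for '%s' outside [0, %d]", scheme[[a]], a, L),
               "p4_error_scheme")
    }
  }
  scheme
}
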
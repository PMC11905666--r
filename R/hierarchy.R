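#' Build a generalization hierarchy
#'
#' A generalization hierarchy maps every leaf value of an attribute to its
#' generalized value at each level `0..L`.  Level 0 is the value itself;
#' the highest level is conventionally the single suppression symbol `"*"`.
#' Hierarchies drive both value generalization and the domain-coverage
#' fidelity metric.
#'
#' @param rows The hierarchy table: a data frame, character matrix, or list
#'   of equal-length character vectors.  One row per distinct leaf value;
#'   column `j` (1-based) holds the generalization at level `j - 1`.
#'
#' @return An object of class `gen_hierarchy` with fields `levels`
#'   (character matrix, one row per leaf, columns `level_0..level_L`),
#'   `L` (maximum level) and `n_leaves` (domain size).
#'
#' @details Validation enforces that leaf values (level 0) are unique, that
#'   the table is rectangular, and that the mapping is functionally
#'   consistent: two rows that agree at level `j` must also agree at every
#'   level above `j`, otherwise a generalized value would not determine its
#'   own further generalization.
#'
#' @examples
#' h <- build_hierarchy(list(
#'   c("30", "30-31", "*"), c("31", "30-31", "*"),
#'   c("32", "32-33", "*"), c("33", "32-33", "*")
#' ))
#' generalize_value(h, "30", 1)
#' leaves_covered(h, "30-31", 1)
#' @seealso [load_hierarchy()], [generalize_value()], [leaves_covered()]
#' @export
build_hierarchy <- function(rows) {
  if (is.data.frame(rows)) {
    m <- as.matrix(rows)
  } else if (is.matrix(rows)) {
    m <- rows
  } else if (is.list(rows)) {
    lens <- lengths(rows)
    if (length(rows) == 0L) abort_p4("hierarchy has no rows", "p4_error_hierarchy")
    if (length(unique(lens)) != 1L) {
      bad <- which(lens != lens[[1L]])[1L]
      abort_p4(
        sprintf("hierarchy rows are ragged: row %d has %d column(s), expected %d",
                bad, lens[[bad]], lens[[1L]]),
        "p4_error_ragged"
      )
    }
    m <- do.call(rbind, lapply(rows, as.character))
  } else {
    abort_p4("`rows` must be a data frame, matrix or list of character vectors",
             "p4_error_hierarchy")
  }
  if (nrow(m) == 0L || ncol(m) == 0L) {
    abort_p4("hierarchy has no rows", "p4_error_hierarchy")
  }
  storage.mode(m) <- "character"
  m[is.na(m)] <- ""
  dimnames(m) <- list(NULL, paste0("level_", seq_len(ncol(m)) - 1L))

  dup <- m[duplicated(m[, 1L]), 1L]
  if (length(dup) > 0L) {
    abort_p4(sprintf("duplicate leaf value '%s' in hierarchy", dup[[1L]]),
             "p4_error_duplicate_leaf")
  }
  L <- ncol(m) - 1L
  if (L >= 1L) {
    for (j in seq_len(L)) {
      images <- split(m[, j + 1L], m[, j])
      n_img <- vapply(images, function(v) length(unique(v)), integer(1))
      if (any(n_img > 1L)) {
        v <- names(images)[n_img > 1L][[1L]]
        tg <- unique(images[[v]])
        abort_p4(
          sprintf(
            "hierarchy is not functionally consistent: level-%d value '%s' maps to both '%s' and '%s' at level %d",
            j - 1L, v, tg[[1L]], tg[[2L]], j
          ),
          "p4_error_inconsistent"
        )
      }
    }
  }
  structure(
    list(levels = m, L = L, n_leaves = nrow(m)),
    class = "gen_hierarchy"
  )
}

#' @export
print.gen_hierarchy <- function(x, ...) {
  cat(sprintf("<gen_hierarchy: %d leaves, levels 0..%d>\n", x$n_leaves, x$L))
  print(utils::head(tibble::as_tibble(x$levels), 6))
  if (x$n_leaves > 6) cat(sprintf("# ... with %d more leaves\n", x$n_leaves - 6))
  invisible(x)
}

check_level <- function(h, level) {
  if (length(level) != 1L || is.na(level) || level < 0 || level > h$L) {
    abort_p4(sprintf("level %s out of range [0, %d]", toString(level), h$L),
             "p4_error_level")
  }
  as.integer(level)
}

#' Generalize leaf values to a hierarchy level
#'
#' @param h A [build_hierarchy()] object.
#' @param value Character vector of leaf values.
#' @param level Single generalization level in `[0, L]`; level 0 returns the
#'   values unchanged.
#' @return Character vector of generalized values.
#' @export
generalize_value <- function(h, value, level) {
  stopifnot(inherits(h, "gen_hierarchy"))
  level <- check_level(h, level)
  idx <- match(value, h$levels[, 1L])
  if (anyNA(idx)) {
    abort_p4(sprintf("value '%s' is not a leaf of the hierarchy",
                     value[is.na(idx)][[1L]]),
             "p4_error_unknown_value")
  }
  unname(h$levels[idx, level + 1L])
}

#' Count the leaves covered by a generalized value
#'
#' The number of distinct leaf values that generalize to `value` at `level`.
#' A leaf covers exactly itself (1); the single top value of a hierarchy
#' covers the whole domain.  This count is the raw ingredient of the
#' domain-coverage fidelity metric.
#'
#' @inheritParams generalize_value
#' @param value Character vector of values occurring in the `level` column.
#' @return Integer vector of leaf counts.
#' @export
leaves_covered <- function(h, value, level) {
  stopifnot(inherits(h, "gen_hierarchy"))
  level <- check_level(h, level)
  col <- h$levels[, level + 1L]
  cnt <- vapply(value, function(v) sum(col == v), integer(1), USE.NAMES = FALSE)
  if (any(cnt == 0L)) {
    abort_p4(sprintf("value '%s' does not occur at level %d",
                     value[cnt == 0L][[1L]], level),
             "p4_error_unknown_value")
  }
  cnt
}

#' Read a generalization hierarchy from a delimited text file
#'
#' Hierarchy files are header-less delimited text, one row per leaf value,
#' columns running from the leaf (level 0) to the most general level.
#'
#' @param path File path.
#' @param delimiter Field delimiter, `";"` by default.
#' @return A `gen_hierarchy`.
#' @export
load_hierarchy <- function(path, delimiter = ";") {
  if (!file.exists(path)) {
    abort_p4(sprintf("hierarchy file '%s' does not exist", path), "p4_error_io")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    abort_p4(sprintf("hierarchy file '%s' is empty", path), "p4_error_io")
  }
  ## sentinel keeps trailing empty fields that strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), delimiter, fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  lens <- lengths(fields)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[[1L]])[1L]
    abort_p4(
      sprintf("'%s' line %d: %d field(s), expected %d",
              path, bad, lens[[bad]], lens[[1L]]),
      "p4_error_ragged"
    )
  }
  tryCatch(
    build_hierarchy(fields),
    p4_error = function(e) {
      abort_p4(sprintf("'%s': %s", path, conditionMessage(e)), class(e)[[1L]])
    }
  )
}

#' Write a generalization hierarchy to a delimited text file
#'
#' @param h A `gen_hierarchy`.
#' @inheritParams load_hierarchy
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path, delimiter = ";") {
  stopifnot(inherits(h, "gen_hierarchy"))
  writeLines(apply(h$levels, 1L, paste, collapse = delimiter), path)
  invisible(path)
}
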
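## Full-domain generalization: node evaluation and lattice search.
##
## A "node" of the generalization lattice is one scheme (a vector of
## levels, one per quasi-identifier).  Evaluating a node groups the
## records into equivalence classes, suppresses classes that fail a
## class-level privacy model, checks the dataset-level models on the
## surviving classes, and scores the node by domain-coverage fidelity
## (suppressed records contribute 0).

## Vectorized class-level checks on a count matrix (classes x sensitive
## values).  `cms` is a named list of such matrices keyed by sensitive
## attribute; columns are aligned with the reference support.
class_level_pass <- function(models, sizes, cms, ref) {
  nc <- length(sizes)
  pass <- rep(TRUE, nc)
  for (m in models) {
    cm <- if (!is.null(m$sensitive)) cms[[m$sensitive]]
    ok <- switch(m$kind,
      k_anonymity = sizes >= m$params$k,
      distinct_l = rowSums(cm > 0) >= m$params$l,
      entropy_l = {
        if (!is.null(m$estimator_fn)) {
          apply(cm, 1L, function(r) m$estimator_fn(r)) >= log(m$params$l) - .p4_eps
        } else if (m$estimator == "shannon") {
          P <- cm / sizes
          Plog <- P * log(P)
          Plog[P == 0] <- 0
          -rowSums(Plog) >= log(m$params$l) - .p4_eps
        } else {
          G <- matrix(0, nrow = nrow(cm), ncol = ncol(cm))
          pos <- cm > 0
          x <- cm[pos]
          G[pos] <- digamma(x) + ((-1)^x / 2) * (digamma((x + 1) / 2) - digamma(x / 2))
          log(sizes) - rowSums(cm * G) / sizes >= log(m$params$l) - .p4_eps
        }
      },
      recursive_cl = {
        l <- m$params$l
        cc <- m$params$c
        apply(cm, 1L, function(r) {
          r <- sort(r[r > 0], decreasing = TRUE)
          if (l > length(r)) return(FALSE)
          r[[1L]] < cc * sum(r[l:length(r)])
        })
      },
      t_closeness = {
        q <- ref$dist[[m$sensitive]]
        Q <- matrix(q, nrow = nc, ncol = length(q), byrow = TRUE)
        P <- cm / sizes
        if (m$variant == "equal") {
          0.5 * rowSums(abs(P - Q)) <= m$params$t + .p4_eps
        } else {
          ord <- m$order %||% sort_c(names(q))
          D <- (P - Q)[, match(ord, colnames(cm)), drop = FALSE]
          mm <- ncol(D)
          if (mm < 2L) rep(TRUE, nc) else {
            CS <- D
            for (j in 2:mm) CS[, j] <- CS[, j - 1L] + D[, j]
            rowSums(abs(CS[, -mm, drop = FALSE])) / (mm - 1) <= m$params$t + .p4_eps
          }
        }
      },
      delta_disclosure = {
        q <- ref$dist[[m$sensitive]]
        Q <- matrix(q, nrow = nc, ncol = length(q), byrow = TRUE)
        P <- cm / sizes
        bad <- rowSums(P > 0 & Q == 0) > 0
        R <- matrix(0, nrow = nc, ncol = ncol(cm))
        pos <- P > 0 & Q > 0
        R[pos] <- abs(log(P[pos] / Q[pos]) / log(m$log_base))
        apply(R, 1L, max) < m$params$delta & !bad
      },
      beta_likeness = {
        q <- ref$dist[[m$sensitive]]
        Q <- matrix(q, nrow = nc, ncol = length(q), byrow = TRUE)
        P <- cm / sizes
        viol <- matrix(FALSE, nrow = nc, ncol = ncol(cm))
        sel <- Q > 0 & P > Q
        if (any(sel)) {
          gain <- (P[sel] - Q[sel]) / Q[sel]
          bound <- if (isTRUE(m$enhanced)) pmin(m$params$beta, -log(Q[sel])) else m$params$beta
          viol[sel] <- gain > bound + .p4_eps
        }
        rowSums(viol) == 0
      },
      abort_p4(sprintf("'%s' is not a class-level model", m$kind), "p4_error_model")
    )
    pass <- pass & ok
  }
  pass
}

dataset_level_pass <- function(models, sizes) {
  all(vapply(models, check_dataset_model, logical(1), sizes = sizes))
}

## Count matrices for the sensitive attributes the class-level models
## need, with columns aligned to the reference support.
build_cms <- function(ctx, ci, nclass, models, ref) {
  attrs <- unique(unlist(lapply(models, function(m) m$sensitive)))
  cms <- list()
  for (a in attrs) {
    lev <- names(ref$dist[[a]])
    si <- match(ctx$data[[a]], lev)
    if (anyNA(si)) {
      abort_p4(sprintf("sensitive value '%s' missing from the reference distribution",
                       ctx$data[[a]][is.na(si)][[1L]]),
               "p4_error_dist")
    }
    cm <- matrix(0L, nrow = nclass, ncol = length(lev),
                 dimnames = list(NULL, lev))
    tab <- table(factor(ci, levels = seq_len(nclass)), factor(si, levels = seq_along(lev)))
    cm[] <- as.integer(tab)
    cms[[a]] <- cm
  }
  cms
}

## Suppress the smallest surviving classes (ties: lexicographically first
## key) until the dataset-level models pass.  Used by the forced
## fall-back (top node) and the finalization repair, where privacy
## outranks the configured suppression limit.
repair_dataset_level <- function(pass, sizes, data_models) {
  if (dataset_level_pass(data_models, sizes[pass])) return(pass)
  cand <- which(pass)
  cand <- cand[order(sizes[cand], cand)]
  for (i in cand) {
    pass[[i]] <- FALSE
    if (dataset_level_pass(data_models, sizes[pass])) break
  }
  pass
}

## Core node evaluation.  `force` suppresses class-level failures without
## regard to the suppression limit and repairs dataset-level violations by
## additional suppression (smallest classes first).
eval_node_ctx <- function(ctx, scheme, ref, limit, force = FALSE) {
  config <- ctx$config
  class_models <- purrr::keep(config$models, ~ .x$level == "class")
  data_models <- purrr::keep(config$models, ~ .x$level == "dataset")

  cols <- ctx_gen_cols(ctx, scheme)
  key <- do.call(paste, c(unname(cols), list(sep = .p4_sep)))
  kf <- factor(key, levels = sort_c(key))
  ci <- as.integer(kf)
  nclass <- nlevels(kf)
  sizes <- tabulate(ci, nbins = nclass)

  cms <- build_cms(ctx, ci, nclass, class_models, ref)
  pass <- if (length(class_models) > 0L) {
    class_level_pass(class_models, sizes, cms, ref)
  } else {
    rep(TRUE, nclass)
  }

  ds_ok <- dataset_level_pass(data_models, sizes[pass])
  if (force && !ds_ok) {
    pass <- repair_dataset_level(pass, sizes, data_models)
    ds_ok <- TRUE
  }

  supp_local <- which(!pass[ci])
  frac <- length(supp_local) / max(ctx$n, 1L)
  valid <- (force || frac <= limit + .p4_eps) && ds_ok

  recf <- ctx_record_fid(ctx, scheme)
  recf[supp_local] <- 0
  fidelity <- if (ctx$n > 0L) mean(recf) else NA_real_

  list(scheme = scheme, valid = valid, fidelity = fidelity,
       supp_local = supp_local, frac = frac, ds_ok = ds_ok,
       ci = ci, pass = pass, sizes = sizes, gen_cols = cols)
}

## Deterministic lattice enumeration: all level vectors, ordered by total
## generalization (sum of levels) ascending, ties in lexicographic order
## of the level vector (first quasi-identifier most significant).
enumerate_lattice <- function(config) {
  qis <- config$quasi_identifiers
  Ls <- vapply(config$hierarchies, function(h) h$L, integer(1))[qis]
  n_nodes <- prod(Ls + 1)
  if (n_nodes > config$lattice_node_cap) {
    abort_p4(sprintf("generalization lattice has %.0f nodes, above the cap of %.0f",
                     n_nodes, config$lattice_node_cap),
             "p4_error_lattice")
  }
  grid <- do.call(expand.grid, rev(lapply(Ls, function(L) 0:L)))
  grid <- as.matrix(grid)[, rev(seq_along(qis)), drop = FALSE]
  colnames(grid) <- qis
  grid[order(rowSums(grid)), , drop = FALSE]  # stable: preserves lex order
}

## Assemble the anonymized output for a chosen node.
build_output <- function(ctx, ev) {
  config <- ctx$config
  out <- ctx$data
  for (a in ctx$qis) out[[a]] <- ev$gen_cols[[a]]
  if (length(ev$supp_local) > 0L) {
    for (a in ctx$qis) out[[a]][ev$supp_local] <- .p4_star
  }
  for (a in config$identifiers) out[[a]] <- rep(.p4_star, nrow(out))
  out
}

new_anon_result <- function(output, config, scheme, suppressed_row_ids,
                            mode, scheme_assignment = NULL, empty = FALSE) {
  fs <- dataset_fidelity(output, config)
  structure(
    list(
      output = output,
      scheme = scheme,
      scheme_assignment = scheme_assignment,
      suppressed_row_ids = suppressed_row_ids,
      fidelity = fs$mean_fidelity,
      fidelity_summary = fs,
      n = nrow(output),
      mode = mode,
      empty = empty
    ),
    class = "anon_result"
  )
}

#' @export
print.anon_result <- function(x, ...) {
  cat(sprintf("<anon_result: %d records, %s mode, %d suppressed, fidelity %.4f>\n",
              x$n, x$mode, length(x$suppressed_row_ids), x$fidelity))
  if (!is.null(x$scheme)) {
    cat("  scheme:", paste(names(x$scheme), x$scheme, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Apply a generalization scheme to a dataset
#'
#' Replaces every quasi-identifier cell by its generalization at the
#' scheme's level; sensitive and insensitive cells are untouched, and row
#' ids are preserved.  No suppression is performed.
#'
#' @inheritParams group_into_classes
#' @return The generalized dataset (tibble).
#' @export
apply_scheme <- function(data, config, scheme) {
  stopifnot(inherits(config, "anon_config"))
  data <- ensure_row_ids(data)
  scheme <- normalize_scheme(scheme, config)
  ctx <- build_ctx(data, config)
  cols <- ctx_gen_cols(ctx, scheme)
  for (a in ctx$qis) data[[a]] <- cols[[a]]
  data
}

#' Evaluate one lattice node
#'
#' Groups the dataset's records under `scheme`, suppresses equivalence
#' classes failing any class-level privacy model, checks the dataset-level
#' models on the surviving classes, and scores the node by fidelity
#' (suppressed records score 0).  The node is valid when the suppressed
#' fraction stays within the suppression limit and the dataset-level
#' models pass.  Invalid nodes are returned, not raised.
#'
#' @inheritParams group_into_classes
#' @param ref A [reference_stats()] object; defaults to the distribution
#'   of `data`.
#' @param suppression_limit Overrides the configuration's limit.
#' @return A list: `scheme`, `valid`, `fidelity`, `suppressed_row_ids`,
#'   `suppressed_fraction`.
#' @export
evaluate_node <- function(data, config, scheme, ref = NULL,
                          suppression_limit = NULL) {
  stopifnot(inherits(config, "anon_config"))
  data <- ensure_row_ids(data)
  scheme <- normalize_scheme(scheme, config)
  ctx <- build_ctx(data, config)
  ref <- ref %||% reference_stats(data, config, "global")
  limit <- suppression_limit %||% config$suppression_limit
  ev <- eval_node_ctx(ctx, scheme, ref, limit)
  list(
    scheme = ev$scheme,
    valid = ev$valid,
    fidelity = ev$fidelity,
    suppressed_row_ids = data$.row_id[ev$supp_local],
    suppressed_fraction = ev$frac
  )
}

#' Search the generalization lattice for the optimal valid scheme
#'
#' Exhaustively enumerates the full-domain generalization lattice and
#' returns the valid node with maximal fidelity.  Ties are broken in
#' favour of (1) the smaller total generalization (sum of levels), then
#' (2) the lexicographically smaller level vector.  If no node is valid
#' within the suppression limit, the top node is returned with all
#' residually failing classes suppressed when the limit allows it
#' (always the case at limit 1), otherwise the configuration is reported
#' as infeasible.
#'
#' With `prune = TRUE` and a configuration of exclusively monotonic
#' models, nodes dominated by an already-valid, suppression-free node
#' skip the privacy re-check (their classes are merges of passing
#' classes); their fidelity is still computed.  Pruning never changes the
#' chosen node.
#'
#' @inheritParams evaluate_node
#' @param prune Enable monotonicity-based pruning of privacy checks.
#' @return An `anon_result`: `output` (generalized dataset, suppressed
#'   rows `"*"`-filled), `scheme`, `suppressed_row_ids`, `fidelity`,
#'   `classes` (equivalence classes of the non-suppressed output).
#' @examples
#' syn <- generate_dataset(60, qi_domains = c(6, 6), seed = 4)
#' cfg <- anon_config(syn$quasi_identifiers, syn$hierarchies,
#'                    sensitive = syn$sensitive,
#'                    models = list(k_anonymity(3)))
#' res <- search_optimal(syn$data, cfg)
#' res$scheme
#' @export
search_optimal <- function(data, config, ref = NULL, prune = FALSE) {
  stopifnot(inherits(config, "anon_config"))
  data <- ensure_row_ids(data)
  if (nrow(data) == 0L) {
    scheme <- setNames(rep(0L, length(config$quasi_identifiers)),
                       config$quasi_identifiers)
    return(new_anon_result(data, config, scheme, integer(0), "global",
                           empty = TRUE))
  }
  ctx <- build_ctx(data, config)
  ref <- ref %||% reference_stats(data, config, "global")
  limit <- config$suppression_limit
  nodes <- enumerate_lattice(config)

  all_monotonic <- all(vapply(config$models, is_monotonic, logical(1)))
  use_prune <- prune && all_monotonic
  known_valid <- list()  # suppression-free valid schemes seen so far

  best <- NULL
  best_fid <- -Inf
  for (i in seq_len(nrow(nodes))) {
    s <- nodes[i, ]
    dominated <- use_prune && length(known_valid) > 0L &&
      any(vapply(known_valid, function(v) all(v <= s), logical(1)))
    if (dominated) {
      fid <- mean(ctx_record_fid(ctx, s))
      ev <- list(scheme = s, valid = TRUE, fidelity = fid,
                 supp_local = integer(0), pruned = TRUE)
    } else {
      ev <- eval_node_ctx(ctx, s, ref, limit)
      if (use_prune && ev$valid && length(ev$supp_local) == 0L) {
        known_valid[[length(known_valid) + 1L]] <- s
      }
    }
    ## traversal order (sum, lex) realizes the tie-break: only a strictly
    ## better fidelity displaces the incumbent
    if (ev$valid && ev$fidelity > best_fid + 1e-12) {
      best <- ev
      best_fid <- ev$fidelity
    }
  }

  if (is.null(best)) {
    top <- nodes[nrow(nodes), ]
    ev <- eval_node_ctx(ctx, top, ref, limit, force = TRUE)
    if (ev$frac > limit + .p4_eps) {
      abort_p4(
        sprintf("infeasible configuration: even the top node requires suppressing %.1f%% of records, above the limit of %.1f%%",
                100 * ev$frac, 100 * limit),
        "p4_infeasible"
      )
    }
    best <- ev
  }
  if (is.null(best$gen_cols)) best <- eval_node_ctx(ctx, best$scheme, ref, limit)

  output <- build_output(ctx, best)
  result <- new_anon_result(output, config, best$scheme,
                            data$.row_id[best$supp_local], "global")
  keep <- setdiff(seq_len(ctx$n), best$supp_local)
  result$classes <- group_into_classes(data[keep, , drop = FALSE], config,
                                       best$scheme)
  result
}

#' Iterative local recoding
#'
#' Local transformation allows different generalization schemes in
#' different parts of the dataset.  Iteration 1 runs [search_optimal()]
#' on the full input; records in passing classes are fixed at that node's
#' generalization, and the suppressed residual is re-anonymized in the
#' next iteration (typically at a more general scheme).  After the last
#' iteration any remaining residual is fully suppressed.  The per-record
#' scheme assignment is recorded.
#'
#' @inheritParams search_optimal
#' @param iterations Number of recoding iterations (>= 1).
#' @return An `anon_result` with `scheme_assignment`: a tibble mapping
#'   each `.row_id` to its iteration and generalization levels (`NA` for
#'   suppressed records).
#' @export
local_recoding <- function(data, config, iterations = NULL, ref = NULL) {
  stopifnot(inherits(config, "anon_config"))
  data <- ensure_row_ids(data)
  iterations <- check_positive_int(iterations %||% config$local_iterations,
                                   "iterations")
  if (nrow(data) == 0L) {
    scheme <- setNames(rep(0L, length(config$quasi_identifiers)),
                       config$quasi_identifiers)
    return(new_anon_result(data, config, NULL, integer(0), "local",
                           empty = TRUE))
  }
  ref <- ref %||% reference_stats(data, config, "global")
  qis <- config$quasi_identifiers

  residual <- data
  chunks <- list()
  assigns <- list()
  for (it in seq_len(iterations)) {
    if (nrow(residual) == 0L) break
    res <- search_optimal(residual, config, ref = ref)
    supp <- residual$.row_id %in% res$suppressed_row_ids
    kept <- res$output[!supp, , drop = FALSE]
    if (nrow(kept) > 0L) {
      chunks[[length(chunks) + 1L]] <- kept
      asg <- tibble::tibble(.row_id = kept$.row_id, iteration = it)
      for (a in qis) asg[[a]] <- res$scheme[[a]]
      assigns[[length(assigns) + 1L]] <- asg
    }
    residual <- residual[supp, , drop = FALSE]
  }
  suppressed_row_ids <- residual$.row_id
  if (nrow(residual) > 0L) {
    supp_out <- residual
    for (a in qis) supp_out[[a]] <- rep(.p4_star, nrow(supp_out))
    for (a in config$identifiers) supp_out[[a]] <- rep(.p4_star, nrow(supp_out))
    chunks[[length(chunks) + 1L]] <- supp_out
    asg <- tibble::tibble(.row_id = residual$.row_id, iteration = NA_integer_)
    for (a in qis) asg[[a]] <- NA_integer_
    assigns[[length(assigns) + 1L]] <- asg
  }
  combined <- dplyr::bind_rows(chunks)
  combined <- combined[match(data$.row_id, combined$.row_id), , drop = FALSE]
  assignment <- dplyr::bind_rows(assigns)
  assignment <- assignment[match(data$.row_id, assignment$.row_id), , drop = FALSE]

  ## Dataset-level models hold per iteration; pooling the iterations can
  ## only merge classes, so a violation here means an engine defect.
  data_models <- purrr::keep(config$models, ~ .x$level == "dataset")
  if (length(data_models) > 0L) {
    oc <- output_classes(combined, config)
    if (!dataset_level_pass(data_models, oc$sizes)) {
      abort_p4("internal error: locally recoded output violates a dataset-level model",
               "p4_error_internal")
    }
  }

  result <- new_anon_result(combined, config, NULL, suppressed_row_ids,
                            "local", scheme_assignment = assignment)
  oc <- output_classes(combined, config)
  result$classes <- oc$classes
  result
}
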
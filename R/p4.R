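## The four-step partition-parallel anonymization procedure:
## 1. sort lexicographically, partition, anonymize partitions in parallel;
## 2. harmonize the per-partition generalization schemes (global mode) and
##    re-apply the harmonized scheme;
## 3. compliance-check equivalence classes that coincide after merging
##    against the non-monotonic models, with the global reference;
## 4. merge, verify, repair dataset-level models if needed, and report.

## Equivalence classes of a (possibly mixed-level) output dataset.  Rows
## with "*" in every quasi-identifier cell are suppressed and excluded
## from all risk computations.
output_classes <- function(output, config, ref = NULL) {
  qis <- config$quasi_identifiers
  n <- nrow(output)
  if (n == 0L) {
    return(list(sizes = integer(0), keep = logical(0),
                classes = tibble::tibble(key = character(0), size = integer(0))))
  }
  supp <- rep(TRUE, n)
  for (a in qis) supp <- supp & output[[a]] == .p4_star
  keep <- !supp
  kept <- output[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(list(sizes = integer(0), keep = keep,
                classes = tibble::tibble(key = character(0), size = integer(0)),
                ci = integer(0), kept = kept))
  }
  key <- do.call(paste, c(unname(as.list(kept[qis])), list(sep = .p4_sep)))
  kf <- factor(key, levels = sort_c(key))
  ci <- as.integer(kf)
  sizes <- tabulate(ci, nbins = nlevels(kf))
  classes <- tibble::tibble(
    key = gsub(.p4_sep, "|", levels(kf), fixed = TRUE),
    size = sizes
  )
  list(sizes = sizes, keep = keep, classes = classes, ci = ci, kept = kept,
       keys = levels(kf))
}

#' Sort lexicographically and split into balanced partitions
#'
#' Records are stably sorted by their quasi-identifier tuple (attribute
#' order as configured, codepoint string comparison) and cut into `P`
#' contiguous chunks whose sizes differ by at most one record.  Sorting
#' keeps similar records together, which is what lets the partitions be
#' anonymized at generalization levels close to the whole-dataset
#' optimum.
#'
#' @inheritParams search_optimal
#' @param P Number of partitions (>= 1).
#' @return A list of `P` tibbles (row ids preserved); empty tibbles only
#'   when `P > nrow(data)`.
#' @export
lexicographic_partition <- function(data, config, P) {
  stopifnot(inherits(config, "anon_config"))
  P <- check_positive_int(P, "P")
  data <- ensure_row_ids(data)
  qis <- config$quasi_identifiers
  ord <- do.call(order_c, unname(as.list(data[qis])))
  sorted <- data[ord, , drop = FALSE]
  n <- nrow(sorted)
  base <- n %/% P
  sizes <- rep(base, P)
  extra <- n %% P
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(P), function(i) {
    if (sizes[[i]] == 0L) sorted[0L, , drop = FALSE]
    else sorted[starts[[i]]:ends[[i]], , drop = FALSE]
  })
}

#' Anonymize partitions independently (and in parallel)
#'
#' Each partition is processed by [search_optimal()] (global mode) or
#' [local_recoding()] (local mode) with the same settings, against its
#' own partition-local reference distribution.  Results are identical
#' regardless of worker count or scheduling order: the engine draws no
#' random numbers and results are collected in partition order.
#'
#' @param parts List of partitions from [lexicographic_partition()].
#' @param config An [anon_config()].
#' @param workers Number of forked workers (capped at the number of
#'   partitions; sequential on platforms without fork).
#' @return List of `anon_result` objects, one per partition, each carrying
#'   `partition` (index) and `elapsed` (seconds).
#' @export
anonymize_partitions <- function(parts, config, workers = NULL) {
  stopifnot(inherits(config, "anon_config"))
  workers <- workers %||% config$workers
  run_one <- function(i) {
    part <- parts[[i]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      ref <- reference_stats(part, config, "partition")
      if (config$transformation == "global") {
        search_optimal(part, config, ref = ref)
      } else {
        local_recoding(part, config, ref = ref)
      }
    }, p4_error = function(e) e)
    if (inherits(res, "error")) return(list(error = res, partition = i))
    res$partition <- i
    res$elapsed <- proc.time()[["elapsed"]] - t0
    res
  }
  idx <- seq_along(parts)
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, run_one, mc.cores = min(workers, length(parts)),
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, run_one)
  }
  for (r in results) {
    if (!is.null(r$error)) {
      abort_p4(sprintf("partition %d: %s", r$partition,
                       conditionMessage(r$error)),
               "p4_error_partition")
    }
  }
  for (r in results) {
    if (!r$empty && r$n > 0L && length(r$suppressed_row_ids) == r$n) {
      warn(sprintf("partition %d was fully suppressed (too small for the configured models)",
                   r$partition))
    }
  }
  results
}

#' Harmonize per-partition generalization schemes
#'
#' In global mode the independently chosen per-partition schemes must be
#' replaced by one common scheme.  Per attribute: `"average"` takes the
#' arithmetic mean of the levels rounded half-up, `"minimum"` the
#' minimum, `"median"` the lower median.  The result always lies within
#' the per-attribute range of the inputs.
#'
#' @param schemes List of named level vectors (one per partition).
#' @param strategy `"average"`, `"minimum"` or `"median"`.
#' @return A named integer scheme.
#' @export
harmonize_schemes <- function(schemes, strategy = c("average", "minimum", "median")) {
  strategy <- match.arg(strategy)
  schemes <- schemes[!vapply(schemes, is.null, logical(1))]
  if (length(schemes) == 0L) {
    abort_p4("no schemes to harmonize", "p4_error_harmonize")
  }
  m <- do.call(rbind, schemes)
  harm <- apply(m, 2L, function(v) {
    switch(strategy,
      average = floor(mean(v) + 0.5),       # round half-up
      minimum = min(v),
      median = sort(v)[(length(v) + 1L) %/% 2L]  # lower median
    )
  })
  setNames(as.integer(harm), colnames(m))
}

#' Re-apply a harmonized scheme to every partition
#'
#' Partitions whose chosen scheme already equals the harmonized scheme
#' are reused unchanged; every other partition is re-generalized at
#' exactly the harmonized scheme, suppressing classes that fail a
#' class-level model.  No suppression limit applies at this stage:
#' once the scheme is fixed, suppression is the only remaining lever and
#' privacy outranks the configured limit.
#'
#' @param parts Partitions from [lexicographic_partition()].
#' @param results Per-partition `anon_result`s from [anonymize_partitions()].
#' @param scheme The harmonized scheme.
#' @param config An [anon_config()].
#' @return List of `anon_result`s at the common scheme.
#' @export
reapply_harmonized <- function(parts, results, scheme, config) {
  stopifnot(inherits(config, "anon_config"))
  lapply(seq_along(results), function(i) {
    res <- results[[i]]
    if (res$empty || identical(unname(res$scheme), unname(scheme[names(res$scheme)]))) {
      return(res)
    }
    part <- parts[[i]]
    ctx <- build_ctx(part, config)
    ref <- reference_stats(part, config, "partition")
    ev <- eval_node_ctx(ctx, normalize_scheme(scheme, config), ref,
                        limit = 1, force = TRUE)
    output <- build_output(ctx, ev)
    out <- new_anon_result(output, config, ev$scheme,
                           part$.row_id[ev$supp_local], "global")
    out$partition <- res$partition
    out$elapsed <- res$elapsed
    out
  })
}

#' Compliance-check merged equivalence classes
#'
#' When a non-monotonic privacy model is configured, classes that fall
#' together when the partitions are merged are not guaranteed to satisfy
#' it even though every partition does.  This step pools the
#' non-suppressed output records of all partitions, groups them by their
#' generalized quasi-identifier tuple, evaluates every non-monotonic
#' class-level model on each merged class against the global reference
#' distribution, and suppresses the records of failing classes.  With
#' only monotonic models configured this is a no-op.
#'
#' @param results Per-partition `anon_result`s (post-harmonization in
#'   global mode).
#' @param config An [anon_config()].
#' @param global_ref [reference_stats()] of the complete input dataset.
#' @return A list: `suppressed_row_ids`, `classes_checked`,
#'   `classes_removed`.
#' @export
compliance_check <- function(results, config, global_ref) {
  stopifnot(inherits(config, "anon_config"))
  nm_models <- purrr::keep(config$models,
                           ~ .x$level == "class" && !is_monotonic(.x))
  if (length(nm_models) == 0L) {
    return(list(suppressed_row_ids = integer(0), classes_checked = 0L,
                classes_removed = 0L))
  }
  pooled <- dplyr::bind_rows(lapply(results, function(r) r$output))
  oc <- output_classes(pooled, config)
  if (length(oc$sizes) == 0L) {
    return(list(suppressed_row_ids = integer(0), classes_checked = 0L,
                classes_removed = 0L))
  }
  ctx <- list(data = oc$kept)  # only the sensitive columns are consulted
  cms <- build_cms(ctx, oc$ci, length(oc$sizes), nm_models, global_ref)
  pass <- class_level_pass(nm_models, oc$sizes, cms, global_ref)
  supp_ids <- oc$kept$.row_id[!pass[oc$ci]]
  list(
    suppressed_row_ids = supp_ids,
    classes_checked = length(oc$sizes),
    classes_removed = sum(!pass)
  )
}

suppress_rows <- function(output, config, row_ids) {
  if (length(row_ids) == 0L) return(output)
  hit <- output$.row_id %in% row_ids
  for (a in config$quasi_identifiers) output[[a]][hit] <- .p4_star
  output
}

#' Merge partitions, verify, and report
#'
#' Concatenates the anonymized partitions in partition (sorted) order,
#' defensively re-verifies the monotonic class-level models on the merged
#' classes (a violation signals an engine defect and raises an error),
#' re-checks the dataset-level models — repairing a violation introduced
#' by compliance suppression by suppressing the smallest surviving
#' classes — and cross-checks pooled against whole-output fidelity.
#'
#' @inheritParams compliance_check
#' @param durations Named numeric vector of step durations (seconds).
#' @param suppressed_counts Named integer vector of per-stage suppression.
#' @param harmonized Harmonized scheme, or `NULL` in local mode.
#' @return A list with `output` (merged dataset) and `report`
#'   (`p4_report`).
#' @export
finalize_p4 <- function(results, config, global_ref,
                        durations = NULL, suppressed_counts = NULL,
                        harmonized = NULL) {
  stopifnot(inherits(config, "anon_config"))
  t0 <- proc.time()[["elapsed"]]
  outputs <- lapply(results, function(r) r$output)
  merged <- dplyr::bind_rows(outputs)
  part_of <- rep(seq_along(results), vapply(outputs, nrow, integer(1)))

  oc <- output_classes(merged, config)

  ## Defensive re-check: merged classes are unions of per-partition
  ## passing classes, so a monotonic class-level model cannot fail here.
  mono_models <- purrr::keep(config$models,
                             ~ .x$level == "class" && is_monotonic(.x))
  if (length(mono_models) > 0L && length(oc$sizes) > 0L) {
    ctx <- list(data = oc$kept)
    cms <- build_cms(ctx, oc$ci, length(oc$sizes), mono_models, global_ref)
    pass <- class_level_pass(mono_models, oc$sizes, cms, global_ref)
    if (!all(pass)) {
      abort_p4("internal error: merged output violates a monotonic privacy model",
               "p4_error_internal")
    }
  }

  ## Dataset-level repair: compliance suppression removes whole classes,
  ## which can push the class-count ratio of the remainder above an
  ## average-risk threshold; suppress smallest classes until compliant.
  data_models <- purrr::keep(config$models, ~ .x$level == "dataset")
  repair_ids <- integer(0)
  if (length(data_models) > 0L && length(oc$sizes) > 0L &&
      !dataset_level_pass(data_models, oc$sizes)) {
    pass <- repair_dataset_level(rep(TRUE, length(oc$sizes)), oc$sizes,
                                 data_models)
    repair_ids <- oc$kept$.row_id[!pass[oc$ci]]
    merged <- suppress_rows(merged, config, repair_ids)
  }

  part_summaries <- lapply(seq_along(results), function(i) {
    dataset_fidelity(merged[part_of == i, , drop = FALSE], config)
  })
  whole <- dataset_fidelity(merged, config)
  pooled <- pooled_fidelity(part_summaries)
  if (abs(pooled - whole$mean_fidelity) > 1e-9) {
    abort_p4("internal error: pooled fidelity disagrees with whole-output fidelity",
             "p4_error_internal")
  }

  supp_now <- rep(TRUE, nrow(merged))
  for (a in config$quasi_identifiers) supp_now <- supp_now & merged[[a]] == .p4_star

  durations <- durations %||% c(anonymization = 0, harmonization = 0, compliance = 0)
  durations[["finalization"]] <- proc.time()[["elapsed"]] - t0
  suppressed_counts <- suppressed_counts %||%
    c(anonymization = NA_integer_, harmonization = NA_integer_,
      compliance = NA_integer_)
  suppressed_counts[["finalization"]] <- sum(supp_now)

  report <- structure(
    list(
      step_durations = durations[c("anonymization", "harmonization",
                                   "compliance", "finalization")],
      per_partition_schemes = lapply(results, function(r) r$scheme),
      harmonized_scheme = harmonized,
      suppressed_counts = suppressed_counts[c("anonymization", "harmonization",
                                              "compliance", "finalization")],
      fidelity = whole$mean_fidelity,
      fidelity_summary = whole,
      partitions = length(results),
      n = nrow(merged),
      mode = config$transformation,
      models = vapply(config$models, model_label, character(1))
    ),
    class = "p4_report"
  )
  list(output = merged, report = report)
}

#' Partition-parallel anonymization
#'
#' Runs the four-step procedure: lexicographic partitioning, independent
#' (parallel) anonymization of the partitions, harmonization of the
#' per-partition generalization schemes (global mode only), compliance
#' checking of merged equivalence classes against non-monotonic models
#' (skipped when every configured model is monotonic), and finalization.
#' The merged output satisfies every configured privacy model under the
#' global reference distribution — see [check_privacy()] for the
#' independent verifier.
#'
#' The trade-off: anonymizing `P` partitions independently is (nearly)
#' `P`-way parallel, but each partition is optimized without seeing the
#' rest of the data, so output fidelity decreases with `P`.
#'
#' @inheritParams search_optimal
#' @param partitions Number of partitions `P` (defaults to the
#'   configuration).
#' @param workers Worker processes for the parallel step (defaults to the
#'   configuration; results are identical for any worker count).
#' @return A `p4_anonymization` object: `output` (merged anonymized
#'   dataset, rows in sorted order, `.row_id` preserving the input order)
#'   and `report` (a `p4_report` with per-step durations, per-partition
#'   and harmonized schemes, per-stage suppression and final fidelity).
#' @examples
#' syn <- generate_dataset(200, qi_domains = c(6, 6), seed = 11)
#' cfg <- anon_config(syn$quasi_identifiers, syn$hierarchies,
#'                    sensitive = syn$sensitive,
#'                    models = list(k_anonymity(4)))
#' fit <- run_p4(syn$data, cfg, partitions = 4)
#' glance(fit)
#' @export
run_p4 <- function(data, config, partitions = NULL, workers = NULL) {
  stopifnot(inherits(config, "anon_config"))
  P <- check_positive_int(partitions %||% config$partitions, "partitions")
  data <- ensure_row_ids(data)
  global_ref <- reference_stats(data, config, "global")

  parts <- lexicographic_partition(data, config, P)

  results <- anonymize_partitions(parts, config, workers = workers)
  dur_anon <- max(vapply(results, function(r) r$elapsed %||% 0, numeric(1)))
  supp_anon <- sum(vapply(results, function(r) length(r$suppressed_row_ids),
                          integer(1)))

  harmonized <- NULL
  dur_harm <- 0
  if (config$transformation == "global") {
    t0 <- proc.time()[["elapsed"]]
    schemes <- lapply(results, function(r) if (r$empty) NULL else r$scheme)
    harmonized <- harmonize_schemes(schemes, config$harmonization)
    results <- reapply_harmonized(parts, results, harmonized, config)
    dur_harm <- proc.time()[["elapsed"]] - t0
  }
  supp_harm <- sum(vapply(results, function(r) length(r$suppressed_row_ids),
                          integer(1)))

  dur_comp <- 0
  supp_comp <- supp_harm
  if (any(!vapply(config$models, is_monotonic, logical(1)))) {
    t0 <- proc.time()[["elapsed"]]
    cc <- compliance_check(results, config, global_ref)
    if (length(cc$suppressed_row_ids) > 0L) {
      results <- lapply(results, function(r) {
        r$output <- suppress_rows(r$output, config, cc$suppressed_row_ids)
        r
      })
    }
    supp_comp <- supp_harm + length(cc$suppressed_row_ids)
    dur_comp <- proc.time()[["elapsed"]] - t0
  }

  fin <- finalize_p4(
    results, config, global_ref,
    durations = c(anonymization = dur_anon, harmonization = dur_harm,
                  compliance = dur_comp),
    suppressed_counts = c(anonymization = supp_anon, harmonization = supp_harm,
                          compliance = supp_comp),
    harmonized = harmonized
  )
  structure(
    list(output = fin$output, report = fin$report, config = config),
    class = "p4_anonymization"
  )
}

#' Restore the input record order of an anonymized output
#'
#' @param x A `p4_anonymization` or an output tibble carrying `.row_id`.
#' @return The output tibble reordered by `.row_id`.
#' @export
restore_order <- function(x) {
  out <- if (inherits(x, "p4_anonymization")) x$output else x
  out[order(out$.row_id), , drop = FALSE]
}

#' @export
print.p4_anonymization <- function(x, ...) {
  r <- x$report
  cat(sprintf("<p4_anonymization: %d records, %d partition(s), %s mode>\n",
              r$n, r$partitions, r$mode))
  cat(sprintf("  fidelity %.4f | suppressed %d | models: %s\n",
              r$fidelity, r$suppressed_counts[["finalization"]],
              paste(r$models, collapse = "; ")))
  invisible(x)
}

#' @export
print.p4_report <- function(x, ...) {
  cat(sprintf("<p4_report: %d records, %d partition(s), %s mode>\n",
              x$n, x$partitions, x$mode))
  cat("  durations (s):",
      paste(names(x$step_durations), sprintf("%.3f", x$step_durations),
            sep = "=", collapse = ", "), "\n")
  cat("  suppressed:",
      paste(names(x$suppressed_counts), x$suppressed_counts,
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$harmonized_scheme)) {
    cat("  harmonized scheme:",
        paste(names(x$harmonized_scheme), x$harmonized_scheme,
              sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  fidelity: %.4f\n", x$fidelity))
  invisible(x)
}
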
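#' Assemble a run configuration
#'
#' The configuration binds together everything one anonymization run needs:
#' the attribute roles, the generalization hierarchies of the
#' quasi-identifiers, the privacy models, the transformation mode and its
#' knobs, and the partitioning settings for partition-parallel runs.
#'
#' @param quasi_identifiers Character vector of quasi-identifier attribute
#'   names.  Their order fixes the lexicographic sort order used by
#'   [lexicographic_partition()] and the component order of generalization
#'   schemes.
#' @param hierarchies Named list of [build_hierarchy()] objects, one per
#'   quasi-identifier.
#' @param sensitive Character vector of sensitive attribute names.
#' @param insensitive Character vector of attributes carried through
#'   unchanged.
#' @param identifiers Character vector of directly identifying attributes;
#'   these are unconditionally replaced by `"*"` in every output.
#' @param models List of [privacy_models] objects (conjunctive).
#' @param transformation `"global"` (one generalization scheme for the
#'   whole dataset) or `"local"` (iterative recoding; different schemes in
#'   different parts of the data).
#' @param suppression_limit Maximum tolerated fraction of suppressed
#'   records in `[0, 1]`.  The default 1 always permits suppression and
#'   lets the fidelity metric arbitrate between suppressing and
#'   generalizing.
#' @param partitions Default number of partitions for [run_p4()].
#' @param workers Number of parallel workers; defaults to `partitions`.
#' @param harmonization Strategy for combining per-partition generalization
#'   levels: `"average"` (mean, rounded half-up), `"minimum"`, or
#'   `"median"` (lower median).
#' @param local_iterations Number of recoding iterations in local mode.
#' @param seed Seed echoed into reports (the anonymization engine itself is
#'   deterministic; only synthetic-data generation draws random numbers).
#' @param lattice_node_cap Guard against enumerating pathologically large
#'   generalization lattices.
#' @param csv_delimiter,csv_quote CSV dialect for [load_dataset()] /
#'   [write_dataset()].
#' @param hierarchy_delimiter Field delimiter of hierarchy files.
#' @return An `anon_config` object.
#' @examples
#' h <- generate_hierarchy(4, 2)
#' cfg <- anon_config("age", hierarchies = list(age = h),
#'                    models = list(k_anonymity(2)))
#' @export
anon_config <- function(quasi_identifiers,
                        hierarchies,
                        sensitive = character(),
                        insensitive = character(),
                        identifiers = character(),
                        models = list(),
                        transformation = c("global", "local"),
                        suppression_limit = 1,
                        partitions = 1L,
                        workers = NULL,
                        harmonization = c("average", "minimum", "median"),
                        local_iterations = 10L,
                        seed = NULL,
                        lattice_node_cap = 1e6,
                        csv_delimiter = ",",
                        csv_quote = "\"",
                        hierarchy_delimiter = ";") {
  transformation <- match.arg(transformation)
  harmonization <- match.arg(harmonization)

  all_names <- c(quasi_identifiers, sensitive, insensitive, identifiers)
  if (anyDuplicated(all_names)) {
    abort_p4(sprintf("attribute '%s' is assigned more than one role",
                     all_names[duplicated(all_names)][[1L]]),
             "p4_error_config")
  }
  if (length(quasi_identifiers) == 0L) {
    abort_p4("at least one quasi-identifier is required", "p4_error_config")
  }
  if (!is.list(hierarchies) || !setequal(names(hierarchies), quasi_identifiers)) {
    missing <- setdiff(quasi_identifiers, names(hierarchies))
    if (length(missing) > 0L) {
      abort_p4(sprintf("no hierarchy supplied for quasi-identifier '%s'",
                       missing[[1L]]),
               "p4_error_config")
    }
    abort_p4("exactly the quasi-identifiers must have hierarchies",
             "p4_error_config")
  }
  for (a in quasi_identifiers) {
    if (!inherits(hierarchies[[a]], "gen_hierarchy")) {
      abort_p4(sprintf("hierarchies[['%s']] is not a gen_hierarchy", a),
               "p4_error_config")
    }
  }
  for (m in models) {
    if (!inherits(m, "privacy_model")) {
      abort_p4("`models` must be a list of privacy_model objects",
               "p4_error_config")
    }
    if (!is.null(m$sensitive) && !m$sensitive %in% sensitive) {
      abort_p4(
        sprintf("model %s requires sensitive attribute '%s', which is not declared with role sensitive",
                m$kind, m$sensitive),
        "p4_error_config"
      )
    }
  }
  if (length(suppression_limit) != 1L || is.na(suppression_limit) ||
      suppression_limit < 0 || suppression_limit > 1) {
    abort_p4("`suppression_limit` must be in [0, 1]", "p4_error_config")
  }
  partitions <- check_positive_int(partitions, "partitions")
  local_iterations <- check_positive_int(local_iterations, "local_iterations")
  workers <- if (is.null(workers)) partitions else check_positive_int(workers, "workers")

  structure(
    list(
      quasi_identifiers = quasi_identifiers,
      sensitive = sensitive,
      insensitive = insensitive,
      identifiers = identifiers,
      hierarchies = hierarchies[quasi_identifiers],
      models = models,
      transformation = transformation,
      suppression_limit = as.numeric(suppression_limit),
      partitions = partitions,
      workers = workers,
      harmonization = harmonization,
      local_iterations = local_iterations,
      seed = seed,
      lattice_node_cap = lattice_node_cap,
      csv_delimiter = csv_delimiter,
      csv_quote = csv_quote,
      hierarchy_delimiter = hierarchy_delimiter
    ),
    class = "anon_config"
  )
}

#' @export
print.anon_config <- function(x, ...) {
  cat("<anon_config>\n")
  cat("  quasi-identifiers:", paste(x$quasi_identifiers, collapse = ", "), "\n")
  if (length(x$sensitive)) cat("  sensitive:", paste(x$sensitive, collapse = ", "), "\n")
  cat("  models:", if (length(x$models)) paste(vapply(x$models, model_label, character(1)), collapse = "; ") else "(none)", "\n")
  cat("  transformation:", x$transformation,
      "| suppression limit:", x$suppression_limit,
      "| partitions:", x$partitions,
      "| harmonization:", x$harmonization, "\n")
  invisible(x)
}

#' Attribute roles of a configuration
#'
#' @param config An [anon_config()].
#' @return A tibble with columns `name` and `role`.
#' @export
attribute_roles <- function(config) {
  stopifnot(inherits(config, "anon_config"))
  tibble::tibble(
    name = c(config$quasi_identifiers, config$sensitive,
             config$insensitive, config$identifiers),
    role = rep(
      c("quasi_identifier", "sensitive", "insensitive", "identifier"),
      c(length(config$quasi_identifiers), length(config$sensitive),
        length(config$insensitive), length(config$identifiers))
    )
  )
}

model_from_spec <- function(spec) {
  type <- spec$type %||% abort_p4("model block lacks a `type`", "p4_error_config")
  switch(type,
    k_anonymity = k_anonymity(spec$k),
    distinct_l_diversity = distinct_l_diversity(spec$l, spec$sensitive),
    entropy_l_diversity = entropy_l_diversity(spec$l, spec$sensitive,
                                              spec$estimator %||% "shannon"),
    recursive_cl_diversity = recursive_cl_diversity(spec$c, spec$l, spec$sensitive),
    t_closeness = t_closeness(spec$t, spec$sensitive,
                              spec$variant %||% "equal",
                              order = unlist(spec$order) %||% NULL),
    delta_disclosure = delta_disclosure(spec$delta, spec$sensitive,
                                        spec$log_base %||% exp(1)),
    beta_likeness = beta_likeness(spec$beta, spec$sensitive,
                                  spec$enhanced %||% FALSE),
    average_risk = average_risk(spec$threshold),
    sample_uniqueness = sample_uniqueness(spec$threshold),
    abort_p4(sprintf("unknown model type '%s'", type), "p4_error_config")
  )
}

#' Load a run configuration from YAML or JSON
#'
#' The file format mirrors [anon_config()]: an `attributes` list of
#' `{name, role, hierarchy}` blocks (hierarchy paths are resolved relative
#' to the configuration file), a `models` list of `{type, ...}` blocks,
#' and scalar settings (`transformation`, `suppression_limit`,
#' `partitions`, `workers`, `harmonization`, `local_iterations`, `seed`,
#' `csv: {delimiter, quote}`, `hierarchy_delimiter`).  Unstated settings
#' take the [anon_config()] defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `anon_config` with all hierarchies loaded and validated.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_p4(sprintf("config file '%s' does not exist", path), "p4_error_io")
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  attrs <- raw$attributes %||%
    abort_p4(sprintf("'%s': missing `attributes`", path), "p4_error_config")
  roles <- vapply(attrs, function(a) a$role %||% "insensitive", character(1))
  names_ <- vapply(attrs, function(a) {
    a$name %||% abort_p4(sprintf("'%s': attribute block lacks a `name`", path),
                         "p4_error_config")
  }, character(1))
  qis <- names_[roles == "quasi_identifier"]
  hdel <- raw$hierarchy_delimiter %||% ";"
  hierarchies <- list()
  for (i in seq_along(attrs)) {
    if (roles[[i]] != "quasi_identifier") next
    href <- attrs[[i]]$hierarchy %||%
      abort_p4(sprintf("'%s': quasi-identifier '%s' lacks a `hierarchy` path",
                       path, names_[[i]]),
               "p4_error_config")
    hpath <- if (file.exists(href)) href else file.path(dirname(path), href)
    hierarchies[[names_[[i]]]] <- load_hierarchy(hpath, hdel)
  }
  models <- lapply(raw$models %||% list(), model_from_spec)
  anon_config(
    quasi_identifiers = qis,
    hierarchies = hierarchies,
    sensitive = names_[roles == "sensitive"],
    insensitive = names_[roles == "insensitive"],
    identifiers = names_[roles == "identifier"],
    models = models,
    transformation = raw$transformation %||% "global",
    suppression_limit = raw$suppression_limit %||% 1,
    partitions = raw$partitions %||% 1L,
    workers = raw$workers %||% NULL,
    harmonization = raw$harmonization %||% "average",
    local_iterations = raw$local_iterations %||% 10L,
    seed = raw$seed %||% NULL,
    lattice_node_cap = raw$lattice_node_cap %||% 1e6,
    csv_delimiter = raw$csv$delimiter %||% ",",
    csv_quote = raw$csv$quote %||% "\"",
    hierarchy_delimiter = hdel
  )
}
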
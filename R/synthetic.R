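#' Generate a balanced generalization hierarchy
#'
#' Builds a hierarchy over leaves `v01..vD` by grouping `fanout`
#' consecutive leaves into an interval label per level, up to the single
#' top `"*"`.  The construction is deterministic given `domain_size` and
#' `fanout`.
#'
#' @param domain_size Number of leaf values `D` (>= 1).
#' @param fanout Group size per level (>= 2).
#' @param seed Unused; kept for interface symmetry with the other
#'   generators (balanced hierarchies are deterministic).
#' @return A [build_hierarchy()] object with
#'   `L = ceiling(log(D, fanout))` (0 for a single-leaf domain).
#' @examples
#' generate_hierarchy(4, 2)
#' @export
generate_hierarchy <- function(domain_size, fanout = 3L, seed = NULL) {
  domain_size <- check_positive_int(domain_size, "domain_size")
  fanout <- check_positive_int(fanout, "fanout", min = 2L)
  width <- max(2L, nchar(as.character(domain_size)))
  leaves <- sprintf("v%0*d", width, seq_len(domain_size))
  cols <- list(leaves)
  if (domain_size > 1L) {
    span <- 1L
    repeat {
      span <- span * fanout
      grp <- (seq_len(domain_size) - 1L) %/% span
      if (max(grp) == 0L) {
        cols[[length(cols) + 1L]] <- rep(.p4_star, domain_size)
        break
      }
      labels <- vapply(unique(grp), function(g) {
        members <- leaves[grp == g]
        if (length(members) == 1L) members else {
          paste0("[", members[[1L]], "-", members[[length(members)]], "]")
        }
      }, character(1))
      cols[[length(cols) + 1L]] <- labels[grp + 1L]
    }
  }
  build_hierarchy(do.call(cbind, cols))
}

zipf_probs <- function(D, skew) {
  w <- seq_len(D)^(-skew)
  w / sum(w)
}

#' Generate a synthetic microdata dataset with hierarchies
#'
#' Emulates the shape of demographic survey microdata: a handful of
#' categorical quasi-identifiers plus one sensitive attribute, all cells
#' text.  Quasi-identifier values are drawn independently per attribute
#' from a Zipf-like distribution with exponent `skew` (`skew = 0` is
#' uniform); the sensitive attribute uses `sensitive_skew` for
#' controllable class imbalance.  With `plant_m`, the dataset instead
#' consists of `n / plant_m` distinct quasi-identifier tuples, each
#' repeated exactly `plant_m` times, so the equivalence-class structure
#' at the identity scheme is known exactly — handy for constructing
#' worked examples with known optima.  Fully reproducible from `seed`.
#'
#' @param n Number of records.
#' @param qi_domains Integer vector of quasi-identifier domain sizes.
#' @param sensitive_domain Number of distinct sensitive values.
#' @param skew,sensitive_skew Zipf exponents (0 = uniform).
#' @param plant_m Optional planted class size; requires `n` divisible by
#'   `plant_m`.
#' @param fanout Hierarchy fanout passed to [generate_hierarchy()].
#' @param seed RNG seed; the caller's RNG state is preserved.
#' @return A list: `data` (tibble with columns `qi1..qiK`, `sensitive`,
#'   `.row_id`), `hierarchies` (named list), `quasi_identifiers`,
#'   `sensitive` (attribute name).
#' @examples
#' syn <- generate_dataset(100, qi_domains = c(4, 5, 6), seed = 7)
#' head(syn$data)
#' @export
generate_dataset <- function(n, qi_domains = c(8L, 8L), sensitive_domain = 2L,
                             skew = 0, sensitive_skew = 0, plant_m = NULL,
                             fanout = 3L, seed = NULL) {
  n <- check_positive_int(n, "n")
  qis <- paste0("qi", seq_along(qi_domains))
  hierarchies <- setNames(
    lapply(qi_domains, generate_hierarchy, fanout = fanout), qis
  )
  with_preserved_seed(seed, {
    cols <- list()
    if (is.null(plant_m)) {
      for (j in seq_along(qi_domains)) {
        D <- qi_domains[[j]]
        leaves <- hierarchies[[j]]$levels[, 1L]
        cols[[qis[[j]]]] <- sample(leaves, n, replace = TRUE,
                                   prob = zipf_probs(D, skew))
      }
    } else {
      plant_m <- check_positive_int(plant_m, "plant_m")
      if (n %% plant_m != 0L) {
        abort_p4("`n` must be divisible by `plant_m`", "p4_error_synth")
      }
      n_tuples <- n %/% plant_m
      if (prod(qi_domains) < n_tuples) {
        abort_p4("quasi-identifier domains too small for the requested number of distinct tuples",
                 "p4_error_synth")
      }
      ## draw distinct tuples by sampling linear indices without replacement
      lin <- sample(prod(qi_domains), n_tuples, replace = FALSE)
      rest <- lin - 1L
      for (j in seq_along(qi_domains)) {
        D <- qi_domains[[j]]
        leaves <- hierarchies[[j]]$levels[, 1L]
        vals <- leaves[(rest %% D) + 1L]
        rest <- rest %/% D
        cols[[qis[[j]]]] <- rep(vals, each = plant_m)
      }
      perm <- sample(n)
      cols <- lapply(cols, function(v) v[perm])
    }
    svals <- sprintf("s%02d", seq_len(sensitive_domain))
    cols[["sensitive"]] <- sample(svals, n, replace = TRUE,
                                  prob = zipf_probs(sensitive_domain,
                                                    sensitive_skew))
    data <- tibble::as_tibble(cols)
    data$.row_id <- seq_len(n)
    list(data = data, hierarchies = hierarchies,
         quasi_identifiers = qis, sensitive = "sensitive")
  })
}

#' Extrapolate a dataset to a larger size
#'
#' A documented stand-in for record-level dataset extrapolation: seeded
#' sampling with replacement from the input records, so every output
#' record is an input record and the marginal value sets of every
#' attribute are subsets of the input's.  Intended for scalability
#' testing, where size matters and distributional fidelity does not; the
#' single interface point makes it easy to substitute a more faithful
#' extrapolation scheme.
#'
#' @param data A dataset tibble.
#' @param factor Size multiplier (>= 1); the output has
#'   `ceiling(factor * nrow(data))` records.
#' @param seed RNG seed.
#' @return A tibble with fresh `.row_id`s.
#' @export
extrapolate_dataset <- function(data, factor = 1, seed = NULL) {
  if (length(factor) != 1L || is.na(factor) || factor < 1) {
    abort_p4("`factor` must be a single number >= 1", "p4_error_synth")
  }
  n <- nrow(data)
  m <- as.integer(ceiling(factor * n))
  with_preserved_seed(seed, {
    out <- data[sample(n, m, replace = TRUE), , drop = FALSE]
    out$.row_id <- seq_len(m)
    out
  })
}

#' Draw a randomized anonymization scenario
#'
#' Generates a synthetic dataset together with a randomly drawn but
#' always-satisfiable run configuration: 1–3 privacy models (optionally
#' forcing one particular kind), random partition count, transformation
#' mode, domain sizes and skew.  Used for randomized end-to-end testing
#' of the partition-parallel guarantee and by the acceptance script.
#'
#' @param seed RNG seed driving every choice.
#' @param n_range Range the (log-uniform) record count is drawn from.
#' @param force_kind Optionally force the inclusion of one model kind:
#'   one of `"k_anonymity"`, `"distinct_l"`, `"entropy_l_shannon"`,
#'   `"entropy_l_grassberger"`, `"recursive_cl"`, `"t_closeness_equal"`,
#'   `"t_closeness_ordered"`, `"delta_disclosure"`,
#'   `"beta_likeness_basic"`, `"beta_likeness_enhanced"`,
#'   `"average_risk"`, `"sample_uniqueness"`.
#' @param partitions Optionally fix the partition count (else drawn from
#'   1, 2, 4, 8).
#' @param mode Optionally fix the transformation mode.
#' @return A list: `data`, `config` (with `partitions` set), `n`.
#' @export
generate_scenario <- function(seed, n_range = c(100, 10000),
                              force_kind = NULL, partitions = NULL,
                              mode = NULL) {
  with_preserved_seed(seed, {
    n <- round(10^stats::runif(1, log10(n_range[[1L]]), log10(n_range[[2L]])))
    n_qi <- sample(2:3, 1)
    qi_domains <- sample(6:12, n_qi, replace = TRUE)
    sdom <- sample(2:4, 1)
    syn <- generate_dataset(
      n, qi_domains = qi_domains, sensitive_domain = sdom,
      skew = stats::runif(1, 0, 0.8), sensitive_skew = stats::runif(1, 0, 0.7),
      fanout = sample(2:3, 1), seed = sample.int(.Machine$integer.max, 1)
    )
    sens <- syn$sensitive
    kinds <- c("k_anonymity", "distinct_l", "entropy_l_shannon",
               "entropy_l_grassberger", "recursive_cl", "t_closeness_equal",
               "t_closeness_ordered", "delta_disclosure",
               "beta_likeness_basic", "beta_likeness_enhanced",
               "average_risk", "sample_uniqueness")
    draw_model <- function(kind) {
      switch(kind,
        k_anonymity = k_anonymity(sample(2:10, 1)),
        distinct_l = distinct_l_diversity(2L, sens),
        entropy_l_shannon = entropy_l_diversity(2L, sens, "shannon"),
        entropy_l_grassberger = entropy_l_diversity(2L, sens, "grassberger"),
        recursive_cl = recursive_cl_diversity(stats::runif(1, 1, 4), 2L, sens),
        t_closeness_equal = t_closeness(stats::runif(1, 0.15, 0.5), sens, "equal"),
        t_closeness_ordered = t_closeness(stats::runif(1, 0.15, 0.5), sens, "ordered"),
        delta_disclosure = delta_disclosure(stats::runif(1, 1, 3), sens),
        beta_likeness_basic = beta_likeness(stats::runif(1, 0.5, 3), sens),
        beta_likeness_enhanced = beta_likeness(stats::runif(1, 0.5, 3), sens,
                                               enhanced = TRUE),
        average_risk = average_risk(stats::runif(1, 0.05, 0.5)),
        sample_uniqueness = sample_uniqueness(stats::runif(1, 0.05, 0.5))
      )
    }
    chosen <- sample(kinds, sample(1:3, 1))
    if (!is.null(force_kind)) chosen <- unique(c(force_kind, chosen))
    models <- lapply(chosen, draw_model)
    config <- anon_config(
      quasi_identifiers = syn$quasi_identifiers,
      hierarchies = syn$hierarchies,
      sensitive = sens,
      models = models,
      transformation = mode %||% sample(c("global", "local"), 1),
      suppression_limit = 1,
      partitions = partitions %||% sample(c(1L, 2L, 4L, 8L), 1),
      local_iterations = 3L,
      seed = seed
    )
    list(data = syn$data, config = config, n = n)
  })
}
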
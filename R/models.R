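## Privacy models
##
## Each constructor returns a `privacy_model` object describing one
## syntactic privacy requirement.  `level` is "class" for models checked on
## every equivalence class and "dataset" for models checked on the dataset
## as a whole.  `monotonic` is looked up in the registry below: a model is
## monotonic when merging equivalence classes that fulfil it always yields
## a class that fulfils it, which is what allows the partition-merge step
## to skip compliance checking.

## Monotonicity registry.  t-closeness is the canonical non-monotonic
## model; all models that compare a class against a reference distribution
## are conservatively flagged non-monotonic here because the per-partition
## reference differs from the global one, and the Grassberger entropy
## estimator is flagged non-monotonic because the estimator's behaviour
## under class merging is not guaranteed.  A conservative flag only adds
## compliance checking; it never weakens the guarantee.
.p4_monotonic <- c(
  k_anonymity           = TRUE,
  distinct_l            = TRUE,
  entropy_l_shannon     = TRUE,
  entropy_l_grassberger = FALSE,
  recursive_cl          = TRUE,
  t_closeness_equal     = FALSE,
  t_closeness_ordered   = FALSE,
  delta_disclosure      = FALSE,
  beta_likeness_basic   = FALSE,
  beta_likeness_enhanced = FALSE,
  average_risk          = TRUE,
  sample_uniqueness     = TRUE
)

new_privacy_model <- function(kind, registry_key, params, sensitive = NULL,
                              level = "class", extra = list()) {
  structure(
    c(list(
      kind = kind,
      registry_key = registry_key,
      params = params,
      sensitive = sensitive,
      level = level,
      monotonic = unname(.p4_monotonic[[registry_key]])
    ), extra),
    class = c(paste0("p4_", kind), "privacy_model")
  )
}

check_positive_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort_p4(sprintf("`%s` must be a single integer >= %d", name, min),
             "p4_error_model_param")
  }
  as.integer(x)
}

check_unit_interval <- function(x, name, lo_open = TRUE) {
  ok <- length(x) == 1L && !is.na(x) && x <= 1 && (if (lo_open) x > 0 else x >= 0)
  if (!ok) {
    abort_p4(sprintf("`%s` must be a single number in %s0, 1]",
                     name, if (lo_open) "(" else "["),
             "p4_error_model_param")
  }
  as.numeric(x)
}

#' Privacy model constructors
#'
#' Declare the privacy requirements an anonymized dataset has to meet.
#' Models are combined conjunctively: a transformation is valid only when
#' every configured model is satisfied.  Class-level models constrain every
#' equivalence class (a maximal group of records sharing the same
#' generalized quasi-identifier tuple); dataset-level models constrain the
#' dataset as a whole.
#'
#' * `k_anonymity(k)`: every class has at least `k` records, i.e. every
#'   record is indistinguishable from at least `k - 1` others.
#' * `distinct_l_diversity(l, sensitive)`: every class contains at least
#'   `l` distinct values of the sensitive attribute.
#' * `entropy_l_diversity(l, sensitive, estimator)`: the entropy of the
#'   in-class sensitive-value distribution is at least `ln(l)`.  The
#'   `"shannon"` estimator is the plug-in entropy; `"grassberger"` is the
#'   bias-corrected estimator (see [grassberger_entropy()]), which can be
#'   swapped via `estimator_fn`.
#' * `recursive_cl_diversity(c, l, sensitive)`: with in-class sensitive
#'   counts sorted descending `r1 >= ... >= rm`, requires
#'   `r1 < c * (rl + ... + rm)`.
#' * `t_closeness(t, sensitive, variant)`: the earth mover's distance
#'   between the in-class sensitive distribution and the reference
#'   distribution is at most `t`, under the equal (`emd_equal()`) or
#'   ordered (`emd_ordered()`) ground distance.
#' * `delta_disclosure(delta, sensitive)`: for every sensitive value with
#'   in-class frequency `p > 0`, `|log(p/q)| < delta` (strict), where `q`
#'   is the reference frequency.  `log_base` defaults to the natural log.
#' * `beta_likeness(beta, sensitive, enhanced)`: for every sensitive value
#'   whose in-class frequency `p` exceeds its reference frequency `q > 0`,
#'   the relative gain `(p - q)/q` is at most `beta` (basic) or
#'   `min(beta, -ln q)` (enhanced).
#' * `average_risk(threshold)` (dataset level): the mean re-identification
#'   risk over records, `mean(1/|class|)` = `#classes / #records`, is at
#'   most `threshold`.
#' * `sample_uniqueness(threshold)` (dataset level): the fraction of
#'   records in singleton classes is at most `threshold`.
#'
#' All threshold comparisons are inclusive except delta-disclosure, which
#' is strict per its canonical definition.
#'
#' @param k,l,c,t,delta,beta,threshold Model parameters, see above.
#' @param sensitive Name of the sensitive attribute the model constrains.
#' @param estimator Entropy estimator, `"shannon"` or `"grassberger"`.
#' @param estimator_fn Optional replacement entropy estimator, a function
#'   of a count vector returning an entropy in nats.
#' @param variant t-closeness ground distance, `"equal"` or `"ordered"`.
#' @param order Optional explicit value ordering for ordered-distance
#'   t-closeness; defaults to the codepoint-sorted reference support.
#' @param log_base Base of the delta-disclosure logarithm.
#' @param enhanced Use the enhanced beta-likeness bound `min(beta, -ln q)`.
#' @return A `privacy_model` object.
#' @seealso [is_monotonic()], [evaluate_all()], [check_privacy()]
#' @examples
#' models <- list(k_anonymity(4), t_closeness(0.3, "diagnosis"))
#' vapply(models, is_monotonic, logical(1))
#' @name privacy_models
NULL

#' @rdname privacy_models
#' @export
k_anonymity <- function(k) {
  new_privacy_model("k_anonymity", "k_anonymity",
                    list(k = check_positive_int(k, "k")))
}

#' @rdname privacy_models
#' @export
distinct_l_diversity <- function(l, sensitive) {
  new_privacy_model("distinct_l", "distinct_l",
                    list(l = check_positive_int(l, "l")),
                    sensitive = sensitive)
}

#' @rdname privacy_models
#' @export
entropy_l_diversity <- function(l, sensitive,
                                estimator = c("shannon", "grassberger"),
                                estimator_fn = NULL) {
  estimator <- match.arg(estimator)
  new_privacy_model(
    "entropy_l", paste0("entropy_l_", estimator),
    list(l = check_positive_int(l, "l")),
    sensitive = sensitive,
    extra = list(estimator = estimator, estimator_fn = estimator_fn)
  )
}

#' @rdname privacy_models
#' @export
recursive_cl_diversity <- function(c, l, sensitive) {
  if (length(c) != 1L || is.na(c) || c <= 0) {
    abort_p4("`c` must be a single positive number", "p4_error_model_param")
  }
  new_privacy_model("recursive_cl", "recursive_cl",
                    list(c = as.numeric(c), l = check_positive_int(l, "l")),
                    sensitive = sensitive)
}

#' @rdname privacy_models
#' @export
t_closeness <- function(t, sensitive, variant = c("equal", "ordered"),
                        order = NULL) {
  variant <- match.arg(variant)
  new_privacy_model(
    "t_closeness", paste0("t_closeness_", variant),
    list(t = check_unit_interval(t, "t")),
    sensitive = sensitive,
    extra = list(variant = variant, order = order)
  )
}

#' @rdname privacy_models
#' @export
delta_disclosure <- function(delta, sensitive, log_base = exp(1)) {
  if (length(delta) != 1L || is.na(delta) || delta <= 0) {
    abort_p4("`delta` must be a single positive number", "p4_error_model_param")
  }
  new_privacy_model("delta_disclosure", "delta_disclosure",
                    list(delta = as.numeric(delta)),
                    sensitive = sensitive,
                    extra = list(log_base = log_base))
}

#' @rdname privacy_models
#' @export
beta_likeness <- function(beta, sensitive, enhanced = FALSE) {
  if (length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort_p4("`beta` must be a single positive number", "p4_error_model_param")
  }
  new_privacy_model(
    "beta_likeness",
    if (enhanced) "beta_likeness_enhanced" else "beta_likeness_basic",
    list(beta = as.numeric(beta)),
    sensitive = sensitive,
    extra = list(enhanced = isTRUE(enhanced))
  )
}

#' @rdname privacy_models
#' @export
average_risk <- function(threshold) {
  new_privacy_model("average_risk", "average_risk",
                    list(threshold = check_unit_interval(threshold, "threshold")),
                    level = "dataset")
}

#' @rdname privacy_models
#' @export
sample_uniqueness <- function(threshold) {
  new_privacy_model("sample_uniqueness", "sample_uniqueness",
                    list(threshold = check_unit_interval(threshold, "threshold",
                                                         lo_open = FALSE)),
                    level = "dataset")
}

#' @export
print.privacy_model <- function(x, ...) {
  cat("<privacy_model>", model_label(x), "\n")
  invisible(x)
}

model_label <- function(m) {
  p <- paste(names(m$params), unlist(m$params), sep = "=", collapse = ", ")
  extra <- c(
    if (!is.null(m$estimator)) m$estimator,
    if (!is.null(m$variant)) m$variant,
    if (isTRUE(m$enhanced)) "enhanced",
    if (!is.null(m$sensitive)) paste0("on ", m$sensitive)
  )
  paste0(m$kind, "(", p, ")", if (length(extra)) paste0(" [", paste(extra, collapse = ", "), "]"))
}

#' Is a privacy model monotonic?
#'
#' A privacy model is monotonic when merging equivalence classes that
#' fulfil the model always yields a class that fulfils it.  Monotonic
#' models need no compliance checking after merging independently
#' anonymized partitions; non-monotonic models do.
#'
#' @param m A `privacy_model`.
#' @return `TRUE` or `FALSE`.
#' @export
is_monotonic <- function(m) {
  stopifnot(inherits(m, "privacy_model"))
  key <- m$registry_key
  if (!key %in% names(.p4_monotonic)) {
    abort_p4(sprintf("unknown privacy model kind '%s'", key), "p4_error_model")
  }
  unname(.p4_monotonic[[key]])
}

## ---------------------------------------------------------------------------
## Scalar checkers.  Each takes the sensitive-value counts of ONE class (a
## named or unnamed count vector) and/or class sizes, and is a pure
## function of its inputs.

#' Class- and dataset-level privacy checks
#'
#' Low-level checkers underlying the [privacy_models].  Class-level
#' checkers take the class size or the vector of in-class sensitive-value
#' counts; dataset-level checkers take the vector of equivalence-class
#' sizes.  Reference distributions (`ref_dist`) are named probability
#' vectors as produced by [reference_stats()].
#'
#' @param size Class size (number of records).
#' @param counts Named count vector of sensitive values within one class.
#' @param sizes Integer vector of equivalence-class sizes.
#' @param ref_dist Named reference probability vector over sensitive values.
#' @param k,l,c,t,delta,beta,threshold Model parameters.
#' @param estimator,estimator_fn,variant,order,log_base,enhanced See
#'   [privacy_models].
#' @return `TRUE` if the requirement holds, else `FALSE`.
#' @name privacy_checks
NULL

#' @rdname privacy_checks
#' @export
check_k_anonymity <- function(size, k) {
  size >= k
}

#' @rdname privacy_checks
#' @export
check_distinct_l <- function(counts, l) {
  sum(counts > 0) >= l
}

#' Plug-in (Shannon) and bias-corrected (Grassberger) entropy
#'
#' `shannon_entropy()` is the plug-in estimator `-sum(p * ln p)` of the
#' in-class sensitive distribution.  `grassberger_entropy()` is the
#' bias-corrected estimator `ln(n) - (1/n) * sum(n_i * G(n_i))` with
#' `G(x) = digamma(x) + (-1)^x/2 * (digamma((x+1)/2) - digamma(x/2))`.
#' The correction term variant is deliberately isolated here so an
#' alternative estimator can be supplied via the `estimator_fn` argument
#' of [entropy_l_diversity()].
#'
#' @param counts Positive count vector.
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(counts) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' @rdname shannon_entropy
#' @export
grassberger_entropy <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  G <- digamma(counts) +
    ((-1)^counts / 2) * (digamma((counts + 1) / 2) - digamma(counts / 2))
  log(n) - sum(counts * G) / n
}

#' @rdname privacy_checks
#' @export
check_entropy_l <- function(counts, l, estimator = c("shannon", "grassberger"),
                            estimator_fn = NULL) {
  estimator <- match.arg(estimator)
  fn <- estimator_fn %||%
    switch(estimator, shannon = shannon_entropy, grassberger = grassberger_entropy)
  fn(counts) >= log(l) - .p4_eps
}

#' @rdname privacy_checks
#' @export
check_recursive_cl <- function(counts, c, l) {
  counts <- sort(counts[counts > 0], decreasing = TRUE)
  m <- length(counts)
  if (l > m) return(FALSE)
  counts[[1L]] < c * sum(counts[l:m])
}

align_dists <- function(p, q) {
  if (is.null(names(p)) && is.null(names(q))) {
    if (length(p) != length(q)) {
      abort_p4("unnamed distributions must have equal length", "p4_error_dist")
    }
    return(list(p = p, q = q))
  }
  support <- sort_c(c(names(p), names(q)))
  pp <- setNames(numeric(length(support)), support)
  qq <- pp
  pp[names(p)] <- p
  qq[names(q)] <- q
  list(p = pp, q = qq)
}

#' Earth mover's distance between sensitive-value distributions
#'
#' `emd_equal()` uses the unit ground distance (all distinct values equally
#' far apart) and equals half the L1 distance, `0.5 * sum(|p - q|)`.
#' `emd_ordered()` uses the ordered ground distance `|i - j|/(m - 1)` over
#' a total order of the `m` values and equals
#' `(1/(m-1)) * sum_i |cumsum(p - q)_i|`.  Both lie in `[0, 1]`.
#' Distributions may be named; supports are aligned by union with zero
#' padding before the distance is computed.
#'
#' @param p,q Probability vectors, each summing to 1.
#' @param order Optional character vector giving the value order for
#'   `emd_ordered()`; defaults to the codepoint-sorted union support for
#'   named inputs, or the given element order for unnamed inputs.
#' @return The distance, a number in `[0, 1]`.
#' @examples
#' emd_equal(c(a = 1, b = 0), c(a = 0.5, b = 0.5))
#' emd_ordered(c(1, 0, 0), c(1, 3, 1) / 5)
#' @export
emd_equal <- function(p, q) {
  al <- align_dists(p, q)
  0.5 * sum(abs(al$p - al$q))
}

#' @rdname emd_equal
#' @export
emd_ordered <- function(p, q, order = NULL) {
  al <- align_dists(p, q)
  p <- al$p
  q <- al$q
  if (!is.null(order)) {
    if (!setequal(order, names(p))) {
      abort_p4("`order` must be a permutation of the union support", "p4_error_dist")
    }
    p <- p[order]
    q <- q[order]
  }
  m <- length(p)
  if (m < 2L) return(0)
  cum <- cumsum(p - q)
  sum(abs(cum[-m])) / (m - 1)
}

class_dist <- function(counts, ref_dist) {
  p <- counts / sum(counts)
  full <- setNames(numeric(length(ref_dist)), names(ref_dist))
  extra <- setdiff(names(p), names(ref_dist))
  if (length(extra) > 0L) {
    abort_p4(sprintf("sensitive value '%s' missing from the reference distribution",
                     extra[[1L]]),
             "p4_error_dist")
  }
  full[names(p)] <- p
  full
}

#' @rdname privacy_checks
#' @export
check_t_closeness <- function(counts, ref_dist, t,
                              variant = c("equal", "ordered"), order = NULL) {
  variant <- match.arg(variant)
  p <- class_dist(counts, ref_dist)
  d <- switch(variant,
    equal = emd_equal(p, ref_dist),
    ordered = emd_ordered(p, ref_dist,
                          order = order %||% sort_c(names(ref_dist)))
  )
  d <= t + .p4_eps
}

#' @rdname privacy_checks
#' @export
check_delta_disclosure <- function(counts, ref_dist, delta, log_base = exp(1)) {
  p <- class_dist(counts, ref_dist)
  pos <- p > 0
  if (any(pos & ref_dist[names(p)] == 0)) return(FALSE)
  ratios <- abs(log(p[pos] / ref_dist[names(p)][pos], base = log_base))
  all(ratios < delta)
}

#' @rdname privacy_checks
#' @export
check_beta_likeness <- function(counts, ref_dist, beta, enhanced = FALSE) {
  p <- class_dist(counts, ref_dist)
  q <- ref_dist[names(p)]
  sel <- q > 0 & p > q
  if (!any(sel)) return(TRUE)
  gain <- (p[sel] - q[sel]) / q[sel]
  bound <- if (enhanced) pmin(beta, -log(q[sel])) else rep(beta, sum(sel))
  all(gain <= bound + .p4_eps)
}

#' @rdname privacy_checks
#' @export
check_average_risk <- function(sizes, threshold) {
  n <- sum(sizes)
  if (n == 0) return(TRUE)
  length(sizes) / n <= threshold + .p4_eps
}

#' @rdname privacy_checks
#' @export
check_sample_uniqueness <- function(sizes, threshold) {
  n <- sum(sizes)
  if (n == 0) return(TRUE)
  sum(sizes == 1) / n <= threshold + .p4_eps
}

## Dispatch a class-level model on one class given a reference-stats object.
check_class_model <- function(m, size, counts_by_attr, ref) {
  switch(m$kind,
    k_anonymity = check_k_anonymity(size, m$params$k),
    distinct_l = check_distinct_l(counts_by_attr[[m$sensitive]], m$params$l),
    entropy_l = check_entropy_l(counts_by_attr[[m$sensitive]], m$params$l,
                                m$estimator, m$estimator_fn),
    recursive_cl = check_recursive_cl(counts_by_attr[[m$sensitive]],
                                      m$params$c, m$params$l),
    t_closeness = check_t_closeness(counts_by_attr[[m$sensitive]],
                                    ref$dist[[m$sensitive]], m$params$t,
                                    m$variant, m$order),
    delta_disclosure = check_delta_disclosure(counts_by_attr[[m$sensitive]],
                                              ref$dist[[m$sensitive]],
                                              m$params$delta, m$log_base),
    beta_likeness = check_beta_likeness(counts_by_attr[[m$sensitive]],
                                        ref$dist[[m$sensitive]], m$params$beta,
                                        m$enhanced),
    abort_p4(sprintf("'%s' is not a class-level model", m$kind), "p4_error_model")
  )
}

check_dataset_model <- function(m, sizes) {
  switch(m$kind,
    average_risk = check_average_risk(sizes, m$params$threshold),
    sample_uniqueness = check_sample_uniqueness(sizes, m$params$threshold),
    abort_p4(sprintf("'%s' is not a dataset-level model", m$kind), "p4_error_model")
  )
}

#' Evaluate all configured privacy models on a set of equivalence classes
#'
#' Class-level models are evaluated per class and combined conjunctively;
#' dataset-level models are evaluated on the classes that survive
#' class-level suppression (classes failing any class-level model).
#'
#' @param models List of [privacy_models] objects.
#' @param classes Equivalence classes as returned by [group_into_classes()].
#' @param ref A [reference_stats()] object for the reference-dependent
#'   models; may be `NULL` when no configured model needs one.
#' @return A list with `per_class` (tibble: `key`, `pass`), `dataset_pass`
#'   (named logical, one entry per dataset-level model), `pass` (overall)
#'   and `failing_models` (character labels).
#' @export
evaluate_all <- function(models, classes, ref = NULL) {
  class_models <- purrr::keep(models, ~ .x$level == "class")
  data_models <- purrr::keep(models, ~ .x$level == "dataset")
  nc <- nrow(classes)
  per_class <- rep(TRUE, nc)
  fail_class <- character()
  for (m in class_models) {
    ok <- vapply(seq_len(nc), function(i) {
      check_class_model(m, classes$size[[i]], classes$counts[[i]], ref)
    }, logical(1))
    if (!all(ok)) fail_class <- c(fail_class, model_label(m))
    per_class <- per_class & ok
  }
  surviving <- classes$size[per_class]
  dataset_pass <- vapply(data_models, function(m) {
    check_dataset_model(m, surviving)
  }, logical(1))
  names(dataset_pass) <- vapply(data_models, model_label, character(1))
  list(
    per_class = tibble::tibble(key = classes$key, pass = per_class),
    dataset_pass = dataset_pass,
    pass = all(per_class) && all(dataset_pass),
    failing_models = c(fail_class, names(dataset_pass)[!dataset_pass])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
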
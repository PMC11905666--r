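# Shared fixtures, built in code.

# Interval hierarchy over ages 30..33: 30,31 -> "30-31", 32,33 -> "32-33" -> "*"
age_hierarchy <- function() {
  build_hierarchy(list(
    c("30", "30-31", "*"), c("31", "30-31", "*"),
    c("32", "32-33", "*"), c("33", "32-33", "*")
  ))
}

# A tiny two-attribute dataset: one QI (age) + one sensitive column.
toy_data <- function(ages, sex = rep(c("F", "M"), length.out = length(ages))) {
  tibble::tibble(age = as.character(ages), sex = sex,
                 .row_id = seq_along(ages))
}

toy_config <- function(models = list(), ...) {
  anon_config("age", hierarchies = list(age = age_hierarchy()),
              sensitive = "sex", models = models, ...)
}

# Synthetic dataset + config in one call.
synth_config <- function(n, qi_domains = c(6, 6), sensitive_domain = 2,
                         models = list(), seed = 1, ...) {
  syn <- generate_dataset(n, qi_domains = qi_domains,
                          sensitive_domain = sensitive_domain, seed = seed)
  list(
    data = syn$data,
    config = anon_config(syn$quasi_identifiers, syn$hierarchies,
                         sensitive = syn$sensitive, models = models, ...)
  )
}

# Independent minimum-cost-transport oracle for earth mover's distance,
# solved as a linear program with boot::simplex.  Variables f_ij >= 0 move
# mass from p_i to q_j at cost c_ij; row constraints spend p, column
# constraints fill q (the last column constraint is implied and dropped to
# keep the system full-rank).
transport_emd <- function(p, q, cost) {
  # zero-mass sources/sinks carry no flow; dropping them keeps the basis
  # non-degenerate
  keep_i <- p > 0
  keep_j <- q > 0
  p <- p[keep_i]
  q <- q[keep_j]
  cost <- cost[keep_i, keep_j, drop = FALSE]
  m <- length(p)
  k <- length(q)
  if (m == 1L || k == 1L) return(sum(outer(p, q) * cost))
  obj <- as.vector(t(cost))          # f_11..f_1k, f_21..f_2k, ...
  A3 <- matrix(0, nrow = m + k - 1L, ncol = m * k)
  for (i in seq_len(m)) A3[i, ((i - 1L) * k + 1L):(i * k)] <- 1
  for (j in seq_len(k - 1L)) A3[m + j, seq(j, m * k, by = k)] <- 1
  b3 <- c(p, q[-k])
  sol <- boot::simplex(a = obj, A3 = A3, b3 = b3, maxi = FALSE)
  sol$value
}

# Ground-distance matrices for the two t-closeness variants.
unit_cost <- function(m) 1 - diag(m)
ordered_cost <- function(m) abs(outer(seq_len(m), seq_len(m), "-")) / (m - 1)

# Random probability vector with optional structural zeros.
random_dist <- function(m, zeros = FALSE) {
  x <- stats::rgamma(m, shape = 1)
  if (zeros && m > 2) {
    kill <- sample(m, sample(0:(m - 2), 1))
    x[kill] <- 0
  }
  if (sum(x) == 0) x[sample(m, 1)] <- 1
  x / sum(x)
}

all_model_kinds <- c(
  "k_anonymity", "distinct_l", "entropy_l_shannon", "entropy_l_grassberger",
  "recursive_cl", "t_closeness_equal", "t_closeness_ordered",
  "delta_disclosure", "beta_likeness_basic", "beta_likeness_enhanced",
  "average_risk", "sample_uniqueness"
)

# Brute-force lattice selection, independent of search_optimal's loop:
# evaluate every node, keep the valid ones, and pick max fidelity with the
# smaller-sum-then-lexicographic tie-break.
brute_force_best <- function(data, config, ref = NULL) {
  qis <- config$quasi_identifiers
  Ls <- vapply(config$hierarchies, function(h) h$L, integer(1))[qis]
  grid <- expand.grid(lapply(Ls, function(L) 0:L))
  names(grid) <- qis
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- unlist(grid[i, , drop = FALSE])
    ev <- evaluate_node(data, config, s, ref = ref)
    list(scheme = s, valid = ev$valid, fidelity = ev$fidelity)
  })
  valid <- Filter(function(r) r$valid, rows)
  if (length(valid) == 0L) return(NULL)
  fids <- vapply(valid, function(r) r$fidelity, numeric(1))
  cand <- valid[fids >= max(fids) - 1e-12]
  sums <- vapply(cand, function(r) sum(r$scheme), numeric(1))
  cand <- cand[sums == min(sums)]
  keys <- vapply(cand, function(r) paste(sprintf("%03d", r$scheme), collapse = ","),
                 character(1))
  cand[[order(keys)[1L]]]$scheme
}
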
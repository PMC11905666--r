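test_that("k-anonymity compares class size against k", {
  expect_true(check_k_anonymity(4, 4))   # indistinguishable from >= 3 others
  expect_false(check_k_anonymity(3, 4))
  expect_true(check_k_anonymity(1, 1))
})

test_that("distinct l-diversity counts distinct sensitive values", {
  expect_true(check_distinct_l(c(F = 2, M = 2), 2))
  expect_false(check_distinct_l(c(F = 4), 2))
  expect_true(check_distinct_l(c(F = 4), 1))
})

test_that("entropy l-diversity thresholds the class entropy at ln(l)", {
  expect_equal(shannon_entropy(c(2, 2)), log(2))
  expect_true(check_entropy_l(c(A = 2, B = 2), 2, "shannon"))
  expect_false(check_entropy_l(c(A = 2, B = 2), 3, "shannon"))
  expect_true(check_entropy_l(c(A = 4), 1, "shannon"))  # H = 0 >= 0

  # the bias-corrected estimator is more conservative on tiny classes
  expect_lt(grassberger_entropy(c(2, 2)), log(2))
  expect_false(check_entropy_l(c(A = 2, B = 2), 2, "grassberger"))
  # but converges towards the plug-in value for large balanced classes
  expect_equal(grassberger_entropy(c(5000, 5000)), log(2), tolerance = 1e-3)

  # a custom estimator can be swapped in
  expect_true(check_entropy_l(c(A = 2, B = 2), 3, estimator_fn = function(cnt) log(4)))
})

test_that("recursive (c,l)-diversity follows r1 < c * tail-sum", {
  expect_true(check_recursive_cl(c(5, 3, 2), c = 2, l = 2))   # 5 < 2*(3+2)
  expect_false(check_recursive_cl(c(5, 3, 2), c = 1, l = 2))  # 5 < 5 fails
  expect_false(check_recursive_cl(c(1, 1), c = 1, l = 3))     # fewer than l values
})

test_that("earth mover's distances match their closed forms", {
  expect_equal(emd_equal(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(emd_equal(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7)), 0)
  expect_equal(emd_equal(c(1, 0), c(0, 1)), 1.0)

  expect_equal(emd_ordered(c(1, 0, 0), c(1, 1, 1) / 3), 0.5)
  expect_equal(emd_ordered(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(emd_ordered(c(1, 0), c(0, 1)), 1.0)
  expect_equal(emd_ordered(c(a = 1), c(a = 1)), 0)  # single support point

  # named supports are aligned by union with zero padding
  expect_equal(emd_equal(c(a = 1), c(b = 1)), 1.0)
})

test_that("t-closeness thresholds the EMD inclusively", {
  ref <- c(F = 0.5, M = 0.5)
  expect_true(check_t_closeness(c(F = 3, M = 3), ref, t = 0.01))
  expect_false(check_t_closeness(c(F = 9, M = 1), ref, t = 0.2))  # EMD 0.4
  expect_true(check_t_closeness(c(F = 9, M = 1), ref, t = 0.4))   # boundary inclusive
})

test_that("delta-disclosure bounds the log-ratio strictly", {
  ref <- c(A = 0.5, B = 0.5)
  expect_true(check_delta_disclosure(c(A = 3, B = 3), ref, delta = 0.01))
  expect_true(check_delta_disclosure(c(A = 8, B = 2), ref, delta = 1.0))   # max |ln| ~ 0.916
  expect_false(check_delta_disclosure(c(A = 8, B = 2), ref, delta = 0.9))
  # a value absent from the reference is infinite disclosure
  expect_false(check_delta_disclosure(c(A = 1), c(A = 0, B = 1), delta = 10))
})

test_that("beta-likeness bounds the relative frequency gain", {
  ref <- c(A = 0.5, B = 0.5)
  expect_true(check_beta_likeness(c(A = 3, B = 1), ref, beta = 0.5))   # gain exactly 0.5
  expect_false(check_beta_likeness(c(A = 2), ref, beta = 0.5))         # gain 1.0
  # no value exceeds its reference frequency: vacuously passes any beta
  expect_true(check_beta_likeness(c(A = 2, B = 2), ref, beta = 0.01))
  # enhanced bound min(beta, -ln q) is tighter for common values
  expect_true(check_beta_likeness(c(A = 66, B = 34), c(A = 0.5, B = 0.5),
                                  beta = 5, enhanced = FALSE))
  expect_false(check_beta_likeness(c(A = 95, B = 5), c(A = 0.5, B = 0.5),
                                   beta = 5, enhanced = TRUE))
})

test_that("dataset-level models use class-size statistics", {
  expect_true(check_average_risk(c(5, 3, 2), 0.5))    # 3/10
  expect_false(check_average_risk(c(1, 1, 1), 0.5))   # all singletons
  expect_true(check_average_risk(10, 1 / 10))

  expect_true(check_sample_uniqueness(c(1, 1, 3), 0.5))  # 2/5
  expect_false(check_sample_uniqueness(c(1, 1, 1), 0.5))
  expect_true(check_sample_uniqueness(c(2, 3), 0))
})

test_that("the monotonicity registry flags each model kind", {
  expect_true(is_monotonic(k_anonymity(2)))
  expect_true(is_monotonic(distinct_l_diversity(2, "s")))
  expect_true(is_monotonic(entropy_l_diversity(2, "s", "shannon")))
  expect_false(is_monotonic(entropy_l_diversity(2, "s", "grassberger")))
  expect_true(is_monotonic(recursive_cl_diversity(2, 2, "s")))
  expect_false(is_monotonic(t_closeness(0.2, "s", "equal")))
  expect_false(is_monotonic(t_closeness(0.2, "s", "ordered")))
  expect_false(is_monotonic(delta_disclosure(1, "s")))
  expect_false(is_monotonic(beta_likeness(1, "s")))
  expect_true(is_monotonic(average_risk(0.5)))
  expect_true(is_monotonic(sample_uniqueness(0.5)))
})

test_that("merging classes preserves every monotonic class-level model", {
  # randomized merge trials: two passing classes with the same key merge
  # into a class that must still pass
  set.seed(42)
  models <- list(
    list(m = k_anonymity(3),
         chk = function(cnt) check_k_anonymity(sum(cnt), 3)),
    list(m = distinct_l_diversity(2, "s"),
         chk = function(cnt) check_distinct_l(cnt, 2)),
    list(m = entropy_l_diversity(2, "s", "shannon"),
         chk = function(cnt) check_entropy_l(cnt, 2, "shannon")),
    list(m = recursive_cl_diversity(2, 2, "s"),
         chk = function(cnt) check_recursive_cl(cnt, 2, 2))
  )
  n_trials <- 2500L
  for (spec in models) {
    expect_true(is_monotonic(spec$m))
    violations <- 0L
    tried <- 0L
    while (tried < n_trials) {
      a <- stats::rpois(4, 2)
      b <- stats::rpois(4, 2)
      if (!spec$chk(a) || !spec$chk(b)) next
      tried <- tried + 1L
      if (!spec$chk(a + b)) violations <- violations + 1L
    }
    expect_identical(violations, 0L)
  }
})

test_that("pooling partitions preserves the dataset-level models", {
  set.seed(7)
  for (trial in 1:2500) {
    sizes_a <- 1L + stats::rpois(sample(1:5, 1), 3)
    sizes_b <- 1L + stats::rpois(sample(1:5, 1), 3)
    tau <- stats::runif(1, 0.05, 1)
    if (check_average_risk(sizes_a, tau) && check_average_risk(sizes_b, tau)) {
      # pooled classes merge or stay distinct; either way the count ratio
      # cannot exceed the worst partition's
      expect_true(check_average_risk(c(sizes_a, sizes_b), tau))
    }
    if (check_sample_uniqueness(sizes_a, tau) && check_sample_uniqueness(sizes_b, tau)) {
      expect_true(check_sample_uniqueness(c(sizes_a, sizes_b), tau))
    }
  }
})

test_that("evaluate_all composes class- and dataset-level verdicts", {
  d <- toy_data(c(30, 30, 31, 32), sex = c("F", "M", "F", "M"))
  cfg <- toy_config()
  classes <- group_into_classes(d, cfg, 0)
  ref <- reference_stats(d, cfg)

  v <- evaluate_all(list(k_anonymity(2)), classes, ref)
  expect_equal(v$per_class$pass, classes$size >= 2)
  expect_false(v$pass)

  v0 <- evaluate_all(list(), classes, ref)
  expect_true(v0$pass)

  v2 <- evaluate_all(list(k_anonymity(1), average_risk(0.8)), classes, ref)
  expect_true(v2$pass)
  v3 <- evaluate_all(list(k_anonymity(1), average_risk(0.5)), classes, ref)
  expect_false(v3$pass)  # 3 classes / 4 records = 0.75
  expect_match(v3$failing_models, "average_risk", all = FALSE)
})

test_that("model parameter validation rejects out-of-range values", {
  expect_error(k_anonymity(0), class = "p4_error_model_param")
  expect_error(t_closeness(1.5, "s"), class = "p4_error_model_param")
  expect_error(t_closeness(0, "s"), class = "p4_error_model_param")
  expect_error(delta_disclosure(-1, "s"), class = "p4_error_model_param")
  expect_error(distinct_l_diversity(2.5, "s"), class = "p4_error_model_param")
})
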
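test_that("generated hierarchies are balanced with a single top", {
  h <- generate_hierarchy(4, 2)
  expect_equal(h$L, 2L)
  expect_equal(h$n_leaves, 4L)
  expect_equal(unique(h$levels[, 3]), "*")
  expect_equal(leaves_covered(h, h$levels[1, 2], 1), 2L)

  h1 <- generate_hierarchy(1, 2)
  expect_equal(h1$L, 0L)
  expect_equal(h1$n_leaves, 1L)

  h9 <- generate_hierarchy(9, 3)
  expect_equal(h9$L, 2L)
  expect_equal(sort(as.vector(table(h9$levels[, 2]))), rep(3L, 3))

  # uneven domains still close at "*"
  h7 <- generate_hierarchy(7, 3)
  expect_equal(unique(h7$levels[, h7$L + 1]), "*")
})

test_that("generated datasets respect shape, domains, and the seed", {
  syn <- generate_dataset(100, qi_domains = c(4, 5, 6), sensitive_domain = 2,
                          seed = 7)
  expect_equal(dim(syn$data), c(100L, 5L))  # 3 QI + sensitive + .row_id
  for (j in 1:3) {
    expect_true(all(syn$data[[paste0("qi", j)]] %in%
                      syn$hierarchies[[j]]$levels[, 1]))
  }
  syn2 <- generate_dataset(100, qi_domains = c(4, 5, 6), sensitive_domain = 2,
                           seed = 7)
  expect_identical(syn$data, syn2$data)
  syn3 <- generate_dataset(100, qi_domains = c(4, 5, 6), sensitive_domain = 2,
                           seed = 8)
  expect_false(identical(syn$data, syn3$data))
})

test_that("an unskewed generator is uniform within binomial bounds", {
  n <- 20000
  D <- 4
  syn <- generate_dataset(n, qi_domains = c(D), skew = 0, seed = 99)
  counts <- table(syn$data$qi1)
  expected <- n / D
  sigma <- sqrt(n * (1 / D) * (1 - 1 / D))
  expect_true(all(abs(counts - expected) <= 5 * sigma))
})

test_that("skew concentrates mass on the first values", {
  syn <- generate_dataset(5000, qi_domains = c(6), skew = 1.2, seed = 15)
  counts <- table(factor(syn$data$qi1, levels = sort(unique(syn$data$qi1))))
  expect_gt(counts[[1]], counts[[length(counts)]])
})

test_that("planted structure yields classes of exactly m at the identity scheme", {
  syn <- generate_dataset(60, qi_domains = c(5, 5), plant_m = 4, seed = 12)
  cfg <- anon_config(syn$quasi_identifiers, syn$hierarchies,
                     sensitive = syn$sensitive)
  cl <- group_into_classes(syn$data, cfg, c(0, 0))
  expect_true(all(cl$size == 4L))
  expect_equal(nrow(cl), 15L)
  expect_error(generate_dataset(10, qi_domains = c(4), plant_m = 3, seed = 1),
               class = "p4_error_synth")
})

test_that("extrapolation resamples input records reproducibly", {
  syn <- generate_dataset(10, qi_domains = c(4), seed = 3)
  e1 <- extrapolate_dataset(syn$data, factor = 3, seed = 5)
  expect_equal(nrow(e1), 30L)
  # every output record is an input record
  in_keys <- do.call(paste, syn$data[c("qi1", "sensitive")])
  out_keys <- do.call(paste, e1[c("qi1", "sensitive")])
  expect_true(all(out_keys %in% in_keys))

  e2 <- extrapolate_dataset(syn$data, factor = 3, seed = 5)
  expect_identical(e1, e2)
  expect_equal(nrow(extrapolate_dataset(syn$data, factor = 1, seed = 1)), 10L)
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_dataset(50, seed = 9))
  invisible(generate_scenario(11, n_range = c(50, 60)))
  expect_identical(.Random.seed, before)
})

test_that("scenarios cover every model kind on request", {
  for (kind in all_model_kinds) {
    sc <- generate_scenario(77, n_range = c(50, 100), force_kind = kind)
    keys <- vapply(sc$config$models, function(m) m$registry_key, character(1))
    expect_true(kind %in% keys)
  }
})
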
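test_that("lexicographic partitioning sorts and balances", {
  d <- tibble::tibble(
    a = c("b", "a", "a"), b = c("1", "2", "1"),
    sex = c("F", "M", "F"), .row_id = 1:3
  )
  cfg <- anon_config(c("a", "b"),
                     hierarchies = list(a = build_hierarchy(list(c("a", "*"), c("b", "*"))),
                                        b = build_hierarchy(list(c("1", "*"), c("2", "*")))),
                     sensitive = "sex")
  parts <- lexicographic_partition(d, cfg, 1)
  expect_equal(parts[[1]]$a, c("a", "a", "b"))
  expect_equal(parts[[1]]$b, c("1", "2", "1"))

  syn <- generate_dataset(10, qi_domains = c(4), seed = 5)
  cfg10 <- anon_config(syn$quasi_identifiers, syn$hierarchies,
                       sensitive = syn$sensitive)
  p3 <- lexicographic_partition(syn$data, cfg10, 3)
  expect_equal(vapply(p3, nrow, integer(1)), c(4L, 3L, 3L))
  # disjoint and covering
  ids <- unlist(lapply(p3, function(p) p$.row_id))
  expect_setequal(ids, syn$data$.row_id)
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("harmonization follows the stated per-attribute rules", {
  schemes <- list(c(a = 1L), c(a = 2L), c(a = 2L))
  expect_equal(harmonize_schemes(schemes, "average"), c(a = 2L))  # 5/3 rounds half-up
  expect_equal(harmonize_schemes(schemes, "minimum"), c(a = 1L))
  expect_equal(harmonize_schemes(schemes, "median"), c(a = 2L))

  expect_equal(harmonize_schemes(list(c(a = 0L), c(a = 0L)), "average"), c(a = 0L))
  # lower median on an even count
  expect_equal(harmonize_schemes(list(c(a = 1L), c(a = 2L)), "median"), c(a = 1L))
  # half-up rounding: mean 1.5 -> 2
  expect_equal(harmonize_schemes(list(c(a = 1L), c(a = 2L)), "average"), c(a = 2L))

  # harmonized level stays within the per-attribute range
  set.seed(8)
  for (trial in 1:50) {
    ss <- lapply(1:4, function(i) c(x = sample(0:5, 1), y = sample(0:3, 1)))
    for (strat in c("average", "minimum", "median")) {
      h <- harmonize_schemes(ss, strat)
      m <- do.call(rbind, ss)
      expect_true(all(h >= apply(m, 2, min) & h <= apply(m, 2, max)))
    }
  }
})

test_that("reapplying the harmonized scheme suppresses sub-threshold classes", {
  sc <- synth_config(80, qi_domains = c(6), models = list(k_anonymity(3)),
                     seed = 31)
  parts <- lexicographic_partition(sc$data, sc$config, 2)
  results <- anonymize_partitions(parts, sc$config, workers = 1)
  # force a scheme below what the partitions chose
  forced <- setNames(0L, sc$config$quasi_identifiers)
  re <- reapply_harmonized(parts, results, forced, sc$config)
  for (i in seq_along(re)) {
    chk <- check_privacy(re[[i]]$output, sc$config,
                         ref = reference_stats(parts[[i]], sc$config, "partition"))
    expect_true(chk$pass)
    expect_equal(unname(re[[i]]$scheme), 0L)
  }
  # partitions already at the harmonized scheme are reused untouched
  same <- reapply_harmonized(parts, results, results[[1]]$scheme, sc$config)
  expect_identical(same[[1]], results[[1]])
})

test_that("compliance checking suppresses a merged class that only passes locally", {
  # two partitions, each a single equivalence class that satisfies
  # t-closeness against its own partition-local distribution (EMD = 0),
  # but whose merged class (9 F, 1 M) is far from the global (0.5, 0.5)
  # reference: EMD 0.4 > t = 0.2
  h <- build_hierarchy(list(c("a", "*"), c("b", "*")))
  cfg <- anon_config("qi", hierarchies = list(qi = h), sensitive = "sex",
                     models = list(t_closeness(0.2, "sex", "equal")))
  p1 <- tibble::tibble(qi = rep("a", 5), sex = rep("F", 5), .row_id = 1:5)
  p2 <- tibble::tibble(qi = rep("a", 5), sex = c("F", "F", "F", "F", "M"),
                       .row_id = 6:10)

  # each partition passes against its local reference
  for (p in list(p1, p2)) {
    expect_true(check_privacy(p, cfg,
                              ref = reference_stats(p, cfg, "partition"))$pass)
  }

  global_ref <- structure(
    list(n = 20L, dist = list(sex = c(F = 0.5, M = 0.5)), scope = "global"),
    class = "reference_stats"
  )
  results <- list(list(output = p1), list(output = p2))
  cc <- compliance_check(results, cfg, global_ref)
  expect_equal(cc$classes_checked, 1L)
  expect_equal(cc$classes_removed, 1L)
  expect_setequal(cc$suppressed_row_ids, 1:10)
})

test_that("compliance checking is a no-op for monotonic-only configurations", {
  sc <- synth_config(60, models = list(k_anonymity(2)), seed = 13)
  parts <- lexicographic_partition(sc$data, sc$config, 2)
  results <- anonymize_partitions(parts, sc$config, workers = 1)
  cc <- compliance_check(results, sc$config,
                         reference_stats(sc$data, sc$config))
  expect_length(cc$suppressed_row_ids, 0)
  expect_equal(cc$classes_checked, 0L)
})

test_that("a single partition degenerates to the direct anonymizer", {
  sc <- synth_config(120, models = list(k_anonymity(3)), seed = 17)
  fit <- run_p4(sc$data, sc$config, partitions = 1)
  sorted <- lexicographic_partition(sc$data, sc$config, 1)[[1]]
  direct <- search_optimal(sorted, sc$config)
  expect_identical(fit$output, direct$output)
  expect_equal(fit$report$fidelity, direct$fidelity)
})

test_that("the merged output honours k-anonymity record-for-record", {
  # with k = 4, every non-suppressed output record shares its generalized
  # tuple with at least 3 others
  sc <- synth_config(200, models = list(k_anonymity(4)), seed = 23)
  fit <- run_p4(sc$data, sc$config, partitions = 4)
  out <- fit$output
  qis <- sc$config$quasi_identifiers
  supp <- Reduce(`&`, lapply(qis, function(a) out[[a]] == "*"))
  key <- do.call(paste, c(out[qis], sep = "\x1F"))
  tab <- table(key[!supp])
  expect_true(all(tab >= 4))
})

test_that("the report carries the four pipeline stages and echo fields", {
  sc <- synth_config(100, models = list(k_anonymity(2)), seed = 29,
                     partitions = 2)
  fit <- run_p4(sc$data, sc$config)
  r <- fit$report
  expect_named(r$step_durations,
               c("anonymization", "harmonization", "compliance", "finalization"))
  expect_true(all(r$step_durations >= 0))
  expect_named(r$suppressed_counts,
               c("anonymization", "harmonization", "compliance", "finalization"))
  # suppression accumulates from harmonization onward
  sp <- r$suppressed_counts
  expect_gte(sp[["compliance"]], sp[["harmonization"]])
  expect_gte(sp[["finalization"]], sp[["compliance"]])
  expect_equal(r$partitions, 2L)
  expect_length(r$per_partition_schemes, 2L)
  expect_equal(nrow(fit$output), 100L)

  # local mode: no harmonization, compliance skipped for monotonic-only
  scl <- synth_config(100, models = list(k_anonymity(2)), seed = 29,
                      transformation = "local", local_iterations = 2)
  fitl <- run_p4(scl$data, scl$config, partitions = 2)
  expect_equal(fitl$report$step_durations[["harmonization"]], 0)
  expect_null(fitl$report$harmonized_scheme)
})

test_that("restore_order returns records to input order", {
  sc <- synth_config(50, models = list(k_anonymity(2)), seed = 37)
  fit <- run_p4(sc$data, sc$config, partitions = 2)
  back <- restore_order(fit)
  expect_equal(back$.row_id, sc$data$.row_id)
  expect_equal(back$sensitive, sc$data$sensitive)
})

test_that("partitions smaller than k are fully suppressed with a warning", {
  d <- toy_data(c(30, 30, 31, 31, 32, 32))
  cfg <- toy_config(models = list(k_anonymity(3)))
  parts <- lexicographic_partition(d, cfg, 3)  # 2 records per partition
  w <- capture_warnings(anonymize_partitions(parts, cfg, workers = 1))
  expect_match(w, "fully suppressed", all = TRUE)
  expect_length(w, 3)
})

test_that("tidiers summarize runs as tibbles", {
  sc <- synth_config(80, models = list(k_anonymity(2)), seed = 41)
  fit <- run_p4(sc$data, sc$config, partitions = 2)
  g <- glance(fit)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n, 80L)
  expect_equal(g$partitions, 2L)
  td <- tidy(fit$report)
  expect_equal(td$stage,
               c("anonymization", "harmonization", "compliance", "finalization"))
  expect_s3_class(autoplot(fit), "ggplot")
})
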
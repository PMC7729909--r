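test_that("equivalence classes partition the dataset deterministically", {
  d <- tiny_dataset(trow("A", "left", "yes", 11))
  classes <- partition_classes(d, c("group", "side"))
  expect_equal(nrow(classes), 1L)
  expect_equal(classes$n, 11L)

  d2 <- tiny_dataset(trow("A", "left", "yes", 2), trow("B", "left", "yes", 1))
  classes2 <- partition_classes(d2, c("group", "side"))
  expect_equal(classes2$n, c(2L, 1L))
  expect_setequal(unlist(classes2$record_ids), d2$record_id)  # exhaustive partition
  expect_error(partition_classes(d2, character(0L)), "no key variables")
})

test_that("k-anonymity violations sit exactly at the class-size boundary", {
  classes11 <- partition_classes(tiny_dataset(trow("A", "left", "yes", 11)), "group")
  classes10 <- partition_classes(tiny_dataset(trow("A", "left", "yes", 10)), "group")
  expect_equal(nrow(check_k_anonymity(classes11, 11)), 0L)
  expect_equal(nrow(check_k_anonymity(classes10, 11)), 1L)
  expect_equal(nrow(check_k_anonymity(classes10, 1)), 0L)  # k = 1 never violated
})

test_that("prosecutor risk aggregates 1/|class| over records", {
  d <- tiny_dataset(trow("A", "left", "yes", 11))
  profile <- risk_profile(d, "group")
  expect_equal(profile$highest, 1 / 11)

  with_singleton <- tiny_dataset(trow("A", "left", "yes", 5), trow("B", "left", "yes", 1))
  expect_equal(risk_profile(with_singleton, "group")$highest, 1)

  two_pairs <- tiny_dataset(trow("A", "left", "yes", 2), trow("B", "left", "yes", 2))
  p <- risk_profile(two_pairs, "group")
  expect_equal(p$average, 0.5)  # four records, each at risk 1/2
  expect_true(p$lowest <= p$average && p$average <= p$highest)
  expect_error(risk_profile(two_pairs[0, ], "group"), "empty")
})

test_that("hierarchical EMD matches hand-derived reference values", {
  flat2 <- flat_hierarchy("x", c("a", "b"))
  expect_equal(hierarchical_emd(c(a = 0.3, b = 0.7), c(a = 0.3, b = 0.7), flat2), 0)
  expect_equal(hierarchical_emd(c(a = 1, b = 0), c(a = 0, b = 1), flat2), 1)

  # balanced binary tree over 4 leaves: shifting 0.5 mass across the root
  # moves at ground distance 1, within a subtree at distance 1/2
  bin4 <- hierarchy("x", list(a = "L", b = "L", c = "R", d = "R"))
  expect_equal(
    hierarchical_emd(c(a = 0.5, b = 0.5, c = 0, d = 0),
                     c(a = 0, b = 0.5, c = 0.5, d = 0), bin4),
    0.5
  )
  expect_equal(
    hierarchical_emd(c(a = 0.5, b = 0.5, c = 0, d = 0),
                     c(a = 0, b = 1, c = 0, d = 0), bin4),
    0.25  # all movement stays below the L node
  )

  expect_error(hierarchical_emd(c(a = 1, b = 0), c(a = 2, b = -1), flat2), "sum to 1")
  expect_error(hierarchical_emd(c(a = 1, z = 0), c(a = 0, b = 1), flat2), "leaves")
})

test_that("hierarchical EMD equals the minimum-cost transport oracle", {
  set.seed(401)
  for (trial in 1:220) {
    h <- random_hierarchy()
    leaves <- names(h$paths)
    p <- random_distribution(leaves, sparse = trial %% 3 == 0)
    q <- random_distribution(leaves, sparse = trial %% 4 == 0)
    expect_equal(hierarchical_emd(p, q, h), emd_oracle(p, q, h), tolerance = 1e-9)
  }
})

test_that("hierarchical EMD behaves like a metric on its leaf simplex", {
  set.seed(402)
  for (trial in 1:40) {
    h <- random_hierarchy()
    leaves <- names(h$paths)
    p <- random_distribution(leaves)
    q <- random_distribution(leaves)
    r <- random_distribution(leaves)
    d_pq <- hierarchical_emd(p, q, h)
    expect_equal(d_pq, hierarchical_emd(q, p, h), tolerance = 1e-12)  # symmetry
    expect_lte(d_pq, hierarchical_emd(p, r, h) + hierarchical_emd(r, q, h) + 1e-12)
    expect_gte(d_pq, 0)
    expect_lte(d_pq, 1)
    # flat hierarchy reduces to total variation distance
    flat <- flat_hierarchy("x", leaves)
    expect_equal(hierarchical_emd(p, q, flat), sum(abs(p - q[names(p)])) / 2,
                 tolerance = 1e-12)
  }
})

test_that("t-closeness compares class distributions to the overall one", {
  # one class = whole dataset: distance 0, never violating
  d <- tiny_dataset(trow("A", "left", "yes", 6), trow("A", "left", "no", 6))
  h <- tiny_config()$hierarchies$outcome
  expect_equal(nrow(check_t_closeness(d, "group", "outcome", 0.01, h)), 0L)

  # two point-mass classes against a 50/50 overall: each at distance 0.5
  d2 <- tiny_dataset(trow("A", "left", "yes", 6), trow("B", "left", "no", 6))
  at_half <- check_t_closeness(d2, "group", "outcome", 0.5, h)
  expect_equal(nrow(at_half), 0L)  # violation requires emd > t strictly
  below <- check_t_closeness(d2, "group", "outcome", 0.49, h)
  expect_equal(nrow(below), 2L)
  expect_equal(below$emd, c(0.5, 0.5))
  expect_equal(nrow(check_t_closeness(d2, "group", "outcome", 1, h)), 0L)
})

test_that("the value-frequency rule triggers strictly below the minimum count", {
  config <- tiny_config()
  d <- tiny_dataset(trow("A", "left", "yes", 10), trow("A", "left", "no", 9))
  out <- check_value_frequency(d, config, min_count = 10)
  expect_equal(out$rare_values$value, "no")  # exactly 10 passes, 9 does not
  expect_equal(out$rare_values$n, 9L)
  expect_length(out$record_ids, 9L)
  expect_setequal(out$record_ids, d$record_id[d$outcome == "no"])
  # absent domain values ("rare", "C", "right") are vacuously safe
  expect_false(any(out$rare_values$value %in% c("rare", "C", "right")))
})

test_that("explicit not-applicable codes are exempt unless asked otherwise", {
  vars <- list(variable_spec("g", "key", c("a", "b")),
               variable_spec("s", "sensitive", c("x", "NA"), na_code = "NA"))
  config <- pipeline_config(vars, list(flat_hierarchy("s", c("x", "NA"))))
  d <- tibble::tibble(record_id = 1:12, g = rep("a", 12),
                      s = c(rep("x", 9), rep("NA", 3)))
  exempt <- check_value_frequency(d, config, min_count = 10)
  expect_equal(exempt$rare_values$value, "x")
  counted <- check_value_frequency(d, config, min_count = 10, exempt_na = FALSE)
  expect_setequal(counted$rare_values$value, c("x", "NA"))
})
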
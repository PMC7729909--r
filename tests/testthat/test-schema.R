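test_that("the bundled registry schema has the expected shape", {
  schema <- leoss_schema()
  expect_length(schema$variables, 16L)
  roles <- vapply(schema$variables, `[[`, character(1L), "role")
  expect_equal(sum(roles == "key"), 4L)
  expect_equal(sum(roles == "sensitive"), 8L)
  expect_equal(sum(roles == "derived"), 4L)
  # every sensitive variable has a balanced hierarchy over exactly its domain
  for (spec in schema$variables[roles == "sensitive"]) {
    h <- schema$hierarchies[[spec$name]]
    expect_s3_class(h, "puf_hierarchy")
    expect_gte(h$height, 1L)
    expect_setequal(names(h$paths), spec$domain)
  }
  # and the whole thing passes full config validation
  expect_s3_class(leoss_config(), "pipeline_config")
})

test_that("variable and hierarchy constructors reject malformed input", {
  expect_error(variable_spec("x", "key", c("a", "a")), "unique")
  expect_error(variable_spec("x", "sensitive", c("a", "b"), na_code = "c"), "not in its domain")
  expect_error(hierarchy("x", list(a = "p", b = character(0L))), "unbalanced")
  expect_equal(flat_hierarchy("x", c("a", "b", "c"))$height, 1L)
})

test_that("config validation enforces hierarchy coverage and disjoint roles", {
  vars <- list(variable_spec("g", "key", c("a", "b")),
               variable_spec("s", "sensitive", c("x", "y")))
  expect_error(pipeline_config(vars), "'s' has no hierarchy")
  expect_error(
    pipeline_config(vars, list(flat_hierarchy("s", c("x", "z")))),
    "do not match its domain"
  )
  expect_error(
    pipeline_config(vars, list(flat_hierarchy("s", c("x", "y"))),
                    key_vars = c("g", "s"), sensitive_vars = "s"),
    "disjoint"
  )
})

test_that("config files round-trip and absent parameters take defaults", {
  vars <- list(
    list(name = "g", role = "key", domain = list("a", "b")),
    list(name = "s", role = "sensitive", domain = list("x", "y", "NA"), na_code = "NA")
  )
  hier <- list(s = list(x = list(), y = list(), "NA" = list()))

  # minimal JSON config: no params block at all
  path_json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(variables = vars, hierarchies = hier), path_json,
                       auto_unbox = TRUE)
  config <- read_config(path_json)
  expect_equal(config$k, 11L)
  expect_equal(config$t, 0.5)
  expect_equal(config$min_value_count, 10L)
  expect_equal(config$key_threshold, 5L)
  expect_equal(config$variables$s$na_code, "NA")

  # explicit parameter overrides the default
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(variables = vars, hierarchies = hier,
                            params = list(t = 0.2)), path2, auto_unbox = TRUE)
  expect_equal(read_config(path2)$t, 0.2)

  # write_config -> read_config round trip, YAML dialect
  path_yaml <- withr::local_tempfile(fileext = ".yaml")
  write_config(leoss_config(k = 7L), path_yaml)
  back <- read_config(path_yaml)
  expect_equal(back$k, 7L)
  expect_equal(config_vars(back), config_vars(leoss_config()))
  expect_equal(back$hierarchies[["Last known patient status"]]$paths,
               leoss_config()$hierarchies[["Last known patient status"]]$paths)

  # a config whose hierarchy leaves do not match the domain is rejected
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(variables = vars,
                            hierarchies = list(s = list(x = list(), wrong = list(), "NA" = list()))),
                       bad, auto_unbox = TRUE)
  expect_error(read_config(bad), "do not match its domain")
})

test_that("dataset CSV i/o validates cells and round-trips literally", {
  config <- tiny_config()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("group,side,outcome", "A,left,yes", "B,right,no", "A,left,rare"), path)
  d <- read_dataset(path, config)
  expect_equal(nrow(d), 3L)
  expect_equal(d$record_id, 0:2)  # 0-based input row index
  expect_equal(d$group, c("A", "B", "A"))

  # out-of-domain cell names row, column and value
  writeLines(c("group,side,outcome", "A,left,purple"), path)
  expect_error(read_dataset(path, config), "row 1, column 'outcome'.*purple")

  # unknown / missing columns
  writeLines(c("group,side,outcome,extra", "A,left,yes,1"), path)
  expect_error(read_dataset(path, config), "unknown column")
  writeLines(c("group,side", "A,left"), path)
  expect_error(read_dataset(path, config), "missing column")

  # header-only file is an empty, valid dataset
  writeLines("group,side,outcome", path)
  expect_equal(nrow(read_dataset(path, config)), 0L)

  # write -> read reproduces every cell, with the explicit "NA" code intact
  d <- simulate_primary(50, seed = 42)
  out <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, out)
  back <- read_dataset(out, leoss_config())
  expect_equal(as.data.frame(back[-1L]), as.data.frame(d[-1L]))
  expect_true(any(back[["Vasopressors in critical phase"]] == "NA"))
})
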
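test_that("generation is exactly reproducible from config + seed", {
  cfg <- mixture_config(C = 6, d = 2, n_base = 50, n_pool = 60, n_test = 20,
                        seed = 7)
  a <- generate_mixture(cfg)
  b <- generate_mixture(cfg)
  expect_identical(a$base$features, b$base$features)
  expect_identical(a$pool$features, b$pool$features)
  expect_identical(a$test$features, b$test$features)
  expect_identical(a$pool_roles, b$pool_roles)
  # a different seed changes the draw
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(generate_mixture(cfg2)$base$features,
                         a$base$features))
})

test_that("per-class counts match the config bookkeeping", {
  cfg <- mixture_config(C = 5, d = 3, n_base = 7, n_pool = 20, n_test = 4,
                        boundary_fraction = 0.2, seed = 1)
  ds <- generate_mixture(cfg)
  expect_equal(nrow(ds$base$features), 5 * 7)
  expect_equal(nrow(ds$pool$features), 5 * 20)
  expect_equal(nrow(ds$test$features), 5 * 4)
  expect_equal(unname(table(ds$base$labels)), rep(7L, 5),
               ignore_attr = TRUE)
  # boundary count is round(fraction * n_pool) per class slot
  expect_equal(sum(ds$pool_roles == "BOUNDARY"), 5 * round(0.2 * 20))
})

test_that("sigma -> 0 limit: cores collapse to zero entropy, midpoints to 1 bit", {
  # two classes so the midpoint's flanking classes are always its nearest:
  # boundary mass splits exactly between them, giving 1 bit
  cfg <- mixture_config(C = 2, d = 2, n_base = 5, n_pool = 20, n_test = 0,
                        r = 10, sigma = 1e-9, boundary_fraction = 0.25,
                        seed = 3)
  ds <- generate_mixture(cfg)
  st <- score_pool(ds$pool, compute_prototypes(ds$base))
  roles <- ds$pool_roles[st$sample_id]
  expect_lt(max(st$entropy[roles == "CORE"]), 1e-6)
  expect_equal(unname(st$entropy[roles == "BOUNDARY"]),
               rep(1, sum(roles == "BOUNDARY")), tolerance = 1e-6)
  # with many classes the degenerate limit still ranks every planted
  # boundary sample above every core sample
  cfg6 <- mixture_config(C = 6, d = 2, n_base = 5, n_pool = 20, n_test = 0,
                         r = 10, sigma = 1e-9, boundary_fraction = 0.25,
                         seed = 4)
  ds6 <- generate_mixture(cfg6)
  st6 <- score_pool(ds6$pool, compute_prototypes(ds6$base))
  roles6 <- ds6$pool_roles[st6$sample_id]
  expect_gt(min(st6$entropy[roles6 == "BOUNDARY"]),
            max(st6$entropy[roles6 == "CORE"]))
})

test_that("boundary samples out-score cores when clusters are well separated", {
  for (seed in 1:5) {
    ds <- generate_mixture(mixture_config(
      C = 6, d = 2, n_base = 20, n_pool = 30, n_test = 0, r = 8, sigma = 1,
      boundary_fraction = 0.2, seed = seed
    ))
    st <- score_pool(ds$pool, compute_prototypes(ds$base))
    roles <- ds$pool_roles[st$sample_id]
    expect_gt(mean(st$entropy[roles == "BOUNDARY"]),
              mean(st$entropy[roles == "CORE"]))
  }
})

test_that("raw_dim lifts every split to the raw dimension", {
  cfg <- mixture_config(C = 3, d = 2, n_base = 4, n_pool = 6, n_test = 2,
                        raw_dim = 10, seed = 2)
  ds <- generate_mixture(cfg)
  expect_equal(ncol(ds$base$features), 10)
  expect_equal(ncol(ds$pool$features), 10)
  expect_equal(ncol(ds$test$features), 10)
})

test_that("datasets round-trip through a directory of plain-text files", {
  cfg <- mixture_config(C = 3, d = 2, n_base = 4, n_pool = 10, n_test = 3,
                        boundary_fraction = 0.1, seed = 5)
  ds <- generate_mixture(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_setequal(list.files(dir),
                  c("base.csv", "pool.csv", "test.csv", "roles.csv",
                    "config.json"))
  back <- read_dataset(dir)
  expect_identical(back$base$features, ds$base$features)
  expect_identical(back$pool$features, ds$pool$features)
  expect_identical(back$pool_roles, ds$pool_roles)
  # the stored config regenerates the identical dataset
  regen <- generate_mixture(back$config)
  expect_identical(regen$base$features, ds$base$features)
})

test_that("empty pool writes a header-only file and reads back as NULL", {
  cfg <- mixture_config(C = 2, d = 2, n_base = 3, n_pool = 0, n_test = 2,
                        boundary_fraction = 0, seed = 1)
  ds <- generate_mixture(cfg)
  expect_null(ds$pool)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_equal(length(readLines(file.path(dir, "pool.csv"))), 1L)
  expect_null(read_dataset(dir)$pool)
})

test_that("invalid configs are rejected", {
  expect_error(mixture_config(C = 1), "C must be")
  expect_error(mixture_config(sigma = 0), "sigma")
  expect_error(mixture_config(boundary_fraction = 1.5), "boundary_fraction")
  expect_error(mixture_config(d = 4, raw_dim = 2), "raw_dim")
})
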
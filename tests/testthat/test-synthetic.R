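test_that("R-group attachment joins fragments at the dummies", {
  expect_identical(attach_rgroup("[*]c1ccccc1", "[*]C"),
                   canon_smiles("Cc1ccccc1"))
  expect_identical(attach_rgroup("[*]C1CCN(Cc2ccccc2)CC1", "[*]OC"),
                   canon_smiles("COC1CCN(Cc2ccccc2)CC1"))
  expect_error(attach_rgroup("c1ccccc1", "[*]C"), "attachment point")
})

test_that("generation is deterministic in config and seed", {
  cfg <- generator_config(seed = 5L)
  b1 <- generate_target_set(cfg, "TD")
  b2 <- generate_target_set(cfg, "TD")
  expect_identical(b1$set, b2$set)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_target_set(generator_config(seed = 6L), "TD")
  expect_false(identical(b1$set$actives$pki, b3$set$actives$pki))
  # the generator restores the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_target_set(cfg, "TD")); after <- runif(1)
  expect_identical(before, after)
})

test_that("a single 3-analog series yields exactly its 3 tsr pairs", {
  b <- generate_target_set(
    generator_config(n_series = 1L, series_size = 3L, inactive_fraction = 0,
                     planted_cliff_fraction = 0, seed = 2L), "T3")
  expect_identical(nrow(b$set$actives), 3L)
  pairs <- find_matched_pairs(b$set$actives[, c("compound_id", "smiles")])
  pairs <- pairs[apply_tsr_filter(pairs), ]
  expect_identical(nrow(pairs), 3L)  # C(3,2), all sharing the series core
})

test_that("at least one active per series survives full inactive marking", {
  b <- generate_target_set(
    generator_config(n_series = 2L, series_size = 2L, inactive_fraction = 1,
                     planted_cliff_fraction = 0, seed = 3L), "TI")
  tab <- table(b$truth$compounds$series[b$truth$compounds$status == "active"])
  expect_true(all(tab >= 1L))
  expect_identical(nrow(b$set$actives) + sum(b$truth$compounds$status ==
                                               "inactive"), 4L)
})

test_that("flat sets are generated but fail qualification", {
  b <- generate_target_set(
    generator_config(potency_sigma = 0, series_sigma = 0,
                     planted_cliff_fraction = 0, seed = 4L), "TFLAT")
  expect_false(qualify_target_set(b$set))
})

test_that("generated structures are valid, unique and size-restricted", {
  b <- generate_target_set(generator_config(seed = 8L), "TV")
  comp <- b$truth$compounds
  expect_identical(anyDuplicated(comp$compound_id), 0L)
  expect_identical(anyDuplicated(comp$smiles), 0L)
  canon <- vapply(comp$smiles, canon_smiles, character(1))
  expect_identical(unname(canon), comp$smiles)  # emitted canonical
  rg_sizes <- vapply(comp$rgroup, heavy_atom_count, integer(1))
  core_sizes <- vapply(comp$core, heavy_atom_count, integer(1))
  expect_true(all(rg_sizes <= 13L))
  expect_true(all(core_sizes >= 2L * rg_sizes))
  expect_true(all(b$set$actives$pki >= 3 & b$set$actives$pki <= 12))
  expect_false(any(b$set$inactives$compound_id %in%
                     b$set$actives$compound_id))
})

test_that("the benchmark suite panel is deterministic and spans conditions", {
  s1 <- generate_benchmark_suite(n_sets = 5, seed = 9L)
  s2 <- generate_benchmark_suite(n_sets = 5, seed = 9L)
  expect_identical(lapply(s1, `[[`, "set"), lapply(s2, `[[`, "set"))
  qual <- vapply(s1, function(b) qualify_target_set(b$set), logical(1))
  expect_false(qual[["T001"]])  # flat panel member is rejected
  expect_true(any(qual))
  expect_identical(nrow(s1$T003$set$inactives), 0L)  # no-inactive member
})

test_that("synthetic table emission matches the reader dialects", {
  suite <- generate_benchmark_suite(n_sets = 4, seed = 10L,
                                    base = list(n_series = 4L,
                                                series_size = 5L))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_tables(suite, dir)
  meas <- read_activity_table(paths[[1L]])
  expect_identical(attr(meas, "summary")$n_dropped, 0L)
  sets <- aggregate_potency(meas)
  sets <- read_inactives(paths[[2L]], sets)
  expect_setequal(names(sets), names(suite)[vapply(suite, function(b)
    nrow(b$set$actives) > 0, logical(1))])
  # potencies and structures survive the round trip
  for (tid in names(sets)) {
    orig <- suite[[tid]]$set$actives
    got <- sets[[tid]]$actives
    m <- match(orig$compound_id, got$compound_id)
    expect_false(anyNA(m))
    expect_equal(got$pki[m], orig$pki)
    expect_identical(got$smiles[m], orig$smiles)
  }
})
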
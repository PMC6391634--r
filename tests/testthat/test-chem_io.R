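write_toy_table <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("activity reader drops non-numeric potencies and counts them", {
  path <- write_toy_table(c(
    "compound_id\ttarget_id\tsmiles\tpki",
    "C1\tT1\tCCO\t7.2",
    "C2\tT1\tCCN\t",
    "C3\tT1\tCCC\t9.1"))
  m <- read_activity_table(path)
  expect_identical(nrow(m), 2L)
  expect_identical(attr(m, "summary")$n_dropped, 1L)

  path2 <- write_toy_table(c(
    "compound_id\ttarget_id\tsmiles\tpki",
    "C1\tT1\tCCO\t7.2",
    "C2\tT1\tCCN\tnotext",
    "C3\tT1\tCCC\t9.1"))
  m2 <- read_activity_table(path2)
  expect_identical(m2$pki, c(7.2, 9.1))

  empty <- write_toy_table("compound_id\ttarget_id\tsmiles\tpki")
  expect_identical(nrow(read_activity_table(empty)), 0L)

  nocol <- write_toy_table(c("compound_id\tsmiles\tpki", "C1\tCCO\t7"))
  expect_error(read_activity_table(nocol), "required column")
  expect_error(read_activity_table(tempfile()), "not found")
})

test_that("Ki(nM) dialect converts to pKi", {
  path <- write_toy_table(c("compound_id\ttarget_id\tsmiles\tki",
                            "C1\tT1\tCCO\t1", "C2\tT1\tCCN\t1000"))
  m <- read_activity_table(path, table_dialect(pki = "ki",
                                               potency_unit = "ki_nM"))
  expect_equal(m$pki, c(9, 6))
})

test_that("potency aggregation averages replicates and applies the spread cap", {
  meas <- data.frame(
    compound_id = c("C1", "C1", "C2", "C2", "C3"),
    target_id = "T1",
    smiles = c("CCO", "CCO", "CCN", "CCN", "CCC"),
    pki = c(7.0, 7.4, 5.0, 6.5, 8.1), stringsAsFactors = FALSE)
  sets <- aggregate_potency(meas, max_spread = 1.0)
  act <- sets[["T1"]]$actives
  expect_setequal(act$compound_id, c("C1", "C3"))  # C2 spread 1.5 discarded
  expect_equal(act$pki[act$compound_id == "C1"], 7.2)
  expect_equal(act$pki[act$compound_id == "C3"], 8.1)
  expect_identical(attr(sets, "summary")$n_spread_discarded, 1L)
  # aggregated potency stays within the range of its readings
  expect_true(act$pki[act$compound_id == "C1"] >= 7.0 &&
                act$pki[act$compound_id == "C1"] <= 7.4)
  # empty input
  expect_length(aggregate_potency(meas[0, ]), 0L)
})

test_that("inactive reader enforces set membership invariants", {
  sets <- list(T1 = target_set("T1", actives = data.frame(
    compound_id = "C1", smiles = "CCO", pki = 7, stringsAsFactors = FALSE)))
  path <- write_toy_table(c(
    "compound_id\ttarget_id\tsmiles",
    "I1\tT1\tCCCN",
    "I2\tT1\tCCCO",
    "C1\tT1\tCCO",      # id clash with an active: rejected
    "I3\tT9\tCCC"))     # unknown target: ignored
  sets2 <- read_inactives(path, sets)
  expect_identical(nrow(sets2$T1$inactives), 2L)
  s <- attr(sets2, "summary")
  expect_identical(s$n_conflicts, 1L)
  expect_identical(s$n_unknown_target, 1L)
  expect_false(any(sets2$T1$inactives$compound_id %in%
                     sets2$T1$actives$compound_id))
})

test_that("target set construction rejects invariant violations", {
  act <- data.frame(compound_id = c("A", "B"), smiles = c("CC", "CCC"),
                    pki = c(7, 8), stringsAsFactors = FALSE)
  expect_error(target_set("T", actives = transform(act, pki = c(7, NA))),
               "finite")
  expect_error(target_set("T", actives = act,
                          inactives = data.frame(compound_id = "A",
                                                 smiles = "CCN")),
               "both active and inactive")
})

test_that("deposition write/read round-trips field for field", {
  entries <- list(
    list(target_id = "T1", target_name = "Synthetic target one",
         assay_ids = c("AID1", "AID2"), family = "MMP",
         set_threshold = 2.3456789012345, acrp_threshold = 8.25,
         cliffs = data.frame(
           cliff_type = c("sd", "isd"),
           compound_a = c("A1", "A1"), smiles_a = "Cc1ccccc1",
           pki_a = c(9.1, 9.1),
           compound_b = c("A2", "I1"), smiles_b = c("CCc1ccccc1",
                                                    "CCCc1ccccc1"),
           pki_b = c(5.2, NA), delta_pki = c(3.9, NA),
           core_smiles = "[*]c1ccccc1", sub_a_smiles = "[*]C",
           sub_b_smiles = c("[*]CC", "[*]CCC"), stringsAsFactors = FALSE)),
    list(target_id = "T2", target_name = "Synthetic target two",
         assay_ids = character(0), family = "RMMP",
         set_threshold = 1.75, acrp_threshold = NA_real_,
         cliffs = data.frame(
           cliff_type = character(0), compound_a = character(0),
           smiles_a = character(0), pki_a = numeric(0),
           compound_b = character(0), smiles_b = character(0),
           pki_b = numeric(0), delta_pki = numeric(0),
           core_smiles = character(0), sub_a_smiles = character(0),
           sub_b_smiles = character(0), stringsAsFactors = FALSE)))
  paths <- c(withr::local_tempfile(fileext = ".tsv"),
             withr::local_tempfile(fileext = ".tsv"))
  write_deposition(entries, paths)
  back <- read_deposition(paths)
  expect_length(back, 2L)
  expect_identical(back[[1L]]$target_id, "T1")
  expect_identical(back[[1L]]$assay_ids, c("AID1", "AID2"))
  expect_identical(back[[1L]]$family, "MMP")
  expect_equal(back[[1L]]$set_threshold, entries[[1L]]$set_threshold)
  expect_equal(back[[1L]]$cliffs, entries[[1L]]$cliffs,
               ignore_attr = TRUE)
  # isd record carries potency only for the active partner
  expect_true(is.na(back[[1L]]$cliffs$pki_b[2L]))
  expect_false(is.na(back[[1L]]$cliffs$pki_a[2L]))
  expect_identical(back[[2L]]$family, "RMMP")
  expect_identical(nrow(back[[2L]]$cliffs), 0L)
})

test_that("deposition reader reports malformed input with line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#FORMAT\tacmine-deposition\t1\tMMP",
               "#TARGET\tT1\tname\t\t8.0\t2.0\t2",
               "sd\tA1\tCC\t9\tA2\tCCC\t5\t4\t[*]C\t[*]C\t[*]CC"),
             path)
  expect_error(read_deposition(path), "truncated")
  writeLines(c("#FORMAT\tacmine-deposition\t1\tMMP",
               "#TARGET\tT1\tname\t\t8.0\t2.0\t1",
               "sd\tA1\tCC"), path)
  expect_error(read_deposition(path), "line 3")
  # empty file: no targets
  writeLines(character(0), path)
  expect_length(read_deposition(path), 0L)
})
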
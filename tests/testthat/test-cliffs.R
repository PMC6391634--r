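flat_set <- function(n, pki) {
  target_set("TF", actives = data.frame(
    compound_id = sprintf("C%03d", seq_len(n)),
    smiles = rep("CCO", n),  # structures irrelevant for qualification
    pki = pki, stringsAsFactors = FALSE))
}

test_that("qualification requires size and potency spread", {
  expect_false(qualify_target_set(flat_set(100, rep(7, 100))))  # flat
  set.seed(42)
  expect_true(qualify_target_set(flat_set(100, runif(100, 5, 9))))
  set.seed(42)
  expect_false(qualify_target_set(flat_set(10, runif(10, 5, 9))))
  # pluggable criterion overrides the default rule
  expect_true(qualify_target_set(flat_set(3, c(7, 7, 7)),
                                 criterion = function(s) TRUE))
})

test_that("set threshold is mean plus two sample standard deviations", {
  thr <- compute_set_threshold(c(1, 1, 1), "T", "MMP")
  expect_equal(thr$mean_delta, 1)
  expect_equal(thr$sigma_delta, 0)
  expect_equal(thr$threshold, 1)
  thr2 <- compute_set_threshold(c(0.5, 1.5))
  expect_equal(thr2$threshold, 1 + 2 * sd(c(0.5, 1.5)))
  expect_equal(thr2$threshold, 2.4142135623730951)
  # single pair: sigma defined as 0
  expect_equal(compute_set_threshold(0.7)$threshold, 0.7)
  expect_error(compute_set_threshold(numeric(0)), "empty")
  expect_error(compute_set_threshold(c(1, NA)), "finite")
})

make_delta_pairs <- function(deltas, base = 5) {
  n <- length(deltas)
  data.frame(
    compound_a = sprintf("P%03da", seq_len(n)),
    compound_b = sprintf("P%03db", seq_len(n)),
    core_smiles = "[*]c1ccccc1", sub_a_smiles = "[*]C",
    sub_b_smiles = "[*]CC", family = "MMP",
    core_heavy_atoms = 6L, sub_a_heavy_atoms = 1L, sub_b_heavy_atoms = 2L,
    pki_a = base + deltas, pki_b = base, delta_pki = deltas,
    stringsAsFactors = FALSE)
}

test_that("sd cliff calling uses the inclusive set threshold", {
  deltas <- c(rep(0.2, 20), 3.0)
  pairs <- make_delta_pairs(deltas)
  thr <- compute_set_threshold(pairs, "T", "MMP")
  # independent recomputation of the rule
  expect_equal(thr$threshold, mean(deltas) + 2 * sd(deltas))
  cl <- call_sd_cliffs(pairs, thr)
  expect_identical(cl$compound_a, if (3.0 >= thr$threshold) "P021a"
                   else character(0))
  expect_identical(nrow(cl), 1L)  # 3.0 >= 1.555... here
  expect_identical(cl$potent_partner, "P021a")

  # all deltas equal: threshold equals the common value, all pairs called
  pairs_eq <- make_delta_pairs(rep(1.2, 5))
  thr_eq <- compute_set_threshold(pairs_eq)
  expect_identical(nrow(call_sd_cliffs(pairs_eq, thr_eq)), 5L)

  # empty pair list
  expect_identical(nrow(call_sd_cliffs(pairs_eq[0, ], thr_eq)), 0L)
})

test_that("original cliffs use the inclusive 2 log-unit cutoff", {
  pairs <- make_delta_pairs(c(2.0, 1.99, 3.5))
  cl <- call_original_cliffs(pairs)
  expect_identical(nrow(cl), 2L)
  expect_setequal(cl$delta_pki, c(2.0, 3.5))
})

test_that("threshold monotonicity orders original and sd cliff sets", {
  pairs_lo <- make_delta_pairs(c(rep(0.3, 30), 2.2, 2.6))  # threshold < 2
  thr_lo <- compute_set_threshold(pairs_lo)
  expect_lt(thr_lo$threshold, 2)
  orig <- call_original_cliffs(pairs_lo)
  sdc <- call_sd_cliffs(pairs_lo, thr_lo)
  expect_true(all(pair_key(orig$compound_a, orig$compound_b) %in%
                    pair_key(sdc$compound_a, sdc$compound_b)))
})

test_that("ACRP selection takes the median of unique potent partners", {
  set <- flat_set(4, c(8.0, 9.0, 8.7, 4.0))
  # X forms two sd cliffs, Y one; Z (8.7) forms none but exceeds the median
  sd_cliffs <- data.frame(
    cliff_type = "sd", family = "MMP",
    compound_a = c("C001", "C001", "C002"),
    compound_b = c("C004", "C004", "C004"),
    potent_partner = c("C001", "C001", "C002"),
    other_partner = "C004", delta_pki = 4,
    pki_a = c(8, 8, 9), pki_b = 4,
    core_smiles = "[*]C", sub_a_smiles = "[*]C", sub_b_smiles = "[*]CC",
    stringsAsFactors = FALSE)
  acrp <- determine_acrp_compounds(sd_cliffs, set)
  expect_equal(acrp$acrp_threshold, 8.5)  # median of unique {8.0, 9.0}
  expect_setequal(acrp$acrp_compound_ids, c("C002", "C003"))  # 9.0 and 8.7
  # single potent partner: inclusive threshold
  acrp1 <- determine_acrp_compounds(sd_cliffs[3, ], flat_set(2, c(9.0, 9.0)))
  expect_equal(acrp1$acrp_threshold, 9.0)
  expect_setequal(acrp1$acrp_compound_ids, c("C001", "C002"))
  expect_error(determine_acrp_compounds(sd_cliffs[0, ], set), "no sd cliffs")
})

test_that("isd cliffs pair ACRP compounds with inactive analogs only", {
  set <- toy_series_set(rgroups = c("[*]C", "[*]CC", "[*]CCC"),
                        pki = c(9.5, 5.0, 9.0),
                        inactive_rgroups = c("[*]OC", "[*]F"))
  acrp <- structure(list(target_id = "TOY", family = "MMP",
                         acrp_threshold = 9.0,
                         acrp_compound_ids = c("A01", "A03"),
                         n_potent_partners = 2L),
                    class = "acrp_result")
  isd <- call_isd_cliffs(acrp, set, "MMP")
  # both ACRP actives form a tsr pair with both inactive analogs
  expect_identical(nrow(isd), 4L)
  expect_true(all(isd$potent_partner %in% c("A01", "A03")))
  expect_true(all(isd$other_partner %in% c("I01", "I02")))
  expect_true(all(is.na(isd$delta_pki)))
  # non-ACRP active A02 never appears
  expect_false(any(c(isd$compound_a, isd$compound_b) == "A02"))
  # no inactives: empty result
  set0 <- toy_series_set(rgroups = c("[*]C", "[*]CC"), pki = c(9, 5))
  expect_identical(nrow(call_isd_cliffs(acrp, set0, "MMP")), 0L)
})

test_that("RMMP cliffs are subsets of MMP cliffs under identical inputs", {
  # The subset relation holds when threshold and ACRP set are held fixed
  # (it follows from RMMP pairs being a subset of MMP pairs); per-family
  # thresholds can break it, which is why each family derives its own.
  b <- generate_target_set(generator_config(seed = 77L), "TSUB")
  set <- b$set
  cache <- fragmentation_cache()
  comp <- set$actives[, c("compound_id", "smiles")]
  mmp <- pair_potency_deltas(
    find_matched_pairs(comp, "MMP", cache = cache)[
      apply_tsr_filter(find_matched_pairs(comp, "MMP", cache = cache)), ],
    set$actives)
  rmmp <- pair_potency_deltas(
    find_matched_pairs(comp, "RMMP", cache = cache)[
      apply_tsr_filter(find_matched_pairs(comp, "RMMP", cache = cache)), ],
    set$actives)
  thr <- compute_set_threshold(mmp, "TSUB", "MMP")  # shared threshold
  sd_m <- call_sd_cliffs(mmp, thr)
  sd_r <- call_sd_cliffs(rmmp, thr)
  expect_true(all(pair_key(sd_r$compound_a, sd_r$compound_b) %in%
                    pair_key(sd_m$compound_a, sd_m$compound_b)))
  acrp <- determine_acrp_compounds(sd_m, set)  # shared ACRP set
  isd_m <- call_isd_cliffs(acrp, set, "MMP", cache = cache)
  isd_r <- call_isd_cliffs(acrp, set, "RMMP", cache = cache)
  expect_true(all(pair_key(isd_r$compound_a, isd_r$compound_b) %in%
                    pair_key(isd_m$compound_a, isd_m$compound_b)))
})

test_that("shifting all potencies changes no threshold or cliff set", {
  b <- generate_target_set(generator_config(seed = 23L), "TS")
  set <- b$set
  shifted <- set
  shifted$actives$pki <- shifted$actives$pki + 1.0
  run_one <- function(s) {
    pairs <- find_matched_pairs(s$actives[, c("compound_id", "smiles")])
    pairs <- pairs[apply_tsr_filter(pairs), ]
    pairs <- pair_potency_deltas(pairs, s$actives)
    thr <- compute_set_threshold(pairs, s$target_id, "MMP")
    cl <- call_sd_cliffs(pairs, thr)
    list(thr = thr$threshold, cliffs = sort(pair_key(cl$compound_a,
                                                     cl$compound_b)))
  }
  r1 <- run_one(set); r2 <- run_one(shifted)
  expect_equal(r1$thr, r2$thr, tolerance = 1e-12)
  expect_identical(r1$cliffs, r2$cliffs)
})

test_that("half-normal potency differences recover their moments at n = 1e4", {
  set.seed(99)
  x <- abs(rnorm(1e4, 0, 1))
  thr <- compute_set_threshold(x)
  expect_equal(thr$mean_delta, sqrt(2 / pi), tolerance = 0.05)
  expect_equal(thr$sigma_delta, sqrt(1 - 2 / pi), tolerance = 0.05)
})
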
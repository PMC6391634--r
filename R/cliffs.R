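# Activity-cliff calling with target set-dependent thresholds.
#
# Instead of the classical constant 2-log-unit cutoff, the potency-difference
# threshold is derived per target set as mean + 2*sigma of the |delta pKi|
# distribution over ALL transformation size-restricted pairs of the set, so
# only the statistically most significant potency differences qualify as
# cliffs (sd cliffs). Cliffs with confirmed inactive analogs (isd cliffs)
# have no potency difference; instead the active partner must reach the
# set's activity-cliff-relevant potency (ACRP) level, the median potency of
# the unique highly potent sd-cliff partners.

#' Qualify a target set for cliff analysis
#'
#' Proxy for the statistical qualification of intra-set potency variation:
#' a set qualifies when it has enough actives and a broad enough potency
#' distribution. Sets with narrow ('flat') distributions are excluded since
#' cliff definition is not meaningful there. Both parameters are
#' configurable and the whole criterion may be replaced via `criterion`.
#'
#' @param set A [target_set()].
#' @param min_compounds Minimum number of actives (default 50).
#' @param min_sigma Minimum standard deviation of the actives' pKi values
#'   (log units, default 1.0).
#' @param criterion Optional function(set) -> logical overriding the default
#'   rule.
#' @return `TRUE` or `FALSE`.
#' @export
qualify_target_set <- function(set, min_compounds = 50, min_sigma = 1.0,
                               criterion = NULL) {
  stopifnot(inherits(set, "target_set"))
  if (!is.null(criterion)) return(isTRUE(criterion(set)))
  n <- nrow(set$actives)
  if (n < min_compounds) return(FALSE)
  sig <- stats::sd(set$actives$pki)
  is.finite(sig) && sig >= min_sigma
}

#' Attach potency differences to matched pairs
#'
#' @param pairs Matched pairs from [find_matched_pairs()].
#' @param actives data.frame with `compound_id` and `pki` (e.g.
#'   `set$actives`); every pair partner must be present.
#' @return `pairs` with added columns `pki_a`, `pki_b`, `delta_pki`
#'   (absolute difference).
#' @export
pair_potency_deltas <- function(pairs, actives) {
  ia <- match(pairs$compound_a, actives$compound_id)
  ib <- match(pairs$compound_b, actives$compound_id)
  if (anyNA(ia) || anyNA(ib)) {
    stop("every pair partner must appear among the actives", call. = FALSE)
  }
  pairs$pki_a <- actives$pki[ia]
  pairs$pki_b <- actives$pki[ib]
  pairs$delta_pki <- abs(pairs$pki_a - pairs$pki_b)
  pairs
}

#' Compute the target set-dependent potency-difference threshold
#'
#' Threshold = mean + 2 * sigma of the absolute pKi differences of ALL
#' size-restricted pairs of the set (not only cliffs). Sigma is the sample
#' standard deviation (n-1 denominator; 0 for a single pair).
#'
#' @param pairs Pair data.frame with a `delta_pki` column (see
#'   [pair_potency_deltas()]), or a bare numeric vector of absolute
#'   differences.
#' @param target_id,family Identifiers recorded in the result.
#' @return A `set_threshold` object: `target_id`, `family`, `n_pairs`,
#'   `mean_delta`, `sigma_delta`, `threshold`.
#' @export
compute_set_threshold <- function(pairs, target_id = NA_character_,
                                  family = "MMP") {
  deltas <- if (is.numeric(pairs)) pairs else pairs$delta_pki
  if (length(deltas) == 0L) {
    stop("cannot derive a threshold from an empty pair set", call. = FALSE)
  }
  if (any(!is.finite(deltas) | deltas < 0)) {
    stop("potency differences must be finite and non-negative",
         call. = FALSE)
  }
  m <- mean(deltas)
  s <- if (length(deltas) == 1L) 0 else stats::sd(deltas)
  structure(list(target_id = target_id, family = family,
                 n_pairs = length(deltas), mean_delta = m, sigma_delta = s,
                 threshold = m + 2 * s),
            class = "set_threshold")
}

#' @export
print.set_threshold <- function(x, ...) {
  cat(sprintf(
    "<set_threshold> %s [%s]: %d pairs, mean |dpKi| %.3f, sigma %.3f, threshold %.3f\n",
    x$target_id, x$family, x$n_pairs, x$mean_delta, x$sigma_delta,
    x$threshold))
  invisible(x)
}

cliff_columns <- function(pairs, cliff_type, family) {
  potent_a <- pairs$pki_a >= pairs$pki_b
  data.frame(
    cliff_type = rep(cliff_type, nrow(pairs)),
    family = rep(family, nrow(pairs)),
    compound_a = pairs$compound_a, compound_b = pairs$compound_b,
    potent_partner = ifelse(potent_a, pairs$compound_a, pairs$compound_b),
    other_partner = ifelse(potent_a, pairs$compound_b, pairs$compound_a),
    delta_pki = pairs$delta_pki,
    pki_a = pairs$pki_a, pki_b = pairs$pki_b,
    core_smiles = pairs$core_smiles,
    sub_a_smiles = pairs$sub_a_smiles, sub_b_smiles = pairs$sub_b_smiles,
    stringsAsFactors = FALSE)
}

#' Call target set-dependent (sd) cliffs
#'
#' Every size-restricted pair whose absolute potency difference reaches the
#' set threshold (inclusive) becomes an sd cliff; sd cliffs are formed
#' exclusively by active compounds.
#'
#' @param pairs Pairs with `delta_pki` (see [pair_potency_deltas()]); the
#'   threshold must have been computed from these same pairs.
#' @param threshold A `set_threshold` object (or a single number).
#' @return Cliff data.frame (`cliff_type = "sd"`).
#' @export
call_sd_cliffs <- function(pairs, threshold) {
  thr <- if (inherits(threshold, "set_threshold")) threshold$threshold
         else threshold
  fam <- if (inherits(threshold, "set_threshold")) threshold$family
         else unique(pairs$family)
  hits <- pairs[pairs$delta_pki >= thr, , drop = FALSE]
  cliff_columns(hits, "sd", if (length(fam) == 1L) fam else "MMP")
}

#' Call original constant-threshold cliffs
#'
#' The first-generation definition: a size-restricted pair is a cliff when
#' its potency difference is at least two orders of magnitude (2 pKi units,
#' inclusive), regardless of the set's distribution.
#'
#' @param pairs Pairs with `delta_pki`.
#' @param cutoff Constant threshold in pKi units (default 2.0).
#' @return Cliff data.frame (`cliff_type = "original"`).
#' @export
call_original_cliffs <- function(pairs, cutoff = 2.0) {
  fam <- unique(pairs$family)
  hits <- pairs[pairs$delta_pki >= cutoff, , drop = FALSE]
  cliff_columns(hits, "original", if (length(fam) == 1L) fam else "MMP")
}

#' Determine compounds with activity-cliff-relevant potency (ACRP)
#'
#' The highly potent partner of each sd cliff is extracted; the median pKi
#' of the unique potent partners defines the ACRP threshold, and ALL set
#' actives with pKi greater than or equal to that median are classified as
#' ACRP compounds (not only cliff partners).
#'
#' @param sd_cliffs sd-cliff data.frame from [call_sd_cliffs()].
#' @param set The [target_set()] the cliffs were called in.
#' @param family MMP family the cliffs belong to.
#' @return An `acrp_result`: `target_id`, `family`, `acrp_threshold`,
#'   `acrp_compound_ids`, `n_potent_partners`.
#' @export
determine_acrp_compounds <- function(sd_cliffs, set, family = "MMP") {
  stopifnot(inherits(set, "target_set"))
  if (nrow(sd_cliffs) == 0L) {
    stop("no sd cliffs: the set defines no ACRP compounds (and hence no isd cliffs)",
         call. = FALSE)
  }
  potent_ids <- unique(sd_cliffs$potent_partner)
  pk <- set$actives$pki[match(potent_ids, set$actives$compound_id)]
  if (anyNA(pk)) {
    stop("sd-cliff potent partners must belong to the set's actives",
         call. = FALSE)
  }
  med <- stats::median(pk)
  acrp_ids <- set$actives$compound_id[set$actives$pki >= med]
  structure(list(target_id = set$target_id, family = family,
                 acrp_threshold = med, acrp_compound_ids = acrp_ids,
                 n_potent_partners = length(potent_ids)),
            class = "acrp_result")
}

#' @export
print.acrp_result <- function(x, ...) {
  cat(sprintf(
    "<acrp_result> %s [%s]: threshold pKi %.3f (median of %d potent partners), %d ACRP compounds\n",
    x$target_id, x$family, x$acrp_threshold, x$n_potent_partners,
    length(x$acrp_compound_ids)))
  invisible(x)
}

#' Call inactive-analog (isd) cliffs
#'
#' A systematic matched-pair search over the set's ACRP compounds and its
#' confirmed inactives: every size-restricted active/inactive pair whose
#' active partner is an ACRP compound is an isd cliff. Active/active and
#' inactive/inactive pairs are discarded; no potency difference is recorded.
#'
#' @param acrp An `acrp_result` from [determine_acrp_compounds()].
#' @param set The [target_set()] (its `inactives` may be empty).
#' @param family `"MMP"` or `"RMMP"`; applied consistently with the sd stage.
#' @param rules Retrosynthetic rules (RMMP family).
#' @param cache Optional [fragmentation_cache()] shared with the sd stage.
#' @param tsr Named list overriding tsr parameters, see [apply_tsr_filter()].
#' @return Cliff data.frame (`cliff_type = "isd"`, `delta_pki = NA`).
#' @export
call_isd_cliffs <- function(acrp, set, family = c("MMP", "RMMP"),
                            rules = NULL, cache = NULL, tsr = list()) {
  family <- match.arg(family)
  stopifnot(inherits(acrp, "acrp_result"), inherits(set, "target_set"))
  empty <- cliff_columns(
    data.frame(compound_a = character(0), compound_b = character(0),
               pki_a = numeric(0), pki_b = numeric(0),
               delta_pki = numeric(0), core_smiles = character(0),
               sub_a_smiles = character(0), sub_b_smiles = character(0),
               stringsAsFactors = FALSE), "isd", family)
  if (nrow(set$inactives) == 0L ||
      length(acrp$acrp_compound_ids) == 0L) return(empty)

  acrp_actives <- set$actives[set$actives$compound_id %in%
                                acrp$acrp_compound_ids, , drop = FALSE]
  pool <- rbind(
    data.frame(compound_id = acrp_actives$compound_id,
               smiles = acrp_actives$smiles, stringsAsFactors = FALSE),
    data.frame(compound_id = set$inactives$compound_id,
               smiles = set$inactives$smiles, stringsAsFactors = FALSE))
  pairs <- find_matched_pairs(pool, family = family, rules = rules,
                              cache = cache)
  pairs <- pairs[do.call(apply_tsr_filter, c(list(pairs), tsr)), ,
                 drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)

  a_active <- pairs$compound_a %in% acrp_actives$compound_id
  b_active <- pairs$compound_b %in% acrp_actives$compound_id
  keep <- xor(a_active, b_active)
  pairs <- pairs[keep, , drop = FALSE]
  a_active <- a_active[keep]
  if (nrow(pairs) == 0L) return(empty)

  act_id <- ifelse(a_active, pairs$compound_a, pairs$compound_b)
  inact_id <- ifelse(a_active, pairs$compound_b, pairs$compound_a)
  data.frame(
    cliff_type = "isd", family = family,
    compound_a = pairs$compound_a, compound_b = pairs$compound_b,
    potent_partner = act_id, other_partner = inact_id,
    delta_pki = NA_real_,
    pki_a = set$actives$pki[match(pairs$compound_a,
                                  set$actives$compound_id)],
    pki_b = set$actives$pki[match(pairs$compound_b,
                                  set$actives$compound_id)],
    core_smiles = pairs$core_smiles,
    sub_a_smiles = pairs$sub_a_smiles, sub_b_smiles = pairs$sub_b_smiles,
    stringsAsFactors = FALSE)
}
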
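# End-to-end cliff identification pipeline.
#
# Protocol per MMP family: (1) sets with inactives are noted for the
# inactive-analog stage, (2) sd cliffs are called for every qualifying set
# (with enough size-restricted pairs), (3) ACRP compounds are derived from
# the sd cliffs, (4) a systematic matched-pair search between ACRP compounds
# and inactives yields isd cliffs, (5) sets yielding isd cliffs are
# reported. sd cliffs are computed for ALL qualifying sets; the availability
# of inactives gates only the isd stage.

#' Pipeline run configuration
#'
#' Defaults reproduce the published constants: qualification at >= 50
#' actives with potency sd >= 1 log unit, cliff eligibility at >= 100
#' size-restricted pairs, tsr parameters (2x core, diff <= 8, substituent
#' <= 13), original-cliff cutoff 2 pKi units.
#'
#' @param families MMP families to run (`"MMP"`, `"RMMP"` or both).
#' @param min_compounds,min_sigma Qualification parameters
#'   ([qualify_target_set()]).
#' @param min_pairs Minimum size-restricted pairs for cliff eligibility.
#' @param tsr Named list of tsr parameters ([apply_tsr_filter()]).
#' @param rules_path Retrosynthetic rule file (default: packaged rules).
#' @param original_cutoff Constant threshold of the first-generation cliff
#'   definition.
#' @param out_dir Output directory; `NULL` disables file output.
#' @param seed Recorded in the run summary for provenance.
#' @return A `run_config` object.
#' @export
run_config <- function(families = c("MMP", "RMMP"), min_compounds = 50,
                       min_sigma = 1.0, min_pairs = 100,
                       tsr = list(core_min_ratio = 2, max_size_diff = 8,
                                  max_sub_size = 13),
                       rules_path = NULL, original_cutoff = 2.0,
                       out_dir = NULL, seed = NA_integer_) {
  families <- match.arg(families, c("MMP", "RMMP"), several.ok = TRUE)
  structure(list(families = families, min_compounds = min_compounds,
                 min_sigma = min_sigma, min_pairs = min_pairs, tsr = tsr,
                 rules_path = rules_path, original_cutoff = original_cutoff,
                 out_dir = out_dir, seed = seed),
            class = "run_config")
}

as_target_sets <- function(sets) {
  sets <- lapply(sets, function(s) {
    if (inherits(s, "synthetic_target_set")) s$set else s
  })
  stopifnot(all(vapply(sets, inherits, logical(1), "target_set")))
  names(sets) <- vapply(sets, `[[`, character(1), "target_id")
  sets
}

#' Run the cliff identification pipeline
#'
#' @param sets Named list of [target_set()] objects (or
#'   `synthetic_target_set` bundles, whose `$set` is used).
#' @param cfg A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return An `ac_run`: `$summary` (one row per family, mirroring the
#'   filter-cascade layout: total sets, qualifying, meeting the pair cutoff,
#'   with inactives, with isd cliffs, plus compound and cliff counts),
#'   `$results[[family]][[target_id]]` with pairs, threshold, cliffs, ACRP,
#'   networks and comparison, and `$cliff_sets` (deposition entries).
#' @export
run_pipeline <- function(sets, cfg = run_config(), quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  sets <- as_target_sets(sets)
  rules <- if (any(cfg$families == "RMMP")) {
    if (is.null(cfg$rules_path)) read_fragmentation_rules()
    else read_fragmentation_rules(cfg$rules_path)
  } else NULL
  cache <- fragmentation_cache()
  say <- function(...) if (!quiet) message(sprintf(...))

  results <- list()
  summary_rows <- list()
  cliff_sets <- list()

  for (fam in cfg$families) {
    fam_res <- list()
    n_qual <- 0L; n_pairs_ok <- 0L; n_with_inact <- 0L; n_with_isd <- 0L
    acrp_ids <- character(0); inact_ids <- character(0)
    n_sd <- 0L; n_isd <- 0L

    for (tid in names(sets)) {
      set <- sets[[tid]]
      res <- list(target_id = tid, qualified = FALSE, eligible = FALSE)
      qual <- qualify_target_set(set, cfg$min_compounds, cfg$min_sigma)
      res$qualified <- qual
      if (qual) {
        n_qual <- n_qual + 1L
        pairs <- find_matched_pairs(
          set$actives[, c("compound_id", "smiles")], family = fam,
          rules = rules, cache = cache)
        pairs <- pairs[do.call(apply_tsr_filter, c(list(pairs), cfg$tsr)), ,
                       drop = FALSE]
        res$n_tsr_pairs <- nrow(pairs)
        say("[%s] %s: %d tsr pairs", fam, tid, nrow(pairs))
        if (nrow(pairs) >= cfg$min_pairs) {
          n_pairs_ok <- n_pairs_ok + 1L
          res$eligible <- TRUE
          pairs <- pair_potency_deltas(pairs, set$actives)
          res$pairs <- pairs
          thr <- compute_set_threshold(pairs, tid, fam)
          res$threshold <- thr
          res$sd_cliffs <- call_sd_cliffs(pairs, thr)
          res$original_cliffs <- call_original_cliffs(pairs,
                                                      cfg$original_cutoff)
          n_sd <- n_sd + nrow(res$sd_cliffs)
          if (nrow(set$inactives) > 0L) n_with_inact <- n_with_inact + 1L
          if (nrow(res$sd_cliffs) > 0L) {
            res$acrp <- determine_acrp_compounds(res$sd_cliffs, set, fam)
            acrp_ids <- c(acrp_ids, paste0(tid, "::",
                                           res$acrp$acrp_compound_ids))
            if (nrow(set$inactives) > 0L) {
              res$isd_cliffs <- call_isd_cliffs(res$acrp, set, fam,
                                                rules = rules, cache = cache,
                                                tsr = cfg$tsr)
              n_isd <- n_isd + nrow(res$isd_cliffs)
              if (nrow(res$isd_cliffs) > 0L) {
                n_with_isd <- n_with_isd + 1L
                inact_ids <- c(inact_ids,
                               paste0(tid, "::",
                                      unique(res$isd_cliffs$other_partner)))
              }
            }
          }
          if (is.null(res$isd_cliffs)) {
            res$isd_cliffs <- call_sd_cliffs(pairs[0, , drop = FALSE], thr)
          }
          res$sd_network <- build_network(res$sd_cliffs, set, res$acrp)
          combined <- rbind(res$sd_cliffs, res$isd_cliffs)
          res$combined_network <- build_network(combined, set, res$acrp)
          res$comparison <- compare_networks(res$sd_network,
                                             res$combined_network)
          cliff_sets[[length(cliff_sets) + 1L]] <- list(
            target_id = tid, target_name = set$target_name,
            assay_ids = character(0), family = fam,
            set_threshold = thr$threshold,
            acrp_threshold = if (!is.null(res$acrp))
              res$acrp$acrp_threshold else NA_real_,
            cliffs = deposition_records(res, set))
        }
      }
      fam_res[[tid]] <- res
    }
    results[[fam]] <- fam_res
    summary_rows[[fam]] <- data.frame(
      family = fam, n_sets_total = length(sets),
      n_sets_qualifying = n_qual, n_sets_min_pairs = n_pairs_ok,
      n_sets_with_inactives = n_with_inact, n_sets_with_isd = n_with_isd,
      n_acrp_compounds = length(unique(acrp_ids)),
      n_inactive_cliff_compounds = length(unique(inact_ids)),
      n_sd_cliffs = n_sd, n_isd_cliffs = n_isd, stringsAsFactors = FALSE)
  }

  run <- structure(list(summary = do.call(rbind, summary_rows),
                        results = results, cliff_sets = cliff_sets,
                        config = cfg),
                   class = "ac_run")
  rownames(run$summary) <- NULL
  if (!is.null(cfg$out_dir)) write_run_outputs(run, sets, cfg)
  run
}

# Deposition records: active (potent) partner first; inactive partners carry
# no potency.
deposition_records <- function(res, set) {
  recs <- empty_cliff_records()
  for (df in list(res$sd_cliffs, res$isd_cliffs)) {
    if (is.null(df) || nrow(df) == 0L) next
    pk <- function(ids) set$actives$pki[match(ids, set$actives$compound_id)]
    smi <- function(ids) {
      out <- set$actives$smiles[match(ids, set$actives$compound_id)]
      miss <- is.na(out)
      out[miss] <- set$inactives$smiles[match(ids[miss],
                                              set$inactives$compound_id)]
      out
    }
    recs <- rbind(recs, data.frame(
      cliff_type = df$cliff_type,
      compound_a = df$potent_partner, smiles_a = smi(df$potent_partner),
      pki_a = pk(df$potent_partner),
      compound_b = df$other_partner, smiles_b = smi(df$other_partner),
      pki_b = pk(df$other_partner), delta_pki = df$delta_pki,
      core_smiles = df$core_smiles, sub_a_smiles = df$sub_a_smiles,
      sub_b_smiles = df$sub_b_smiles, stringsAsFactors = FALSE))
  }
  rownames(recs) <- NULL
  recs
}

#' @export
print.ac_run <- function(x, ...) {
  cat("<ac_run>\n")
  print(x$summary)
  invisible(x)
}

write_run_outputs <- function(run, sets, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_stable(run$summary, file.path(cfg$out_dir, "summary.tsv"))

  all_cliffs <- list()
  comp_rows <- list()
  net_dir <- file.path(cfg$out_dir, "networks")
  dir.create(net_dir, recursive = TRUE, showWarnings = FALSE)
  for (fam in names(run$results)) {
    for (tid in names(run$results[[fam]])) {
      res <- run$results[[fam]][[tid]]
      if (!isTRUE(res$eligible)) next
      for (df in list(res$sd_cliffs, res$original_cliffs, res$isd_cliffs)) {
        if (is.null(df) || nrow(df) == 0L) next
        df$target_id <- tid
        all_cliffs[[length(all_cliffs) + 1L]] <- df
      }
      prefix <- file.path(net_dir, sprintf("%s_%s", tid, fam))
      export_graph(res$sd_network, paste0(prefix, "_sd"))
      export_graph(res$combined_network, paste0(prefix, "_combined"))
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        target_id = tid, family = fam,
        n_new_clusters = res$comparison$n_new_clusters,
        n_extended_clusters = res$comparison$n_extended_clusters,
        n_merged_clusters = res$comparison$n_merged_clusters,
        n_unchanged_components = res$comparison$n_unchanged_components,
        n_new_isolated_pairs = res$comparison$n_new_isolated_pairs,
        stringsAsFactors = FALSE)
    }
  }
  cliffs_df <- if (length(all_cliffs) > 0L) {
    do.call(rbind, all_cliffs)
  } else {
    data.frame(cliff_type = character(0), family = character(0),
               compound_a = character(0), compound_b = character(0),
               potent_partner = character(0), other_partner = character(0),
               delta_pki = numeric(0), pki_a = numeric(0), pki_b = numeric(0),
               core_smiles = character(0), sub_a_smiles = character(0),
               sub_b_smiles = character(0), target_id = character(0),
               stringsAsFactors = FALSE)
  }
  write_tsv_stable(cliffs_df, file.path(cfg$out_dir, "cliffs.tsv"))
  comp_df <- if (length(comp_rows) > 0L) do.call(rbind, comp_rows) else
    data.frame(target_id = character(0), family = character(0),
               n_new_clusters = integer(0), n_extended_clusters = integer(0),
               n_merged_clusters = integer(0),
               n_unchanged_components = integer(0),
               n_new_isolated_pairs = integer(0), stringsAsFactors = FALSE)
  write_tsv_stable(comp_df, file.path(cfg$out_dir,
                                      "network_comparison.tsv"))
  write_deposition(run$cliff_sets,
                   file.path(cfg$out_dir,
                             c("deposition_mmp.tsv", "deposition_rmmp.tsv")))
  invisible(cfg$out_dir)
}
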
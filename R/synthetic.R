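# Synthetic target sets of analog series.
#
# Each series is one scaffold (core) substituted with distinct R-groups at a
# single fixed attachment site, so every within-series compound pair forms a
# size-restricted MMP by construction. Potencies follow a hierarchical
# Gaussian model (between-series spread around the set mean, within-series
# spread around the series mean) clamped to the plausible bioactivity range
# [3, 12] pKi: potency differences relevant to cliff thresholds arise within
# series, while the between-series spread keeps set-level potency variance
# high enough for qualification, as in curated activity classes. Planted
# cliff pairs with an exact potency gap and inactive analogs provide ground
# truth for every pipeline stage. A configurable fraction of structurally
# unrelated ("diverse") inactives mimics screening decks, which rarely form
# MMPs with the actives.

#' Join a scaffold and an R-group at their attachment points
#'
#' Both SMILES must contain exactly one `[*]` dummy with one neighbor; the
#' dummies are removed and the neighbors joined by a single bond.
#'
#' @param core_smiles,rgroup_smiles Fragment SMILES with one `[*]` each.
#' @return Canonical SMILES of the assembled molecule.
#' @export
attach_rgroup <- function(core_smiles, rgroup_smiles) {
  mc <- parse_smiles(core_smiles)
  mr <- parse_smiles(rgroup_smiles)
  join_at <- function(m, what) {
    d <- which(m$elem == "*")
    if (length(d) != 1L) {
      stop(sprintf("%s must contain exactly one [*] attachment point", what),
           call. = FALSE)
    }
    kb <- which(m$ba == d | m$bb == d)
    if (length(kb) != 1L) {
      stop(sprintf("attachment point of %s must have exactly one neighbor",
                   what), call. = FALSE)
    }
    list(dummy = d, nbr = if (m$ba[kb] == d) m$bb[kb] else m$ba[kb])
  }
  jc <- join_at(mc, "core")
  jr <- join_at(mr, "rgroup")
  keep_c <- setdiff(seq_len(mc$n_atoms), jc$dummy)
  keep_r <- setdiff(seq_len(mr$n_atoms), jr$dummy)
  map_c <- integer(mc$n_atoms); map_c[keep_c] <- seq_along(keep_c)
  map_r <- integer(mr$n_atoms)
  map_r[keep_r] <- length(keep_c) + seq_along(keep_r)
  bc <- map_c[mc$ba] > 0L & map_c[mc$bb] > 0L
  br <- map_r[mr$ba] > 0L & map_r[mr$bb] > 0L
  merged <- new_mol(
    c(mc$elem[keep_c], mr$elem[keep_r]),
    c(mc$arom[keep_c], mr$arom[keep_r]),
    c(mc$charge[keep_c], mr$charge[keep_r]),
    c(mc$hcount[keep_c], mr$hcount[keep_r]),
    c(map_c[mc$ba[bc]], map_r[mr$ba[br]], map_c[jc$nbr]),
    c(map_c[mc$bb[bc]], map_r[mr$bb[br]], map_r[jr$nbr]),
    c(mc$order[bc], mr$order[br], 1L))
  canon_smiles(merged)
}

#' Default scaffold library for the generator
#'
#' Drug-like cores (10-16 heavy atoms) with a single `[*]` attachment point.
#' About half attach through nitrogen or oxygen so that series built on them
#' form retrosynthetic MMPs under the default rule set.
#'
#' @return Character vector of scaffold SMILES.
#' @export
default_core_library <- function() {
  # Each scaffold carries a unique principal ring system: no core contains
  # another core's large scaffold as a fragment, so fragments shared across
  # series are small and the resulting cross-series pairs fail the tsr
  # filter. Otherwise between-series potency differences would leak into
  # the set's pair-delta distribution and inflate its cliff threshold.
  c("[*]c1ccc(-c2ccccc2)cc1",            # biphenyl
    "[*]c1ccc2ncccc2c1",                 # quinoline
    "[*]C1CCN(Cc2ccccc2)CC1",            # benzylpiperidine
    "[*]c1ccc(S(=O)(=O)NC)cc1",          # benzenesulfonamide
    "[*]Nc1ccc2ccccc2c1",                # aminonaphthalene (N-attached)
    "[*]NC(=O)c1cc2ccccc2[nH]1",         # indole-2-carboxamide (N-attached)
    "[*]Oc1ccc(-c2ccncc2)cc1",           # pyridylphenol ether (O-attached)
    "[*]N1CCN(c2ccc(F)cc2)CC1",          # fluorophenylpiperazine (N-attached)
    "[*]c1nc2ccccc2s1",                  # benzothiazole
    "[*]Nc1nc2ccccc2[nH]1",              # aminobenzimidazole (N-attached)
    "[*]C(=O)N1CCC(c2ccccc2)CC1",        # phenylpiperidine amide
    "[*]Oc1ccc(Cn2ccnc2)cc1")            # imidazolylmethyl phenol ether
}

#' Default R-group library for the generator
#'
#' Substituents of 1-6 heavy atoms, within the transformation-size limits by
#' construction.
#'
#' @return Character vector of R-group SMILES with one `[*]` each.
#' @export
default_rgroup_library <- function() {
  c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C", "[*]CCCC", "[*]C(C)(C)C",
    "[*]CC(C)C", "[*]C1CC1", "[*]C1CCC1", "[*]CC=C",
    "[*]F", "[*]Cl", "[*]Br", "[*]I", "[*]C(F)(F)F", "[*]CCl",
    "[*]O", "[*]OC", "[*]OCC", "[*]CO", "[*]CCO", "[*]COC",
    "[*]N", "[*]NC", "[*]N(C)C", "[*]CN", "[*]CCN", "[*]C#N", "[*]CC#N",
    "[*]C(=O)C", "[*]C(=O)OC", "[*]C(=O)N", "[*]C(=O)NC",
    "[*]S", "[*]SC", "[*]S(=O)(=O)C")
}

# Unrelated screening-like molecules used as "diverse" inactives.
diverse_inactive_library <- function() {
  c("CCOC(=O)C1CCCN1C", "CC(C)NCC(O)COc1ccccc1", "OCC1OC(O)C(O)C(O)C1O",
    "CCN(CC)CCNC(=O)c1ccc(N)cc1", "CN1CCCC1CCO", "CC(O)CN1CCOCC1",
    "NCCc1c[nH]cn1", "CC(N)Cc1ccc(O)cc1", "OC(CCN1CCCCC1)c1ccccc1",
    "CCCCN(CCCC)CC(O)=O")
}

#' Configuration for the synthetic target-set generator
#'
#' @param n_series Number of analog series per set (default 8).
#' @param series_size Compounds per series (default 10).
#' @param core_library,rgroup_library Scaffold and substituent SMILES; all
#'   R-groups must stay within the tsr substituent limit (13 heavy atoms).
#' @param potency_mean Set-level mean pKi (default 7).
#' @param potency_sigma Within-series pKi standard deviation (log units,
#'   default 0.5); drives the set threshold (roughly 2.8 * sigma for
#'   Gaussian potencies, i.e. ~1.4 at the default, inside the 0.9-2.7 range
#'   observed for curated sets).
#' @param series_sigma Between-series standard deviation of series mean pKi
#'   (default 1.2), keeping set-level potency variance above the
#'   qualification cutoff.
#' @param planted_cliff_fraction Fraction of within-series pairs planted as
#'   cliffs with an exact gap (default 0.01); planted pairs are disjoint.
#'   Planted compounds also pair with ordinary series members, so a large
#'   fraction would inflate the set threshold past the planted gap; at the
#'   default about 4 pairs are planted per set and the expected threshold
#'   stays near 2.5 log units.
#' @param planted_delta pKi gap of planted cliff pairs (default 3.5, safely
#'   above the expected set threshold at the default sigmas).
#' @param inactive_fraction Fraction of analogs emitted as confirmed
#'   inactives (default 0.15); at least one active per series is guaranteed
#'   and planted cliff members stay active.
#' @param diverse_inactive_fraction Additional structurally unrelated
#'   inactives, as a fraction of the structural inactives (default 0.2).
#' @param seed RNG seed; identical config + seed gives identical output.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_series = 8L, series_size = 10L,
                             core_library = default_core_library(),
                             rgroup_library = default_rgroup_library(),
                             potency_mean = 7.0, potency_sigma = 0.5,
                             series_sigma = 1.2,
                             planted_cliff_fraction = 0.01,
                             planted_delta = 3.5,
                             inactive_fraction = 0.15,
                             diverse_inactive_fraction = 0.2,
                             seed = 1L) {
  stopifnot(n_series >= 1L, series_size >= 2L,
            length(core_library) >= 1L,
            length(rgroup_library) >= series_size,
            potency_sigma >= 0, series_sigma >= 0,
            planted_cliff_fraction >= 0, planted_cliff_fraction <= 1,
            planted_delta >= 0,
            inactive_fraction >= 0, inactive_fraction <= 1,
            diverse_inactive_fraction >= 0)
  rg_sizes <- vapply(rgroup_library, heavy_atom_count, integer(1))
  if (any(rg_sizes > 13L)) {
    stop("all R-groups must have at most 13 heavy atoms", call. = FALSE)
  }
  structure(list(n_series = as.integer(n_series),
                 series_size = as.integer(series_size),
                 core_library = core_library,
                 rgroup_library = rgroup_library,
                 potency_mean = potency_mean, potency_sigma = potency_sigma,
                 series_sigma = series_sigma,
                 planted_cliff_fraction = planted_cliff_fraction,
                 planted_delta = planted_delta,
                 inactive_fraction = inactive_fraction,
                 diverse_inactive_fraction = diverse_inactive_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

clamp_pki <- function(x) pmin(pmax(x, 3), 12)

with_local_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate one synthetic target set with ground truth
#'
#' @param cfg A [generator_config()].
#' @param target_id,target_name Identifiers of the emitted set.
#' @return A `synthetic_target_set`: `$set` (a [target_set()]), `$truth`
#'   (planted cliff pairs, within-series active/inactive analog pairs and
#'   the per-compound series table) and `$config`.
#' @export
generate_target_set <- function(cfg = generator_config(),
                                target_id = "T001",
                                target_name = paste("Synthetic target",
                                                    target_id)) {
  stopifnot(inherits(cfg, "generator_config"))
  with_local_seed(cfg$seed, {
    core_sizes <- vapply(cfg$core_library, heavy_atom_count, integer(1))
    rg_sizes <- vapply(cfg$rgroup_library, heavy_atom_count, integer(1))

    # balanced scaffold assignment: reuse cores as evenly as possible so no
    # core exhausts its size-eligible R-group pool
    cores <- if (cfg$n_series <= length(cfg$core_library)) {
      sample(cfg$core_library, cfg$n_series)
    } else {
      reps <- rep(sample(cfg$core_library),
                  length.out = cfg$n_series)
      sample(reps)
    }
    series_mu <- stats::rnorm(cfg$n_series, cfg$potency_mean,
                              cfg$series_sigma)

    comp <- list()
    used_rg <- list()  # per core: R-groups already used (unique structures)
    for (s in seq_len(cfg$n_series)) {
      core <- cores[s]
      # keep within-series transformations size-restricted by construction
      ok <- which(rg_sizes <= core_sizes[match(core, cfg$core_library)] / 2)
      avail <- setdiff(cfg$rgroup_library[ok], used_rg[[core]])
      if (length(avail) < cfg$series_size) {
        stop("core/R-group libraries too small for ", cfg$n_series,
             " series of ", cfg$series_size, " unique compounds",
             call. = FALSE)
      }
      rgs <- sample(avail, cfg$series_size)
      used_rg[[core]] <- c(used_rg[[core]], rgs)
      smi <- vapply(rgs, function(r) attach_rgroup(core, r), character(1),
                    USE.NAMES = FALSE)
      pki <- clamp_pki(stats::rnorm(cfg$series_size, series_mu[s],
                                    cfg$potency_sigma))
      comp[[s]] <- data.frame(
        compound_id = sprintf("%s-S%02d-C%02d", target_id, s,
                              seq_len(cfg$series_size)),
        series = s, core = core, rgroup = rgs, smiles = smi, pki = pki,
        stringsAsFactors = FALSE)
    }
    comp <- do.call(rbind, comp)
    rownames(comp) <- NULL

    # plant cliff pairs: disjoint within-series pairs with an exact gap
    n_within <- cfg$n_series * choose(cfg$series_size, 2)
    n_plant <- round(cfg$planted_cliff_fraction * n_within)
    planted <- data.frame(compound_a = character(0),
                          compound_b = character(0),
                          series = integer(0), delta_pki = numeric(0),
                          stringsAsFactors = FALSE)
    used <- character(0)
    if (n_plant > 0L) {
      half <- cfg$planted_delta / 2
      for (p in seq_len(n_plant)) {
        s <- sample.int(cfg$n_series, 1L)
        avail <- comp$compound_id[comp$series == s &
                                    !comp$compound_id %in% used]
        if (length(avail) < 2L) next
        pick <- sample(avail, 2L)
        center <- min(max(series_mu[s], 3 + half), 12 - half)
        comp$pki[comp$compound_id == pick[1L]] <- center - half
        comp$pki[comp$compound_id == pick[2L]] <- center + half
        used <- c(used, pick)
        planted <- rbind(planted, data.frame(
          compound_a = min(pick), compound_b = max(pick), series = s,
          delta_pki = cfg$planted_delta, stringsAsFactors = FALSE))
      }
    }

    # mark inactives (never planted compounds; >=1 active per series)
    comp$status <- "active"
    if (cfg$inactive_fraction > 0) {
      for (s in seq_len(cfg$n_series)) {
        idx <- which(comp$series == s & !comp$compound_id %in% used)
        if (length(idx) <= 1L) next
        n_in <- min(stats::rbinom(1L, length(idx), cfg$inactive_fraction),
                    length(idx) - 1L)
        n_active_series <- sum(comp$series == s) - n_in
        if (n_active_series < 1L) n_in <- sum(comp$series == s) - 1L
        if (n_in > 0L) {
          comp$status[sample(idx, n_in)] <- "inactive"
        }
      }
    }

    actives <- comp[comp$status == "active", , drop = FALSE]
    inactives <- comp[comp$status == "inactive", , drop = FALSE]

    # structurally unrelated inactives from the diverse library
    n_div <- round(cfg$diverse_inactive_fraction * nrow(inactives))
    if (n_div > 0L) {
      lib <- diverse_inactive_library()
      pickd <- sample(lib, n_div, replace = n_div > length(lib))
      inactives <- rbind(inactives, data.frame(
        compound_id = sprintf("%s-DIV-%02d", target_id, seq_len(n_div)),
        series = NA_integer_, core = NA_character_, rgroup = NA_character_,
        smiles = vapply(pickd, canon_smiles, character(1),
                        USE.NAMES = FALSE),
        pki = NA_real_, status = "inactive", stringsAsFactors = FALSE))
    }

    set <- target_set(
      target_id, target_name,
      actives = data.frame(compound_id = actives$compound_id,
                           smiles = actives$smiles, pki = actives$pki,
                           source = "synthetic", stringsAsFactors = FALSE),
      inactives = if (nrow(inactives) > 0L)
        data.frame(compound_id = inactives$compound_id,
                   smiles = inactives$smiles, source = "synthetic",
                   stringsAsFactors = FALSE) else NULL)

    # ground-truth active/inactive analog pairs (same series => tsrMMP)
    ia_pairs <- do.call(rbind, lapply(seq_len(cfg$n_series), function(s) {
      act <- actives$compound_id[actives$series == s]
      inact <- inactives$compound_id[!is.na(inactives$series) &
                                       inactives$series == s]
      if (length(act) == 0L || length(inact) == 0L) return(NULL)
      expand.grid(active_id = act, inactive_id = inact, series = s,
                  stringsAsFactors = FALSE)
    }))
    if (is.null(ia_pairs)) {
      ia_pairs <- data.frame(active_id = character(0),
                             inactive_id = character(0), series = integer(0),
                             stringsAsFactors = FALSE)
    }

    truth <- list(planted_cliffs = planted, inactive_analogs = ia_pairs,
                  compounds = comp[, c("compound_id", "series", "core",
                                       "rgroup", "smiles", "pki", "status")])
    structure(list(set = set, truth = truth, config = cfg),
              class = "synthetic_target_set")
  })
}

#' Generate a deterministic panel of synthetic target sets
#'
#' The panel spans the conditions the pipeline must separate: a flat
#' (zero-variance) set that fails qualification, a set too small for the
#' pair-count cutoff, a set without inactives, and default-condition sets
#' with inactives. Identical `seed` reproduces the panel exactly.
#'
#' @param n_sets Number of sets (default 10, minimum 4).
#' @param seed Panel seed.
#' @param base Optional list of [generator_config()] overrides applied to
#'   every set (e.g. `list(series_size = 6)`).
#' @return List of `synthetic_target_set` bundles, named by target id.
#' @export
generate_benchmark_suite <- function(n_sets = 10L, seed = 1L, base = list()) {
  stopifnot(n_sets >= 4L)
  set_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max, n_sets))
  make_cfg <- function(overrides, s) {
    args <- utils::modifyList(base, overrides)
    args$seed <- set_seeds[s]
    do.call(generator_config, args)
  }
  suite <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    overrides <- if (s == 1L) {
      # flat potency distribution: rejected by qualification
      list(potency_sigma = 0, series_sigma = 0, planted_cliff_fraction = 0)
    } else if (s == 2L) {
      # too small: fails compound- and pair-count cutoffs
      list(n_series = 3L, series_size = 4L)
    } else if (s == 3L) {
      # no inactives: sd stage only
      list(inactive_fraction = 0, diverse_inactive_fraction = 0)
    } else {
      list(potency_mean = 6.5 + 0.25 * (s %% 4),
           inactive_fraction = 0.1 + 0.02 * (s %% 3))
    }
    tid <- sprintf("T%03d", s)
    suite[[s]] <- generate_target_set(make_cfg(overrides, s), target_id = tid)
  }
  names(suite) <- vapply(suite, function(b) b$set$target_id, character(1))
  suite
}

#' Write a synthetic suite as activity / inactivity / truth tables
#'
#' Emits the same dialects the readers consume: `activity.tsv`
#' (compound_id, target_id, smiles, pki, target_name), `inactives.tsv`
#' (compound_id, target_id, smiles) and `ground_truth.tsv` (planted cliff
#' pairs and analog labels).
#'
#' @param suite Output of [generate_benchmark_suite()] (or a list of
#'   `synthetic_target_set`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic_tables <- function(suite, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  act <- do.call(rbind, lapply(suite, function(b) {
    data.frame(compound_id = b$set$actives$compound_id,
               target_id = b$set$target_id,
               smiles = b$set$actives$smiles, pki = b$set$actives$pki,
               target_name = b$set$target_name, stringsAsFactors = FALSE)
  }))
  inact <- do.call(rbind, lapply(suite, function(b) {
    if (nrow(b$set$inactives) == 0L) return(NULL)
    data.frame(compound_id = b$set$inactives$compound_id,
               target_id = b$set$target_id,
               smiles = b$set$inactives$smiles, stringsAsFactors = FALSE)
  }))
  if (is.null(inact)) {
    inact <- data.frame(compound_id = character(0), target_id = character(0),
                        smiles = character(0), stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, lapply(suite, function(b) {
    tp <- b$truth$planted_cliffs
    if (nrow(tp) == 0L) return(NULL)
    data.frame(target_id = b$set$target_id, compound_a = tp$compound_a,
               compound_b = tp$compound_b, delta_pki = tp$delta_pki,
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(target_id = character(0), compound_a = character(0),
                        compound_b = character(0), delta_pki = numeric(0),
                        stringsAsFactors = FALSE)
  }
  paths <- file.path(dir, c("activity.tsv", "inactives.tsv",
                            "ground_truth.tsv"))
  write_tsv_stable(act, paths[1L])
  write_tsv_stable(inact, paths[2L])
  write_tsv_stable(truth, paths[3L])
  invisible(paths)
}
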
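# MMP generation by single-cut fragmentation and fragment indexing.
#
# Every acyclic single bond between two heavy atoms is cut once, yielding a
# core/substituent fragment pair with labeled attachment points. Matched
# molecular pairs (MMPs) are found by indexing all fragments by canonical
# SMILES: compounds meeting at an identical core differ by one substituent
# exchange. Retrosynthetic MMPs (RMMPs) restrict cuttable bonds to those
# matching a configurable rule set of bond environments, hence RMMPs are a
# subset of MMPs by construction.

#' Enumerate single-cut fragmentations of a molecule
#'
#' One fragmentation per acyclic single bond between two heavy atoms; bonds
#' to hydrogen and ring bonds are never cut. The core is the larger fragment
#' (ties broken by the lexicographically smaller canonical SMILES).
#'
#' @param smiles SMILES of a single connected molecule.
#' @return A data.frame with columns `core_smiles`, `substituent_smiles`,
#'   `core_heavy_atoms`, `substituent_heavy_atoms`, `rule_id`.
#' @export
enumerate_single_cuts <- function(smiles) {
  mol <- if (inherits(smiles, "mol")) smiles else parse_smiles(smiles)
  if (!mol_is_connected(mol)) {
    stop("molecule must be a single connected component", call. = FALSE)
  }
  cuts <- single_cut_table(mol)
  orient_cuts(cuts, rule_id = rep("random-cut", nrow(cuts)))
}

# Choose core (larger fragment) vs substituent for each cut.
orient_cuts <- function(cuts, rule_id) {
  n <- nrow(cuts)
  if (n == 0L) {
    return(data.frame(core_smiles = character(0),
                      substituent_smiles = character(0),
                      core_heavy_atoms = integer(0),
                      substituent_heavy_atoms = integer(0),
                      rule_id = character(0), stringsAsFactors = FALSE))
  }
  first_is_core <- cuts$n1 > cuts$n2 |
    (cuts$n1 == cuts$n2 & smaller_string(cuts$frag1, cuts$frag2))
  data.frame(
    core_smiles = ifelse(first_is_core, cuts$frag1, cuts$frag2),
    substituent_smiles = ifelse(first_is_core, cuts$frag2, cuts$frag1),
    core_heavy_atoms = ifelse(first_is_core, cuts$n1, cuts$n2),
    substituent_heavy_atoms = ifelse(first_is_core, cuts$n2, cuts$n1),
    rule_id = rule_id, stringsAsFactors = FALSE)
}

# Locale-independent string comparison (C collation via radix order).
smaller_string <- function(a, b) {
  vapply(seq_along(a), function(i) {
    if (a[i] == b[i]) return(TRUE)
    order(c(a[i], b[i]), method = "radix")[1L] == 1L
  }, logical(1))
}

# ---- retrosynthetic rules ---------------------------------------------------

#' Read a retrosynthetic fragmentation rule file
#'
#' Each non-comment line holds `rule_id<TAB>pattern`. A pattern describes the
#' two atoms of a cuttable single bond as `SIDE-SIDE`; each SIDE is an
#' element symbol (lowercase = aromatic) optionally followed by neighbor
#' conditions in braces, e.g. `C{=O}-N` (carbon bearing a double-bonded
#' oxygen, bonded to aliphatic nitrogen). Conditions are comma-separated
#' `<bond><element>` terms with bond `-`, `=` or `#`. Matching is symmetric
#' in the two sides.
#'
#' @param path Rule file path; default: the RECAP-style rules shipped with
#'   the package (a documented stand-in, fully configurable).
#' @return A `retro_rules` object (data.frame of parsed rules).
#' @export
read_fragmentation_rules <- function(path = default_rules_path()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("rule file contains no rules", call. = FALSE)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  rules <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (length(p) != 2L) {
      stop(sprintf("rule line %d: expected 'id<TAB>pattern'", i),
           call. = FALSE)
    }
    sides <- split_rule_pattern(p[2L], i)
    list(rule_id = p[1L],
         side1 = parse_rule_side(sides[1L], i),
         side2 = parse_rule_side(sides[2L], i))
  })
  structure(rules, class = "retro_rules")
}

default_rules_path <- function() {
  system.file("extdata", "retro_rules.tsv", package = "acmine",
              mustWork = TRUE)
}

# Split "SIDE-SIDE" at the top-level dash (dashes inside {} are conditions).
split_rule_pattern <- function(pat, line) {
  ch <- strsplit(pat, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(ch)) {
    if (ch[i] == "{") depth <- depth + 1L
    else if (ch[i] == "}") depth <- depth - 1L
    else if (ch[i] == "-" && depth == 0L && i > 1L) {
      return(c(substr(pat, 1L, i - 1L), substr(pat, i + 1L, nchar(pat))))
    }
  }
  stop(sprintf("rule line %d: pattern must contain a top-level '-'", line),
       call. = FALSE)
}

parse_rule_side <- function(side, line) {
  m <- regmatches(side, regexec("^([A-Za-z][a-z]?)(\\{([^}]*)\\})?$", side))[[1L]]
  if (length(m) == 0L) {
    stop(sprintf("rule line %d: bad side '%s'", line, side), call. = FALSE)
  }
  sym <- m[2L]
  arom <- sym == tolower(sym) && !sym %in% c("Cl", "Br")
  conds <- list()
  if (nzchar(m[4L])) {
    for (term in strsplit(m[4L], ",", fixed = TRUE)[[1L]]) {
      term <- trimws(term)
      cm <- regmatches(term, regexec("^([-=#])([A-Za-z][a-z]?)$", term))[[1L]]
      if (length(cm) == 0L) {
        stop(sprintf("rule line %d: bad condition '%s'", line, term),
             call. = FALSE)
      }
      conds[[length(conds) + 1L]] <-
        list(order = switch(cm[2L], "-" = 1L, "=" = 2L, "#" = 3L),
             elem = toupper(cm[3L]))
    }
  }
  list(elem = toupper(sym), arom = arom, conds = conds)
}

rule_side_matches <- function(mol, adj, atom, side) {
  if (mol$elem[atom] != side$elem || mol$arom[atom] != side$arom) return(FALSE)
  for (cond in side$conds) {
    a <- adj[[atom]]
    if (ncol(a) == 0L) return(FALSE)
    hit <- any(mol$order[a[2L, ]] == cond$order &
               mol$elem[a[1L, ]] == cond$elem)
    if (!hit) return(FALSE)
  }
  TRUE
}

# Bond indices of `mol` matching at least one rule; returns the first
# matching rule_id per bond ("" for non-matching bonds).
match_retro_bonds <- function(mol, rules, bonds, adj = mol_adjacency(mol)) {
  hit <- character(length(bonds))
  for (q in seq_along(bonds)) {
    k <- bonds[q]
    a <- mol$ba[k]; b <- mol$bb[k]
    for (r in rules) {
      if ((rule_side_matches(mol, adj, a, r$side1) &&
           rule_side_matches(mol, adj, b, r$side2)) ||
          (rule_side_matches(mol, adj, b, r$side1) &&
           rule_side_matches(mol, adj, a, r$side2))) {
        hit[q] <- r$rule_id
        break
      }
    }
  }
  hit
}

#' Enumerate retrosynthetic single cuts
#'
#' The subset of [enumerate_single_cuts()] whose cut bond matches at least
#' one retrosynthetic rule; the first matching rule is recorded as `rule_id`.
#'
#' @param smiles SMILES of a single connected molecule.
#' @param rules A `retro_rules` object from [read_fragmentation_rules()].
#' @return As [enumerate_single_cuts()].
#' @export
enumerate_retrosynthetic_cuts <- function(smiles,
                                          rules = read_fragmentation_rules()) {
  if (!inherits(rules, "retro_rules") || length(rules) == 0L) {
    stop("rules must be a non-empty 'retro_rules' object", call. = FALSE)
  }
  mol <- if (inherits(smiles, "mol")) smiles else parse_smiles(smiles)
  if (!mol_is_connected(mol)) {
    stop("molecule must be a single connected component", call. = FALSE)
  }
  cuts <- single_cut_table(mol)
  if (nrow(cuts) == 0L) return(orient_cuts(cuts, character(0)))
  rid <- match_retro_bonds(mol, rules, cuts$bond)
  keep <- nzchar(rid)
  orient_cuts(cuts[keep, , drop = FALSE], rid[keep])
}

# ---- fragment cache ---------------------------------------------------------

#' Create a fragmentation cache
#'
#' Fragmenting a compound is the dominant cost of MMP generation; a cache
#' (keyed by SMILES) lets the sd- and isd-cliff stages of a run share work.
#'
#' @return An environment usable as the `cache` argument of
#'   [find_matched_pairs()].
#' @export
fragmentation_cache <- function() new.env(parent = emptyenv(), hash = TRUE)

compound_cuts <- function(smiles, cache = NULL) {
  if (!is.null(cache) && !is.null(cache[[smiles]])) return(cache[[smiles]])
  mol <- parse_smiles(smiles)
  if (!mol_is_connected(mol)) {
    stop(sprintf("compound SMILES '%s' is not connected", smiles),
         call. = FALSE)
  }
  cuts <- single_cut_table(mol)
  rid_env <- new.env(parent = emptyenv())  # per-rule-set bond matches
  res <- list(mol = mol, cuts = cuts, rid = rid_env)
  if (!is.null(cache)) cache[[smiles]] <- res
  res
}

retro_bond_ids <- function(entry, rules) {
  key <- paste(vapply(rules, `[[`, character(1), "rule_id"), collapse = "|")
  got <- entry$rid[[key]]
  if (!is.null(got)) return(got)
  rid <- if (nrow(entry$cuts) == 0L) character(0) else
    match_retro_bonds(entry$mol, rules, entry$cuts$bond)
  entry$rid[[key]] <- rid
  rid
}

# ---- matched pair finding ---------------------------------------------------

#' Find matched molecular pairs by fragment indexing
#'
#' All fragments of all compounds are indexed by canonical SMILES in both
#' orientations (either side of a cut may serve as the shared core). Two
#' compounds meeting at an identical core with different complementary
#' substituents form an MMP. Per unordered compound pair the largest shared
#' core (smallest transformation) is kept; ties are broken by canonical core
#' string, then substituent strings, so the result is order-independent.
#'
#' @param compounds A data.frame with columns `compound_id` and `smiles`
#'   (unique ids, connected curated structures).
#' @param family `"MMP"` (all single cuts) or `"RMMP"` (retrosynthetic cuts
#'   only).
#' @param rules Retrosynthetic rules, used when `family = "RMMP"`.
#' @param cache Optional [fragmentation_cache()].
#' @return A data.frame of matched pairs: `compound_a`, `compound_b`
#'   (with `compound_a` < `compound_b`), `core_smiles`, `sub_a_smiles`,
#'   `sub_b_smiles`, `family`, `core_heavy_atoms`, `sub_a_heavy_atoms`,
#'   `sub_b_heavy_atoms`.
#' @export
find_matched_pairs <- function(compounds, family = c("MMP", "RMMP"),
                               rules = NULL, cache = NULL) {
  family <- match.arg(family)
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "smiles") %in% names(compounds)))
  if (anyDuplicated(compounds$compound_id)) {
    stop("compound ids must be unique", call. = FALSE)
  }
  if (family == "RMMP" && is.null(rules)) rules <- read_fragmentation_rules()

  idx <- vector("list", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    entry <- compound_cuts(compounds$smiles[i], cache)
    cuts <- entry$cuts
    if (family == "RMMP" && nrow(cuts) > 0L) {
      cuts <- cuts[nzchar(retro_bond_ids(entry, rules)), , drop = FALSE]
    }
    if (nrow(cuts) == 0L) next
    idx[[i]] <- data.table::data.table(
      compound_id = compounds$compound_id[i],
      core = c(cuts$frag1, cuts$frag2),
      sub = c(cuts$frag2, cuts$frag1),
      core_n = c(cuts$n1, cuts$n2),
      sub_n = c(cuts$n2, cuts$n1))
  }
  empty <- data.frame(compound_a = character(0), compound_b = character(0),
                      core_smiles = character(0), sub_a_smiles = character(0),
                      sub_b_smiles = character(0), family = character(0),
                      core_heavy_atoms = integer(0),
                      sub_a_heavy_atoms = integer(0),
                      sub_b_heavy_atoms = integer(0),
                      stringsAsFactors = FALSE)
  idx <- idx[!vapply(idx, is.null, logical(1))]
  if (length(idx) == 0L) return(empty)
  dt <- unique(data.table::rbindlist(idx))

  core <- sub <- compound_id <- core_n <- sub_n <- NULL  # R CMD check
  i.compound_id <- i.sub <- i.sub_n <- NULL
  cand <- dt[dt, on = "core", allow.cartesian = TRUE][compound_id < i.compound_id]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[sub != i.sub]
  if (nrow(cand) == 0L) return(empty)
  pairs <- data.table::data.table(
    compound_a = cand$compound_id, compound_b = cand$i.compound_id,
    core_smiles = cand$core,
    sub_a_smiles = cand$sub, sub_b_smiles = cand$i.sub,
    core_heavy_atoms = cand$core_n,
    sub_a_heavy_atoms = cand$sub_n, sub_b_heavy_atoms = cand$i.sub_n)
  data.table::setkeyv(pairs, c("compound_a", "compound_b"))
  data.table::setorderv(pairs,
    c("compound_a", "compound_b", "core_heavy_atoms", "core_smiles",
      "sub_a_smiles", "sub_b_smiles"),
    order = c(1L, 1L, -1L, 1L, 1L, 1L))
  best <- pairs[!duplicated(pairs, by = c("compound_a", "compound_b"))]
  out <- as.data.frame(best)
  out$family <- family
  out[, c("compound_a", "compound_b", "core_smiles", "sub_a_smiles",
          "sub_b_smiles", "family", "core_heavy_atoms", "sub_a_heavy_atoms",
          "sub_b_heavy_atoms")]
}

#' Transformation-size restriction (tsr) filter
#'
#' A matched pair passes when the shared core has at least twice the heavy
#' atoms of each exchanged substituent, the substituents differ by at most 8
#' heavy atoms, and neither substituent exceeds 13 heavy atoms.
#'
#' @param pairs A matched-pair data.frame from [find_matched_pairs()] (or any
#'   data.frame with the three size columns).
#' @param core_min_ratio,max_size_diff,max_sub_size The three restriction
#'   parameters (defaults 2, 8 and 13 heavy atoms).
#' @return Logical vector, one element per pair.
#' @export
apply_tsr_filter <- function(pairs, core_min_ratio = 2,
                             max_size_diff = 8, max_sub_size = 13) {
  with(pairs,
       core_heavy_atoms >= core_min_ratio * sub_a_heavy_atoms &
       core_heavy_atoms >= core_min_ratio * sub_b_heavy_atoms &
       abs(sub_a_heavy_atoms - sub_b_heavy_atoms) <= max_size_diff &
       sub_a_heavy_atoms <= max_sub_size &
       sub_b_heavy_atoms <= max_sub_size)
}
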
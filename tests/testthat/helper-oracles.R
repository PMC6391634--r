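# Shared helpers: an exhaustive O(n^2) matched-pair oracle and small
# constructors for hand-built cliff tables.

# Both orientations of every single-cut fragmentation of one molecule.
all_fragments <- function(smiles) {
  cuts <- enumerate_single_cuts(smiles)
  data.frame(
    core = c(cuts$core_smiles, cuts$substituent_smiles),
    sub = c(cuts$substituent_smiles, cuts$core_smiles),
    core_n = c(cuts$core_heavy_atoms, cuts$substituent_heavy_atoms),
    sub_n = c(cuts$substituent_heavy_atoms, cuts$core_heavy_atoms),
    stringsAsFactors = FALSE)
}

# Brute-force matched pairs: compare all fragmentation cores of every
# compound pair directly, then apply the same largest-core tie-break as the
# indexing implementation. Quadratic in compounds and fragments.
brute_force_pairs <- function(compounds) {
  frs <- lapply(compounds$smiles, all_fragments)
  out <- list()
  n <- nrow(compounds)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- i; b <- j
      if (compounds$compound_id[a] > compounds$compound_id[b]) {
        a <- j; b <- i
      }
      fa <- frs[[a]]; fb <- frs[[b]]
      hit <- merge(fa, fb, by = "core", suffixes = c("_a", "_b"))
      hit <- hit[hit$sub_a != hit$sub_b, , drop = FALSE]
      if (nrow(hit) == 0L) next
      hit <- hit[order(-hit$core_n_a, hit$core, hit$sub_a, hit$sub_b,
                       method = "radix"), , drop = FALSE]
      best <- hit[1L, ]
      out[[length(out) + 1L]] <- data.frame(
        compound_a = compounds$compound_id[a],
        compound_b = compounds$compound_id[b],
        core_smiles = best$core,
        sub_a_smiles = best$sub_a, sub_b_smiles = best$sub_b,
        core_heavy_atoms = best$core_n_a,
        sub_a_heavy_atoms = best$sub_n_a,
        sub_b_heavy_atoms = best$sub_n_b,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(compound_a = character(0), compound_b = character(0),
                      core_smiles = character(0), sub_a_smiles = character(0),
                      sub_b_smiles = character(0),
                      core_heavy_atoms = integer(0),
                      sub_a_heavy_atoms = integer(0),
                      sub_b_heavy_atoms = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\1")

# Minimal cliff row(s) for network tests.
make_cliffs <- function(a, b, type, family = "MMP") {
  n <- length(a)
  data.frame(cliff_type = type, family = rep(family, n),
             compound_a = a, compound_b = b,
             potent_partner = a, other_partner = b,
             delta_pki = ifelse(type == "isd", NA_real_, 2.5),
             pki_a = rep(8, n),
             pki_b = ifelse(type == "isd", NA_real_, 5.5),
             core_smiles = rep("[*]c1ccccc1", n),
             sub_a_smiles = rep("[*]C", n),
             sub_b_smiles = rep("[*]CC", n), stringsAsFactors = FALSE)
}

# Small analog series assembled from one scaffold; deterministic potencies.
toy_series_set <- function(target_id = "TOY",
                           rgroups = c("[*]C", "[*]CC", "[*]CCC", "[*]OC"),
                           pki = c(9.0, 5.5, 7.0, 8.5),
                           inactive_rgroups = character(0)) {
  core <- "[*]c1ccc(-c2ccccc2)cc1"
  actives <- data.frame(
    compound_id = sprintf("A%02d", seq_along(rgroups)),
    smiles = vapply(rgroups, function(r) attach_rgroup(core, r),
                    character(1), USE.NAMES = FALSE),
    pki = pki, stringsAsFactors = FALSE)
  inactives <- if (length(inactive_rgroups) > 0L) {
    data.frame(
      compound_id = sprintf("I%02d", seq_along(inactive_rgroups)),
      smiles = vapply(inactive_rgroups, function(r) attach_rgroup(core, r),
                      character(1), USE.NAMES = FALSE),
      stringsAsFactors = FALSE)
  } else NULL
  target_set(target_id, actives = actives, inactives = inactives)
}
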
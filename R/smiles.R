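# Minimal molecular graph machinery for MMP analysis.
#
# Molecules are stored as plain-vector graphs ("mol" objects): atom element,
# aromatic flag, formal charge, explicit hydrogen count (NA = implicit), and
# a bond list with integer orders (1, 2, 3; 4 = aromatic). The supported
# SMILES dialect covers the organic subset, bracket atoms with charge and
# explicit H, branches, ring closures (incl. %nn) and disconnected
# components. Stereo descriptors (/ \ @) and isotopes are accepted on input
# and discarded: configuration does not define a transformation site, so two
# stereoisomers compare as identical structures. No valence model or
# aromaticity perception is applied; aromatic input must use lowercase
# (aromatic) SMILES consistently.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
AROMATIC_SYMBOLS <- c("b", "c", "n", "o", "p", "s")
TWO_LETTER_ELEMS <- c("Cl", "Br", "Si", "Se", "Na", "Li", "Mg", "Ca", "Fe",
                      "Zn", "Cu", "Mn", "Co", "Ni", "As", "Al", "Sn", "Te")

new_mol <- function(elem, arom, charge, hcount, ba, bb, order) {
  structure(list(
    elem = elem, arom = arom, charge = charge, hcount = hcount,
    ba = ba, bb = bb, order = order,
    n_atoms = length(elem), n_bonds = length(order)
  ), class = "mol")
}

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms (charge, explicit H), branches,
#' ring closures and dot-separated components. Stereochemistry and isotopes
#' are dropped; kekulized aromatic input is not normalized (use lowercase
#' aromatic SMILES consistently).
#'
#' @param smiles A single SMILES string.
#' @return A `mol` object (possibly disconnected; see [mol_components()]).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("SMILES must be a single non-empty string", call. = FALSE)
  }
  ch <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  nc <- length(ch)

  elem <- character(0); arom <- logical(0)
  charge <- integer(0); hcount <- integer(0)
  ba <- integer(0); bb <- integer(0); ord <- integer(0)

  prev <- NA_integer_      # atom awaiting the next bond
  pend <- NA_integer_      # explicit bond order for the next bond
  stack <- integer(0)      # branch stack
  ring_atom <- integer(0)  # open ring closures, indexed by closure number
  ring_ord <- integer(0)

  bad <- function(i, what) {
    stop(sprintf("SMILES parse error at position %d ('%s'): %s",
                 i, ch[i], what), call. = FALSE)
  }

  add_bond <- function(a, b, o) {
    if (is.na(o)) o <- if (arom[a] && arom[b]) 4L else 1L
    ba[length(ba) + 1L] <<- a
    bb[length(bb) + 1L] <<- b
    ord[length(ord) + 1L] <<- o
  }
  add_atom <- function(e, ar, chg, hc) {
    elem[length(elem) + 1L] <<- e
    arom[length(arom) + 1L] <<- ar
    charge[length(charge) + 1L] <<- chg
    hcount[length(hcount) + 1L] <<- hc
    idx <- length(elem)
    if (!is.na(prev)) add_bond(prev, idx, pend)
    pend <<- NA_integer_
    prev <<- idx
    idx
  }
  close_ring <- function(num, i) {
    if (is.na(prev)) bad(i, "ring closure before any atom")
    if (num <= length(ring_atom) && !is.na(ring_atom[num])) {
      a <- ring_atom[num]; o_open <- ring_ord[num]
      if (a == prev) bad(i, "ring closure to the same atom")
      o <- pend
      if (!is.na(o_open) && !is.na(o) && o_open != o) {
        bad(i, "conflicting ring-closure bond orders")
      }
      if (is.na(o)) o <- o_open
      add_bond(a, prev, o)
      ring_atom[num] <<- NA_integer_
      pend <<- NA_integer_
    } else {
      ring_atom[num] <<- prev
      ring_ord[num] <<- pend
      pend <<- NA_integer_
    }
  }

  i <- 1L
  while (i <= nc) {
    c1 <- ch[i]
    if (c1 == "[") {
      j <- i + 1L
      while (j <= nc && ch[j] != "]") j <- j + 1L
      if (j > nc) bad(i, "unclosed bracket atom")
      body <- ch[(i + 1L):(j - 1L)]
      k <- 1L; nb <- length(body)
      while (k <= nb && grepl("[0-9]", body[k])) k <- k + 1L  # isotope
      if (k > nb) bad(i, "empty bracket atom")
      e <- body[k]; ar <- FALSE
      if (e == "*") {
        k <- k + 1L
      } else if (e %in% AROMATIC_SYMBOLS) {
        ar <- TRUE; e <- toupper(e); k <- k + 1L
      } else if (grepl("[A-Z]", e)) {
        if (k < nb && paste0(e, body[k + 1L]) %in% TWO_LETTER_ELEMS) {
          e <- paste0(e, body[k + 1L]); k <- k + 2L
        } else {
          k <- k + 1L
        }
      } else {
        bad(i, "unsupported bracket atom symbol")
      }
      hc <- 0L; chg <- 0L
      while (k <= nb) {
        b1 <- body[k]
        if (b1 == "@") {
          k <- k + 1L  # stereo dropped
        } else if (b1 == "H") {
          k <- k + 1L; d <- ""
          while (k <= nb && grepl("[0-9]", body[k])) {
            d <- paste0(d, body[k]); k <- k + 1L
          }
          hc <- if (nzchar(d)) as.integer(d) else 1L
        } else if (b1 %in% c("+", "-")) {
          sgn <- if (b1 == "+") 1L else -1L
          k <- k + 1L; d <- ""; reps <- 1L
          while (k <= nb && body[k] == b1) { reps <- reps + 1L; k <- k + 1L }
          while (k <= nb && grepl("[0-9]", body[k])) {
            d <- paste0(d, body[k]); k <- k + 1L
          }
          chg <- sgn * if (nzchar(d)) as.integer(d) else reps
        } else if (b1 == ":") {
          k <- k + 1L  # atom map dropped
          while (k <= nb && grepl("[0-9]", body[k])) k <- k + 1L
        } else {
          bad(i, "unsupported bracket atom annotation")
        }
      }
      # Aliphatic uncharged organic-subset atoms (e.g. the [C@H] left by
      # stereo stripping) carry their H count implicitly, like bare atoms;
      # explicit H is only structural for aromatic atoms ([nH]) and charged
      # or exotic atoms.
      if (e == "*" || (!ar && chg == 0L && e %in% ORGANIC_SUBSET)) {
        hc <- NA_integer_
      }
      add_atom(e, ar, chg, hc)
      i <- j + 1L
    } else if (c1 %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      e <- c1
      if (i < nc && paste0(c1, ch[i + 1L]) %in% c("Cl", "Br")) {
        e <- paste0(c1, ch[i + 1L]); i <- i + 1L
      }
      add_atom(e, FALSE, 0L, NA_integer_)
      i <- i + 1L
    } else if (c1 %in% AROMATIC_SYMBOLS) {
      add_atom(toupper(c1), TRUE, 0L, NA_integer_)
      i <- i + 1L
    } else if (c1 == "*") {
      add_atom("*", FALSE, 0L, NA_integer_)
      i <- i + 1L
    } else if (c1 == "(") {
      if (is.na(prev)) bad(i, "branch before any atom")
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (c1 == ")") {
      if (length(stack) == 0L) bad(i, "unmatched ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (c1 == "-") { pend <- 1L; i <- i + 1L
    } else if (c1 == "=") { pend <- 2L; i <- i + 1L
    } else if (c1 == "#") { pend <- 3L; i <- i + 1L
    } else if (c1 == ":") { pend <- 4L; i <- i + 1L
    } else if (c1 %in% c("/", "\\")) { pend <- 1L; i <- i + 1L  # stereo bond
    } else if (c1 == ".") {
      prev <- NA_integer_; pend <- NA_integer_
      i <- i + 1L
    } else if (grepl("[0-9]", c1)) {
      close_ring(as.integer(c1), i)
      i <- i + 1L
    } else if (c1 == "%") {
      if (i + 2L > nc || !grepl("[0-9]", ch[i + 1L]) ||
          !grepl("[0-9]", ch[i + 2L])) bad(i, "bad %nn ring closure")
      close_ring(as.integer(paste0(ch[i + 1L], ch[i + 2L])), i)
      i <- i + 3L
    } else {
      bad(i, "unsupported SMILES token")
    }
  }
  if (length(stack) > 0L) stop("SMILES parse error: unclosed branch",
                               call. = FALSE)
  if (any(!is.na(ring_atom))) stop("SMILES parse error: unclosed ring bond",
                                   call. = FALSE)
  if (length(elem) == 0L) stop("SMILES parse error: no atoms", call. = FALSE)
  new_mol(elem, arom, charge, hcount, ba, bb, ord)
}

# Adjacency list: per atom, 2-row matrix (neighbor atom; bond index).
mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  if (mol$n_bonds > 0L) {
    for (k in seq_len(mol$n_bonds)) {
      a <- mol$ba[k]; b <- mol$bb[k]
      adj[[a]] <- c(adj[[a]], b, k)
      adj[[b]] <- c(adj[[b]], a, k)
    }
  }
  lapply(adj, function(v) {
    if (is.null(v)) matrix(integer(0), nrow = 2L)
    else matrix(v, nrow = 2L)
  })
}

# Connected components as a membership vector.
mol_component_membership <- function(mol) {
  n <- mol$n_atoms
  comp <- integer(n)
  adj <- mol_adjacency(mol)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][1L, ]
      fresh <- nb[comp[nb] == 0L]
      comp[fresh] <- cid
      queue <- c(queue, fresh)
    }
  }
  comp
}

#' Split a molecule into connected components
#'
#' @param mol A `mol` object.
#' @return List of connected `mol` objects.
#' @export
mol_components <- function(mol) {
  comp <- mol_component_membership(mol)
  lapply(seq_len(max(comp)), function(ci) {
    mol_induced(mol, which(comp == ci))
  })
}

# Induced submolecule on a set of atom indices.
mol_induced <- function(mol, atoms) {
  map <- integer(mol$n_atoms)
  map[atoms] <- seq_along(atoms)
  keep <- map[mol$ba] > 0L & map[mol$bb] > 0L
  new_mol(mol$elem[atoms], mol$arom[atoms], mol$charge[atoms],
          mol$hcount[atoms],
          map[mol$ba[keep]], map[mol$bb[keep]], mol$order[keep])
}

mol_is_connected <- function(mol) {
  mol$n_atoms == 1L || max(mol_component_membership(mol)) == 1L
}

#' Count heavy atoms in a SMILES fragment
#'
#' Hydrogens and attachment-point dummies (`[*]`) are excluded.
#'
#' @param smiles SMILES string, possibly with one or more `[*]` dummies.
#' @return Integer heavy-atom count.
#' @export
heavy_atom_count <- function(smiles) {
  mol <- parse_smiles(smiles)
  sum(mol$elem != "*" & mol$elem != "H")
}

mol_heavy_atoms <- function(mol) sum(mol$elem != "*" & mol$elem != "H")

# ---- canonicalization -------------------------------------------------------

# Canonical atom ranks via BLISS on the bond-subdivided colored graph.
# Vertex colors encode (element, aromaticity, charge, explicit H); each bond
# becomes an auxiliary vertex colored by bond order so edge labels take part
# in the canonical form.
canon_ranks <- function(mol) {
  n <- mol$n_atoms
  if (n == 1L) return(1L)
  m <- mol$n_bonds
  key <- paste(mol$elem, mol$arom, mol$charge,
               ifelse(is.na(mol$hcount), "i", mol$hcount), sep = "\1")
  ukey <- sort(unique(key))
  acol <- match(key, ukey)
  bcol <- length(ukey) + mol$order
  edges <- integer(4L * m)
  if (m > 0L) {
    bidx <- n + seq_len(m)
    edges <- c(rbind(mol$ba, bidx), rbind(mol$bb, bidx))
  }
  g <- igraph::make_graph(edges, n = n + m, directed = FALSE)
  lab <- igraph::canonical_permutation(g, colors = c(acol, bcol))$labeling
  rank(lab[seq_len(n)])
}

bond_symbol <- function(mol, k) {
  o <- mol$order[k]
  if (o == 2L) return("=")
  if (o == 3L) return("#")
  both_arom <- mol$arom[mol$ba[k]] && mol$arom[mol$bb[k]]
  if (o == 4L) return(if (both_arom) "" else ":")
  if (both_arom) "-" else ""  # explicit single between aromatic atoms
}

atom_token <- function(mol, i) {
  e <- mol$elem[i]
  if (e == "*") return("[*]")
  sym <- if (mol$arom[i]) tolower(e) else e
  chg <- mol$charge[i]; hc <- mol$hcount[i]
  if (chg == 0L && is.na(hc) && e %in% ORGANIC_SUBSET) return(sym)
  h <- if (is.na(hc) || hc == 0L) "" else if (hc == 1L) "H" else paste0("H", hc)
  cs <- if (chg == 0L) "" else if (chg > 0L) {
    paste0("+", if (chg > 1L) chg else "")
  } else {
    paste0("-", if (chg < -1L) -chg else "")
  }
  paste0("[", sym, h, cs, "]")
}

ring_digit <- function(d) if (d < 10L) as.character(d) else sprintf("%%%02d", d)

# Deterministic SMILES writer: given per-atom ranks, traversal order (start
# atom, neighbor order, ring-closure numbering) is a pure function of the
# ranked graph, so molecules with identical canonical ranks yield identical
# strings. Assumes a connected molecule.
write_smiles_ranked <- function(mol, ranks) {
  n <- mol$n_atoms
  if (n == 1L) return(atom_token(mol, 1L))
  adj <- mol_adjacency(mol)
  adj <- lapply(adj, function(a) a[, order(ranks[a[1L, ]]), drop = FALSE])

  visited <- logical(n)
  edge_seen <- logical(mol$n_bonds)
  ring_of_atom <- vector("list", n)   # atom -> c(digit, bond, digit, bond, ...)
  n_digits <- 0L
  children <- vector("list", n)       # atom -> c(child, bond, ...)

  # pass 1: classify tree vs ring edges, assign ring-closure digits
  dfs1 <- function(root) {
    visited[root] <<- TRUE
    # iterative DFS preserving child order
    rec <- function(v, pe) {
      a <- adj[[v]]
      if (ncol(a) == 0L) return(invisible())
      for (q in seq_len(ncol(a))) {
        j <- a[1L, q]; e <- a[2L, q]
        if (!is.na(pe) && e == pe) next
        if (edge_seen[e]) next
        if (visited[j]) {
          edge_seen[e] <<- TRUE
          n_digits <<- n_digits + 1L
          ring_of_atom[[j]] <<- c(ring_of_atom[[j]], n_digits, e)
          ring_of_atom[[v]] <<- c(ring_of_atom[[v]], n_digits, e)
        } else {
          edge_seen[e] <<- TRUE
          visited[j] <<- TRUE
          children[[v]] <<- c(children[[v]], j, e)
          rec(j, e)
        }
      }
    }
    rec(root, NA_integer_)
  }
  start <- which.min(ranks)
  dfs1(start)

  out <- character(0)
  emit <- function(v, in_bond) {
    parts <- if (is.na(in_bond)) atom_token(mol, v) else
      paste0(bond_symbol(mol, in_bond), atom_token(mol, v))
    r <- ring_of_atom[[v]]
    if (!is.null(r)) {
      rm_ <- matrix(r, nrow = 2L)
      rm_ <- rm_[, order(rm_[1L, ]), drop = FALSE]
      for (q in seq_len(ncol(rm_))) {
        parts <- paste0(parts, bond_symbol(mol, rm_[2L, q]),
                        ring_digit(rm_[1L, q]))
      }
    }
    kids <- children[[v]]
    if (!is.null(kids)) {
      km <- matrix(kids, nrow = 2L)
      nk <- ncol(km)
      for (q in seq_len(nk)) {
        sub <- emit(km[1L, q], km[2L, q])
        parts <- if (q < nk) paste0(parts, "(", sub, ")")
                 else paste0(parts, sub)
      }
    }
    parts
  }
  emit(start, NA_integer_)
}

#' Canonical SMILES of a molecule
#'
#' Produces a canonical string such that two parsed molecules compare equal
#' iff their labeled molecular graphs are isomorphic (element, aromaticity,
#' charge, explicit H and bond orders; stereochemistry is ignored).
#' Disconnected inputs yield dot-joined, lexicographically sorted component
#' strings.
#'
#' @param x A SMILES string or a `mol` object.
#' @return Canonical SMILES string.
#' @export
canon_smiles <- function(x) {
  mol <- if (inherits(x, "mol")) x else parse_smiles(x)
  comp <- mol_component_membership(mol)
  if (max(comp) == 1L) {
    return(write_smiles_ranked(mol, canon_ranks(mol)))
  }
  parts <- vapply(mol_components(mol), function(cm) {
    write_smiles_ranked(cm, canon_ranks(cm))
  }, character(1))
  paste(sort(parts), collapse = ".")
}

#' Curate a raw SMILES string
#'
#' Keeps the largest organic component (most heavy atoms; components
#' containing carbon are preferred, ties broken by canonical string), i.e.
#' strips salts and solvents, and canonicalizes. Returns `NA` for
#' unparseable input instead of raising, so table readers can count failures.
#'
#' @param smiles Raw SMILES string.
#' @return Canonical SMILES of the curated structure, or `NA_character_`.
#' @export
curate_smiles <- function(smiles) {
  mol <- tryCatch(parse_smiles(smiles), error = function(e) NULL)
  if (is.null(mol)) return(NA_character_)
  comps <- mol_components(mol)
  has_c <- vapply(comps, function(m) any(m$elem == "C"), logical(1))
  if (any(has_c)) comps <- comps[has_c]
  sizes <- vapply(comps, mol_heavy_atoms, integer(1))
  cand <- comps[sizes == max(sizes)]
  strs <- sort(vapply(cand, canon_smiles, character(1)))
  strs[1L]
}

# ---- fragmentation primitives ----------------------------------------------

# Bonds eligible for a single cut: acyclic (bridge) single bonds between two
# heavy atoms, not involving a dummy.
cuttable_bonds <- function(mol) {
  if (mol$n_bonds == 0L) return(integer(0))
  single <- which(mol$order == 1L &
                  mol$elem[mol$ba] != "*" & mol$elem[mol$bb] != "*" &
                  mol$elem[mol$ba] != "H" & mol$elem[mol$bb] != "H")
  if (length(single) == 0L) return(integer(0))
  g <- igraph::make_graph(as.vector(rbind(mol$ba, mol$bb)),
                          n = mol$n_atoms, directed = FALSE)
  br <- as.integer(igraph::bridges(g))
  intersect(single, br)
}

# Atoms reachable from `from` without traversing bond `skip`.
reachable_atoms <- function(adj, from, skip) {
  seen <- integer(0)
  queue <- from
  mark <- logical(length(adj))
  mark[from] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    seen <- c(seen, v)
    a <- adj[[v]]
    if (ncol(a) == 0L) next
    keep <- a[2L, ] != skip & !mark[a[1L, ]]
    nb <- a[1L, keep]
    mark[nb] <- TRUE
    queue <- c(queue, nb)
  }
  seen
}

# Fragment: induced submolecule plus a dummy atom bonded to `attach`.
mol_fragment <- function(mol, atoms, attach) {
  map <- integer(mol$n_atoms)
  map[atoms] <- seq_along(atoms)
  keep <- map[mol$ba] > 0L & map[mol$bb] > 0L
  na <- length(atoms)
  new_mol(c(mol$elem[atoms], "*"),
          c(mol$arom[atoms], FALSE),
          c(mol$charge[atoms], 0L),
          c(mol$hcount[atoms], NA_integer_),
          c(map[mol$ba[keep]], map[attach]),
          c(map[mol$bb[keep]], na + 1L),
          c(mol$order[keep], 1L))
}

# All single cuts of a connected molecule. Returns a data.frame with one row
# per cuttable bond: canonical fragment SMILES on each side and heavy-atom
# counts. Used by both the public fragmentation API and the pair indexer.
single_cut_table <- function(mol) {
  stopifnot(inherits(mol, "mol"))
  bonds <- cuttable_bonds(mol)
  if (length(bonds) == 0L) {
    return(data.frame(bond = integer(0),
                      frag1 = character(0), frag2 = character(0),
                      n1 = integer(0), n2 = integer(0),
                      stringsAsFactors = FALSE))
  }
  adj <- mol_adjacency(mol)
  frag1 <- character(length(bonds)); frag2 <- character(length(bonds))
  n1 <- integer(length(bonds)); n2 <- integer(length(bonds))
  for (q in seq_along(bonds)) {
    k <- bonds[q]
    a <- mol$ba[k]; b <- mol$bb[k]
    side_a <- reachable_atoms(adj, a, k)
    side_b <- setdiff(seq_len(mol$n_atoms), side_a)
    fa <- mol_fragment(mol, side_a, a)
    fb <- mol_fragment(mol, side_b, b)
    frag1[q] <- canon_smiles(fa)
    frag2[q] <- canon_smiles(fb)
    n1[q] <- sum(mol$elem[side_a] != "H")
    n2[q] <- sum(mol$elem[side_b] != "H")
  }
  data.frame(bond = bonds, frag1 = frag1, frag2 = frag2,
             n1 = n1, n2 = n2, stringsAsFactors = FALSE)
}
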
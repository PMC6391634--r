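# Compound / target-set data model and table I/O.
#
# A target set is the curated collection of active compounds for one protein
# target (its activity class), optionally with confirmed-inactive screening
# compounds attached. Potency is carried as pKi = -log10(Ki [mol/L]); a
# difference of 2 pKi units is a 100-fold potency difference.

#' Describe the layout of an activity / inactivity table
#'
#' @param sep Field separator (default tab).
#' @param compound_id,target_id,smiles,pki,target_name Column names in the
#'   file (`pki` is ignored by [read_inactives()]; `target_name` is optional).
#' @param potency_unit `"pki"` (values already on the pKi scale) or
#'   `"ki_nM"` (converted as `pki = 9 - log10(Ki[nM])`).
#' @return A `table_dialect` object.
#' @export
table_dialect <- function(sep = "\t", compound_id = "compound_id",
                          target_id = "target_id", smiles = "smiles",
                          pki = "pki", target_name = "target_name",
                          potency_unit = c("pki", "ki_nM")) {
  structure(list(sep = sep, compound_id = compound_id, target_id = target_id,
                 smiles = smiles, pki = pki, target_name = target_name,
                 potency_unit = match.arg(potency_unit)),
            class = "table_dialect")
}

read_delim_table <- function(path, dialect) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  tab <- tryCatch(
    utils::read.table(path, sep = dialect$sep, header = TRUE,
                      quote = "", comment.char = "",
                      colClasses = "character", check.names = FALSE),
    error = function(e) {
      stop(sprintf("cannot parse table '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  tab
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, names(tab))
  if (length(missing) > 0L) {
    stop(sprintf("table '%s' lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read an activity table into potency measurements
#'
#' One measurement per row; rows whose potency is missing or non-numeric are
#' dropped and counted in the attached summary (`attr(x, "summary")`) —
#' only numerically specified values qualify as potency measurements.
#'
#' @param path Delimited text file.
#' @param dialect A [table_dialect()].
#' @return data.frame with columns `compound_id`, `target_id`, `smiles`,
#'   `pki` (+ `target_name` when present); attribute `summary` holds row and
#'   drop counts.
#' @export
read_activity_table <- function(path, dialect = table_dialect()) {
  tab <- read_delim_table(path, dialect)
  require_columns(tab, c(dialect$compound_id, dialect$target_id,
                         dialect$smiles, dialect$pki), path)
  raw <- tab[[dialect$pki]]
  val <- suppressWarnings(as.numeric(raw))
  if (identical(dialect$potency_unit, "ki_nM")) {
    val <- ifelse(is.finite(val) & val > 0, 9 - log10(val), NA_real_)
  }
  keep <- is.finite(val)
  out <- data.frame(compound_id = tab[[dialect$compound_id]][keep],
                    target_id = tab[[dialect$target_id]][keep],
                    smiles = tab[[dialect$smiles]][keep],
                    pki = val[keep], stringsAsFactors = FALSE)
  if (dialect$target_name %in% names(tab)) {
    out$target_name <- tab[[dialect$target_name]][keep]
  }
  attr(out, "summary") <- list(n_rows = nrow(tab), n_measurements = nrow(out),
                               n_dropped = nrow(tab) - nrow(out))
  out
}

#' Construct a target set
#'
#' @param target_id,target_name Identifiers.
#' @param actives data.frame (`compound_id`, `smiles`, `pki`, optional
#'   `source`); all potencies must be finite.
#' @param inactives Optional data.frame (`compound_id`, `smiles`, optional
#'   `source`); ids must not collide with the actives.
#' @return A `target_set` object.
#' @export
target_set <- function(target_id, target_name = target_id, actives,
                       inactives = NULL) {
  stopifnot(is.data.frame(actives),
            all(c("compound_id", "smiles", "pki") %in% names(actives)))
  if (!all(is.finite(actives$pki))) {
    stop("all active compounds must carry a finite pKi", call. = FALSE)
  }
  if (anyDuplicated(actives$compound_id)) {
    stop("duplicate compound ids among actives", call. = FALSE)
  }
  if (is.null(actives$source)) actives$source <- "medchem"
  if (is.null(inactives)) {
    inactives <- data.frame(compound_id = character(0), smiles = character(0),
                            source = character(0), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("compound_id", "smiles") %in% names(inactives)))
    if (is.null(inactives$source)) inactives$source <- "screening"
    if (anyDuplicated(inactives$compound_id)) {
      stop("duplicate compound ids among inactives", call. = FALSE)
    }
    clash <- intersect(actives$compound_id, inactives$compound_id)
    if (length(clash) > 0L) {
      stop(sprintf("compound id(s) both active and inactive: %s",
                   paste(clash, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(target_id = target_id, target_name = target_name,
                 actives = actives[, c("compound_id", "smiles", "pki",
                                       "source")],
                 inactives = inactives[, c("compound_id", "smiles", "source")]),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %s (%s): %d actives, %d inactives\n",
              x$target_id, x$target_name, nrow(x$actives),
              nrow(x$inactives)))
  if (nrow(x$actives) > 0L) {
    cat(sprintf("  pKi range %.2f-%.2f (sd %.2f)\n",
                min(x$actives$pki), max(x$actives$pki),
                stats::sd(x$actives$pki)))
  }
  invisible(x)
}

#' Aggregate replicate potency measurements into target sets
#'
#' Per (target, compound): replicate pKi readings are averaged; a compound
#' whose readings spread over more than `max_spread` log units is discarded
#' for that target. Structures are curated ([curate_smiles()]); compounds
#' whose SMILES fail to parse are dropped and counted.
#'
#' @param measurements Output of [read_activity_table()].
#' @param max_spread Maximum allowed max-min range of replicate pKi values
#'   (log units, default 1.0).
#' @return Named list of [target_set()] objects; attribute `summary` counts
#'   discarded compounds.
#' @export
aggregate_potency <- function(measurements, max_spread = 1.0) {
  if (nrow(measurements) == 0L) {
    out <- list()
    attr(out, "summary") <- list(n_spread_discarded = 0L, n_bad_smiles = 0L)
    return(out)
  }
  dt <- data.table::as.data.table(measurements)
  target_id <- compound_id <- pki <- smiles <- NULL
  has_name <- "target_name" %in% names(dt)
  agg <- dt[, list(pki_mean = mean(pki), spread = max(pki) - min(pki),
                   smiles = smiles[1L],
                   target_name = if (has_name) .SD$target_name[1L] else
                     target_id[1L]),
            by = c("target_id", "compound_id")]
  n_spread <- sum(agg$spread > max_spread)
  agg <- agg[agg$spread <= max_spread, ]
  curated <- vapply(agg$smiles, curate_smiles, character(1), USE.NAMES = FALSE)
  n_bad <- sum(is.na(curated))
  agg$smiles <- curated
  agg <- agg[!is.na(curated), ]
  sets <- lapply(split(agg, agg$target_id), function(g) {
    target_set(g$target_id[1L], g$target_name[1L],
               actives = data.frame(compound_id = g$compound_id,
                                    smiles = g$smiles, pki = g$pki_mean,
                                    source = "medchem",
                                    stringsAsFactors = FALSE))
  })
  attr(sets, "summary") <- list(n_spread_discarded = n_spread,
                                n_bad_smiles = n_bad)
  sets
}

#' Attach confirmed-inactive compounds to target sets
#'
#' Inactives for targets without actives are ignored; an inactive whose id
#' already exists among a set's actives is rejected. Both events are counted
#' in the attached summary.
#'
#' @param path Delimited text file with columns `compound_id`, `target_id`,
#'   `smiles` (per dialect).
#' @param sets Named list of [target_set()] objects.
#' @param dialect A [table_dialect()].
#' @return The updated list of target sets; attribute `summary` holds counts
#'   (`n_unknown_target`, `n_conflicts`, `n_bad_smiles`, `n_attached`).
#' @export
read_inactives <- function(path, sets, dialect = table_dialect()) {
  tab <- read_delim_table(path, dialect)
  require_columns(tab, c(dialect$compound_id, dialect$target_id,
                         dialect$smiles), path)
  n_unknown <- 0L; n_conflict <- 0L; n_bad <- 0L; n_attached <- 0L
  if (nrow(tab) > 0L) {
    for (i in seq_len(nrow(tab))) {
      tid <- tab[[dialect$target_id]][i]
      if (!tid %in% names(sets)) { n_unknown <- n_unknown + 1L; next }
      cid <- tab[[dialect$compound_id]][i]
      set <- sets[[tid]]
      if (cid %in% set$actives$compound_id) {
        n_conflict <- n_conflict + 1L; next
      }
      if (cid %in% set$inactives$compound_id) next  # duplicate record
      smi <- curate_smiles(tab[[dialect$smiles]][i])
      if (is.na(smi)) { n_bad <- n_bad + 1L; next }
      set$inactives <- rbind(set$inactives,
                             data.frame(compound_id = cid, smiles = smi,
                                        source = "screening",
                                        stringsAsFactors = FALSE))
      sets[[tid]] <- set
      n_attached <- n_attached + 1L
    }
  }
  attr(sets, "summary") <- list(n_unknown_target = n_unknown,
                                n_conflicts = n_conflict,
                                n_bad_smiles = n_bad,
                                n_attached = n_attached)
  sets
}

# ---- deposition format ------------------------------------------------------

# Numbers are serialized with %.17g so doubles round-trip exactly.
fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

deposition_header <- c("cliff_type", "compound_a", "smiles_a", "pki_a",
                       "compound_b", "smiles_b", "pki_b", "delta_pki",
                       "core_smiles", "sub_a_smiles", "sub_b_smiles")

#' Write cliff results to deposition files
#'
#' One UTF-8 tab-separated file per MMP family. Each target contributes a
#' '#TARGET' header line (target id, name, assay ids, AC-relevant potency
#' threshold, set threshold, cliff count) followed by one record per cliff.
#' Active partners carry a potency value; inactive partners (isd cliffs)
#' carry none. Output is byte-stable for a fixed input order.
#'
#' @param cliff_sets List of per-target results as produced by
#'   [run_pipeline()]: each element has `target_id`, `target_name`,
#'   `assay_ids`, `family`, `set_threshold`, `acrp_threshold` and a `cliffs`
#'   data.frame with the deposition record columns.
#' @param out_paths Character vector of length 2: output paths for the
#'   MMP-derived and RMMP-derived results.
#' @return Invisibly, the paths written.
#' @export
write_deposition <- function(cliff_sets, out_paths) {
  stopifnot(length(out_paths) == 2L)
  fams <- c("MMP", "RMMP")
  for (fi in 1:2) {
    lines <- c(paste0("#FORMAT\tacmine-deposition\t1\t", fams[fi]),
               paste(c("#COLUMNS", deposition_header), collapse = "\t"))
    for (entry in cliff_sets) {
      if (!identical(entry$family, fams[fi])) next
      lines <- c(lines, paste(
        c("#TARGET", entry$target_id, entry$target_name,
          paste(entry$assay_ids, collapse = ";"),
          fmt_num(entry$acrp_threshold), fmt_num(entry$set_threshold),
          as.character(nrow(entry$cliffs))), collapse = "\t"))
      cl <- entry$cliffs
      if (nrow(cl) > 0L) {
        recs <- vapply(seq_len(nrow(cl)), function(i) {
          paste(c(cl$cliff_type[i], cl$compound_a[i], cl$smiles_a[i],
                  fmt_num(cl$pki_a[i]), cl$compound_b[i], cl$smiles_b[i],
                  fmt_num(cl$pki_b[i]), fmt_num(cl$delta_pki[i]),
                  cl$core_smiles[i], cl$sub_a_smiles[i], cl$sub_b_smiles[i]),
                collapse = "\t")
        }, character(1))
        lines <- c(lines, recs)
      }
    }
    con <- file(out_paths[fi], open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(out_paths)
}

parse_num <- function(x) ifelse(nzchar(x), as.numeric(x), NA_real_)

#' Read deposition files written by [write_deposition()]
#'
#' Exact inverse of the writer on well-formed files; malformed lines raise a
#' format error naming the offending line number.
#'
#' @param paths Character vector of deposition file paths (typically the two
#'   per-family files).
#' @return List of per-target entries with the same structure the writer
#'   consumes.
#' @export
read_deposition <- function(paths) {
  out <- list()
  for (path in paths) {
    lines <- readLines(path, warn = FALSE)
    fam <- deposition_family(lines)
    entry <- NULL
    expect_n <- 0L
    for (ln in seq_along(lines)) {
      line <- lines[ln]
      if (!nzchar(line)) next
      f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
      if (startsWith(line, "#FORMAT") || startsWith(line, "#COLUMNS")) next
      if (startsWith(line, "#TARGET")) {
        if (!is.null(entry) && nrow(entry$cliffs) != expect_n) {
          stop(sprintf("%s: truncated cliff block before line %d", path, ln),
               call. = FALSE)
        }
        if (length(f) != 7L) {
          stop(sprintf("%s: malformed #TARGET header at line %d", path, ln),
               call. = FALSE)
        }
        if (!is.null(entry)) out[[length(out) + 1L]] <- entry
        entry <- list(target_id = f[2L], target_name = f[3L],
                      assay_ids = if (nzchar(f[4L]))
                        strsplit(f[4L], ";", fixed = TRUE)[[1L]] else
                        character(0),
                      family = fam,
                      acrp_threshold = parse_num(f[5L]),
                      set_threshold = parse_num(f[6L]),
                      cliffs = empty_cliff_records())
        expect_n <- as.integer(f[7L])
        next
      }
      if (is.null(entry)) {
        stop(sprintf("%s: record before any #TARGET header at line %d",
                     path, ln), call. = FALSE)
      }
      if (length(f) != length(deposition_header)) {
        stop(sprintf("%s: malformed record at line %d (%d fields, expected %d)",
                     path, ln, length(f), length(deposition_header)),
             call. = FALSE)
      }
      rec <- data.frame(cliff_type = f[1L], compound_a = f[2L],
                        smiles_a = f[3L], pki_a = parse_num(f[4L]),
                        compound_b = f[5L], smiles_b = f[6L],
                        pki_b = parse_num(f[7L]), delta_pki = parse_num(f[8L]),
                        core_smiles = f[9L], sub_a_smiles = f[10L],
                        sub_b_smiles = f[11L], stringsAsFactors = FALSE)
      entry$cliffs <- rbind(entry$cliffs, rec)
    }
    if (!is.null(entry)) {
      if (nrow(entry$cliffs) != expect_n) {
        stop(sprintf("%s: truncated cliff block at end of file", path),
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- entry
    }
  }
  out
}

deposition_family <- function(lines) {
  fmt <- lines[startsWith(lines, "#FORMAT")]
  if (length(fmt) == 1L) {
    f <- strsplit(fmt, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 4L) return(f[4L])
  }
  NA_character_
}

empty_cliff_records <- function() {
  data.frame(cliff_type = character(0), compound_a = character(0),
             smiles_a = character(0), pki_a = numeric(0),
             compound_b = character(0), smiles_b = character(0),
             pki_b = numeric(0), delta_pki = numeric(0),
             core_smiles = character(0), sub_a_smiles = character(0),
             sub_b_smiles = character(0), stringsAsFactors = FALSE)
}
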
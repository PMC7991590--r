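## Readers and writers for the tabular formats the pipeline touches.
## All tables use 1-based residue indices in the coordinate system of the
## DMS dataset; `numbering_offset` (see run_predict) maps structure
## numbering onto DMS numbering when the two disagree.

# sniff TSV vs CSV from the header line; decimal points only, never commas
detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop_format("empty file: %s", path)
  if (grepl("\t", first)) "\t" else ","
}

read_delim_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          na.strings = c("NA", ""))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop_format("malformed header in %s: missing column(s) %s",
                path, paste(missing_cols, collapse = ", "))
  }
  df
}

check_positions <- function(position, where) {
  if (any(!is.finite(position)) || any(position < 1) ||
      any(position != floor(position))) {
    bad <- which(!is.finite(position) | position < 1 | position != floor(position))[1]
    stop_validation("%s: position must be a positive integer (row %d)", where, bad)
  }
  as.integer(position)
}

check_aa <- function(aa, what, where) {
  aa <- toupper(trimws(aa))
  bad <- which(!aa %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    stop_validation("%s: %s '%s' at row %d is not a canonical amino acid",
                    where, what, aa[bad[1]], bad[1])
  }
  aa
}

#' Construct a validated per-mutation effect score table
#'
#' The central input type: one row per observed single amino-acid
#' substitution with its raw, dimensionless mutational effect score
#' (typically a log-transformed enrichment ratio with wild type near 0).
#' Missing mutants are represented by absence, never by sentinel scores.
#'
#' @param position 1-based residue indices.
#' @param wt_aa,mut_aa One-letter amino acid codes; `wt_aa` must be
#'   consistent within a position and differ from `mut_aa`.
#' @param score Numeric raw effect scores.
#' @param dataset_id Optional label carried through to reports.
#' @return A `data.frame` of class `mut_effect_table` with columns
#'   `position`, `wt_aa`, `mut_aa`, `score`.
#' @export
mut_effect_table <- function(position, wt_aa, mut_aa, score, dataset_id = NA_character_) {
  where <- "mut_effect_table"
  position <- check_positions(position, where)
  wt_aa <- check_aa(wt_aa, "wt_aa", where)
  mut_aa <- check_aa(mut_aa, "mut_aa", where)
  if (!is.numeric(score)) stop_validation("%s: score must be numeric", where)
  if (any(!is.finite(score))) {
    stop_validation("%s: non-numeric or missing score at row %d",
                    where, which(!is.finite(score))[1])
  }
  same <- which(wt_aa == mut_aa)
  if (length(same) > 0L) {
    stop_validation("%s: wt_aa equals mut_aa at position %d",
                    where, position[same[1]])
  }
  key <- paste(position, mut_aa)
  if (anyDuplicated(key)) {
    dup <- position[which(duplicated(key))[1]]
    stop_validation("%s: duplicate mutant at position %d", where, dup)
  }
  wt_by_pos <- tapply(wt_aa, position, function(x) length(unique(x)))
  if (any(wt_by_pos > 1L)) {
    stop_validation("%s: inconsistent wt_aa at position %s", where,
                    names(wt_by_pos)[which(wt_by_pos > 1L)[1]])
  }
  out <- data.frame(position = position, wt_aa = wt_aa, mut_aa = mut_aa,
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(out$position, out$mut_aa), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("mut_effect_table", "data.frame"),
            dataset_id = dataset_id)
}

#' Read a per-mutation effect score table
#'
#' Two dialects are supported. `long`: one row per mutant with header
#' columns `position`, `wt_aa`, `mut_aa`, `score`. `matrix`: one row per
#' position with columns `position`, `wt_aa` and one column per amino
#' acid; empty cells are missing mutants and the wild-type cell is
#' ignored (a synonymous "substitution" is not a mutant). Both dialects
#' of the same dataset yield identical record sets.
#'
#' @param path TSV or CSV file (separator sniffed from the header).
#' @param dialect `"long"` or `"matrix"`.
#' @param dataset_id Optional label; defaults to the file name.
#' @return A [mut_effect_table].
#' @export
read_mut_effect_table <- function(path, dialect = c("long", "matrix"),
                                  dataset_id = NULL) {
  dialect <- match.arg(dialect)
  dataset_id <- dataset_id %||% basename(path)
  if (dialect == "long") {
    df <- read_delim_checked(path, c("position", "wt_aa", "mut_aa", "score"))
    if (!is.numeric(df$score)) {
      bad <- which(is.na(suppressWarnings(as.numeric(df$score))) & !is.na(df$score))
      stop_validation("non-numeric score at row %d of %s",
                      if (length(bad)) bad[1] else which(is.na(df$score))[1], path)
    }
    if (any(is.na(df$score))) {
      stop_validation("non-numeric or missing score at row %d of %s",
                      which(is.na(df$score))[1], path)
    }
    mut_effect_table(df$position, df$wt_aa, df$mut_aa, df$score, dataset_id)
  } else {
    df <- read_delim_checked(path, c("position", "wt_aa"))
    aa_cols <- intersect(names(df), AA_ALPHABET)
    if (length(aa_cols) == 0L) {
      stop_format("matrix dialect needs amino-acid columns in %s", path)
    }
    recs <- lapply(seq_len(nrow(df)), function(i) {
      wt <- toupper(trimws(df$wt_aa[i]))
      vals <- unlist(df[i, aa_cols])
      keep <- !is.na(vals) & aa_cols != wt
      if (!any(keep)) return(NULL)
      data.frame(position = df$position[i], wt_aa = wt,
                 mut_aa = aa_cols[keep],
                 score = as.numeric(vals[keep]),
                 stringsAsFactors = FALSE)
    })
    recs <- do.call(rbind, recs)
    if (is.null(recs)) stop_format("no mutant records in %s", path)
    mut_effect_table(recs$position, recs$wt_aa, recs$mut_aa, recs$score,
                     dataset_id)
  }
}

#' Construct a validated per-residue accessibility table
#'
#' @param position 1-based residue indices, unique.
#' @param rel_acc Percent relative side-chain accessibility, `>= 0`
#'   (values above 100 are permitted: extended conformations can exceed
#'   the reference state).
#' @param source `"structure"` (e.g. NACCESS on a PDB entry) or
#'   `"sequence_predicted"` (e.g. PROF, NetSurfP, SPIDER3).
#' @param method Free-text provenance tag.
#' @return A `data.frame` of class `accessibility_table`.
#' @export
accessibility_table <- function(position, rel_acc,
                                source = c("sequence_predicted", "structure"),
                                method = NA_character_) {
  source <- match.arg(source)
  position <- check_positions(position, "accessibility_table")
  if (anyDuplicated(position)) {
    stop_validation("accessibility_table: duplicate position %d",
                    position[which(duplicated(position))[1]])
  }
  if (any(!is.finite(rel_acc)) || any(rel_acc < 0)) {
    stop_validation("accessibility_table: rel_acc must be finite and >= 0 (position %d)",
                    position[which(!is.finite(rel_acc) | rel_acc < 0)[1]])
  }
  out <- data.frame(position = position, rel_acc = as.numeric(rel_acc),
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("accessibility_table", "data.frame"),
            source = source, method = method)
}

#' Accessibility source tag
#' @param acc An [accessibility_table].
#' @return `"structure"` or `"sequence_predicted"`.
#' @export
acc_source <- function(acc) attr(acc, "source")

#' Read a NACCESS .rsa file
#'
#' Parses the fixed-layout `RES` lines of a NACCESS relative
#' accessibility file and returns the *side-chain* relative accessibility
#' (the burial rule is defined on side-chain accessibility, so the
#' all-atom column is deliberately not used).
#'
#' @param path Path to a `.rsa` file.
#' @param chain Chain identifier to select. May be omitted when the file
#'   contains a single chain; required otherwise.
#' @return An [accessibility_table] with `source = "structure"`.
#' @export
read_rsa <- function(path, chain = NULL) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  res <- lines[startsWith(lines, "RES ")]
  if (length(res) == 0L) stop_format("no RES lines in %s", path)
  chains <- trimws(substr(res, 9, 9))
  resnum <- suppressWarnings(as.integer(trimws(substr(res, 10, 13))))
  # numeric block: abs/rel all-atoms, abs/rel side-chain, then main-chain etc.
  nums <- lapply(strsplit(trimws(substr(res, 14, nchar(res))), "\\s+"),
                 function(x) suppressWarnings(as.numeric(x)))
  sc_rel <- vapply(nums, function(x) if (length(x) >= 4) x[4] else NA_real_,
                   numeric(1))
  if (any(is.na(resnum)) || any(is.na(sc_rel))) {
    stop_format("unparseable RES line %d in %s",
                which(is.na(resnum) | is.na(sc_rel))[1], path)
  }
  uniq <- unique(chains)
  if (is.null(chain)) {
    if (length(uniq) > 1L) {
      stop_lookup("%s contains chains %s; pass `chain` to select one",
                  path, paste(uniq, collapse = ", "))
    }
    chain <- uniq
  }
  if (!chain %in% uniq) {
    stop_lookup("chain '%s' not present in %s (available: %s)",
                chain, path, paste(uniq, collapse = ", "))
  }
  keep <- chains == chain
  # NACCESS reports negative rel values for residues with no side chain
  # atoms resolved; clip to 0 as they are operationally fully buried
  accessibility_table(resnum[keep], pmax(sc_rel[keep], 0),
                      source = "structure", method = "naccess")
}

#' Read a generic per-residue accessibility table
#'
#' Carrier for sequence-based accessibility predictor exports (PROF,
#' NetSurfP, SPIDER3, ...): TSV/CSV with columns `position`, `rel_acc`
#' and an optional `method` column.
#'
#' @param path TSV or CSV file.
#' @return An [accessibility_table] with `source = "sequence_predicted"`.
#' @export
read_accessibility_table <- function(path) {
  df <- read_delim_checked(path, c("position", "rel_acc"))
  method <- if ("method" %in% names(df)) as.character(df$method[1]) else NA_character_
  accessibility_table(df$position, df$rel_acc,
                      source = "sequence_predicted", method = method)
}

TRUTH_CLASSES <- c("active_site", "buried", "exposed_nonactive")

#' Construct residue truth labels for evaluation
#'
#' @param position 1-based residue indices, unique.
#' @param true_class One of `"active_site"`, `"buried"`,
#'   `"exposed_nonactive"` per position.
#' @param exclusions Positions to omit from buried-class prediction and
#'   evaluation (e.g. metal-coordinating cysteines that are buried but
#'   catalytically essential, hence labelled active-site).
#' @return A `data.frame` of class `residue_truth`.
#' @export
residue_truth <- function(position, true_class, exclusions = integer()) {
  position <- check_positions(position, "residue_truth")
  if (anyDuplicated(position)) {
    stop_validation("residue_truth: duplicate position %d",
                    position[which(duplicated(position))[1]])
  }
  true_class <- as.character(true_class)
  bad <- which(!true_class %in% TRUTH_CLASSES)
  if (length(bad) > 0L) {
    stop_validation("residue_truth: unknown class '%s' at position %d",
                    true_class[bad[1]], position[bad[1]])
  }
  out <- data.frame(position = position, true_class = true_class,
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("residue_truth", "data.frame"),
            exclusions = as.integer(sort(unique(exclusions))))
}

#' Read truth labels from a TSV/CSV file
#'
#' Header `position`, `true_class`, optionally `excluded` (0/1 flag
#' feeding the buried-call exclusion list).
#'
#' @param path TSV or CSV file.
#' @return A [residue_truth].
#' @export
read_truth <- function(path) {
  df <- read_delim_checked(path, c("position", "true_class"))
  excl <- if ("excluded" %in% names(df)) df$position[df$excluded %in% c(1, TRUE)] else integer()
  residue_truth(df$position, df$true_class, exclusions = excl)
}

#' Truth exclusion list
#' @param truth A [residue_truth].
#' @return Integer vector of excluded positions.
#' @export
truth_exclusions <- function(truth) attr(truth, "exclusions") %||% integer()

#' Write a prediction table to TSV
#'
#' Columns `position`, `z_mut_sens`, `z_acc`, `score_active`,
#' `score_buried`, `predicted_class`, `flags`, sorted by position,
#' numeric columns at 6 decimals so a round-trip through
#' [read_predictions] reproduces the table at printed precision.
#'
#' @param predictions A non-empty prediction table (see [assign_classes]).
#' @param path Output file path.
#' @export
write_predictions <- function(predictions, path) {
  if (is.null(predictions) || nrow(predictions) == 0L) {
    stop_validation("write_predictions: empty prediction set")
  }
  df <- predictions[order(predictions$position),
                    c("position", "z_mut_sens", "z_acc", "score_active",
                      "score_buried", "predicted_class", "flags")]
  for (col in c("z_mut_sens", "z_acc", "score_active", "score_buried")) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_dmsites("dmsites_io_error", "cannot write %s: %s",
                                path, conditionMessage(ok))
  invisible(path)
}

#' Read back a prediction table written by [write_predictions]
#' @param path TSV file.
#' @return A `data.frame` of class `prediction_table`.
#' @export
read_predictions <- function(path) {
  df <- read_delim_checked(path, c("position", "z_mut_sens", "z_acc",
                                   "score_active", "score_buried",
                                   "predicted_class", "flags"))
  df$position <- check_positions(df$position, "read_predictions")
  df$flags <- ifelse(is.na(df$flags), "", as.character(df$flags))
  structure(df, class = c("prediction_table", "data.frame"))
}
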
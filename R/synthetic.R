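## Seeded generator of synthetic saturation-mutagenesis datasets with the
## substitution-preference structure seen in real DMS data:
##   - active-site residues: deleterious for every substitution category;
##   - buried residues: deleterious for polar/charged/aromatic (and Pro),
##     neutral with probability `aliphatic_tolerance` for aliphatic
##     substitutions, except when the wild type is Ala or Gly (no room to
##     repack, every substitution hurts);
##   - exposed non-active-site residues: neutral.
## Raw scores live on a log-ratio-like scale with wild type near 0.

#' Configuration of the synthetic dataset generator
#'
#' Defaults describe a mid-sized single-domain protein under a phenotypic
#' screen where roughly a third of substitutions have measurable effects:
#' 200 positions, 10% active-site / 25% buried / 65% exposed
#' non-active-site, deleterious effects of -4 +/- 1 on the raw log-ratio
#' scale against neutral noise of SD 0.3, 70% of aliphatic substitutions
#' tolerated at buried positions, a sequence-based accessibility
#' predictor of quality r = 0.9, and 10% of mutants unobserved.
#'
#' @param n_positions Number of mutagenized positions (>= 10).
#' @param class_fractions Named or ordered fractions
#'   (active_site, buried, exposed_nonactive) summing to 1.
#' @param wt_score_sd SD of neutral scores around 0 (raw scale).
#' @param deleterious_mean,deleterious_sd Raw-scale effect of deleterious
#'   mutants.
#' @param aliphatic_tolerance Probability an aliphatic substitution at a
#'   buried position is neutral.
#' @param target_r Desired Pearson correlation between true and predicted
#'   accessibility, in (0, 1].
#' @param missing_rate Probability a mutant is unobserved, in [0, 1).
#' @param seed Integer seed; all three generators derive their RNG state
#'   from it, so a config reproduces its dataset exactly.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_positions = 200,
                             class_fractions = c(active_site = 0.10,
                                                 buried = 0.25,
                                                 exposed_nonactive = 0.65),
                             wt_score_sd = 0.3,
                             deleterious_mean = -4,
                             deleterious_sd = 1,
                             aliphatic_tolerance = 0.7,
                             target_r = 0.9,
                             missing_rate = 0.1,
                             seed = 1L) {
  f <- unname(class_fractions)
  if (length(f) != 3L || any(f < 0) || any(f > 1) || abs(sum(f) - 1) > 1e-9) {
    stop_validation("synthetic_config: class_fractions must be 3 values in [0,1] summing to 1")
  }
  if (!(target_r > 0 && target_r <= 1)) {
    stop_validation("synthetic_config: target_r must be in (0, 1]")
  }
  if (!(missing_rate >= 0 && missing_rate < 1)) {
    stop_validation("synthetic_config: missing_rate must be in [0, 1)")
  }
  if (n_positions < 10) stop_validation("synthetic_config: n_positions must be >= 10")
  structure(list(n_positions = as.integer(n_positions),
                 class_fractions = stats::setNames(f, TRUTH_CLASSES),
                 wt_score_sd = wt_score_sd,
                 deleterious_mean = deleterious_mean,
                 deleterious_sd = deleterious_sd,
                 aliphatic_tolerance = aliphatic_tolerance,
                 target_r = target_r,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# largest-remainder apportionment of n among fractions
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  as.integer(counts)
}

#' Generate residue truth labels and structure accessibility
#'
#' Class counts follow largest-remainder rounding of the configured
#' fractions; class labels are shuffled over positions 1..n. Buried
#' residues draw relative side-chain accessibility uniformly from
#' [0, 5] percent, active-site and exposed residues from (5, 100], so the
#' 5% burial rule on the structure table recovers the buried labels
#' exactly by construction.
#'
#' @param cfg A [synthetic_config].
#' @return List with `truth` (a [residue_truth]) and `acc` (an
#'   [accessibility_table] with `source = "structure"`).
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n_positions
  counts <- apportion(n, cfg$class_fractions)
  labels <- sample(rep(TRUTH_CLASSES, counts))
  rel_acc <- ifelse(labels == "buried",
                    stats::runif(n, 0, 5),
                    stats::runif(n, 5, 100))
  list(truth = residue_truth(seq_len(n), labels),
       acc = accessibility_table(seq_len(n), rel_acc,
                                 source = "structure",
                                 method = "synthetic_structure"))
}

#' Generate a synthetic per-mutation effect score table
#'
#' Wild-type residues are drawn uniformly per class, except buried
#' positions which are biased 4:1 toward hydrophobic residues (the
#' aliphatic-tolerance rule references the wild-type identity). Each
#' position receives the 19 non-wild-type substitutions minus dropouts at
#' `missing_rate`; scores are drawn Normal(0, `wt_score_sd`) for neutral
#' and Normal(`deleterious_mean`, `deleterious_sd`) for deleterious
#' outcomes according to the class/category rules described above.
#'
#' @param truth A [residue_truth] from [generate_truth].
#' @param cfg A [synthetic_config].
#' @return A [mut_effect_table].
#' @export
generate_dms <- function(truth, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed + 1L)
  hydrophobic <- c(AA_CATEGORIES$aliphatic, setdiff(AA_CATEGORIES$aromatic, "H"))
  aliphatic <- AA_CATEGORIES$aliphatic
  n <- nrow(truth)
  wt_weights <- function(class) {
    w <- rep(1, 20)
    if (class == "buried") w[AA_ALPHABET %in% hydrophobic] <- 4
    w / sum(w)
  }
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- truth$true_class[i]
    wt <- sample(AA_ALPHABET, 1, prob = wt_weights(cls))
    muts <- setdiff(AA_ALPHABET, wt)
    muts <- muts[stats::runif(19) >= cfg$missing_rate]
    if (length(muts) == 0L) next
    deleterious <- switch(
      cls,
      active_site = rep(TRUE, length(muts)),
      exposed_nonactive = rep(FALSE, length(muts)),
      buried = {
        is_ali <- muts %in% aliphatic
        if (wt %in% c("A", "G")) rep(TRUE, length(muts))
        else !(is_ali & stats::runif(length(muts)) < cfg$aliphatic_tolerance)
      })
    score <- ifelse(deleterious,
                    stats::rnorm(length(muts), cfg$deleterious_mean, cfg$deleterious_sd),
                    stats::rnorm(length(muts), 0, cfg$wt_score_sd))
    recs[[i]] <- data.frame(position = truth$position[i], wt_aa = wt,
                            mut_aa = muts, score = score,
                            stringsAsFactors = FALSE)
  }
  recs <- do.call(rbind, recs)
  mut_effect_table(recs$position, recs$wt_aa, recs$mut_aa, recs$score,
                   dataset_id = sprintf("synthetic_seed%d", cfg$seed))
}

#' Generate noisy sequence-predicted accessibility
#'
#' Emulates a sequence-based accessibility predictor of a chosen quality:
#' the true accessibility is standardized, Gaussian noise of variance
#' `1/target_r^2 - 1` is added (so the expected Pearson correlation with
#' the truth is `target_r`), and the result is mapped back onto the
#' percent scale of the input and floored at 0. With `target_r = 1` the
#' prediction equals the truth.
#'
#' @param true_acc An [accessibility_table] (`source = "structure"`).
#' @param target_r Desired correlation, in (0, 1].
#' @param seed Integer seed.
#' @return An [accessibility_table] with `source = "sequence_predicted"`.
#' @export
generate_predicted_accessibility <- function(true_acc, target_r, seed) {
  if (!(target_r > 0 && target_r <= 1)) {
    stop_validation("generate_predicted_accessibility: target_r must be in (0, 1]")
  }
  set.seed(as.integer(seed) + 2L)
  x <- true_acc$rel_acc
  mu <- mean(x); s <- pop_sd(x)
  z <- (x - mu) / s
  sigma <- sqrt(1 / target_r^2 - 1)
  zp <- z + stats::rnorm(length(z), 0, sigma)
  pred <- pmax(mu + s * zp, 0)
  accessibility_table(true_acc$position, pred,
                      source = "sequence_predicted",
                      method = sprintf("synthetic_r%.2f", target_r))
}

#' Write a complete synthetic dataset to disk
#'
#' Produces the four standard pipeline inputs plus a JSON manifest:
#' `scores.tsv` (long-format effect scores), `accessibility_predicted.tsv`
#' (sequence-predicted table), `accessibility_structure.rsa` (a synthetic
#' NACCESS-layout file, chain A), `truth.tsv` (labels), and
#' `manifest.json` (full config incl. seed, sufficient to reproduce the
#' files exactly).
#'
#' @param cfg A [synthetic_config].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a named list of the generated objects and paths.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gt <- generate_truth(cfg)
  dms <- generate_dms(gt$truth, cfg)
  pred_acc <- generate_predicted_accessibility(gt$acc, cfg$target_r, cfg$seed)

  scores_path <- file.path(out_dir, "scores.tsv")
  utils::write.table(as.data.frame(dms), scores_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pred_path <- file.path(out_dir, "accessibility_predicted.tsv")
  utils::write.table(data.frame(position = pred_acc$position,
                                rel_acc = sprintf("%.4f", pred_acc$rel_acc),
                                method = attr(pred_acc, "method")),
                     pred_path, sep = "\t", quote = FALSE, row.names = FALSE)
  rsa_path <- file.path(out_dir, "accessibility_structure.rsa")
  write_rsa_synthetic(gt$acc, dms, rsa_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  utils::write.table(data.frame(position = gt$truth$position,
                                true_class = gt$truth$true_class),
                     truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(generator = "dmsites::simulate_dataset",
                            package_version = as.character(utils::packageVersion("dmsites")),
                            config = unclass(cfg),
                            files = list(scores = basename(scores_path),
                                         predicted_accessibility = basename(pred_path),
                                         structure_accessibility = basename(rsa_path),
                                         truth = basename(truth_path))),
                       manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = gt$truth, structure_acc = gt$acc, dms = dms,
                 predicted_acc = pred_acc,
                 paths = c(scores = scores_path, predicted = pred_path,
                           structure = rsa_path, truth = truth_path,
                           manifest = manifest_path)))
}

# NACCESS-layout .rsa writer for synthetic structure accessibility (clearly
# labelled synthetic: only the side-chain rel column carries signal; the
# other columns are placeholders). Residue names come from the DMS wt.
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

write_rsa_synthetic <- function(acc, dms, path) {
  wt <- tapply(dms$wt_aa, dms$position, function(x) x[1])
  res3 <- AA_THREE[wt[as.character(acc$position)]]
  res3[is.na(res3)] <- "GLY"
  lines <- c(
    "REM  Synthetic relative accessibility file (dmsites generator)",
    "REM  RES _ NUM      All-atoms   Total-Side   Main-Chain    Non-polar    All polar",
    "REM                 ABS   REL    ABS   REL    ABS   REL    ABS   REL    ABS   REL",
    sprintf("RES %3s A%4d  %7.2f%6.2f%7.2f%6.2f%7.2f%6.2f%7.2f%6.2f%7.2f%6.2f",
            res3, acc$position,
            acc$rel_acc * 1.5, acc$rel_acc, acc$rel_acc * 1.2, acc$rel_acc,
            acc$rel_acc * 0.3, acc$rel_acc, acc$rel_acc * 0.8, acc$rel_acc,
            acc$rel_acc * 0.7, acc$rel_acc))
  writeLines(lines, path)
  invisible(path)
}
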
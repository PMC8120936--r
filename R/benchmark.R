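# Decoy-set benchmarking: pairwise ranking accuracy per quality category,
# per-target correlations, average predicted ranks, scorer comparisons and
# class-based subsetting.
#
# A decoy table is a plain data.frame with one row per scored model:
# columns target_id, model_id, tm (TM-score to native), score (lower =
# better) and is_native (logical).

#' Validate a decoy table
#'
#' @param table data.frame with columns `target_id`, `model_id`, `tm`,
#'   `score`, `is_native` (the last defaults to `FALSE` if absent).
#' @return the table, checked and with `is_native` filled in.
#' @export
as_decoy_table <- function(table) {
  needed <- c("target_id", "model_id", "tm", "score")
  missing <- setdiff(needed, names(table))
  if (length(missing))
    stop("decoy table lacks columns: ", paste(missing, collapse = ", "))
  if (is.null(table$is_native)) table$is_native <- FALSE
  if (any(table$tm < 0 | table$tm > 1, na.rm = TRUE))
    stop("tm values must lie in [0, 1]")
  if (any(table$is_native & abs(table$tm - 1) > 1e-9))
    stop("native records must have tm = 1")
  id <- paste(table$target_id, table$model_id)
  if (anyDuplicated(id)) stop("(target_id, model_id) must be unique")
  if (any(tabulate(factor(table$target_id)) < 2L))
    stop("every target needs at least 2 records")
  table
}

#' Pairwise ranking accuracy per quality category
#'
#' Within each target, every unordered pair of models whose TM-scores differ
#' by at least `min_delta_tm` is ranked by the scoring function; a pair is
#' correct when the model with the higher TM-score received the lower
#' (better) score. Pairs are pooled over targets and attributed to the
#' quality category of the higher-TM member (configurable). A random scorer
#' yields 50% accuracy.
#'
#' @param table decoy table (see [as_decoy_table()]).
#' @param min_delta_tm minimum TM-score difference for a pair to count;
#'   default 0.1.
#' @param attribution category attribution of a pair spanning two
#'   categories: `"higher"` (default; higher-TM member), `"lower"`, or
#'   `"both"` (counted in both categories; the overall row still counts each
#'   pair once).
#' @param per_target if `TRUE`, accuracies are computed per target and then
#'   averaged; default pools pairs over targets.
#' @return data.frame with columns `category`, `n_pairs`, `accuracy` (%),
#'   one row per quality category plus `"overall"`. Categories with no
#'   qualifying pairs report `NA`.
#' @export
pairwise_accuracy <- function(table, min_delta_tm = 0.1,
                              attribution = c("higher", "lower", "both"),
                              per_target = FALSE) {
  table <- as_decoy_table(table)
  attribution <- match.arg(attribution)
  per_tgt <- lapply(split(table, table$target_id), function(d) {
    n <- nrow(d)
    if (n < 2L) return(NULL)
    ij <- utils::combn(n, 2L)
    dtm <- d$tm[ij[1L, ]] - d$tm[ij[2L, ]]
    keep <- abs(dtm) >= min_delta_tm
    if (!any(keep)) return(NULL)
    i <- ij[1L, keep]; j <- ij[2L, keep]; dtm <- dtm[keep]
    hi <- ifelse(dtm > 0, i, j); lo <- ifelse(dtm > 0, j, i)
    correct <- d$score[hi] < d$score[lo]
    data.frame(cat_hi = quality_category(d$tm[hi]),
               cat_lo = quality_category(d$tm[lo]),
               correct = correct, target_id = d$target_id[1L],
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, per_tgt[!vapply(per_tgt, is.null, TRUE)])
  acc_rows <- function(p) {
    by_cat <- function(cat) {
      sel <- switch(attribution,
                    higher = p$cat_hi == cat,
                    lower  = p$cat_lo == cat,
                    both   = p$cat_hi == cat | p$cat_lo == cat)
      n <- sum(sel)
      data.frame(category = cat, n_pairs = n,
                 accuracy = if (n) 100 * mean(p$correct[sel]) else NA_real_,
                 stringsAsFactors = FALSE)
    }
    rbind(do.call(rbind, lapply(QUALITY_LEVELS, by_cat)),
          data.frame(category = "overall", n_pairs = nrow(p),
                     accuracy = if (nrow(p)) 100 * mean(p$correct)
                                else NA_real_))
  }
  if (is.null(pairs))
    return(acc_rows(data.frame(cat_hi = character(0), cat_lo = character(0),
                               correct = logical(0))))
  if (!per_target) return(acc_rows(pairs))
  per <- lapply(split(pairs, pairs$target_id), acc_rows)
  out <- per[[1L]]
  out$accuracy <- rowMeans(do.call(cbind, lapply(per, `[[`, "accuracy")),
                           na.rm = TRUE)
  out$n_pairs <- Reduce(`+`, lapply(per, `[[`, "n_pairs"))
  out
}

# Per-pair correctness indicators for one scorer, on the qualifying pair set
# (used to compare two scorers on identical pairs).
pair_outcomes <- function(table, min_delta_tm = 0.1) {
  table <- as_decoy_table(table)
  out <- lapply(split(table, table$target_id), function(d) {
    n <- nrow(d)
    if (n < 2L) return(logical(0))
    ij <- utils::combn(n, 2L)
    dtm <- d$tm[ij[1L, ]] - d$tm[ij[2L, ]]
    keep <- abs(dtm) >= min_delta_tm
    i <- ij[1L, keep]; j <- ij[2L, keep]; dtm <- dtm[keep]
    hi <- ifelse(dtm > 0, i, j); lo <- ifelse(dtm > 0, j, i)
    d$score[hi] < d$score[lo]
  })
  unlist(out, use.names = FALSE)
}

#' Mean per-target correlations between score and TM-score
#'
#' Pearson, Spearman and Kendall correlations between the TM-score and the
#' negated score (so perfect agreement gives +1), computed per target and
#' averaged without weighting. Targets with fewer than 3 models or zero
#' score/tm variance are skipped with a warning.
#'
#' @param table decoy table.
#' @return list with `pearson`, `spearman`, `kendall` (mean over targets)
#'   and `n_targets` used.
#' @export
per_target_correlations <- function(table) {
  table <- as_decoy_table(table)
  per <- lapply(split(table, table$target_id), function(d) {
    if (nrow(d) < 3L || stats::sd(d$score) == 0 || stats::sd(d$tm) == 0)
      return(NULL)
    c(pearson = stats::cor(d$tm, -d$score, method = "pearson"),
      spearman = stats::cor(d$tm, -d$score, method = "spearman"),
      kendall = stats::cor(d$tm, -d$score, method = "kendall"))
  })
  skipped <- vapply(per, is.null, TRUE)
  if (any(skipped))
    warning(sum(skipped), " target(s) skipped (too few models or zero variance)")
  if (all(skipped)) stop("no target has enough score variance to correlate")
  m <- do.call(rbind, per[!skipped])
  list(pearson = mean(m[, "pearson"]), spearman = mean(m[, "spearman"]),
       kendall = mean(m[, "kendall"]), n_targets = sum(!skipped))
}

#' Average predicted rank of a quality category
#'
#' Within each target all records are ranked by ascending score (rank 1 =
#' best score; ties get mean ranks); the ranks of the records whose
#' TM-score falls in the requested category are pooled over targets and
#' averaged. For near-native and good models, lower is better.
#'
#' @param table decoy table.
#' @param category one of `"near_native"`, `"good"`, `"medium"`, `"poor"`.
#' @param include_native include native records (tm = 1) in the rankings;
#'   default `TRUE`.
#' @return mean predicted rank, or `NA` if the category is empty.
#' @export
average_predicted_rank <- function(table, category,
                                   include_native = TRUE) {
  table <- as_decoy_table(table)
  category <- match.arg(category, QUALITY_LEVELS)
  if (!include_native) table <- table[!table$is_native, , drop = FALSE]
  ranks <- unlist(lapply(split(table, table$target_id), function(d) {
    r <- rank(d$score, ties.method = "average")
    r[quality_category(d$tm) == category]
  }), use.names = FALSE)
  if (!length(ranks)) return(NA_real_)
  mean(ranks)
}

#' Compare two scorers on paired outcomes
#'
#' Wilcoxon signed-rank test on per-pair correctness indicators of two
#' scorers evaluated on the identical pair set; zero differences are dropped
#' per standard practice. Significance at alpha = 0.05.
#'
#' @param outcomes_a,outcomes_b equal-length logical/0-1 vectors.
#' @return list with `p_value`, `significant`, `n_discordant`.
#' @export
compare_scorers <- function(outcomes_a, outcomes_b) {
  a <- as.numeric(outcomes_a); b <- as.numeric(outcomes_b)
  if (length(a) != length(b)) stop("outcome sequences must have equal length")
  d <- a - b
  if (all(d == 0))
    return(list(p_value = NA_real_, significant = FALSE, n_discordant = 0L))
  p <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  list(p_value = p, significant = is.finite(p) && p < 0.05,
       n_discordant = sum(d != 0))
}

#' Full benchmark of a scored decoy table
#'
#' @param table decoy table.
#' @param min_delta_tm pairwise-accuracy threshold; default 0.1.
#' @return list of class `benchmark_result`: `accuracy` (per-category
#'   data.frame), `correlations`, `ranks` (near_native/good/poor),
#'   `n_structures`.
#' @export
benchmark_decoys <- function(table, min_delta_tm = 0.1) {
  table <- as_decoy_table(table)
  structure(list(
    accuracy = pairwise_accuracy(table, min_delta_tm),
    correlations = suppressWarnings(tryCatch(per_target_correlations(table),
                                             error = function(e) NULL)),
    ranks = list(
      near_native = average_predicted_rank(table, "near_native"),
      good = average_predicted_rank(table, "good"),
      poor = average_predicted_rank(table, "poor")),
    n_structures = nrow(table)),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark of %d structures>\n", x$n_structures))
  print(x$accuracy, row.names = FALSE)
  invisible(x)
}

#' Benchmark per structural class
#'
#' Splits the targets by a class labeling (e.g. mainly-alpha / mainly-beta /
#' alpha-beta) and recomputes the full benchmark per class. Unlabeled
#' targets are excluded with a warning.
#'
#' @param table decoy table.
#' @param labels named character vector (names = target ids) or 2-column
#'   data.frame (target_id, class).
#' @param min_delta_tm passed to [benchmark_decoys()].
#' @return named list class -> `benchmark_result`.
#' @export
subset_by_class <- function(table, labels, min_delta_tm = 0.1) {
  table <- as_decoy_table(table)
  if (is.data.frame(labels)) {
    lab <- as.character(labels[[2L]]); names(lab) <- as.character(labels[[1L]])
  } else lab <- labels
  cls <- lab[as.character(table$target_id)]
  if (any(is.na(cls))) {
    warning("excluding ", length(unique(table$target_id[is.na(cls)])),
            " unlabeled target(s)")
    table <- table[!is.na(cls), , drop = FALSE]
    cls <- cls[!is.na(cls)]
  }
  lapply(split(table, cls), benchmark_decoys, min_delta_tm = min_delta_tm)
}
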
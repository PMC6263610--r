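#' Cover rate of a predicted segment over a true leaf
#'
#' Fraction of the true leaf's points captured by the predicted segment:
#' `|pred intersect truth| / |truth|`. Point count stands in for area,
#' which is adequate under near-uniform sampling.
#'
#' @param pred_points integer ids of the predicted segment's points.
#' @param truth_points integer ids of the true leaf's points (nonempty).
#' @return A fraction in `[0, 1]`.
#' @export
cover_rate <- function(pred_points, truth_points) {
  if (length(truth_points) == 0) {
    abort("True leaf is empty; cover rate undefined.")
  }
  length(intersect(pred_points, truth_points)) / length(truth_points)
}

#' Match a predicted segmentation against ground truth
#'
#' Leaf-level scoring under the 70%-coverage rule:
#' * **TP** -- a real leaf is a true positive when some predicted segment
#'   covers strictly more than `coverage` (70%) of its points. Each real
#'   leaf is creditable once, and each predicted segment credits at most
#'   one leaf.
#' * **FP** -- a predicted segment under which two (or more) real leaves
#'   are each majority-covered counts as a merge: one false positive per
#'   merged pair, and the merged leaves are not credited as TPs through
#'   that segment.
#' * **FN** -- a real leaf more than `coverage` of whose points fall in no
#'   predicted segment (i.e. are unassigned) is a false negative.
#'
#' A leaf covered only partially (no segment above the TP cut, but less
#' than the FN cut uncovered) is neither TP nor FN; it shows up as the
#' shortfall against `reference`.
#'
#' @param pred integer per-point predicted labels (`-1`/`NA` = unassigned).
#' @param truth integer per-point true leaf labels (`-1`/`NA` = non-leaf).
#' @param coverage the coverage threshold (default 0.7); both the TP and
#'   FN rules are strict (`>`).
#' @return An object of class `leaf_eval`: list with counts `tp`, `fp`,
#'   `fn`, `reference` (number of real leaves) and `cover_rates`, a tibble
#'   with one row per real leaf (`truth_label`, `n_points`, `cover_rate`
#'   of its best-covering segment, `matched` flag).
#' @examples
#' truth <- c(1, 1, 1, 2, 2, 2)
#' pred <- c(1, 1, 1, 2, 2, -1)
#' ev <- match_segments(pred, truth)
#' glance(ev)
#' @export
match_segments <- function(pred, truth, coverage = 0.7) {
  if (length(pred) != length(truth)) {
    abort(paste0("Label vectors differ in length (", length(pred), " vs ",
                 length(truth), ")."))
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  pred[is.na(pred)] <- -1L
  truth[is.na(truth)] <- -1L
  leaf_ids <- sort(unique(truth[truth >= 0]))
  seg_ids <- sort(unique(pred[pred >= 0]))
  leaf_n <- vapply(leaf_ids, function(l) sum(truth == l), integer(1))
  # coverage[s, l]: fraction of leaf l's points inside segment s
  cov <- matrix(0, nrow = length(seg_ids), ncol = length(leaf_ids))
  if (length(seg_ids) && length(leaf_ids)) {
    tab <- table(factor(pred, levels = seg_ids),
                 factor(truth, levels = leaf_ids))
    cov <- sweep(unclass(tab), 2, leaf_n, "/")
  }
  # merge events: a segment majority-covering >= 2 leaves
  fp <- 0L
  merged <- matrix(FALSE, nrow = length(seg_ids), ncol = length(leaf_ids))
  for (s in seq_along(seg_ids)) {
    inside <- which(cov[s, ] > 0.5)
    if (length(inside) >= 2) {
      fp <- fp + (length(inside) - 1L)
      merged[s, inside] <- TRUE
    }
  }
  # TP: credit leaves in ascending label order; a segment credits one leaf
  tp <- 0L
  seg_used <- logical(length(seg_ids))
  matched <- logical(length(leaf_ids))
  for (l in seq_along(leaf_ids)) {
    cand <- which(cov[, l] > coverage & !merged[, l] & !seg_used)
    if (length(cand)) {
      best <- cand[which.max(cov[cand, l])]
      seg_used[best] <- TRUE
      matched[l] <- TRUE
      tp <- tp + 1L
    }
  }
  # FN: leaf mostly uncovered by any segmentation
  uncovered <- vapply(leaf_ids, function(l) {
    sum(truth == l & pred < 0) / sum(truth == l)
  }, numeric(1))
  fn <- sum(uncovered > coverage)
  best_cover <- if (length(seg_ids)) apply(cov, 2, max) else
    rep(0, length(leaf_ids))
  structure(list(
    tp = tp, fp = fp, fn = as.integer(fn),
    reference = length(leaf_ids),
    coverage = coverage,
    cover_rates = tibble(truth_label = leaf_ids, n_points = leaf_n,
                         cover_rate = as.numeric(best_cover),
                         matched = matched)
  ), class = "leaf_eval")
}

#' Segmentation quality metrics
#'
#' Leaf-level metrics from the TP/FP/FN counts, on the percentage scale:
#' recall `TP / (TP + FN) * 100`, precision `TP / (TP + FP) * 100`, and
#' F-measure `2 TP / (2 TP + FP + FN) * 100`. Undefined ratios (zero
#' denominator) are reported as `NA`.
#'
#' @param counts a `leaf_eval` from [match_segments()], or any list with
#'   `tp`, `fp`, `fn`.
#' @return A percentage in `[0, 100]`, or `NA`.
#' @examples
#' ev <- list(tp = 21, fp = 2, fn = 0)
#' seg_recall(ev)
#' seg_precision(ev)
#' seg_f_measure(ev)
#' @export
seg_recall <- function(counts) {
  if (counts$tp + counts$fn == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fn) * 100
}

#' @rdname seg_recall
#' @export
seg_precision <- function(counts) {
  if (counts$tp + counts$fp == 0) return(NA_real_)
  counts$tp / (counts$tp + counts$fp) * 100
}

#' @rdname seg_recall
#' @export
seg_f_measure <- function(counts) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(NA_real_)
  2 * counts$tp / den * 100
}

#' @export
print.leaf_eval <- function(x, ...) {
  cat("Leaf-level evaluation (coverage rule > ",
      format(x$coverage * 100), "%)\n", sep = "")
  print(glance(x))
  invisible(x)
}

#' @rdname match_segments
#' @param x a `leaf_eval`.
#' @param ... unused.
#' @method tidy leaf_eval
#' @export
tidy.leaf_eval <- function(x, ...) x$cover_rates

#' @rdname match_segments
#' @method glance leaf_eval
#' @export
glance.leaf_eval <- function(x, ...) {
  tibble(tp = x$tp, reference = x$reference, fp = x$fp, fn = x$fn,
         recall = seg_recall(x), precision = seg_precision(x),
         f_measure = seg_f_measure(x),
         mean_cover_rate = if (nrow(x$cover_rates)) {
           mean(x$cover_rates$cover_rate)
         } else {
           NA_real_
         })
}
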
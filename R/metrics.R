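# Detection and abundance metrics: TP/FP/FN sets, precision/recall/F1, the L1
# distance between relative-abundance vectors, relative-abundance threshold
# filtering, precision-recall curves and trapezoid AUPRC.

# Resolve ground-truth taxa to taxids at the evaluation rank. Species-level
# truths queried at genus rank map to their genus. Returns a character vector
# of unique taxids; errors listing any unresolvable taxon.
truth_taxa_at_rank <- function(truth, ref, rank) {
  stopifnot(inherits(truth, "ground_truth"), inherits(ref, "taxonomy_ref"))
  e <- truth$entries
  out <- character(nrow(e))
  bad <- character(0)
  for (i in seq_len(nrow(e))) {
    tid <- e$taxid[i]
    if (is.na(tid)) {
      nm <- tolower(e$name[i])
      if (!is.na(nm) && nm %in% names(ref$name_index)) {
        tid <- ref$name_index[[nm]]
      }
    } else {
      res <- resolve_taxid(ref, tid)
      tid <- if (res$status %in% c("current", "merged")) res$current_taxid
             else NA_integer_
    }
    if (is.na(tid)) {
      bad <- c(bad, if (!is.na(e$name[i])) e$name[i] else as.character(e$taxid[i]))
      next
    }
    anc <- ancestor_at_rank(ref, tid, rank)
    out[i] <- if (is.na(anc)) NA_character_ else as.character(anc)
  }
  if (length(bad) > 0L) {
    stop("unresolvable ground-truth taxa: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unique(out[!is.na(out)])
}

# Ground-truth abundance vector at the evaluation rank (species truths are
# aggregated by genus at genus rank). NULL when abundances are unavailable.
truth_abundance_at_rank <- function(truth, ref, rank,
                                    type = c("sequence", "taxonomic")) {
  type <- match.arg(type)
  if (!truth$abundances_available) return(NULL)
  e <- truth$entries
  ids <- character(nrow(e))
  for (i in seq_len(nrow(e))) {
    tid <- e$taxid[i]
    if (is.na(tid)) tid <- ref$name_index[[tolower(e$name[i])]]
    res <- resolve_taxid(ref, tid)
    anc <- ancestor_at_rank(ref, res$current_taxid, rank)
    ids[i] <- if (is.na(anc)) NA_character_ else as.character(anc)
  }
  keep <- !is.na(ids)
  w <- tapply(e$fraction[keep], ids[keep], sum)
  v <- abundance_vector(w / sum(w), rank = rank)
  if (type == "taxonomic") {
    L <- tapply(e$genome_length[keep], ids[keep], mean)
    v <- sequence_to_taxonomic(v, L)
  }
  v
}

#' Classify detections into true/false positives and false negatives
#'
#' A detected taxon present in the mock community is a TP; a detected taxon
#' absent from it is an FP; a community taxon that was not detected is an FN.
#' Identities are matched on synchronized taxids at the evaluation rank (truth
#' species map to their genus at genus rank), with name-index fallback for
#' name-only truth entries.
#'
#' @param predicted An `abundance_vector` over taxids at `rank` (typically
#'   from [renormalize_classified()], possibly after
#'   [apply_abundance_filter()]).
#' @param truth A `ground_truth`.
#' @param ref A `taxonomy_ref`.
#' @param rank `"genus"` or `"species"`.
#'
#' @return An object of class `detection_outcome`: list of character vectors
#'   `tp`, `fp`, `fn` (pairwise disjoint; `tp + fn` spans the truth,
#'   `tp + fp` spans the prediction).
#' @export
detection_sets <- function(predicted, truth, ref, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(predicted, "abundance_vector"))
  truth_taxa <- truth_taxa_at_rank(truth, ref, rank)
  pred_taxa <- names(predicted)
  structure(list(tp = intersect(pred_taxa, truth_taxa),
                 fp = setdiff(pred_taxa, truth_taxa),
                 fn = setdiff(truth_taxa, pred_taxa)),
            class = "detection_outcome")
}

#' Precision, recall and F1 from a detection outcome
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is their
#' harmonic mean, `2 * precision * recall / (precision + recall)`. Each is 0
#' when its denominator is 0, so a classifier that detects nothing scores 0
#' across the board rather than propagating NaN.
#'
#' @param outcome A `detection_outcome` from [detection_sets()].
#' @return A list with `precision`, `recall`, `f1` (each in \[0, 1\]) and the
#'   counts `tp`, `fp`, `fn`.
#' @export
confusion_metrics <- function(outcome) {
  tp <- length(outcome$tp); fp <- length(outcome$fp); fn <- length(outcome$fn)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' L1 distance between two relative-abundance vectors
#'
#' The sum of absolute differences `sum_i |p_i - q_i|` over the union of the
#' two supports, taxa absent from a vector contributing 0. On vectors that
#' each sum to 1 the distance ranges from 0 (every truth taxon detected at
#' exactly its expected abundance) to 2 (disjoint supports: no TP at all).
#'
#' @param p,q `abundance_vector`s at the same rank (ground truth and
#'   classifier output, in either order: the distance is symmetric).
#' @return A number in \[0, 2\].
#' @export
l1_distance <- function(p, q) {
  stopifnot(inherits(p, "abundance_vector"), inherits(q, "abundance_vector"))
  rp <- attr(p, "rank"); rq <- attr(q, "rank")
  if (!is.na(rp) && !is.na(rq) && rp != rq) {
    stop("abundance vectors are at different ranks: ", rp, " vs ", rq,
         call. = FALSE)
  }
  taxa <- union(names(p), names(q))
  pv <- unclass(p)[taxa]; pv[is.na(pv)] <- 0
  qv <- unclass(q)[taxa]; qv[is.na(qv)] <- 0
  sum(abs(pv - qv))
}

#' Remove taxa below a relative-abundance threshold
#'
#' Taxa whose weight is strictly below `t` are considered absent; a weight
#' exactly equal to the threshold is retained. The surviving weights are NOT
#' renormalized: detection after filtering is about which taxa remain, and
#' renormalizing would silently move every remaining taxon up the next
#' threshold.
#'
#' @param v An `abundance_vector`.
#' @param t Threshold as a fraction in \[0, 1\] (0.0005 for the commonly used
#'   0.05% cut).
#' @return The filtered vector, of class `filtered_abundance` /
#'   `abundance_vector` (its weights may sum to less than 1).
#' @export
apply_abundance_filter <- function(v, t) {
  stopifnot(inherits(v, "abundance_vector"), length(t) == 1L)
  if (is.na(t) || t < 0 || t > 1) {
    stop("threshold must lie in [0, 1], got ", t, call. = FALSE)
  }
  w <- unclass(v)[unclass(v) >= t]
  structure(w, rank = attr(v, "rank"),
            class = c("filtered_abundance", "abundance_vector"))
}

#' Area under a precision-recall curve by the trapezoid rule
#'
#' For each distinct recall value the maximum precision attained there is
#' kept; points are sorted by ascending recall; an anchor at recall 0 carries
#' the precision of the smallest-recall point (so a perfectly separable
#' profile, precision 1 at every recall, integrates to exactly 1); and
#' precision is integrated over recall by trapezoids. A curve that never
#' detects a truth taxon collapses to the single point (0, 0) and scores 0.
#'
#' @param precision,recall Numeric vectors of equal length.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(precision, recall) {
  stopifnot(length(precision) == length(recall), length(recall) >= 1L)
  best <- tapply(precision, recall, max)
  r <- as.numeric(names(best))
  ord <- order(r)
  r <- r[ord]; p <- as.numeric(best)[ord]
  if (r[1] > 0) {
    r <- c(0, r)
    p <- c(p[1], p)
  }
  if (length(r) == 1L) return(0)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

pr_point <- function(predicted, truth, ref, rank, t) {
  kept <- apply_abundance_filter(predicted, t)
  cm <- confusion_metrics(detection_sets(kept, truth, ref, rank))
  data.frame(threshold = t, precision = cm$precision, recall = cm$recall,
             f1 = cm$f1, tp = cm$tp, fp = cm$fp, fn = cm$fn)
}

#' Precision-recall curve over all observed abundance thresholds
#'
#' Sweeps the detection threshold over 0 and every distinct predicted weight,
#' recomputing TP/FP/FN and the confusion metrics at each, and summarizes the
#' curve by its trapezoid [auprc()]. Recall is non-increasing along ascending
#' thresholds; precision need not be monotone (a single high-abundance FP can
#' make it collapse at large thresholds).
#'
#' @inheritParams detection_sets
#' @return An object of class `pr_curve`: list with `points` (data frame of
#'   threshold, precision, recall, f1, tp, fp, fn ordered by ascending
#'   threshold) and `auprc`.
#' @export
pr_curve <- function(predicted, truth, ref, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  thresholds <- sort(unique(c(0, as.numeric(predicted))))
  points <- do.call(rbind, lapply(thresholds, function(t)
    pr_point(predicted, truth, ref, rank, t)))
  structure(list(points = points,
                 auprc = auprc(points$precision, points$recall)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d threshold points, AUPRC = %.4f\n",
              nrow(x$points), x$auprc))
  invisible(x)
}

#' Default relative-abundance threshold grid
#'
#' 0% to 1.20% in steps of 0.05%, i.e. 25 thresholds, expressed as fractions.
#' @return Numeric vector of length 25.
#' @export
default_threshold_grid <- function() seq(0, 0.012, by = 0.0005)

#' Confusion metrics along a fixed threshold grid
#'
#' Like [pr_curve()] but over a fixed, shared grid of thresholds, so sweep
#' tables from different samples can be aggregated row-wise. The default grid
#' spans 0% to 1.20% in 0.05% steps.
#'
#' @inheritParams detection_sets
#' @param grid Thresholds as fractions, ascending.
#' @return Data frame with one row per threshold: `threshold`, `precision`,
#'   `recall`, `f1`, `tp`, `fp`, `fn`.
#' @export
threshold_sweep_table <- function(predicted, truth, ref,
                                  rank = c("species", "genus"),
                                  grid = default_threshold_grid()) {
  rank <- match.arg(rank)
  do.call(rbind, lapply(grid, function(t)
    pr_point(predicted, truth, ref, rank, t)))
}
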
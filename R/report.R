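# Per-sample evaluation reports and per-classifier aggregation across mock
# communities: medians, quartiles, per-threshold median lines, dotplot data
# with filtering shifts, and chemistry-to-chemistry relative change.

#' Evaluate one classifier profile against a mock community
#'
#' Runs the full per-sample pipeline at genus and species rank: taxonomy
#' synchronization, rank projection, classified-only renormalization,
#' detection sets and precision/recall/F1, the L1 distance to the expected
#' composition, the precision-recall curve with its AUPRC, and a confusion
#' sweep over a fixed threshold grid. When the community's expected abundances
#' are unknown the L1 distance is reported as unavailable (never silently 0)
#' and the sample is excluded from L1 aggregation.
#'
#' @param predicted An `mc_profile`.
#' @param truth A `ground_truth`.
#' @param ref A `taxonomy_ref`.
#' @param ranks Ranks to evaluate, subset of `c("genus", "species")`.
#' @param grid Threshold grid for the sweep table, see
#'   [threshold_sweep_table()].
#' @param abundance_type `"sequence"` (fraction of classified reads; the scale
#'   of per-read classifiers) or `"taxonomic"` (genome-length corrected;
#'   the scale of marker-based profilers). Applied to the ground-truth vector;
#'   the classifier vector is taken on the scale the classifier reports.
#'
#' @return An object of class `dmc_sample_report`: `sample_id`,
#'   `classifier_id`, `dmc_id`, and per rank a record with `precision`,
#'   `recall`, `f1`, `tp`, `fp`, `fn`, `l1` (`NA` when unavailable),
#'   `l1_available`, `auprc`, `curve` (a `pr_curve`) and `sweep` (data frame).
#' @export
evaluate_sample <- function(predicted, truth, ref,
                            ranks = c("genus", "species"),
                            grid = default_threshold_grid(),
                            abundance_type = c("sequence", "taxonomic")) {
  abundance_type <- match.arg(abundance_type)
  stopifnot(all(ranks %in% EVAL_RANKS))
  predicted <- sync_profile(ref, predicted)

  per_rank <- lapply(ranks, function(rank) {
    proj <- project_to_rank(predicted, ref, rank)
    vec <- renormalize_classified(proj)
    outcome <- detection_sets(vec, truth, ref, rank)
    cm <- confusion_metrics(outcome)
    truth_vec <- truth_abundance_at_rank(truth, ref, rank,
                                         type = abundance_type)
    l1 <- if (is.null(truth_vec)) NA_real_ else l1_distance(truth_vec, vec)
    curve <- pr_curve(vec, truth, ref, rank)
    sweep <- threshold_sweep_table(vec, truth, ref, rank, grid = grid)
    list(rank = rank, precision = cm$precision, recall = cm$recall,
         f1 = cm$f1, tp = cm$tp, fp = cm$fp, fn = cm$fn,
         l1 = l1, l1_available = !is.null(truth_vec),
         auprc = curve$auprc, curve = curve, sweep = sweep,
         abundance = vec, outcome = outcome)
  })
  names(per_rank) <- ranks
  structure(list(sample_id = predicted$sample_id,
                 classifier_id = predicted$classifier_id,
                 dmc_id = truth$dmc_id, ranks = per_rank),
            class = "dmc_sample_report")
}

#' @export
print.dmc_sample_report <- function(x, ...) {
  cat(sprintf("<dmc_sample_report> sample '%s', classifier '%s' vs DMC '%s'\n",
              x$sample_id, x$classifier_id, x$dmc_id))
  print(summary(x))
  invisible(x)
}

#' @export
summary.dmc_sample_report <- function(object, ...) {
  do.call(rbind, lapply(object$ranks, function(r) {
    data.frame(rank = r$rank, precision = r$precision, recall = r$recall,
               f1 = r$f1, l1 = r$l1, auprc = r$auprc,
               tp = r$tp, fp = r$fp, fn = r$fn, stringsAsFactors = FALSE)
  }))
}

five_num <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
       min = min(x), max = max(x))
}

#' Aggregate per-sample reports for one classifier
#'
#' Summarizes each metric (precision, recall, F1, L1, AUPRC) over samples by
#' its median, quartiles (linear interpolation), IQR, minimum and maximum,
#' and computes the same five-number summary of precision, recall and F1 at
#' every threshold of the shared sweep grid. Samples whose mock community
#' lacks expected abundances are excluded from the L1 statistics only.
#'
#' @param reports List of `dmc_sample_report`s, all for the same classifier.
#' @return An object of class `classifier_aggregate`: `classifier_id`,
#'   `n_samples`, `n_samples_l1`, and per rank a list with `metrics` (data
#'   frame: metric, median, q1, q3, iqr, min, max, n) and `threshold_lines`
#'   (data frame: threshold, metric, median, q1, q3, min, max).
#' @export
aggregate_classifier <- function(reports) {
  stopifnot(length(reports) >= 1L,
            all(vapply(reports, inherits, logical(1), "dmc_sample_report")))
  ids <- unique(vapply(reports, `[[`, character(1), "classifier_id"))
  if (length(ids) != 1L) {
    stop("reports mix classifier ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  ranks <- names(reports[[1]]$ranks)

  per_rank <- lapply(ranks, function(rank) {
    recs <- lapply(reports, function(r) r$ranks[[rank]])
    metric_rows <- lapply(c("precision", "recall", "f1", "l1", "auprc"),
                          function(m) {
      vals <- vapply(recs, `[[`, numeric(1), m)
      if (m == "l1") vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) {
        return(data.frame(metric = m, median = NA_real_, q1 = NA_real_,
                          q3 = NA_real_, iqr = NA_real_, min = NA_real_,
                          max = NA_real_, n = 0L))
      }
      s <- five_num(vals)
      data.frame(metric = m, median = s$median, q1 = s$q1, q3 = s$q3,
                 iqr = s$iqr, min = s$min, max = s$max, n = length(vals))
    })
    grid <- recs[[1]]$sweep$threshold
    same_grid <- all(vapply(recs, function(r)
      identical(r$sweep$threshold, grid), logical(1)))
    if (!same_grid) stop("sweep tables use different threshold grids",
                         call. = FALSE)
    line_rows <- lapply(c("precision", "recall", "f1"), function(m) {
      mat <- vapply(recs, function(r) r$sweep[[m]], numeric(length(grid)))
      mat <- matrix(mat, nrow = length(grid))
      do.call(rbind, lapply(seq_along(grid), function(i) {
        s <- five_num(mat[i, ])
        data.frame(threshold = grid[i], metric = m, median = s$median,
                   q1 = s$q1, q3 = s$q3, min = s$min, max = s$max)
      }))
    })
    list(rank = rank, metrics = do.call(rbind, metric_rows),
         threshold_lines = do.call(rbind, line_rows))
  })
  names(per_rank) <- ranks

  n_l1 <- vapply(ranks, function(rank)
    sum(vapply(reports, function(r) r$ranks[[rank]]$l1_available, logical(1))),
    integer(1))
  structure(list(classifier_id = ids, n_samples = length(reports),
                 n_samples_l1 = min(n_l1), ranks = per_rank),
            class = "classifier_aggregate")
}

#' @export
print.classifier_aggregate <- function(x, ...) {
  cat(sprintf("<classifier_aggregate> '%s' over %d sample(s) (%d with L1)\n",
              x$classifier_id, x$n_samples, x$n_samples_l1))
  for (r in x$ranks) {
    cat(sprintf("-- %s\n", r$rank))
    print(r$metrics, row.names = FALSE)
  }
  invisible(x)
}

#' Dotplot data: median precision/recall with IQR and filtering shifts
#'
#' For each classifier, the unfiltered median precision and recall with their
#' IQRs, and the shifted medians read from the per-threshold median lines at
#' relative-abundance thresholds of 0.05% and 0.1% — the error-flag data of
#' the precision-recall overview plot.
#'
#' @param aggregates List of `classifier_aggregate`s.
#' @param rank Rank to extract.
#' @return Data frame with one row per classifier (input order preserved):
#'   `classifier_id`, `median_precision`, `median_recall`, `iqr_precision`,
#'   `iqr_recall`, `precision_at_0.05pct`, `recall_at_0.05pct`,
#'   `precision_at_0.1pct`, `recall_at_0.1pct`.
#' @export
dotplot_data <- function(aggregates, rank = "species") {
  stopifnot(all(vapply(aggregates, inherits, logical(1),
                       "classifier_aggregate")))
  shift_at <- c(0.0005, 0.001)
  do.call(rbind, lapply(aggregates, function(a) {
    r <- a$ranks[[rank]]
    if (is.null(r)) stop("aggregate for '", a$classifier_id,
                         "' lacks rank ", rank, call. = FALSE)
    m <- r$metrics
    lines <- r$threshold_lines
    pick <- function(metric, t) {
      row <- lines$metric == metric & abs(lines$threshold - t) < 1e-12
      if (!any(row)) stop("threshold lines lack grid point ", t,
                          " needed for the dotplot", call. = FALSE)
      lines$median[row][1]
    }
    data.frame(
      classifier_id = a$classifier_id,
      median_precision = m$median[m$metric == "precision"],
      median_recall = m$median[m$metric == "recall"],
      iqr_precision = m$iqr[m$metric == "precision"],
      iqr_recall = m$iqr[m$metric == "recall"],
      precision_at_0.05pct = pick("precision", shift_at[1]),
      recall_at_0.05pct = pick("recall", shift_at[1]),
      precision_at_0.1pct = pick("precision", shift_at[2]),
      recall_at_0.1pct = pick("recall", shift_at[2]),
      stringsAsFactors = FALSE)
  }))
}

#' Relative percentage change between two metric values
#'
#' `100 * (new - reference) / reference`: the signed percent change of a
#' metric from a reference condition to a new one (e.g. from an older to a
#' newer flowcell chemistry on the same community). Undefined for a
#' non-positive reference, in which case `NA` is returned with a warning
#' rather than a misleading number.
#'
#' @param reference_value,new_value Metric values.
#' @return Signed percent change, or `NA` when not computable.
#' @export
relative_change <- function(reference_value, new_value) {
  if (is.na(reference_value) || reference_value <= 0) {
    warning("relative change undefined for non-positive reference value")
    return(NA_real_)
  }
  100 * (new_value - reference_value) / reference_value
}

#' Compare two sample reports metric by metric
#'
#' Pairs a reference report with a comparison report (typically the same mock
#' community sequenced on two flowcell chemistries, classified by the same
#' tool) and tabulates each metric with its relative percentage change.
#'
#' @param reference,new `dmc_sample_report`s with matching ranks.
#' @return Data frame: `rank`, `metric`, `reference`, `new`, `pct_change`.
#' @export
compare_reports <- function(reference, new) {
  stopifnot(inherits(reference, "dmc_sample_report"),
            inherits(new, "dmc_sample_report"))
  ranks <- intersect(names(reference$ranks), names(new$ranks))
  do.call(rbind, lapply(ranks, function(rank) {
    do.call(rbind, lapply(c("precision", "recall", "f1", "l1", "auprc"),
                          function(m) {
      a <- reference$ranks[[rank]][[m]]
      b <- new$ranks[[rank]][[m]]
      pc <- if (is.na(a) || a <= 0 || is.na(b)) NA_real_ else
        suppressWarnings(relative_change(a, b))
      data.frame(rank = rank, metric = m, reference = a, new = b,
                 pct_change = pc, stringsAsFactors = FALSE)
    }))
  }))
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (col in names(df)[num]) {
    out[[col]] <- ifelse(is.na(df[[col]]), "NA",
                         format(df[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(out), collapse = "\t"),
               if (nrow(out) > 0L)
                 do.call(paste, c(out, sep = "\t"))), con, sep = "\n")
  path
}

#' Render a report or aggregate to TSV and JSON files
#'
#' Deterministic emission: the same object always produces byte-identical
#' files. A sample report yields a metrics table, one sweep table and one
#' PR-curve table per rank, and a JSON summary; a classifier aggregate yields
#' the metric summary table, the per-threshold lines and a JSON summary.
#'
#' @param x A `dmc_sample_report` or `classifier_aggregate`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of the files written (the manifest), invisibly.
#' @export
render_report <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name, df) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  if (inherits(x, "dmc_sample_report")) {
    emit(sprintf("%s_%s_metrics.tsv", x$sample_id, x$classifier_id),
         cbind(data.frame(sample_id = x$sample_id,
                          classifier_id = x$classifier_id,
                          dmc_id = x$dmc_id, stringsAsFactors = FALSE),
               summary(x)))
    for (r in x$ranks) {
      emit(sprintf("%s_%s_%s_sweep.tsv", x$sample_id, x$classifier_id, r$rank),
           r$sweep)
      emit(sprintf("%s_%s_%s_pr_curve.tsv", x$sample_id, x$classifier_id,
                   r$rank), r$curve$points)
    }
    json <- list(sample_id = x$sample_id, classifier_id = x$classifier_id,
                 dmc_id = x$dmc_id,
                 metrics = lapply(x$ranks, function(r)
                   list(precision = r$precision, recall = r$recall,
                        f1 = r$f1, l1 = r$l1, l1_available = r$l1_available,
                        auprc = r$auprc, tp = r$tp, fp = r$fp, fn = r$fn)))
    jp <- file.path(out_dir, sprintf("%s_%s_report.json", x$sample_id,
                                     x$classifier_id))
    jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <- c(files, jp)
  } else if (inherits(x, "classifier_aggregate")) {
    for (r in x$ranks) {
      emit(sprintf("%s_%s_aggregate.tsv", x$classifier_id, r$rank), r$metrics)
      emit(sprintf("%s_%s_threshold_lines.tsv", x$classifier_id, r$rank),
           r$threshold_lines)
    }
    json <- list(classifier_id = x$classifier_id, n_samples = x$n_samples,
                 n_samples_l1 = x$n_samples_l1,
                 medians = lapply(x$ranks, function(r)
                   as.list(structure(r$metrics$median, names = r$metrics$metric))))
    jp <- file.path(out_dir, sprintf("%s_aggregate.json", x$classifier_id))
    jsonlite::write_json(json, jp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    files <- c(files, jp)
  } else {
    stop("render_report handles dmc_sample_report and classifier_aggregate",
         call. = FALSE)
  }
  invisible(files)
}
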
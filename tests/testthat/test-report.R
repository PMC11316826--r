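perfect_profile <- function(tx, truth) {
  mc_profile(truth$dmc_id, "perfect", data.frame(
    taxid = truth$entries$taxid, name = truth$entries$name,
    rank = "species", count = NA_real_, fraction = truth$entries$fraction))
}

test_that("evaluate_sample composes the per-sample pipeline at both ranks", {
  fx <- fixture_taxonomy(n_decoys = 4L)
  tx <- fx$tx; ref <- fx$ref
  spec <- simulation_spec(n_species = 5, seed = 3)
  truth <- make_truth(spec, ref)

  # a prediction identical to the truth is perfect on every metric
  rep1 <- evaluate_sample(perfect_profile(tx, truth), truth, ref)
  for (rank in c("genus", "species")) {
    r <- rep1$ranks[[rank]]
    expect_equal(c(r$precision, r$recall, r$f1, r$auprc), c(1, 1, 1, 1))
    expect_equal(r$l1, 0, tolerance = 1e-12)
    expect_true(r$l1_available)
  }

  # truth without abundances: L1 unavailable, detection metrics intact
  nt <- ground_truth("d_na", data.frame(
    taxid = truth$entries$taxid, name = truth$entries$name,
    fraction = NA_real_, genome_length = NA_real_))
  rep2 <- evaluate_sample(perfect_profile(tx, truth), nt, ref)
  expect_false(rep2$ranks$species$l1_available)
  expect_true(is.na(rep2$ranks$species$l1))
  expect_equal(rep2$ranks$species$recall, 1)

  # empty prediction: recall 0 at both ranks
  rep3 <- evaluate_sample(mc_profile("s", "c", unclassified_fraction = 1),
                          truth, ref)
  expect_equal(rep3$ranks$genus$recall, 0)
  expect_equal(rep3$ranks$species$recall, 0)

  # taxonomic abundance: the L1 of a perfect sequence-abundance prediction
  # is nonzero once the truth is genome-length corrected
  rep4 <- evaluate_sample(perfect_profile(tx, truth), truth, ref,
                          abundance_type = "taxonomic")
  expect_gt(rep4$ranks$species$l1, 0)
})

test_that("aggregation reproduces sort-based order statistics", {
  vals <- list(c(0.1, 0.2, 0.9), c(0.2, 0.4), c(0.5))
  expect_equal(vapply(vals, function(v) unname(quantile(v, 0.5)), numeric(1)),
               c(0.2, 0.3, 0.5))

  fx <- fixture_taxonomy(n_decoys = 6L)
  ref <- fx$ref
  spec <- simulation_spec(n_species = 4, seed = 11)
  truth <- make_truth(spec, ref)
  reports <- lapply(1:5, function(i) {
    s <- simulation_spec(n_species = 4, fn_prob = 0.3, n_fp = 3,
                         noise_cv = 0.2, seed = 100 + i)
    evaluate_sample(simulate_classifier_profile(truth, s, ref,
                                                sample_id = paste0("s", i)),
                    truth, ref)
  })
  agg <- aggregate_classifier(reports)
  expect_equal(agg$n_samples, 5L)

  for (m in c("precision", "recall", "f1", "auprc")) {
    vals <- vapply(reports, function(r) r$ranks$species[[m]], numeric(1))
    row <- agg$ranks$species$metrics
    row <- row[row$metric == m, ]
    # brute-force oracle: sort-based quantiles with linear interpolation
    srt <- sort(vals)
    h <- function(p) {
      hh <- (length(srt) - 1) * p + 1
      srt[floor(hh)] + (hh - floor(hh)) *
        (srt[min(floor(hh) + 1, length(srt))] - srt[floor(hh)])
    }
    expect_equal(row$median, h(0.5))
    expect_equal(row$q1, h(0.25))
    expect_equal(row$q3, h(0.75))
    expect_equal(row$iqr, row$q3 - row$q1)
    expect_equal(c(row$min, row$max), range(vals))
  }

  # permutation invariance of the aggregate
  agg2 <- aggregate_classifier(reports[c(3, 1, 5, 2, 4)])
  expect_equal(agg2$ranks$species$metrics, agg$ranks$species$metrics)
  expect_equal(agg2$ranks$species$threshold_lines,
               agg$ranks$species$threshold_lines)

  # single report: median = min = max, iqr 0
  agg1 <- aggregate_classifier(reports[1])
  r1 <- agg1$ranks$species$metrics
  expect_equal(r1$median, r1$min)
  expect_equal(r1$median, r1$max)
  expect_equal(r1$iqr, rep(0, nrow(r1)))

  # mixed classifier ids are rejected
  other <- reports[[1]]
  other$classifier_id <- "someone_else"
  expect_error(aggregate_classifier(list(reports[[1]], other)), "mix")
})

test_that("samples without truth abundances are excluded from L1 statistics only", {
  fx <- fixture_taxonomy(n_decoys = 4L)
  ref <- fx$ref
  spec <- simulation_spec(n_species = 4, seed = 2)
  truth <- make_truth(spec, ref)
  no_ab <- ground_truth("d_na", data.frame(
    taxid = truth$entries$taxid, name = truth$entries$name,
    fraction = NA_real_, genome_length = NA_real_))
  prof <- simulate_classifier_profile(truth, spec, ref)
  agg <- aggregate_classifier(list(evaluate_sample(prof, truth, ref),
                                   evaluate_sample(prof, no_ab, ref)))
  expect_equal(agg$n_samples, 2L)
  expect_equal(agg$n_samples_l1, 1L)
  m <- agg$ranks$species$metrics
  expect_equal(m$n[m$metric == "l1"], 1L)
  expect_equal(m$n[m$metric == "precision"], 2L)
})

test_that("dotplot data reads medians, IQRs and filtering shifts off the aggregate", {
  fx <- fixture_taxonomy(n_decoys = 6L)
  ref <- fx$ref
  spec <- simulation_spec(n_species = 4, seed = 5)
  truth <- make_truth(spec, ref)
  mk_agg <- function(cid, n_fp) {
    aggregate_classifier(lapply(1:3, function(i) {
      s <- simulation_spec(n_species = 4, n_fp = n_fp, fp_weight_scale = 1e-4,
                          noise_cv = 0.1, seed = 200 + i)
      evaluate_sample(simulate_classifier_profile(truth, s, ref,
                                                  classifier_id = cid),
                      truth, ref)
    }))
  }
  aggs <- list(mk_agg("noisy", 4), mk_agg("clean", 0))
  dots <- dotplot_data(aggs)
  expect_equal(dots$classifier_id, c("noisy", "clean"))   # order-stable
  expect_true(all(dots$median_precision >= 0 & dots$median_precision <= 1))

  m <- aggs[[1]]$ranks$species$metrics
  expect_equal(dots$iqr_precision[1],
               m$q3[m$metric == "precision"] - m$q1[m$metric == "precision"])

  # low-weight FPs vanish at the 0.05% threshold: the shifted median improves
  expect_gte(dots$precision_at_0.05pct[1], dots$median_precision[1])
  # the clean classifier is threshold-invariant: zero-length shift
  expect_equal(dots$precision_at_0.05pct[2], dots$median_precision[2])
  expect_equal(dots$recall_at_0.1pct[2], dots$median_recall[2])

  # a grid without the shift thresholds is an argument error
  rep_bad <- evaluate_sample(
    simulate_classifier_profile(truth, spec, ref, classifier_id = "bad"),
    truth, ref, grid = c(0, 0.01))
  expect_error(dotplot_data(list(aggregate_classifier(list(rep_bad)))),
               "grid")
})

test_that("relative change reports signed percent and refuses zero references", {
  expect_equal(relative_change(0.9, 0.99), 10)
  expect_equal(relative_change(0.5, 0.5), 0)
  expect_warning(out <- relative_change(0, 0.5), "undefined")
  expect_true(is.na(out))

  fx <- fixture_taxonomy(n_decoys = 4L)
  ref <- fx$ref
  spec <- simulation_spec(n_species = 4, seed = 6)
  truth <- make_truth(spec, ref)
  r9 <- evaluate_sample(simulate_classifier_profile(truth, spec, ref), truth, ref)
  r10 <- evaluate_sample(simulate_classifier_profile(
    truth, simulation_spec(n_species = 4, noise_cv = 0.3, seed = 7), ref),
    truth, ref)
  cmp <- compare_reports(r9, r10)
  expect_equal(nrow(cmp), 10L)   # 5 metrics x 2 ranks
  pr <- cmp[cmp$rank == "species" & cmp$metric == "precision", ]
  expect_equal(pr$pct_change, 0)  # identical precision -> 0% bar
})

test_that("rendered reports are deterministic files that round-trip", {
  fx <- fixture_taxonomy(n_decoys = 4L)
  ref <- fx$ref
  spec <- simulation_spec(n_species = 4, n_fp = 2, seed = 9)
  truth <- make_truth(spec, ref)
  rep1 <- evaluate_sample(simulate_classifier_profile(truth, spec, ref),
                          truth, ref)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- render_report(rep1, d1)
  f2 <- render_report(rep1, d2)
  expect_gte(length(f1), 3L)   # metrics + sweeps + curves (+ json)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }

  # sweep TSV round-trips to the in-memory table
  sweep_file <- grep("species_sweep", f1, value = TRUE)
  back <- utils::read.delim(sweep_file)
  expect_equal(back$precision, rep1$ranks$species$sweep$precision)
  expect_equal(back$threshold, rep1$ranks$species$sweep$threshold)

  # aggregates render with the sample count in the JSON
  agg <- aggregate_classifier(list(rep1))
  fa <- render_report(agg, withr::local_tempdir())
  js <- jsonlite::read_json(grep("json$", fa, value = TRUE))
  expect_equal(js$n_samples, 1L)
})
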
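# Metrics are identity-agnostic, so most tests run on a flat taxonomy whose
# species sit directly under the root-level genus nodes of the shared fixture.

truth_from_ids <- function(tx, idx, fractions = NULL) {
  ids <- unname(tx$species[idx])
  ground_truth("d", data.frame(
    taxid = ids, name = names(tx$species)[idx],
    fraction = if (is.null(fractions)) rep(1 / length(ids), length(ids))
               else fractions,
    genome_length = 4e6))
}

av <- function(w, rank = "species") abundance_vector(w, rank = rank)

test_that("detection sets partition predictions and truth correctly", {
  fx <- fixture_taxonomy(n_decoys = 4L)
  tx <- fx$tx; ref <- fx$ref
  truth <- truth_from_ids(tx, 1:2)
  ids <- as.character(unname(c(tx$species[1:2], tx$decoys[1])))

  out <- detection_sets(av(structure(c(0.5, 0.3, 0.2), names = ids)),
                        truth, ref, "species")
  expect_setequal(out$tp, ids[1:2])
  expect_setequal(out$fp, ids[3])
  expect_length(out$fn, 0L)

  # empty prediction: everything is a false negative
  out2 <- detection_sets(av(numeric(0)), truth, ref, "species")
  expect_length(out2$tp, 0L)
  expect_length(out2$fp, 0L)
  expect_setequal(out2$fn, as.character(unname(tx$species[1:2])))

  # perfect prediction
  out3 <- detection_sets(av(structure(c(0.6, 0.4), names = ids[1:2])),
                         truth, ref, "species")
  expect_length(out3$fp, 0L)
  expect_length(out3$fn, 0L)

  # truth species map to their genus at genus rank
  g <- vapply(unname(tx$species[1:2]), function(t)
    as.character(ancestor_at_rank(ref, t, "genus")), character(1))
  outg <- detection_sets(av(structure(1, names = g[1]), rank = "genus"),
                         truth, ref, "genus")
  expect_setequal(outg$tp, g[1])
  expect_setequal(outg$fn, g[2])

  # unresolvable truth taxa are reported by name
  bad <- ground_truth("d", data.frame(taxid = NA_integer_,
                                      name = "Missingus absentus",
                                      fraction = 1, genome_length = NA_real_))
  expect_error(detection_sets(av(numeric(0)), bad, ref, "species"),
               "Missingus absentus")
})

test_that("confusion metrics implement precision, recall and harmonic-mean F1", {
  cm <- confusion_metrics(list(tp = letters[1:3], fp = "x", fn = character(0)))
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 1.0)
  expect_equal(cm$f1, 6 / 7)

  # all-zero convention when nothing true is detected
  cm0 <- confusion_metrics(list(tp = character(0), fp = letters[1:5],
                                fn = letters[6:7]))
  expect_equal(c(cm0$precision, cm0$recall, cm0$f1), c(0, 0, 0))

  # perfect precision and recall give F1 = 1
  cm1 <- confusion_metrics(list(tp = letters[1:4], fp = character(0),
                                fn = character(0)))
  expect_equal(cm1$f1, 1)

  # F1 equals the harmonic mean wherever defined (random count property)
  set.seed(31)
  for (rep in 1:50) {
    tp <- sample(0:9, 1); fp <- sample(0:9, 1); fn <- sample(0:9, 1)
    cm <- confusion_metrics(list(tp = rep("t", tp)[0:tp],
                                 fp = rep("f", fp)[0:fp],
                                 fn = rep("n", fn)[0:fn]))
    expect_gte(min(cm$precision, cm$recall, cm$f1), 0)
    expect_lte(max(cm$precision, cm$recall, cm$f1), 1)
    if (cm$precision + cm$recall > 0) {
      expect_equal(cm$f1,
                   2 * cm$precision * cm$recall / (cm$precision + cm$recall),
                   tolerance = 1e-12)
    } else {
      expect_equal(cm$f1, 0)
    }
  }
})

test_that("l1_distance spans [0, 2] and is a metric on the union support", {
  p <- av(c(A = 0.5, B = 0.5))
  expect_equal(l1_distance(p, p), 0)
  q <- av(c(C = 0.7, D = 0.3))
  expect_equal(l1_distance(p, q), 2)        # disjoint supports
  expect_equal(l1_distance(av(c(A = 1)), av(c(A = 0.5, B = 0.5))), 1.0)

  set.seed(13)
  rand_av <- function() {
    n <- sample(1:6, 1)
    w <- runif(n); names(w) <- sample(LETTERS[1:8], n)
    av(w / sum(w))
  }
  for (rep in 1:50) {
    x <- rand_av(); y <- rand_av(); z <- rand_av()
    dxy <- l1_distance(x, y)
    expect_gte(dxy, 0); expect_lte(dxy, 2)
    expect_equal(dxy, l1_distance(y, x))                    # symmetry
    expect_lte(dxy, l1_distance(x, z) + l1_distance(z, y) + 1e-12)  # triangle
  }
})

test_that("abundance filtering removes strictly-below-threshold taxa without renormalizing", {
  v <- av(c(A = 0.6, B = 0.3495, C = 0.05, D = 0.0005))
  expect_equal(as.numeric(apply_abundance_filter(v, 0)), as.numeric(v))
  f <- apply_abundance_filter(v, 0.0006)
  expect_setequal(names(f), c("A", "B", "C"))
  expect_equal(sum(f), 0.9995)              # no renormalization
  # weight exactly at the threshold is retained
  expect_true("D" %in% names(apply_abundance_filter(v, 0.0005)))
  expect_error(apply_abundance_filter(v, 1.5), "\\[0, 1\\]")
  expect_error(apply_abundance_filter(v, -0.1), "\\[0, 1\\]")
})

test_that("auprc matches hand-computed and extreme curves", {
  expect_equal(auprc(0, 0), 0)                       # never detects anything
  expect_equal(auprc(c(1, 1), c(0.5, 1.0)), 1.0)     # perfect separation
  expect_equal(auprc(c(1.0, 0.5), c(0.5, 1.0)), 0.875)  # hand trapezoid
})

test_that("auprc agrees with a rectangle-refinement oracle on random curves", {
  set.seed(97)
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    precision <- runif(n)
    recall <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    a <- auprc(precision, recall)
    expect_gte(a, 0); expect_lte(a, 1)
    expect_equal(a, auprc_oracle(precision, recall), tolerance = 1e-9)
  }
})

test_that("pr_curve sweeps observed abundances and attains the documented extremes", {
  fx <- fixture_taxonomy(n_decoys = 6L)
  tx <- fx$tx; ref <- fx$ref
  truth <- truth_from_ids(tx, 1:3)
  tp_ids <- as.character(unname(tx$species[1:3]))
  fp_ids <- as.character(unname(tx$decoys[1:4]))

  # every TP weight above every FP weight: separable, AUPRC 1
  w <- structure(c(0.5, 0.3, 0.16, rep(0.01, 4)), names = c(tp_ids, fp_ids))
  curve <- pr_curve(av(w), truth, ref, "species")
  expect_equal(curve$auprc, 1)
  expect_true(any(curve$points$precision == 1 & curve$points$recall == 1))
  expect_equal(curve$points$threshold, sort(unique(c(0, unname(w)))))
  # recall is non-increasing along ascending thresholds
  expect_true(all(diff(curve$points$recall) <= 0))

  # prediction disjoint from truth: flat zero curve
  w2 <- structure(c(0.6, 0.4), names = fp_ids[1:2])
  curve2 <- pr_curve(av(w2), truth, ref, "species")
  expect_true(all(curve2$points$precision == 0))
  expect_true(all(curve2$points$recall == 0))
  expect_equal(curve2$auprc, 0)

  # empty prediction: a single threshold-0 point with recall 0
  curve3 <- pr_curve(av(numeric(0)), truth, ref, "species")
  expect_equal(nrow(curve3$points), 1L)
  expect_equal(curve3$points$recall, 0)
})

test_that("threshold sweep uses the default 0-1.2% grid and shrinks monotonically", {
  fx <- fixture_taxonomy(n_decoys = 6L)
  tx <- fx$tx; ref <- fx$ref
  truth <- truth_from_ids(tx, 1:3)
  w <- structure(c(0.5, 0.3, 0.16, 0.03, 0.008, 0.002),
                 names = as.character(unname(c(tx$species[1:3],
                                               tx$decoys[1:3]))))
  expect_equal(default_threshold_grid(),
               seq(0, 0.012, by = 0.0005), tolerance = 1e-12)
  tab <- threshold_sweep_table(av(w), truth, ref, "species")
  expect_equal(nrow(tab), 25L)
  expect_true(all(diff(tab$recall) <= 0))
  expect_true(all(diff(tab$fp) <= 0))

  # a {0} grid reproduces the unfiltered confusion metrics
  tab0 <- threshold_sweep_table(av(w), truth, ref, "species", grid = 0)
  cm <- confusion_metrics(detection_sets(av(w), truth, ref, "species"))
  expect_equal(tab0$precision, cm$precision)
  expect_equal(tab0$recall, cm$recall)
  expect_equal(tab0$f1, cm$f1)
})

test_that("confusion metrics match exhaustive set comparison on planted configurations", {
  fx <- fixture_taxonomy(n_decoys = 6L)
  tx <- fx$tx; ref <- fx$ref
  all_ids <- unname(c(tx$species, tx$decoys))
  set.seed(8)
  for (rep in 1:30) {
    truth_idx <- sample(1:6, sample(2:6, 1))
    truth <- truth_from_ids(tx, truth_idx)
    pred_ids <- sample(all_ids, sample(1:8, 1))
    w <- runif(length(pred_ids)); w <- w / sum(w)
    cm <- confusion_metrics(detection_sets(
      av(structure(w, names = as.character(pred_ids))), truth, ref, "species"))
    truth_ids <- unname(tx$species[truth_idx])
    tp <- sum(pred_ids %in% truth_ids)
    fp <- sum(!pred_ids %in% truth_ids)
    fn <- sum(!truth_ids %in% pred_ids)
    expect_equal(c(cm$tp, cm$fp, cm$fn), c(tp, fp, fn))
    expect_equal(cm$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_equal(cm$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
  }
})
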
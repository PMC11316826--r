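# Shared fixtures: a six-species mock taxonomy with decoys, and generators of
# random mini-taxonomies / profiles for property-style tests.

SIX_SPECIES <- c("Escherichia coli", "Bacillus subtilis",
                 "Staphylococcus aureus", "Listeria monocytogenes",
                 "Salmonella enterica", "Pseudomonas aeruginosa")

fixture_taxonomy <- function(n_decoys = 6L, n_merged = 2L, n_deleted = 1L) {
  tx <- make_mini_taxonomy(SIX_SPECIES, n_decoys = n_decoys,
                           n_merged = n_merged, n_deleted = n_deleted,
                           dir = withr::local_tempdir(.local_envir =
                                                        parent.frame()))
  list(tx = tx,
       ref = load_taxonomy(tx$nodes, tx$names, tx$merged, tx$delnodes))
}

# A hand-built taxonomy_ref (no files) for walk-oriented property tests:
# random tree with random rank labels, node 1 the root.
random_ref <- function(n_nodes, rank_pool = c("no rank", "superkingdom",
                                              "family", "genus", "species",
                                              "strain")) {
  parent <- c(1L, vapply(seq_len(n_nodes - 1L) + 1L,
                         function(i) sample.int(i - 1L, 1L), integer(1)))
  structure(list(taxid = seq_len(n_nodes), parent = parent,
                 rank = c("no rank", sample(rank_pool, n_nodes - 1L,
                                            replace = TRUE)),
                 name = sprintf("taxon %d", seq_len(n_nodes)), root = 1L,
                 merged = structure(integer(0), names = character(0)),
                 deleted = integer(0),
                 name_index = structure(seq_len(n_nodes),
                                        names = sprintf("taxon %d",
                                                        seq_len(n_nodes)))),
            class = "taxonomy_ref")
}

# Brute-force oracle for ancestor_at_rank: enumerate the full root path, then
# take the first node of the target rank.
ancestor_oracle <- function(ref, taxid, rank) {
  path <- integer(0)
  cur <- taxid
  repeat {
    path <- c(path, cur)
    if (cur == ref$root) break
    cur <- ref$parent[match(cur, ref$taxid)]
  }
  ranks <- ref$rank[match(path, ref$taxid)]
  hit <- which(ranks == rank)
  if (length(hit) == 0L) NA_integer_ else path[hit[1]]
}

# Independent trapezoid oracle for auprc(): rebuild the max-precision step
# points with explicit loops, then integrate the linear interpolant by fine
# midpoint rectangles (exact on piecewise-linear curves up to refinement).
auprc_oracle <- function(precision, recall, refine = 256L) {
  rs <- sort(unique(recall))
  ps <- vapply(rs, function(r) max(precision[recall == r]), numeric(1))
  if (rs[1] > 0) { rs <- c(0, rs); ps <- c(ps[1], ps) }
  if (length(rs) == 1L) return(0)
  f <- stats::approxfun(rs, ps)
  area <- 0
  for (i in seq_len(length(rs) - 1L)) {
    xs <- seq(rs[i], rs[i + 1L], length.out = refine + 1L)
    mid <- (utils::head(xs, -1) + utils::tail(xs, -1)) / 2
    area <- area + sum(f(mid)) * (rs[i + 1L] - rs[i]) / refine
  }
  area
}

# Random valid profile for round-trip property tests.
random_profile <- function(n_entries = sample.int(8L, 1L)) {
  frac <- if (n_entries > 0L) {
    w <- stats::runif(n_entries)
    w / sum(w) * stats::runif(1, 0.5, 1)
  } else numeric(0)
  use_counts <- stats::runif(1) < 0.5
  mc_profile(
    sample_id = paste0("s", sample.int(99L, 1L)),
    classifier_id = paste0("c", sample.int(99L, 1L)),
    entries = data.frame(
      taxid = sample.int(10000L, n_entries),
      name = sprintf("Taxon sp%02d", seq_len(n_entries)),
      rank = sample(c("species", "genus"), n_entries, replace = TRUE),
      count = if (use_counts) sample.int(100000L, n_entries) else NA_real_,
      fraction = if (use_counts) NA_real_ else frac,
      stringsAsFactors = FALSE),
    unclassified_fraction = if (stats::runif(1) < 0.5) stats::runif(1)
                            else NA_real_)
}

expect_profiles_equal <- function(a, b) {
  ka <- order(a$entries$taxid); kb <- order(b$entries$taxid)
  expect_equal(a$sample_id, b$sample_id)
  expect_equal(a$classifier_id, b$classifier_id)
  ea <- a$entries[ka, ]; eb <- b$entries[kb, ]
  rownames(ea) <- rownames(eb) <- NULL
  expect_equal(ea, eb)
  expect_equal(a$unclassified_count, b$unclassified_count)
  expect_equal(a$unclassified_fraction, b$unclassified_fraction)
}
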
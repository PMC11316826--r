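# Synthetic data with the statistical structure the evaluation assumes: mock
# ground truths (even / staggered / logarithmic compositions), classifier
# profiles with planted FN/FP/noise/unclassified structure, mini taxonomy
# dumps in the NCBI dialect, and FASTQ fixtures. Everything is deterministic
# under its seed and round-trips through the package's own parsers.

#' Parameters for synthetic mock-community simulation
#'
#' @param n_species Number of species in the ground truth.
#' @param distribution Composition shape: `"even"` (equal fractions),
#'   `"staggered"` (distinct magnitudes spanning at least two orders), or
#'   `"log"` (each consecutive abundance one tenth of the previous).
#' @param fn_prob Probability that a truth taxon is missed by the simulated
#'   classifier (a planted false negative).
#' @param n_fp Number of spurious off-truth taxa the simulated classifier
#'   reports (planted false positives).
#' @param fp_weight_scale Typical relative-abundance magnitude of a planted
#'   FP; individual FP weights are drawn log-uniformly within a factor of 10
#'   of it, so occasional high-abundance FPs occur.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   abundance noise on detected truth taxa (0 = exact abundances).
#' @param unclassified_frac Fraction of reads the simulated classifier leaves
#'   unclassified.
#' @param depth Optional sequencing depth (classified reads); when given,
#'   integer counts are materialized alongside fractions.
#' @param seed Integer seed driving every draw.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_species = 8L,
                            distribution = c("even", "staggered", "log"),
                            fn_prob = 0, n_fp = 0L, fp_weight_scale = 0.001,
                            noise_cv = 0, unclassified_frac = 0,
                            depth = NULL, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_species >= 1L, fn_prob >= 0, fn_prob <= 1, n_fp >= 0L,
            fp_weight_scale > 0, noise_cv >= 0,
            unclassified_frac >= 0, unclassified_frac < 1)
  structure(list(n_species = as.integer(n_species),
                 distribution = distribution, fn_prob = fn_prob,
                 n_fp = as.integer(n_fp), fp_weight_scale = fp_weight_scale,
                 noise_cv = noise_cv, unclassified_frac = unclassified_frac,
                 depth = depth, seed = as.integer(seed)),
            class = "simulation_spec")
}

species_taxids <- function(ref) ref$taxid[ref$rank == "species"]

#' Generate a synthetic mock-community ground truth
#'
#' Samples `n_species` species from the taxonomy and assigns expected
#' sequence abundances per the spec's distribution: even fractions, a
#' staggered seeded draw of distinct magnitudes spanning at least two orders,
#' or a logarithmic series in which each consecutive abundance is one tenth
#' of the previous one. Plausible genome lengths (2-8 Mbp, seeded uniform)
#' are attached for sequence-to-taxonomic conversion.
#'
#' @param spec A `simulation_spec`.
#' @param ref A `taxonomy_ref` holding at least `n_species` species nodes.
#' @param dmc_id Identifier for the generated community.
#' @return A `ground_truth`.
#' @export
make_truth <- function(spec, ref, dmc_id = "synthetic_dmc") {
  stopifnot(inherits(spec, "simulation_spec"), inherits(ref, "taxonomy_ref"))
  pool <- species_taxids(ref)
  n <- spec$n_species
  if (length(pool) < n) {
    stop(sprintf("taxonomy holds %d species, %d requested", length(pool), n),
         call. = FALSE)
  }
  with_seed(spec$seed, {
    taxa <- sort(pool[sample.int(length(pool), n)])
    frac <- switch(spec$distribution,
      even = rep(1 / n, n),
      log = { w <- 10^(-(seq_len(n) - 1)); w / sum(w) },
      staggered = {
        expo <- if (n == 1L) 0 else
          c(0, -2, if (n > 2L) stats::runif(n - 2L, -2.5, 0))
        w <- 10^expo
        w / sum(w)
      })
    glen <- round(stats::runif(n, 2e6, 8e6))
    ground_truth(dmc_id, data.frame(
      taxid = taxa, name = ref$name[tax_index(ref, taxa)],
      fraction = frac, genome_length = glen, stringsAsFactors = FALSE))
  })
}

#' Simulate a classifier profile with planted errors
#'
#' Produces the profile a noisy classifier would report for a known
#' community: each truth taxon is independently missed with probability
#' `fn_prob`; detected taxa get their expected abundance perturbed by
#' multiplicative lognormal noise with coefficient of variation `noise_cv`
#' (mean-one, so abundances are unbiased); `n_fp` off-truth species are added
#' with log-uniform heavy-tailed weights around `fp_weight_scale`; and the
#' classified mass is scaled so `unclassified_frac` of the read set remains
#' unclassified. With all four knobs at zero the profile reproduces the truth
#' exactly and every evaluation metric is perfect.
#'
#' @param truth A `ground_truth` (see [make_truth()]).
#' @param spec A `simulation_spec`.
#' @param ref A `taxonomy_ref` holding at least `n_fp` species outside the
#'   truth.
#' @param sample_id,classifier_id Identifiers recorded on the profile.
#' @return An `mc_profile` carrying fractions (and counts when `spec$depth`
#'   is set).
#' @export
simulate_classifier_profile <- function(truth, spec, ref,
                                        sample_id = truth$dmc_id,
                                        classifier_id = "simulated") {
  stopifnot(inherits(truth, "ground_truth"), inherits(spec, "simulation_spec"))
  truth_ids <- truth$entries$taxid
  pool <- setdiff(species_taxids(ref), truth_ids)
  if (spec$n_fp > length(pool)) {
    stop(sprintf("taxonomy holds %d off-truth species, %d FPs requested",
                 length(pool), spec$n_fp), call. = FALSE)
  }
  with_seed(spec$seed + 1L, {
    detected <- stats::runif(length(truth_ids)) >= spec$fn_prob
    tp_ids <- truth_ids[detected]
    tp_w <- truth$entries$fraction[detected]
    if (is.null(tp_w) || all(is.na(tp_w))) tp_w <- rep(1, length(tp_ids))
    if (spec$noise_cv > 0 && length(tp_w) > 0L) {
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      tp_w <- tp_w * stats::rlnorm(length(tp_w), -sdlog^2 / 2, sdlog)
    }
    fp_ids <- if (spec$n_fp > 0L) sort(pool[sample.int(length(pool), spec$n_fp)])
              else integer(0)
    fp_w <- spec$fp_weight_scale * 10^stats::runif(spec$n_fp, -1, 1)

    ids <- c(tp_ids, fp_ids)
    w <- c(tp_w, fp_w)
    if (length(ids) == 0L) {
      return(mc_profile(sample_id, classifier_id,
                        unclassified_fraction = 1))
    }
    frac <- w / sum(w) * (1 - spec$unclassified_frac)
    counts <- if (!is.null(spec$depth)) round(frac * spec$depth) else NA_real_
    mc_profile(sample_id, classifier_id,
               data.frame(taxid = ids, name = ref$name[tax_index(ref, ids)],
                          rank = "species", count = counts, fraction = frac,
                          stringsAsFactors = FALSE),
               unclassified_fraction = spec$unclassified_frac)
  })
}

#' Simulate a nanopore-like FASTQ read set
#'
#' Lognormal read lengths and per-read Gaussian-jittered base qualities
#' clipped to \[0, 60\] (constant within a read, so a read's mean quality is
#' exactly its drawn value under either averaging convention), with uniform
#' random A/C/G/T bases. Deterministic under the seed.
#'
#' @param n_reads Number of reads.
#' @param length_meanlog,length_sdlog Mean and sd of log read length; the
#'   defaults give a median length near 3 kb with a long right tail, the
#'   shape of a typical nanopore metagenomic run.
#' @param quality_mean,quality_sd Mean and sd of the per-read Phred quality.
#' @param seed Integer seed.
#' @param path Optional FASTQ output path; when given the read set is also
#'   written there via [write_fastq()].
#' @return A `read_set`.
#' @export
simulate_reads <- function(n_reads, length_meanlog = log(3000),
                           length_sdlog = 0.6, quality_mean = 12,
                           quality_sd = 3, seed = 1L, path = NULL) {
  stopifnot(n_reads >= 1L)
  reads <- with_seed(seed, {
    len <- pmax(1L, as.integer(round(stats::rlnorm(n_reads, length_meanlog,
                                                   length_sdlog))))
    q <- as.integer(round(pmin(60, pmax(0, stats::rnorm(n_reads, quality_mean,
                                                        quality_sd)))))
    seqs <- vapply(len, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    read_set(sprintf("read_%06d", seq_len(n_reads)), seqs,
             lapply(seq_len(n_reads), function(i) rep(q[i], len[i])))
  })
  if (!is.null(path)) write_fastq(reads, path)
  reads
}

dmp_line <- function(...) paste0(paste(list(...), collapse = "\t|\t"), "\t|")

#' Emit a mini taxonomy dump
#'
#' Writes a small but structurally faithful NCBI-style taxdump: a root, a
#' superkingdom, one genus node per distinct genus (the first word of each
#' binomial) and one species node per name, plus optional decoy species
#' (targets for planted false positives), merged-id pairs pointing at real
#' species, and deleted ids. The files use the pipe-delimited dmp dialect, so
#' [load_taxonomy()] exercises the same parser as on a real dump.
#'
#' @param truth_species Character vector of binomial species names.
#' @param n_decoys Number of decoy species (each in its own decoy genus).
#' @param n_merged Number of synthetic merged-id pairs (old ids 9001, 9002,
#'   ... mapped onto the first species ids).
#' @param n_deleted Number of synthetic deleted ids (9501, 9502, ...).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed (reserved for future stochastic structure; the
#'   layout itself is deterministic).
#' @return List with paths `nodes`, `names`, `merged`, `delnodes`, the
#'   `species` taxid vector (named by species name), `decoys`, `merged_ids`
#'   and `deleted_ids`.
#' @export
make_mini_taxonomy <- function(truth_species, n_decoys = 0L, n_merged = 0L,
                               n_deleted = 0L, dir = tempfile("minitax"),
                               seed = 1L) {
  stopifnot(length(truth_species) >= 1L, n_decoys >= 0L, n_merged >= 0L,
            n_deleted >= 0L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  species <- c(truth_species,
               if (n_decoys > 0L) sprintf("Decoyus%02d synthetica",
                                          seq_len(n_decoys)))
  genus_of <- vapply(strsplit(species, " "), `[[`, character(1), 1L)

  nodes <- list(c(1L, 1L, "no rank"), c(2L, 1L, "superkingdom"))
  names_tab <- list(c(1L, "root"), c(2L, "Bacteria"))
  next_id <- 3L
  genus_id <- integer(0)
  species_id <- integer(length(species))
  for (i in seq_along(species)) {
    g <- genus_of[i]
    if (is.na(match(g, names(genus_id)))) {
      genus_id[g] <- next_id
      nodes[[length(nodes) + 1L]] <- c(next_id, 2L, "genus")
      names_tab[[length(names_tab) + 1L]] <- c(next_id, g)
      next_id <- next_id + 1L
    }
    species_id[i] <- next_id
    nodes[[length(nodes) + 1L]] <- c(next_id, genus_id[[g]], "species")
    names_tab[[length(names_tab) + 1L]] <- c(next_id, species[i])
    next_id <- next_id + 1L
  }
  names(species_id) <- species

  merged_old <- if (n_merged > 0L) 9000L + seq_len(n_merged) else integer(0)
  merged_new <- if (n_merged > 0L)
    species_id[rep_len(seq_along(species_id), n_merged)] else integer(0)
  deleted <- if (n_deleted > 0L) 9500L + seq_len(n_deleted) else integer(0)

  paths <- list(nodes = file.path(dir, "nodes.dmp"),
                names = file.path(dir, "names.dmp"),
                merged = file.path(dir, "merged.dmp"),
                delnodes = file.path(dir, "delnodes.dmp"))
  writeLines(vapply(nodes, function(n) dmp_line(n[1], n[2], n[3]),
                    character(1)), paths$nodes)
  writeLines(vapply(names_tab, function(n)
    dmp_line(n[1], n[2], "", "scientific name"), character(1)), paths$names)
  writeLines(if (n_merged > 0L)
    mapply(dmp_line, merged_old, merged_new) else character(0), paths$merged)
  writeLines(if (n_deleted > 0L)
    vapply(deleted, dmp_line, character(1)) else character(0), paths$delnodes)

  c(paths, list(
    species = species_id[truth_species],
    decoys = if (n_decoys > 0L) species_id[setdiff(species, truth_species)]
             else integer(0),
    merged_ids = structure(merged_new, names = as.character(merged_old)),
    deleted_ids = deleted, dir = dir))
}
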
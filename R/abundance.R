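# Rank projection and relative-abundance normalization. Evaluation happens at
# genus and species rank only; the relative abundance is always computed from
# classified reads, so unclassified mass never enters a denominator.

EVAL_RANKS <- c("genus", "species")

#' Project a profile to genus or species rank
#'
#' Maps every entry at or below the target rank to its ancestor at that rank
#' and merges colliding entries by summing counts and fractions. At species
#' rank, entries classified only to genus level (the genus node itself, or a
#' below-genus node whose lineage has no species) become a pseudo-entry
#' `"<Genus> unclassified"`, mirroring the convention of assigning a genus
#' label with an 'unclassified' species designation. Entries above the target
#' rank (and above genus for the pseudo-entry rule) are removed from the entry
#' table and tallied in a reported higher-rank mass; higher ranks are not
#' evaluated. Total mass is conserved exactly across
#' entries + pseudo-entries + higher-rank mass (+ previously dropped mass).
#'
#' @param profile An `mc_profile`; it is synchronized against `ref` first if
#'   it has not been already.
#' @param ref A `taxonomy_ref`.
#' @param rank `"genus"` or `"species"`.
#'
#' @return An `mc_profile` at the target rank. Pseudo-entries carry
#'   `rank == "unclassified <rank>"` and are marked in the logical attribute
#'   column `pseudo` of the entry table; the attribute `higher_rank_mass`
#'   records the count/fraction mass of entries above the target rank.
#' @export
project_to_rank <- function(profile, ref, rank = c("species", "genus")) {
  rank <- match.arg(rank)
  stopifnot(inherits(profile, "mc_profile"), inherits(ref, "taxonomy_ref"))
  if (!isTRUE(attr(profile, "synced"))) profile <- sync_profile(ref, profile)
  e <- profile$entries

  target <- rep(NA_integer_, nrow(e))
  pseudo_genus <- rep(NA_integer_, nrow(e))
  for (i in seq_len(nrow(e))) {
    anc <- ancestor_at_rank(ref, e$taxid[i], rank)
    if (!is.na(anc)) {
      target[i] <- anc
    } else if (rank == "species") {
      g <- ancestor_at_rank(ref, e$taxid[i], "genus")
      if (!is.na(g)) pseudo_genus[i] <- g
    }
  }

  sum_or_na <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  collapse <- function(rows, taxid, name, rnk, pseudo) {
    data.frame(taxid = taxid, name = name, rank = rnk,
               count = sum_or_na(e$count[rows]),
               fraction = sum_or_na(e$fraction[rows]),
               pseudo = pseudo, stringsAsFactors = FALSE)
  }

  main_rows <- which(!is.na(target))
  pseudo_rows <- which(is.na(target) & !is.na(pseudo_genus))
  higher_rows <- which(is.na(target) & is.na(pseudo_genus))

  out <- list()
  for (tid in unique(target[main_rows])) {
    rows <- main_rows[target[main_rows] == tid]
    i <- tax_index(ref, tid)
    out[[length(out) + 1L]] <- collapse(rows, tid, ref$name[i], rank, FALSE)
  }
  for (g in unique(pseudo_genus[pseudo_rows])) {
    rows <- pseudo_rows[pseudo_genus[pseudo_rows] == g]
    i <- tax_index(ref, g)
    out[[length(out) + 1L]] <- collapse(
      rows, g, paste(ref$name[i], "unclassified"),
      paste("unclassified", rank), TRUE)
  }

  higher_mass <- list(count = sum(e$count[higher_rows], na.rm = TRUE),
                      fraction = sum(e$fraction[higher_rows], na.rm = TRUE))

  entries <- if (length(out) > 0L) do.call(rbind, out) else
    cbind(empty_entries(), data.frame(pseudo = logical(0)))
  res <- mc_profile(profile$sample_id, profile$classifier_id,
                    entries[c("taxid", "name", "rank", "count", "fraction")],
                    unclassified_count = profile$unclassified_count,
                    unclassified_fraction = profile$unclassified_fraction)
  res$entries$pseudo <- entries$pseudo
  attr(res, "synced") <- TRUE
  attr(res, "rank") <- rank
  attr(res, "higher_rank_mass") <- higher_mass
  attr(res, "dropped") <- attr(profile, "dropped")
  attr(res, "dropped_mass") <- attr(profile, "dropped_mass")
  res
}

#' Construct an abundance vector
#'
#' A named numeric vector of non-negative weights over taxa at a single rank;
#' non-empty vectors sum to 1 within 1e-9. Names are taxids (as character)
#' for taxonomy-resolved vectors, or lower-cased taxon names otherwise.
#'
#' @param weights Named numeric vector.
#' @param rank Rank label the vector lives at.
#' @return An object of class `abundance_vector`.
#' @export
abundance_vector <- function(weights, rank = NA_character_) {
  weights <- unlist(weights)
  if (length(weights) > 0L) {
    stopifnot(!is.null(names(weights)), all(weights >= 0))
    if (abs(sum(weights) - 1) > 1e-9) {
      stop(sprintf("abundance weights sum to %.12f, not 1", sum(weights)),
           call. = FALSE)
    }
  } else {
    weights <- structure(numeric(0), names = character(0))
  }
  structure(weights, rank = rank, class = "abundance_vector")
}

#' @export
print.abundance_vector <- function(x, ...) {
  cat(sprintf("<abundance_vector> rank %s, %d taxa\n", attr(x, "rank"),
              length(x)))
  if (length(x) > 0L) print(unclass(x)[order(-unclass(x))][seq_len(min(10, length(x)))])
  invisible(x)
}

#' Relative abundances over classified reads
#'
#' Normalizes a rank-projected profile into an abundance vector using only the
#' classified mass at the target rank: the unclassified fraction, mass at
#' ranks above the target, and the `"<Genus> unclassified"` pseudo-entries are
#' all excluded from both the vector and its denominator (pseudo-entries name
#' no species and can match no ground-truth species; their mass is reported
#' separately by [project_to_rank()]). Counts are preferred over fractions
#' when both are present.
#'
#' @param profile An `mc_profile` produced by [project_to_rank()].
#' @return An `abundance_vector` named by taxid; empty when no classified
#'   mass remains (e.g. every read unclassified).
#' @export
renormalize_classified <- function(profile) {
  stopifnot(inherits(profile, "mc_profile"))
  e <- profile$entries
  if (!is.null(e$pseudo)) e <- e[!e$pseudo, , drop = FALSE]
  mass <- if (nrow(e) > 0L && !all(is.na(e$count))) e$count else e$fraction
  keep <- !is.na(mass) & mass > 0
  e <- e[keep, , drop = FALSE]
  mass <- mass[keep]
  if (nrow(e) == 0L || sum(mass) <= 0) {
    return(abundance_vector(numeric(0), rank = attr(profile, "rank")))
  }
  w <- mass / sum(mass)
  names(w) <- ifelse(is.na(e$taxid), tolower(e$name), as.character(e$taxid))
  v <- abundance_vector(w, rank = attr(profile, "rank"))
  attr(v, "taxon_names") <- structure(e$name, names = names(w))
  v
}

#' Convert sequence abundance to taxonomic abundance
#'
#' Sequence abundance (fraction of classified reads per taxon) over-represents
#' taxa with large genomes. Dividing each weight by the taxon's genome length
#' and renormalizing yields taxonomic abundance (fraction of genomes/cells),
#' the scale on which marker-based profilers report:
#' `w'_i = (w_i / L_i) / sum_j (w_j / L_j)`.
#' The conversion is invariant to a common rescaling of all lengths.
#'
#' @param v An `abundance_vector`.
#' @param genome_lengths Named numeric vector of genome lengths in bp,
#'   covering every taxon in `v`.
#' @return The converted `abundance_vector`.
#' @export
sequence_to_taxonomic <- function(v, genome_lengths) {
  stopifnot(inherits(v, "abundance_vector"))
  if (length(v) == 0L) return(v)
  L <- genome_lengths[names(v)]
  bad <- is.na(L) | L <= 0
  if (any(bad)) {
    stop("missing or non-positive genome length for taxa: ",
         paste(names(v)[bad], collapse = ", "), call. = FALSE)
  }
  w <- unclass(v) / L
  out <- abundance_vector(w / sum(w), rank = attr(v, "rank"))
  attr(out, "taxon_names") <- attr(v, "taxon_names")
  out
}
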
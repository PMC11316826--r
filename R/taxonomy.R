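# NCBI-style taxonomy dumps: loading, taxid resolution across taxonomy
# versions, and rank projection by ancestor walks.

# Split one .dmp line into fields. Records end in "\t|" and fields are
# separated by "\t|\t"; names may contain spaces but never tabs.
split_dmp_line <- function(line) {
  line <- sub("\t\\|$", "", line)
  strsplit(line, "\t|\t", fixed = TRUE)[[1]]
}

read_dmp <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(matrix(character(0), ncol = n_fields))
  }
  fields <- lapply(seq_along(lines), function(i) {
    f <- split_dmp_line(lines[[i]])
    if (length(f) < n_fields) {
      stop(sprintf("malformed %s record at %s line %d: expected >= %d fields, found %d",
                   what, path, i, n_fields, length(f)), call. = FALSE)
    }
    f[seq_len(n_fields)]
  })
  do.call(rbind, fields)
}

#' Load an NCBI-style taxonomy dump
#'
#' Reads the four standard taxdump files (`nodes.dmp`, `names.dmp`,
#' `merged.dmp`, `delnodes.dmp`) into a taxonomy reference used for taxid
#' synchronization and rank projection. Only `"scientific name"` entries from
#' `names.dmp` populate the name index, so name-based fallback matching never
#' hits synonyms or common names.
#'
#' @param nodes_path Path to `nodes.dmp` (taxid, parent taxid, rank, ...).
#' @param names_path Path to `names.dmp` (taxid, name, unique name, class).
#' @param merged_path Path to `merged.dmp` (old taxid, new taxid). May be empty.
#' @param delnodes_path Path to `delnodes.dmp` (deleted taxid). May be empty.
#'
#' @return An object of class `taxonomy_ref`: a list with `taxid`, `parent`,
#'   `rank`, `name` (parallel vectors over nodes), `merged` (named integer
#'   vector, old -> new), `deleted` (integer vector), and `name_index` (named
#'   integer vector keyed by lower-cased scientific name).
#'
#' @examples
#' paths <- make_mini_taxonomy(c("Escherichia coli", "Bacillus subtilis"),
#'                             dir = tempfile(), seed = 1)
#' ref <- load_taxonomy(paths$nodes, paths$names, paths$merged, paths$delnodes)
#' ref
#' @export
load_taxonomy <- function(nodes_path, names_path, merged_path, delnodes_path) {
  for (p in c(nodes_path, names_path, merged_path, delnodes_path)) {
    if (!file.exists(p)) stop("taxonomy dump file not found: ", p, call. = FALSE)
  }
  nodes <- read_dmp(nodes_path, 3L, "nodes.dmp")
  taxid <- as.integer(nodes[, 1L])
  parent <- as.integer(nodes[, 2L])
  rank <- nodes[, 3L]
  if (anyNA(taxid) || anyNA(parent)) {
    stop("non-integer taxid in ", nodes_path, call. = FALSE)
  }
  if (anyDuplicated(taxid)) {
    stop("duplicate taxid in ", nodes_path, call. = FALSE)
  }

  root <- taxid[taxid == parent]
  if (length(root) != 1L) {
    stop("taxonomy has no unique root (taxid == parent_taxid): ", nodes_path,
         call. = FALSE)
  }
  missing_parent <- setdiff(parent, taxid)
  if (length(missing_parent) > 0L) {
    stop("parent taxid(s) absent from nodes: ",
         paste(missing_parent, collapse = ", "), call. = FALSE)
  }

  nm <- read_dmp(names_path, 4L, "names.dmp")
  sci <- nm[nm[, 4L] == "scientific name", , drop = FALSE]
  name <- rep(NA_character_, length(taxid))
  idx <- match(as.integer(sci[, 1L]), taxid)
  keep <- !is.na(idx)
  name[idx[keep]] <- sci[keep, 2L]

  mg <- read_dmp(merged_path, 2L, "merged.dmp")
  merged <- as.integer(mg[, 2L])
  names(merged) <- mg[, 1L]

  dl <- read_dmp(delnodes_path, 1L, "delnodes.dmp")
  deleted <- as.integer(dl[, 1L])

  overlap <- intersect(as.integer(names(merged)), taxid)
  if (length(overlap) > 0L) {
    stop("merged taxid(s) also present as nodes: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  bad_del <- intersect(deleted, c(taxid, as.integer(names(merged))))
  if (length(bad_del) > 0L) {
    stop("deleted taxid(s) present in nodes or merged: ",
         paste(bad_del, collapse = ", "), call. = FALSE)
  }

  name_index <- structure(taxid[!is.na(name)], names = tolower(name[!is.na(name)]))
  # first occurrence wins on (rare) duplicate scientific names
  name_index <- name_index[!duplicated(names(name_index))]

  structure(
    list(taxid = taxid, parent = parent, rank = rank, name = name,
         root = root, merged = merged, deleted = deleted,
         name_index = name_index),
    class = "taxonomy_ref"
  )
}

#' @export
print.taxonomy_ref <- function(x, ...) {
  cat(sprintf("<taxonomy_ref> %d nodes (%d ranks), %d merged, %d deleted\n",
              length(x$taxid), length(unique(x$rank)), length(x$merged),
              length(x$deleted)))
  invisible(x)
}

tax_index <- function(ref, taxid) match(taxid, ref$taxid)

#' Resolve a taxid against a taxonomy reference
#'
#' Determines whether a taxid is current, has been merged into another id
#' (chains are followed transitively with a cycle guard), has been deleted,
#' or is unknown to this taxonomy version.
#'
#' @param ref A `taxonomy_ref` from [load_taxonomy()].
#' @param taxid Integer taxid to resolve.
#'
#' @return A list with `status` (one of `"current"`, `"merged"`, `"deleted"`,
#'   `"unknown"`) and `current_taxid` (the up-to-date taxid, or `NA` when the
#'   status is `deleted` or `unknown`).
#' @export
resolve_taxid <- function(ref, taxid) {
  stopifnot(inherits(ref, "taxonomy_ref"), length(taxid) == 1L)
  taxid <- as.integer(taxid)
  if (!is.na(tax_index(ref, taxid))) {
    return(list(status = "current", current_taxid = taxid))
  }
  if (taxid %in% ref$deleted) {
    return(list(status = "deleted", current_taxid = NA_integer_))
  }
  seen <- integer(0)
  cur <- taxid
  while (as.character(cur) %in% names(ref$merged)) {
    if (cur %in% seen) stop("cycle in merged taxid chain at ", cur, call. = FALSE)
    seen <- c(seen, cur)
    cur <- ref$merged[[as.character(cur)]]
    if (!is.na(tax_index(ref, cur))) {
      return(list(status = "merged", current_taxid = cur))
    }
    if (cur %in% ref$deleted) {
      return(list(status = "deleted", current_taxid = NA_integer_))
    }
  }
  list(status = "unknown", current_taxid = NA_integer_)
}

#' Find the ancestor of a taxon at a given rank
#'
#' Walks parent links upward from the (resolved) taxid and returns the first
#' node whose rank equals `rank`. A node already at the target rank returns
#' itself. There is no downward walk: querying a genus at species rank yields
#' `NA`, as does any lineage that lacks the target rank.
#'
#' @param ref A `taxonomy_ref`.
#' @param taxid Integer taxid; merged ids are resolved first.
#' @param rank Target rank label, e.g. `"species"` or `"genus"`.
#'
#' @return The ancestor taxid at `rank`, or `NA_integer_` when the walk
#'   reaches the root without a match.
#' @export
ancestor_at_rank <- function(ref, taxid, rank) {
  res <- resolve_taxid(ref, taxid)
  if (!res$status %in% c("current", "merged")) {
    stop("cannot resolve taxid ", taxid, " (status: ", res$status, ")",
         call. = FALSE)
  }
  cur <- res$current_taxid
  repeat {
    i <- tax_index(ref, cur)
    if (ref$rank[i] == rank) return(cur)
    if (cur == ref$root) return(NA_integer_)
    cur <- ref$parent[i]
  }
}

#' Synchronize a classifier profile against a taxonomy reference
#'
#' Remaps merged taxids to their current ids, combines entries that collide
#' after remapping by summing their counts and fractions, and rescues entries
#' with deleted or unknown taxids through a case-insensitive exact match of the
#' scientific name. Entries that cannot be rescued are dropped; the number of
#' dropped entries and their abundance mass are recorded on the returned
#' profile so no mass disappears silently.
#'
#' @param ref A `taxonomy_ref`.
#' @param profile An `mc_profile` (see [mc_profile()]).
#'
#' @return The synchronized `mc_profile` with attributes `synced = TRUE`,
#'   `dropped` (entry count) and `dropped_mass` (list with `count` and
#'   `fraction` totals of dropped entries).
#' @export
sync_profile <- function(ref, profile) {
  stopifnot(inherits(ref, "taxonomy_ref"), inherits(profile, "mc_profile"))
  e <- profile$entries
  if (nrow(e) == 0L) {
    attr(profile, "synced") <- TRUE
    attr(profile, "dropped") <- 0L
    attr(profile, "dropped_mass") <- list(count = 0, fraction = 0)
    return(profile)
  }
  new_taxid <- rep(NA_integer_, nrow(e))
  dropped <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    tid <- e$taxid[i]
    if (!is.na(tid)) {
      res <- resolve_taxid(ref, tid)
      if (res$status %in% c("current", "merged")) {
        new_taxid[i] <- res$current_taxid
        next
      }
    }
    # fall back to scientific-name lookup
    nm <- tolower(e$name[i])
    if (!is.na(nm) && nm %in% names(ref$name_index)) {
      new_taxid[i] <- ref$name_index[[nm]]
    } else {
      dropped[i] <- TRUE
    }
  }

  dropped_mass <- list(
    count = sum(e$count[dropped], na.rm = TRUE),
    fraction = sum(e$fraction[dropped], na.rm = TRUE)
  )
  e <- e[!dropped, , drop = FALSE]
  new_taxid <- new_taxid[!dropped]

  if (nrow(e) > 0L) {
    idx <- tax_index(ref, new_taxid)
    e$taxid <- new_taxid
    e$name <- ref$name[idx]
    e$rank <- ref$rank[idx]
    if (anyDuplicated(new_taxid)) {
      key <- as.character(new_taxid)
      sum_or_na <- function(x) if (all(is.na(x))) x[1] else sum(x, na.rm = TRUE)
      agg <- lapply(split(seq_len(nrow(e)), key), function(rows) {
        data.frame(taxid = e$taxid[rows[1]], name = e$name[rows[1]],
                   rank = e$rank[rows[1]],
                   count = sum_or_na(e$count[rows]),
                   fraction = sum_or_na(e$fraction[rows]),
                   stringsAsFactors = FALSE)
      })
      e <- do.call(rbind, agg[unique(key)])
      rownames(e) <- NULL
    }
  }

  profile$entries <- e
  attr(profile, "synced") <- TRUE
  attr(profile, "dropped") <- sum(dropped)
  attr(profile, "dropped_mass") <- dropped_mass
  profile
}
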
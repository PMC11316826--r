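# Classifier-profile and ground-truth I/O. Three input dialects are supported:
# kraken-style hierarchical reports, mpa-style clade strings, and a generic
# TSV that doubles as the canonical on-disk representation.

#' Construct a classifier profile
#'
#' A profile holds one classifier's output for one sample: a table of taxon
#' entries (each with a taxid and/or name, a rank label, and a read count
#' and/or relative fraction) plus the unclassified portion of the read set.
#'
#' @param sample_id,classifier_id Identifying strings.
#' @param entries A data frame with columns `taxid` (integer, may be `NA`),
#'   `name` (character), `rank` (character), `count` (numeric, may be `NA`),
#'   `fraction` (numeric in \[0, 1\], may be `NA`).
#' @param unclassified_count,unclassified_fraction Unclassified reads, as an
#'   absolute count and/or a fraction of the read set; `NA` when unknown.
#'
#' @return An object of class `mc_profile`.
#' @export
mc_profile <- function(sample_id, classifier_id,
                       entries = empty_entries(),
                       unclassified_count = NA_real_,
                       unclassified_fraction = NA_real_) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  needed <- c("taxid", "name", "rank", "count", "fraction")
  missing <- setdiff(needed, names(entries))
  for (col in missing) entries[[col]] <- if (col == "taxid") NA_integer_ else NA
  entries <- entries[needed]
  if (nrow(entries) > 0L) {
    entries$taxid <- as.integer(entries$taxid)
    entries$name <- as.character(entries$name)
    entries$rank <- as.character(entries$rank)
    entries$count <- as.numeric(entries$count)
    entries$fraction <- as.numeric(entries$fraction)
    no_id <- is.na(entries$taxid) & (is.na(entries$name) | !nzchar(entries$name))
    if (any(no_id)) stop("profile entries must carry a taxid or a name",
                         call. = FALSE)
    no_mass <- is.na(entries$count) & is.na(entries$fraction)
    if (any(no_mass)) stop("profile entries must carry a count or a fraction",
                           call. = FALSE)
    bad_frac <- !is.na(entries$fraction) &
      (entries$fraction < 0 | entries$fraction > 1)
    if (any(bad_frac)) {
      stop("profile fractions must lie in [0, 1]; offending values: ",
           paste(signif(entries$fraction[bad_frac], 4), collapse = ", "),
           call. = FALSE)
    }
    if (any(!is.na(entries$count) & entries$count < 0)) {
      stop("profile counts must be non-negative", call. = FALSE)
    }
  }
  rownames(entries) <- NULL
  structure(
    list(sample_id = as.character(sample_id),
         classifier_id = as.character(classifier_id),
         entries = entries,
         unclassified_count = as.numeric(unclassified_count),
         unclassified_fraction = as.numeric(unclassified_fraction)),
    class = "mc_profile"
  )
}

empty_entries <- function() {
  data.frame(taxid = integer(0), name = character(0), rank = character(0),
             count = numeric(0), fraction = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mc_profile <- function(x, ...) {
  cat(sprintf("<mc_profile> sample '%s', classifier '%s': %d entries\n",
              x$sample_id, x$classifier_id, nrow(x$entries)))
  if (!is.na(x$unclassified_count)) {
    cat(sprintf("  unclassified reads: %g\n", x$unclassified_count))
  }
  if (!is.na(x$unclassified_fraction)) {
    cat(sprintf("  unclassified fraction: %g\n", x$unclassified_fraction))
  }
  if (nrow(x$entries) > 0L) {
    print(utils::head(x$entries, 10))
    if (nrow(x$entries) > 10L) cat("  ...\n")
  }
  invisible(x)
}

# rank-code letter -> rank label, kraken report convention
KREPORT_RANKS <- c(U = "unclassified", R = "root", D = "superkingdom",
                   K = "kingdom", P = "phylum", C = "class", O = "order",
                   F = "family", G = "genus", S = "species")

#' Read a kraken-style report
#'
#' Parses the tab-separated hierarchical report emitted by kraken-family
#' classifiers (Kraken2, Bracken, Centrifuge's kreport converter): columns are
#' percent of reads, clade read count, direct read count, rank code, taxid and
#' an indentation-prefixed name. Entry counts are the clade counts (reads at or
#' below the taxon); an optional `U` row populates the unclassified count.
#' Sub-rank codes such as `S1` map to their base rank.
#'
#' @param path Path to the report file.
#' @param sample_id,classifier_id Identifiers recorded on the profile.
#'
#' @return An `mc_profile` whose entries carry counts (no fractions).
#' @export
read_kreport <- function(path, sample_id, classifier_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- empty_entries()
  unclassified <- NA_real_
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      stop(sprintf("malformed kreport row at %s line %d: expected 6 fields",
                   path, i), call. = FALSE)
    }
    count <- suppressWarnings(as.numeric(f[2]))
    taxid <- suppressWarnings(as.integer(f[5]))
    if (is.na(count) || is.na(taxid)) {
      stop(sprintf("non-numeric count or taxid at %s line %d", path, i),
           call. = FALSE)
    }
    code <- substr(f[4], 1L, 1L)
    if (code == "U") {
      unclassified <- count
      next
    }
    rank <- if (code %in% names(KREPORT_RANKS)) KREPORT_RANKS[[code]] else "no rank"
    rows[[i]] <- data.frame(taxid = taxid, name = sub("^ +", "", f[6]),
                            rank = rank, count = count, fraction = NA_real_,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) > 0L) entries <- do.call(rbind, rows)
  mc_profile(sample_id, classifier_id, entries,
             unclassified_count = unclassified)
}

MPA_RANKS <- c(k = "superkingdom", p = "phylum", c = "class", o = "order",
               f = "family", g = "genus", s = "species", t = "strain")

#' Read an mpa-style clade profile
#'
#' Parses the two-column clade-string dialect used by marker-based profilers
#' (MetaPhlAn, mOTUs converters): a pipe-separated lineage of `k__`/`p__`/...
#' prefixed names and a relative abundance in percent. Only the deepest clade
#' level of each line becomes an entry, so the profile is not double-counted
#' across ranks. A line named `UNCLASSIFIED`, `unclassified` or `unassigned`
#' populates the unclassified fraction.
#'
#' @inheritParams read_kreport
#' @return An `mc_profile` whose entries carry fractions (no counts).
#' @export
read_mpa <- function(path, sample_id, classifier_id) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- list()
  seen <- character(0)   # lineages that reappear as prefixes of deeper lines
  unclassified <- NA_real_
  parsed <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop(sprintf("malformed mpa row at %s line %d", path, i), call. = FALSE)
    }
    pct <- suppressWarnings(as.numeric(f[2]))
    if (is.na(pct)) {
      stop(sprintf("non-numeric abundance at %s line %d", path, i),
           call. = FALSE)
    }
    if (tolower(f[1]) %in% c("unclassified", "unassigned")) {
      unclassified <- pct / 100
      next
    }
    levels <- strsplit(f[1], "|", fixed = TRUE)[[1]]
    prefixes <- substr(levels, 1L, 1L)
    bad <- !prefixes %in% names(MPA_RANKS) | substr(levels, 2L, 3L) != "__"
    if (any(bad)) {
      stop(sprintf("unknown clade prefix '%s' at %s line %d",
                   levels[bad][1], path, i), call. = FALSE)
    }
    parsed[[length(parsed) + 1L]] <- list(lineage = f[1], levels = levels,
                                          prefix = prefixes[length(prefixes)],
                                          pct = pct)
  }
  lineages <- vapply(parsed, `[[`, character(1), "lineage")
  for (p in parsed) {
    # keep only lines that are not a strict prefix of a deeper line
    deeper <- startsWith(lineages, paste0(p$lineage, "|"))
    if (any(deeper)) next
    name <- gsub("_", " ", sub("^[a-z]__", "", p$levels[length(p$levels)]))
    rows[[length(rows) + 1L]] <- data.frame(
      taxid = NA_integer_, name = name, rank = MPA_RANKS[[p$prefix]],
      count = NA_real_, fraction = p$pct / 100, stringsAsFactors = FALSE)
  }
  entries <- if (length(rows) > 0L) do.call(rbind, rows) else empty_entries()
  mc_profile(sample_id, classifier_id, entries,
             unclassified_fraction = unclassified)
}

GENERIC_HEADER <- c("sample_id", "classifier_id", "taxid", "name", "rank",
                    "count", "fraction")

#' Read a generic TSV profile
#'
#' Reads the canonical tabular profile dialect (also emitted by
#' [write_profile()]): a TSV with header `sample_id`, `classifier_id`,
#' `taxid`, `name`, `rank`, `count`, `fraction`. Empty cells become absent
#' fields. Rows with rank `unclassified` populate the unclassified count and
#' fraction. This dialect is the interoperability contract for classifiers
#' without a dedicated parser (KMA, CCMetagen, Kaiju summaries): convert their
#' native output to this table with any tool and ingest it here.
#'
#' @param path Path to the TSV file.
#' @return An `mc_profile`.
#' @export
read_generic_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  missing <- setdiff(GENERIC_HEADER, names(df))
  if (length(missing) > 0L) {
    stop("generic profile ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  uncl <- df$rank == "unclassified"
  sample_id <- if (nrow(df) > 0L) df$sample_id[1] else ""
  classifier_id <- if (nrow(df) > 0L) df$classifier_id[1] else ""
  entries <- data.frame(
    taxid = as.integer(num(df$taxid[!uncl])),
    name = ifelse(nzchar(df$name[!uncl]), df$name[!uncl], NA_character_),
    rank = df$rank[!uncl],
    count = num(df$count[!uncl]),
    fraction = num(df$fraction[!uncl]),
    stringsAsFactors = FALSE)
  mc_profile(sample_id, classifier_id, entries,
             unclassified_count = if (any(uncl)) num(df$count[uncl])[1] else NA_real_,
             unclassified_fraction = if (any(uncl)) num(df$fraction[uncl])[1] else NA_real_)
}

#' Write a profile in the canonical TSV dialect
#'
#' Entries are sorted by descending fraction (then descending count, then
#' ascending taxid, then name) so that two writes of the same profile are
#' byte-identical. An unclassified row (rank `unclassified`) is appended when
#' the profile records one. Numbers are written with full precision so the
#' read/write round trip is exact.
#'
#' @param profile An `mc_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "mc_profile"))
  e <- profile$entries
  if (nrow(e) > 0L) {
    ord <- order(-replace(e$fraction, is.na(e$fraction), -Inf),
                 -replace(e$count, is.na(e$count), -Inf),
                 e$taxid, e$name, method = "radix")
    e <- e[ord, , drop = FALSE]
  }
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  lines <- paste(GENERIC_HEADER, collapse = "\t")
  if (nrow(e) > 0L) {
    lines <- c(lines, paste(profile$sample_id, profile$classifier_id,
                            fmt(e$taxid), ifelse(is.na(e$name), "", e$name),
                            e$rank, fmt(e$count), fmt(e$fraction), sep = "\t"))
  }
  if (!is.na(profile$unclassified_count) ||
      !is.na(profile$unclassified_fraction)) {
    lines <- c(lines, paste(profile$sample_id, profile$classifier_id, "", "",
                            "unclassified", fmt(profile$unclassified_count),
                            fmt(profile$unclassified_fraction), sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Construct a ground-truth mock community composition
#'
#' @param dmc_id Identifier of the defined mock community.
#' @param entries Data frame with columns `taxid` (integer, may be `NA`),
#'   `name` (character), `fraction` (expected sequence abundance in \[0, 1\],
#'   or all-`NA` when the community's exact abundances are unknown) and
#'   `genome_length` (bp, optional).
#'
#' @return An object of class `ground_truth` with an `abundances_available`
#'   flag: communities distributed without exact abundance certificates can
#'   still be scored on detection metrics, but are excluded from L1 distances.
#' @export
ground_truth <- function(dmc_id, entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  for (col in c("taxid", "name", "fraction", "genome_length")) {
    if (is.null(entries[[col]])) {
      entries[[col]] <- if (col %in% c("taxid")) NA_integer_ else NA_real_
    }
  }
  entries <- entries[c("taxid", "name", "fraction", "genome_length")]
  entries$taxid <- as.integer(entries$taxid)
  entries$name <- as.character(entries$name)
  entries$fraction <- as.numeric(entries$fraction)
  entries$genome_length <- as.numeric(entries$genome_length)

  key <- ifelse(is.na(entries$taxid), tolower(entries$name), entries$taxid)
  if (anyDuplicated(key)) {
    stop("duplicate taxa in ground truth: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  have_frac <- !is.na(entries$fraction)
  abundances_available <- nrow(entries) > 0L && all(have_frac)
  if (any(have_frac) && !all(have_frac)) {
    stop("ground-truth fractions must be given for all taxa or none",
         call. = FALSE)
  }
  if (abundances_available) {
    s <- sum(entries$fraction)
    if (abs(s - 1) > 1e-6) {
      stop(sprintf("ground-truth fractions sum to %.8f, not 1", s),
           call. = FALSE)
    }
  }
  if (any(!is.na(entries$genome_length) & entries$genome_length <= 0)) {
    stop("genome lengths must be positive", call. = FALSE)
  }
  rownames(entries) <- NULL
  structure(list(dmc_id = as.character(dmc_id), entries = entries,
                 abundances_available = abundances_available),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> DMC '%s': %d taxa (%s)\n", x$dmc_id,
              nrow(x$entries),
              if (x$abundances_available) "abundances known"
              else "abundances unavailable"))
  invisible(x)
}

#' Read a ground-truth composition table
#'
#' TSV with header `dmc_id`, `taxid`, `name`, `fraction`, `genome_length`;
#' the fraction and genome-length columns may be empty throughout (a mock
#' community distributed without an exact abundance certificate).
#'
#' @param path Path to the TSV file.
#' @return A `ground_truth`.
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("dmc_id", "taxid", "name")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("ground truth ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num <- function(x) {
    if (is.null(x)) return(rep(NA_real_, nrow(df)))
    suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  }
  ground_truth(
    dmc_id = if (nrow(df) > 0L) df$dmc_id[1] else "",
    entries = data.frame(
      taxid = as.integer(num(df$taxid)),
      name = ifelse(nzchar(df$name), df$name, NA_character_),
      fraction = num(df$fraction),
      genome_length = num(df$genome_length),
      stringsAsFactors = FALSE))
}

#' Write a ground-truth composition table
#'
#' @param truth A `ground_truth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  e <- truth$entries
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  lines <- c(paste(c("dmc_id", "taxid", "name", "fraction", "genome_length"),
                   collapse = "\t"),
             if (nrow(e) > 0L)
               paste(truth$dmc_id, fmt(e$taxid),
                     ifelse(is.na(e$name), "", e$name),
                     fmt(e$fraction), fmt(e$genome_length), sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
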
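# FASTQ read-set statistics and preprocessing: summary statistics (N50,
# length quartiles, Q20/Q30), length/mean-quality filtering, seeded
# subsampling to a base target, and read-length-distribution matching.

# Run `expr` under a fixed Mersenne-Twister seed, restoring the caller's RNG
# state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Construct a read set
#'
#' @param id Character vector of read identifiers.
#' @param sequence Character vector of nucleotide sequences.
#' @param quality List of integer vectors of per-base Phred scores, each the
#'   same length as its sequence.
#' @return An object of class `read_set`.
#' @export
read_set <- function(id, sequence, quality) {
  stopifnot(length(id) == length(sequence), length(sequence) == length(quality))
  lens_ok <- vapply(seq_along(sequence),
                    function(i) nchar(sequence[i]) == length(quality[[i]]),
                    logical(1))
  if (!all(lens_ok)) {
    stop("sequence and quality lengths differ for read(s): ",
         paste(id[!lens_ok], collapse = ", "), call. = FALSE)
  }
  if (length(quality) > 0L && any(unlist(quality) < 0)) {
    stop("Phred scores must be non-negative", call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = as.character(sequence),
                 quality = lapply(quality, as.integer)),
            class = "read_set")
}

#' @export
length.read_set <- function(x) length(x$id)

subset_reads <- function(reads, idx) {
  read_set(reads$id[idx], reads$sequence[idx], reads$quality[idx])
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads, %g bases\n", length(x),
              sum(nchar(x$sequence))))
  invisible(x)
}

#' Read a FASTQ file into a read set
#'
#' Plain or gzip-compressed FASTQ; parsing is delegated to Biostrings and
#' qualities are decoded on the Phred+33 scale.
#'
#' @param path Path to the FASTQ file.
#' @return A `read_set`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping FASTQ metadata columns it parsed itself
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual <- as(Biostrings::quality(x), "IntegerList")
  read_set(sub(" .*$", "", names(x)), as.character(x), as.list(qual))
}

#' Write a read set to FASTQ
#'
#' @param reads A `read_set`.
#' @param path Output path (plain FASTQ).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$id
  quals <- Biostrings::BStringSet(vapply(
    reads$quality, function(q) rawToChar(as.raw(q + 33L)), character(1)))
  # Biostrings warns about dropping (empty) metadata columns when qualities
  # are attached; nothing of ours is lost
  withCallingHandlers(
    Biostrings::writeXStringSet(seqs, path, format = "fastq",
                                qualities = quals),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  invisible(path)
}

#' Summary statistics of a read set
#'
#' The columns reported for each mock-community read set: number of reads,
#' total bases, minimum/mean/maximum read length, length quartiles (linear
#' interpolation between order statistics), N50 (the smallest length L such
#' that reads of length >= L contain at least half of the total bases), and
#' the percentage of bases with Phred score >= 20 and >= 30.
#'
#' @param reads A `read_set`.
#' @return A one-row data frame with columns `num_seqs`, `sum_len`,
#'   `min_len`, `avg_len`, `max_len`, `q1_len`, `median_len`, `q3_len`,
#'   `n50`, `q20_pct`, `q30_pct`; all-`NA` (except `num_seqs = 0`,
#'   `sum_len = 0`) for an empty read set.
#' @export
compute_read_stats <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  if (length(reads) == 0L) {
    return(data.frame(num_seqs = 0L, sum_len = 0, min_len = NA_real_,
                      avg_len = NA_real_, max_len = NA_real_,
                      q1_len = NA_real_, median_len = NA_real_,
                      q3_len = NA_real_, n50 = NA_real_,
                      q20_pct = NA_real_, q30_pct = NA_real_))
  }
  len <- nchar(reads$sequence)
  total <- sum(as.numeric(len))
  desc <- sort(len, decreasing = TRUE)
  n50 <- desc[which(cumsum(as.numeric(desc)) >= total / 2)[1]]
  qv <- unlist(reads$quality)
  quart <- stats::quantile(len, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(num_seqs = length(reads), sum_len = total,
             min_len = min(len), avg_len = mean(len), max_len = max(len),
             q1_len = quart[1], median_len = quart[2], q3_len = quart[3],
             n50 = n50,
             q20_pct = 100 * sum(qv >= 20) / length(qv),
             q30_pct = 100 * sum(qv >= 30) / length(qv))
}

#' Mean quality of a read on the Phred scale
#'
#' The default averages error probabilities, the nanopore community
#' convention: `-10 * log10(mean(10^(-q/10)))`, which weights low-quality
#' bases more heavily than an arithmetic mean of Phred scores. The arithmetic
#' convention is available for comparison with tools that use it.
#'
#' @param quality Integer vector of per-base Phred scores (one read).
#' @param convention `"error_prob"` (default) or `"arithmetic"`.
#' @return Mean quality on the Phred scale.
#' @export
mean_read_quality <- function(quality, convention = c("error_prob", "arithmetic")) {
  convention <- match.arg(convention)
  stopifnot(length(quality) > 0L)
  if (convention == "arithmetic") return(mean(quality))
  -10 * log10(mean(10^(-quality / 10)))
}

#' Filter reads by length and mean quality
#'
#' Retains reads whose length is strictly greater than `min_len` and whose
#' mean quality is strictly greater than `min_mean_q` (a read of exactly 1000
#' bases or mean quality exactly 7 is removed). Defaults match the standard
#' nanopore mock-community cleanup of length > 1000 and mean Phred > 7.
#'
#' @param reads A `read_set`.
#' @param min_len Minimum length in bases (exclusive).
#' @param min_mean_q Minimum mean Phred quality (exclusive).
#' @param convention Mean-quality convention, see [mean_read_quality()].
#' @return The filtered `read_set`.
#' @export
filter_reads <- function(reads, min_len = 1000, min_mean_q = 7,
                         convention = c("error_prob", "arithmetic")) {
  stopifnot(inherits(reads, "read_set"))
  convention <- match.arg(convention)
  if (length(reads) == 0L) return(reads)
  mq <- vapply(reads$quality, mean_read_quality, numeric(1),
               convention = convention)
  keep <- nchar(reads$sequence) > min_len & mq > min_mean_q
  subset_reads(reads, which(keep))
}

#' Randomly subsample a read set to a base target
#'
#' Shuffles the reads with a seeded Mersenne-Twister generator and accumulates
#' them until the cumulative base count reaches the target; the last selected
#' read may overshoot it. The same seed on the same input always selects the
#' same reads, so downsampled mock communities are reproducible. The RNG
#' algorithm and seed are recorded in the result's `rng` attribute.
#'
#' @param reads A `read_set`.
#' @param target_bases Target total bases.
#' @param seed Integer seed.
#' @return The subsampled `read_set`; its total bases `B` satisfy
#'   `B >= target_bases` and `B - length(last read) < target_bases`.
#' @export
subsample_to_bases <- function(reads, target_bases, seed = 1L) {
  stopifnot(inherits(reads, "read_set"), target_bases >= 0)
  len <- as.numeric(nchar(reads$sequence))
  total <- sum(len)
  if (total < target_bases) {
    stop(sprintf("read set holds %.0f bases, %.0f short of the %.0f target",
                 total, target_bases - total, target_bases), call. = FALSE)
  }
  ord <- with_seed(seed, sample.int(length(reads)))
  k <- which(cumsum(len[ord]) >= target_bases)[1]
  if (is.na(k)) k <- length(reads)   # target 0 on an empty set
  out <- subset_reads(reads, ord[seq_len(k)])
  attr(out, "rng") <- list(kind = "Mersenne-Twister", seed = as.integer(seed))
  out
}

#' Subsample reads to match a reference read-length distribution
#'
#' Bins the reference lengths into `bins` quantile bins and, within each bin,
#' samples candidates of matching length without replacement until the
#' reference bin count is met. Used to strip the read-length effect when
#' comparing flowcell chemistries: the newer chemistry's reads are matched to
#' the older run's length distribution and read count before downstream
#' comparison. Bins the candidates cannot fill are reported as shortfalls
#' rather than padded.
#'
#' @param candidates A `read_set` to sample from.
#' @param reference_lengths Integer vector of reference read lengths.
#' @param seed Integer seed.
#' @param bins Number of quantile bins.
#' @return The matched `read_set`, with attribute `shortfall` (named integer
#'   vector of unmet per-bin counts; empty when the match is complete).
#' @export
match_length_distribution <- function(candidates, reference_lengths,
                                      seed = 1L, bins = 20L) {
  stopifnot(inherits(candidates, "read_set"), length(reference_lengths) > 0L)
  probs <- seq(0, 1, length.out = bins + 1L)
  breaks <- unique(stats::quantile(reference_lengths, probs, names = FALSE,
                                   type = 7))
  if (length(breaks) == 1L) breaks <- c(breaks - 0.5, breaks + 0.5)
  ref_bin <- cut(reference_lengths, breaks, include.lowest = TRUE,
                 labels = FALSE)
  cand_len <- nchar(candidates$sequence)
  cand_bin <- cut(cand_len, breaks, include.lowest = TRUE, labels = FALSE)
  ref_counts <- tabulate(ref_bin, nbins = length(breaks) - 1L)

  picked <- with_seed(seed, {
    sel <- integer(0)
    for (b in which(ref_counts > 0L)) {
      avail <- which(!is.na(cand_bin) & cand_bin == b)
      take <- min(ref_counts[b], length(avail))
      if (take > 0L) sel <- c(sel, avail[sample.int(length(avail), take)])
    }
    sel
  })
  out <- subset_reads(candidates, sort(picked))
  got <- tabulate(cand_bin[picked], nbins = length(breaks) - 1L)
  short <- ref_counts - got
  short_bins <- which(short > 0L)
  attr(out, "shortfall") <- structure(short[short_bins],
                                      names = as.character(short_bins))
  attr(out, "rng") <- list(kind = "Mersenne-Twister", seed = as.integer(seed))
  out
}
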
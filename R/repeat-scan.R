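#' Longest perfect repeat tract of a trinucleotide unit
#'
#' Finds the maximal substring of `sequence` that is a window of the
#' infinite repetition of `unit`, at any of the three phases. A tract "of n
#' nt" is any n-nt window of the periodic sequence, so lengths that are not
#' multiples of 3 count (e.g. `GCAGCAGCAG` is a 10-nt CAG tract). `N`
#' characters never belong to a tract.
#'
#' @param sequence A nucleotide string (DNA or RNA spelling).
#' @param unit A trinucleotide unit such as `"CAG"`; rotations of the unit
#'   describe the same tracts, so the reported length is rotation-invariant.
#' @return A list of class `repeat_tract` with fields `unit`, `start`
#'   (0-based offset), `length_nt` and `phase` (offset into `unit` at the
#'   tract start), or `NULL` if no tract of at least 3 nt exists. Ties in
#'   length are broken by the smallest start offset.
#' @examples
#' longest_repeat_tract("UUGCAGCAGCAGUU", "CAG")   # length 9, start 2
#' longest_repeat_tract("UUGCAGCAGCAGCUU", "CAG")  # length 10 (trailing C)
#' @seealso [classify_reads()], [count_pure_repeat_reads()]
#' @export
longest_repeat_tract <- function(sequence, unit) {
  if (length(sequence) != 1L) stop("sequence must be a single string")
  s <- normalize_nt(sequence)
  u <- normalize_nt(unit)
  if (nchar(u) != 3L) stop("unit must be a triplet")
  if (grepl("N", u, fixed = TRUE)) stop("unit may not contain N")
  hit <- tract_hit(strsplit(s, "", fixed = TRUE)[[1L]],
                   strsplit(u, "", fixed = TRUE)[[1L]])
  if (is.null(hit)) return(NULL)
  structure(list(unit = u, start = hit$start, length_nt = hit$len,
                 phase = hit$phase),
            class = "repeat_tract")
}

#' @export
print.repeat_tract <- function(x, ...) {
  cat(sprintf("<repeat_tract> unit=%s length=%d nt start=%d phase=%d\n",
              x$unit, x$length_nt, x$start, x$phase))
  invisible(x)
}

# internal core: best run over the three phases for one character vector.
# Returns list(start 0-based, len, phase) or NULL if best run < 3 nt.
tract_hit <- function(ch, uch) {
  n <- length(ch)
  if (n < 3L) return(NULL)
  best <- NULL
  pos <- seq_len(n) - 1L
  for (p in 0:2) {
    ref <- uch[((pos + p) %% 3L) + 1L]
    r <- rle(ch == ref)
    ends <- cumsum(r$lengths)
    keep <- which(r$values & r$lengths >= 3L)
    for (k in keep) {
      len <- r$lengths[k]
      st <- ends[k] - len # 0-based start
      if (is.null(best) || len > best$len ||
          (len == best$len && st < best$start)) {
        best <- list(start = st, len = len, phase = (st + p) %% 3L)
      }
    }
  }
  best
}

# internal: longest tract length (0 if none) for each sequence of a vector
tract_lengths <- function(sequences, unit) {
  u <- normalize_nt(unit)
  uch <- strsplit(u, "", fixed = TRUE)[[1L]]
  chs <- strsplit(normalize_nt(sequences), "", fixed = TRUE)
  vapply(chs, function(ch) {
    h <- tract_hit(ch, uch)
    if (is.null(h)) 0L else h$len
  }, integer(1))
}

#' Classify reads by the length of their longest repeat tract
#'
#' Bins reads into tract-length classes `min_len..max_len` nt by the length
#' of the longest `unit` tract each read carries; tracts longer than
#' `max_len` are clamped into the top class, and reads whose longest tract
#' is below `min_len` are tallied as unclassified. Each read contributes to
#' exactly one bin, weighted by its (collapsed) count, so class totals plus
#' the unclassified tally conserve the input count exactly.
#'
#' @param reads A character vector of sequences or a data.frame with columns
#'   `read_id`, `sequence` and optional `count` (see [read_reads()]).
#' @param unit Trinucleotide unit to scan for.
#' @param min_len,max_len Inclusive class range in nt.
#' @return An object of class `read_class_table`: a list with `class_counts`
#'   (named numeric vector over `min_len:max_len`), `unclassified`, `total`,
#'   plus the scan parameters. Coerce with `as.data.frame()` for a
#'   `class_nt` / `read_count` / `fraction` table.
#' @examples
#' r <- c(strrep("CAG", 17), "CAGCAGCAG", "ACGTACGTAA")
#' tab <- classify_reads(r, "CAG", min_len = 10, max_len = 50)
#' as.data.frame(tab)[tab$class_counts > 0, ]
#' @export
classify_reads <- function(reads, unit = "CAG", min_len = 10L, max_len = 50L) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  if (min_len < 3L) stop("min_len must be >= 3 (tracts are >= 3 nt)")
  reads <- as_read_records(reads)
  classes <- seq.int(min_len, max_len)
  counts <- stats::setNames(numeric(length(classes)), classes)
  unclassified <- 0
  if (nrow(reads) > 0L) {
    lens <- tract_lengths(reads$sequence, unit)
    cls <- pmin(lens, max_len)
    ok <- lens >= min_len
    if (any(ok)) {
      agg <- tapply(reads$count[ok], cls[ok], sum)
      counts[names(agg)] <- as.numeric(agg)
    }
    unclassified <- sum(reads$count[!ok])
  }
  structure(list(unit = normalize_nt(unit), min_len = as.integer(min_len),
                 max_len = as.integer(max_len), class_counts = counts,
                 unclassified = as.numeric(unclassified),
                 total = sum(counts) + as.numeric(unclassified)),
            class = "read_class_table")
}

#' @export
print.read_class_table <- function(x, ...) {
  cat(sprintf("<read_class_table> unit=%s classes=%d..%d nt\n",
              x$unit, x$min_len, x$max_len))
  cat(sprintf("  total=%g classified=%g unclassified=%g\n",
              x$total, x$total - x$unclassified, x$unclassified))
  nz <- x$class_counts[x$class_counts > 0]
  if (length(nz))
    cat("  non-empty classes:",
        paste(sprintf("%s:%g", names(nz), nz), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.read_class_table <- function(x, ...) {
  data.frame(class_nt = as.integer(names(x$class_counts)),
             read_count = as.numeric(x$class_counts),
             fraction = if (x$total > 0) x$class_counts / x$total else 0,
             row.names = NULL)
}

#' Count reads that are pure phase-0 repeats of given unit rotations
#'
#' A read counts for a unit `u` iff the entire read equals a prefix of the
#' infinite repetition of `u` starting at phase 0 (so a pure 50-mer
#' beginning `CAGCAG...` counts for `CAG`, not for `AGC` or `GCA`). Reads
#' whose length differs from `read_len` are skipped and tallied.
#'
#' @param reads Character vector or read data.frame.
#' @param units Rotations of one triplet to tally separately.
#' @param read_len Required read length in nt.
#' @return Named numeric vector of per-unit counts, with attribute
#'   `skipped` giving the count of wrong-length reads.
#' @examples
#' count_pure_repeat_reads(substr(strrep("CAG", 17), 1, 50))
#' @export
count_pure_repeat_reads <- function(reads, units = c("CAG", "AGC", "GCA"),
                                    read_len = 50L) {
  units <- normalize_nt(units)
  if (any(nchar(units) != 3L)) stop("units must be triplets")
  if (!all(units %in% unit_rotations(units[1L])))
    stop("units must be rotations of a single triplet")
  reads <- as_read_records(reads)
  seqs <- normalize_nt(reads$sequence)
  right_len <- nchar(seqs) == read_len
  skipped <- sum(reads$count[!right_len])
  res <- stats::setNames(numeric(length(units)), units)
  for (u in units) {
    ref <- periodic_sequence(u, read_len, phase = 0L)
    res[u] <- sum(reads$count[right_len & seqs == ref])
  }
  attr(res, "skipped") <- as.numeric(skipped)
  res
}
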
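#' 19-mer definitions of the CAG-phase and CCG-phase read groups
#'
#' Group 1 holds the three rotations of `(CAG)n` and group 2 the three
#' rotations of `(CCG)n`, each written out as a 19-mer. A read belongs to a
#' group when it contains any of the group's 19-mers as a substring.
#'
#' @param unit1,unit2 Triplet units for the two groups.
#' @param k K-mer length in nt.
#' @return List of class `group_definition` with `group1` and `group2`
#'   character vectors.
#' @export
group_definitions <- function(unit1 = "CAG", unit2 = "CCG", k = 19L) {
  make <- function(u)
    vapply(0:2, function(p) periodic_sequence(normalize_nt(u), k, phase = p), "")
  structure(list(group1 = make(unit1), group2 = make(unit2), k = as.integer(k)),
            class = "group_definition")
}

#' Assign reads to CAG-phase, CCG-phase or other groups
#'
#' A read is `group1` if any group-1 19-mer is a substring, else `group2`
#' if any group-2 19-mer is, else `group3`. Reads matching both groups are
#' assigned to group 1; the ambiguous tally is returned so that precedence
#' choice stays auditable.
#'
#' @param sequences Character vector of read sequences (either T/U dialect).
#' @param defs A [group_definitions()] object.
#' @return Factor with levels `group1`, `group2`, `group3` and attribute
#'   `ambiguous` (logical vector marking reads that matched both groups).
#' @export
assign_group <- function(sequences, defs = group_definitions()) {
  s <- normalize_nt(sequences)
  match_any <- function(kmers) {
    kmers <- normalize_nt(kmers)
    Reduce(`|`, lapply(kmers, function(k) grepl(k, s, fixed = TRUE)))
  }
  g1 <- match_any(defs$group1)
  g2 <- match_any(defs$group2)
  grp <- ifelse(g1, "group1", ifelse(g2, "group2", "group3"))
  out <- factor(grp, levels = c("group1", "group2", "group3"))
  attr(out, "ambiguous") <- g1 & g2
  out
}

#' Profile a RISC-bound small-RNA library by read group
#'
#' Splits a library into the CAG-phase, CCG-phase and remaining read groups
#' and reports raw and per-million-normalized counts, per-group read-length
#' histograms, and per-group species tables (distinct sequences sorted by
#' count). Group counts partition the library exactly and normalization is
#' `raw * 1e6 / total`, so group ratios are preserved.
#'
#' @param reads Character vector or read data.frame (see [read_reads()]).
#' @param defs A [group_definitions()] object.
#' @return Object of class `group_profile`: list with `summary`
#'   (group/raw_count/norm_count data.frame), `ambiguous_count`, `total`,
#'   `lengths` (group/length_nt/count) and `species` (named list of
#'   sequence/count data.frames, count-descending).
#' @export
profile_library <- function(reads, defs = group_definitions()) {
  reads <- as_read_records(reads)
  total <- sum(reads$count)
  if (total == 0 || nrow(reads) == 0L)
    stop("empty library: per-million normalization is undefined")
  grp <- assign_group(reads$sequence, defs)
  raw <- vapply(levels(grp), function(g) sum(reads$count[grp == g]), numeric(1))
  summary <- data.frame(group = levels(grp), raw_count = as.numeric(raw),
                        norm_count = as.numeric(raw) * 1e6 / total,
                        row.names = NULL, stringsAsFactors = FALSE)
  len <- nchar(reads$sequence)
  lengths <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    if (!any(sel)) return(NULL)
    agg <- tapply(reads$count[sel], len[sel], sum)
    data.frame(group = g, length_nt = as.integer(names(agg)),
               count = as.numeric(agg), stringsAsFactors = FALSE)
  }))
  rownames(lengths) <- NULL
  species <- lapply(stats::setNames(nm = levels(grp)), function(g) {
    sel <- grp == g
    if (!any(sel))
      return(data.frame(sequence = character(0), count = numeric(0)))
    agg <- tapply(reads$count[sel], reads$sequence[sel], sum)
    out <- data.frame(sequence = names(agg), count = as.numeric(agg),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$sequence), ]
    rownames(out) <- NULL
    out
  })
  structure(list(summary = summary,
                 ambiguous_count = sum(reads$count[attr(grp, "ambiguous")]),
                 total = total, lengths = lengths, species = species),
            class = "group_profile")
}

#' @export
print.group_profile <- function(x, ...) {
  cat(sprintf("<group_profile> %g reads (%g ambiguous, counted in group1)\n",
              x$total, x$ambiguous_count))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' List reads carrying a long repeat tract
#'
#' Every read whose longest `unit` tract is at least `min_len` nt is
#' reported with its tract length and count, the desk version of listing
#' all Argonaute-bound reads with `(CAG)n` of 8 nt or longer.
#'
#' @param reads Character vector or read data.frame.
#' @param unit Trinucleotide unit.
#' @param min_len Minimum tract length in nt (>= 3).
#' @return data.frame `read_id`, `sequence`, `tract_length`, `count`,
#'   sorted by descending tract length.
#' @export
list_long_repeat_reads <- function(reads, unit = "CAG", min_len = 8L) {
  if (min_len < 3L) stop("min_len must be >= 3")
  reads <- as_read_records(reads)
  lens <- tract_lengths(reads$sequence, unit)
  keep <- lens >= min_len
  out <- data.frame(read_id = reads$read_id[keep],
                    sequence = reads$sequence[keep],
                    tract_length = lens[keep], count = reads$count[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$tract_length, out$read_id), ]
  rownames(out) <- NULL
  out
}

#' Write group-profile tables as TSV
#'
#' @param profile A [profile_library()] result.
#' @param summary_path,lengths_path,species_path Optional output paths; a
#'   `NULL` path skips that table. The species TSV gains a `group` column.
#' @export
write_group_profile <- function(profile, summary_path = NULL,
                                lengths_path = NULL, species_path = NULL) {
  stopifnot(inherits(profile, "group_profile"))
  if (!is.null(summary_path))
    utils::write.table(profile$summary, summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(lengths_path))
    utils::write.table(profile$lengths, lengths_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(species_path)) {
    sp <- do.call(rbind, lapply(names(profile$species), function(g) {
      tab <- profile$species[[g]]
      if (nrow(tab) == 0L) return(NULL)
      cbind(group = g, tab)
    }))
    utils::write.table(sp, species_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(profile)
}
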
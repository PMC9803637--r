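#' Read a small-RNA read library from FASTA or FASTQ
#'
#' Reads are returned as a data.frame of `read_id`, `sequence`, `count`.
#' The collapsed-FASTA dialect, in which the multiplicity of a unique
#' sequence is appended to the identifier as `id_count`, is parsed when
#' every identifier carries such a suffix (or when `collapsed = TRUE`);
#' otherwise each record gets count 1. FASTQ qualities are ignored. Files
#' may be gzip-compressed.
#'
#' @param path Path to a FASTA/FASTQ file (.gz transparent).
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param collapsed `"auto"`, `TRUE` or `FALSE`: parse `id_count` suffixes.
#' @return data.frame with columns `read_id`, `sequence`, `count`.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq"),
                       collapsed = "auto") {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2)$", "", path, ignore.case = TRUE)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  set <- Biostrings::readBStringSet(path, format = format)
  ids <- sub("\\s.*$", "", names(set))
  counts <- rep(1L, length(set))
  has_suffix <- grepl("_[0-9]+$", ids)
  use_collapsed <- isTRUE(collapsed) ||
    (identical(collapsed, "auto") && length(ids) > 0L && all(has_suffix))
  if (use_collapsed && any(has_suffix)) {
    counts[has_suffix] <-
      as.integer(sub("^.*_([0-9]+)$", "\\1", ids[has_suffix]))
    ids[has_suffix] <- sub("_[0-9]+$", "", ids[has_suffix])
  }
  data.frame(read_id = ids, sequence = as.character(set), count = counts,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read transcript region sequences
#'
#' `read_region_fasta()` expects FASTA headers of the form
#' `gene_id|region_kind` with `region_kind` one of `utr5`, `orf`, `utr3`;
#' `read_region_tsv()` expects a 3-column table `gene_id`, `region`,
#' `sequence` (header optional, detected from the first line).
#'
#' @param path Input file.
#' @return data.frame with columns `gene_id`, `region`, `sequence`.
#' @seealso [stitch_gene_models()]
#' @export
read_region_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  parts <- strsplit(sub("\\s.*$", "", names(set)), "|", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("region FASTA headers must look like 'gene_id|region_kind'")
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    region = vapply(parts, `[`, "", 2L),
                    sequence = as.character(set),
                    row.names = NULL, stringsAsFactors = FALSE)
  check_region_kinds(out$region)
  out
}

#' @rdname read_region_fasta
#' @export
read_region_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("gene", first, ignore.case = TRUE)
  out <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  if (ncol(out) < 3L) stop("region TSV needs 3 columns: gene_id, region, sequence")
  out <- out[, 1:3]
  names(out) <- c("gene_id", "region", "sequence")
  check_region_kinds(out$region)
  out
}

check_region_kinds <- function(kind) {
  bad <- setdiff(unique(kind), c("utr5", "orf", "utr3"))
  if (length(bad))
    stop("unknown region kind(s): ", paste(bad, collapse = ", "),
         " (expected utr5, orf, utr3)")
  invisible(TRUE)
}

#' Read a ranked-list (RNK) file
#'
#' Two tab-separated columns, gene id and score; lines starting with `#`
#' are ignored.
#'
#' @param path Input RNK file.
#' @return data.frame with columns `gene_id`, `score`.
#' @export
read_rnk <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("RNK files have two columns: gene id and score")
  data.frame(gene_id = as.character(tab[[1L]]), score = as.numeric(tab[[2L]]),
             stringsAsFactors = FALSE)
}

#' Read and write GMT gene-set files (Broad dialect)
#'
#' Each GMT line is `set_name TAB description TAB member1 TAB member2 ...`.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors, with the
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("malformed GMT line (need >= 3 fields)")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' Write a read-classification table as TSV
#'
#' Columns `class_nt`, `read_count`, `fraction`; the unclassified tally and
#' total are recorded in `#`-comment header lines.
#'
#' @param x A [classify_reads()] result.
#' @param path Output file.
#' @export
write_class_table <- function(x, path) {
  stopifnot(inherits(x, "read_class_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# unit=%s total=%g unclassified=%g",
                     x$unit, x$total, x$unclassified), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write folded structures in Vienna format
#'
#' One block per structure: `>name`, sequence, dot-bracket with the free
#' energy in parentheses.
#'
#' @param structures A named list of [fold()] results.
#' @param path Output file.
#' @export
write_vienna <- function(structures, path) {
  if (is.null(names(structures)) || any(!nzchar(names(structures))))
    stop("structures must be a named list")
  lines <- unlist(lapply(names(structures), function(nm) {
    s <- structures[[nm]]
    c(paste0(">", nm), s$sequence,
      sprintf("%s (%.2f)", s$dot_bracket, s$delta_g))
  }))
  writeLines(lines, path)
  invisible(path)
}
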
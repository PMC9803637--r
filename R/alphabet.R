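#' Normalize nucleotide sequences to a single alphabet
#'
#' Upper-cases sequences and converts between the DNA and RNA spellings
#' (T/U). Internally the package works on the DNA alphabet for matching
#' speed; the input dialect is recorded by callers where it matters for
#' reporting.
#'
#' @param x Character vector of sequences.
#' @param to Target alphabet, `"DNA"` (default) or `"RNA"`.
#' @return Character vector over `A,C,G,T,N` (DNA) or `A,C,G,U,N` (RNA).
#' @examples
#' normalize_nt(c("caguu", "ACGTN"))
#' normalize_nt("ACGT", to = "RNA")
#' @export
normalize_nt <- function(x, to = c("DNA", "RNA")) {
  to <- match.arg(to)
  x <- toupper(as.character(x))
  x <- if (to == "DNA") chartr("U", "T", x) else chartr("T", "U", x)
  alphabet <- if (to == "DNA") "ACGTN" else "ACGUN"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    offenders <- unique(unlist(strsplit(
      gsub(sprintf("[%s]", alphabet), "", x[bad]), "", fixed = TRUE)))
    stop("non-nucleotide characters in sequence(s): ",
         paste(offenders, collapse = ", "))
  }
  x
}

#' The three rotations of a trinucleotide unit
#'
#' @param unit A 3-letter unit such as `"CAG"`.
#' @return Character vector of the rotations starting at offsets 0, 1, 2
#'   (e.g. `CAG`, `AGC`, `GCA`).
#' @examples
#' unit_rotations("CAG")
#' @export
unit_rotations <- function(unit) {
  unit <- normalize_nt(unit)
  if (nchar(unit) != 3L) stop("unit must be a 3-letter string")
  vapply(0:2, function(p) periodic_sequence(unit, 3L, phase = p), "")
}

#' A window of the infinite repetition of a unit
#'
#' Returns the first `len` characters of `unit` repeated indefinitely,
#' starting at offset `phase` into the unit.
#'
#' @param unit Repeat unit (any length >= 1).
#' @param len Desired window length in nt.
#' @param phase Integer offset (0-based) into the unit at which the window
#'   starts.
#' @return A string of length `len`.
#' @examples
#' periodic_sequence("CAG", 10, phase = 2) # "GCAGCAGCAG"
#' @export
periodic_sequence <- function(unit, len, phase = 0L) {
  unit <- toupper(unit)
  k <- nchar(unit)
  ch <- strsplit(unit, "", fixed = TRUE)[[1L]]
  idx <- ((seq_len(len) - 1L + as.integer(phase)) %% k) + 1L
  paste(ch[idx], collapse = "")
}

# internal: validate/coerce a reads argument into a data.frame with
# read_id / sequence / count columns. A bare character vector is accepted.
as_read_records <- function(reads) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = sprintf("read_%d", seq_along(reads)),
                        sequence = reads, count = rep(1L, length(reads)),
                        stringsAsFactors = FALSE)
  }
  if (!is.data.frame(reads) || !all(c("read_id", "sequence") %in% names(reads)))
    stop("reads must be a character vector or a data.frame with columns ",
         "read_id, sequence and (optionally) count")
  if (is.null(reads$count)) reads$count <- 1L
  if (any(reads$count < 1L)) stop("read counts must be >= 1")
  reads
}
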
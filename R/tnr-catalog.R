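#' Stitch per-gene mRNA proxies from transcript regions
#'
#' For each gene the longest deposited candidate of each region kind
#' (5'UTR, ORF, 3'UTR) is selected and the three are concatenated
#' `utr5 + orf + utr3` into an mRNA proxy. Missing kinds are treated as
#' empty. Length ties between candidates are broken by taking the
#' lexicographically first sequence; a message reports such ties.
#'
#' @param regions data.frame with columns `gene_id`, `region`
#'   (`utr5`/`orf`/`utr3`) and `sequence`, e.g. from [read_region_fasta()].
#' @return data.frame of class `gene_models` with columns `gene_id`,
#'   `utr5`, `orf`, `utr3`, `mrna`.
#' @seealso [build_gene_set_family()]
#' @export
stitch_gene_models <- function(regions) {
  if (!all(c("gene_id", "region", "sequence") %in% names(regions)))
    stop("regions needs columns gene_id, region, sequence")
  check_region_kinds(regions$region)
  regions$sequence <- normalize_nt(regions$sequence)
  genes <- unique(regions$gene_id)
  pick <- function(cands) {
    if (length(cands) == 0L) return("")
    len <- nchar(cands)
    top <- cands[len == max(len)]
    if (length(top) > 1L && length(unique(top)) > 1L)
      message("length tie among region candidates; ",
              "keeping the lexicographically first")
    sort(top)[1L]
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    sub <- regions[regions$gene_id == g, ]
    u5 <- pick(sub$sequence[sub$region == "utr5"])
    orf <- pick(sub$sequence[sub$region == "orf"])
    u3 <- pick(sub$sequence[sub$region == "utr3"])
    data.frame(gene_id = g, utr5 = u5, orf = orf, utr3 = u3,
               mrna = paste0(u5, orf, u3), stringsAsFactors = FALSE)
  }))
  class(out) <- c("gene_models", class(out))
  out
}

#' Build a nested family of repeat-containing gene sets
#'
#' A gene belongs to the set at threshold `n` iff its stitched mRNA proxy
#' contains a perfect `unit` tract of at least `n` nt (any phase, same
#' tract definition as [longest_repeat_tract()]); tracts may span region
#' junctions because matching is done on the concatenated mRNA. Sets are
#' nested by construction: members at `n + 1` are a subset of members at
#' `n`.
#'
#' @param models A [stitch_gene_models()] result (or any data.frame with
#'   `gene_id` and `mrna` columns).
#' @param unit Trinucleotide unit (rotation-invariant).
#' @param thresholds Ascending integer vector of minimum tract lengths in nt.
#' @return Object of class `gene_set_family`: list with `unit`,
#'   `thresholds` and `sets` (a named list, one character vector of gene
#'   ids per threshold).
#' @export
build_gene_set_family <- function(models, unit, thresholds = 10:19) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  unit <- normalize_nt(unit)
  if (nrow(models) == 0L) {
    warning("no gene models; returning an empty family")
    lens <- integer(0)
    ids <- character(0)
  } else {
    if (anyDuplicated(models$gene_id))
      stop("duplicate gene ids: ",
           paste(unique(models$gene_id[duplicated(models$gene_id)]),
                 collapse = ", "))
    lens <- tract_lengths(models$mrna, unit)
    ids <- models$gene_id
  }
  sets <- lapply(thresholds, function(t) ids[lens >= t])
  names(sets) <- as.character(thresholds)
  structure(list(unit = unit, thresholds = as.integer(thresholds),
                 sets = sets),
            class = "gene_set_family")
}

#' @export
print.gene_set_family <- function(x, ...) {
  cat(sprintf("<gene_set_family> unit=%s thresholds=%s..%s nt\n",
              x$unit, min(x$thresholds), max(x$thresholds)))
  cat("  set sizes:",
      paste(sprintf("%s:%d", names(x$sets), lengths(x$sets)),
            collapse = " "), "\n")
  invisible(x)
}

#' Write a gene-set family as a GMT file
#'
#' One line per non-empty threshold, named `UNIT_GE_<n>NT` with the unit in
#' its RNA spelling. Empty sets are omitted with a message. Round-trips
#' through [read_gmt()].
#'
#' @param family A [build_gene_set_family()] result.
#' @param path Output GMT path.
#' @export
write_gmt <- function(family, path) {
  stopifnot(inherits(family, "gene_set_family"))
  unit_rna <- normalize_nt(family$unit, to = "RNA")
  lines <- character(0)
  for (t in names(family$sets)) {
    members <- family$sets[[t]]
    if (length(members) == 0L) {
      message("threshold ", t, " nt: empty set omitted from GMT")
      next
    }
    name <- sprintf("%s_GE_%sNT", unit_rna, t)
    desc <- sprintf("genes with a (%s)n tract of >= %s nt in the stitched mRNA",
                    unit_rna, t)
    lines <- c(lines, paste(c(name, desc, members), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
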
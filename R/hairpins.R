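#' Synthesized hairpin oligonucleotide sequences
#'
#' The RNA oligonucleotides used in the CAG-repeat hairpin toxicity
#' experiments, exactly as synthesized: pure-CAG control hairpins of
#' increasing repeat count, two androgen-receptor-derived hairpins whose
#' CAG stem is clamped at the base by a short CUG tract (3 CUG with 9 or 17
#' CAG repeats), and the two huntingtin-derived mimetics of the reference
#' (Ref) and loss-of-inhibition (LOI) repeat-region alleles. Note that the
#' `(CAG)21` and `(CAG)29` oligos were synthesized with phase-shifted /
#' truncated ends, so their lengths are 62 and 84 nt rather than exact
#' multiples of 3.
#'
#' @return Named character vector of RNA sequences.
#' @examples
#' nchar(hairpin_oligos())
#' @export
hairpin_oligos <- function() {
  c(CtrHP_CAG7  = "CAGCAGCAGCAGCAGCAGCAG",
    CtrHP_CAG12 = "CAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAG",
    CtrHP_CAG21 = paste0("AGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGC",
                         "AGCAGCAGCAGCAGCAGCAGCAG"),
    CtrHP_CAG29 = paste0("CAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAG",
                         "CAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAG"),
    CtrHP_CAG40 = strrep("CAG", 40),
    AR_HP_3_9   = "UGCUGCUGCUGCAGCAGCAGCAGCAGCAGCAGCAGCAGCAA",
    AR_HP_3_17  = paste0("UGCUGCUGCUGCAGCAGCAGCAGCAGCAGCAGCAGCAGC",
                         "AGCAGCAGCAGCAGCAGCAGCAGCAA"),
    Ref_HP      = paste0(strrep("CAG", 17), "CAACAGCCGCCA",
                         strrep("CCG", 7), "CCU"),
    LOI_HP      = paste0(strrep("CAG", 21), strrep("CCG", 9), "CCU"))
}

#' Describe a repeat-variant RNA as segments
#'
#' A variant spec is an ordered list of `(sequence, times)` segments —
#' repeat units or literal blocks — plus optional 5'/3' flanks, expanded
#' deterministically by [build_variant()].
#'
#' @param name Variant label.
#' @param segments List; each element either a string (repeated once) or a
#'   `list(seq =, times =)` pair.
#' @param flank5,flank3 Literal flanking sequences (default empty).
#' @return Object of class `variant_spec`.
#' @export
variant_spec <- function(name, segments, flank5 = "", flank3 = "") {
  segments <- lapply(segments, function(s) {
    if (is.character(s)) s <- list(seq = s, times = 1L)
    if (!is.list(s) || is.null(s$seq))
      stop("each segment is a string or a list(seq=, times=)")
    if (is.null(s$times)) s$times <- 1L
    s$seq <- normalize_nt(s$seq, to = "RNA")
    s
  })
  structure(list(name = name, segments = segments,
                 flank5 = normalize_nt(flank5, to = "RNA"),
                 flank3 = normalize_nt(flank3, to = "RNA")),
            class = "variant_spec")
}

#' Expand a variant spec into its RNA sequence
#'
#' @param spec A [variant_spec()].
#' @return RNA sequence string, `flank5 + segments + flank3`.
#' @examples
#' nchar(build_variant(htt_repeat_spec("ref"))) # 153
#' @export
build_variant <- function(spec) {
  stopifnot(inherits(spec, "variant_spec"))
  body <- paste(vapply(spec$segments,
                       function(s) strrep(s$seq, s$times), ""),
                collapse = "")
  paste0(spec$flank5, body, spec$flank3)
}

#' Huntingtin repeat-region variant specs
#'
#' The repeat region of the huntingtin mRNA downstream of the CAG
#' expansion: the reference allele interrupts the repeats as
#' `(CAG)n-CAA-CAG-CCG-CCA-(CCG)7` while the loss-of-inhibition (LOI)
#' allele carries two A-to-G substitutions, `(CAG)n-CAG-CAG-CCG-CCG-(CCG)7`,
#' extending the uninterrupted CAG run from n to n+2 units. Genomic 15-nt
#' flanks for the full construct are a user-supplied input (they are not
#' part of the repeat region itself).
#'
#' @param variant `"ref"` or `"loi"`.
#' @param n_cag CAG repeat count before the interruption block (40 for the
#'   predominant full-penetrance allele).
#' @param flank5,flank3 Optional flanking sequences.
#' @return A [variant_spec()].
#' @export
htt_repeat_spec <- function(variant = c("ref", "loi"), n_cag = 40L,
                            flank5 = "", flank3 = "") {
  variant <- match.arg(variant)
  inter <- if (variant == "ref") c("CAACAG", "CCGCCA") else c("CAGCAG", "CCGCCG")
  variant_spec(name = paste0("HTT_", variant, "_CAG", n_cag),
               segments = list(list(seq = "CAG", times = n_cag),
                               inter[1L], inter[2L],
                               list(seq = "CCG", times = 7L)),
               flank5 = flank5, flank3 = flank3)
}
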
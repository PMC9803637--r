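# Folding is delegated to ViennaRNA's RNAfold through a narrow contract:
# sequence + options in, dot-bracket + MFE out. The nearest-neighbor energy
# model itself is never re-implemented here.

the_engine <- new.env(parent = emptyenv())

#' Folding settings for minimum-free-energy structure prediction
#'
#' Captures the engine options used for every hairpin fold: Turner-1999
#' nearest-neighbor parameters, no isolated (lonely) base pairs, and
#' dangling-end energies on both sides of each helix in any case
#' (RNAfold `--dangles=2`). SHAPE pseudo-energy slope/intercept are
#' recorded for settings fidelity but never applied, since no reactivity
#' data accompany the constructs. The settings are serialized into every
#' structure report.
#'
#' @param parameter_set Name of the ViennaRNA parameter file (without
#'   extension); `"rna_turner1999"` by default.
#' @param no_isolated_pairs Forbid helices of a single pair.
#' @param dangles RNAfold dangling-end model (2 = both sides, any case).
#' @param shape_slope,shape_intercept Recorded SHAPE conversion parameters
#'   (kcal/mol), unused without reactivity data.
#' @param param_file Optional explicit path to a parameter file, overriding
#'   discovery next to the RNAfold binary.
#' @return Object of class `fold_settings`.
#' @export
fold_settings <- function(parameter_set = "rna_turner1999",
                          no_isolated_pairs = TRUE, dangles = 2L,
                          shape_slope = 1.9, shape_intercept = 0.7,
                          param_file = NULL) {
  structure(list(parameter_set = parameter_set,
                 no_isolated_pairs = isTRUE(no_isolated_pairs),
                 dangles = as.integer(dangles),
                 shape_slope = shape_slope,
                 shape_intercept = shape_intercept,
                 param_file = param_file),
            class = "fold_settings")
}

find_rnafold <- function() {
  path <- Sys.which("RNAfold")
  if (!nzchar(path))
    stop("RNAfold not found on the PATH. Install ViennaRNA or add its ",
         "bin directory to PATH before folding.")
  unname(path)
}

engine_version <- function() {
  if (is.null(the_engine$version)) {
    out <- suppressWarnings(system2(find_rnafold(), "--version",
                                    stdout = TRUE, stderr = TRUE))
    the_engine$version <- trimws(out[1L])
  }
  the_engine$version
}

locate_param_file <- function(settings) {
  if (!is.null(settings$param_file)) {
    if (!file.exists(settings$param_file))
      stop("parameter file not found: ", settings$param_file)
    return(settings$param_file)
  }
  fname <- paste0(settings$parameter_set, ".par")
  prefix <- dirname(dirname(find_rnafold()))
  candidates <- c(file.path(prefix, "share", "ViennaRNA", fname),
                  file.path(prefix, "share", "vienna_rna", fname))
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0L)
    stop("ViennaRNA parameter file '", fname, "' not found near the ",
         "RNAfold binary; pass fold_settings(param_file = ...) explicitly.")
  hit[1L]
}

#' Predict the minimum-free-energy structure of an RNA
#'
#' Runs RNAfold under the supplied [fold_settings()] and returns the MFE
#' structure; when co-optimal structures exist the engine's canonical
#' choice is reported. The engine name and version are recorded in the
#' result so structures remain attributable.
#'
#' @param sequence RNA (or DNA-spelled) sequence, length >= 10 nt.
#' @param settings A [fold_settings()] object.
#' @return Object of class `hairpin_structure`: list with `sequence`
#'   (RNA), `dot_bracket`, `delta_g` (kcal/mol), `pair_table` (data.frame
#'   of 0-based `i < j` pairs), `settings` and `engine`.
#' @examples
#' \dontrun{fold("GGGGAAAACCCC")}
#' @export
fold <- function(sequence, settings = fold_settings()) {
  stopifnot(inherits(settings, "fold_settings"))
  seq_rna <- normalize_nt(sequence, to = "RNA")
  if (nchar(seq_rna) < 10L) stop("sequence must be at least 10 nt")
  if (grepl("N", seq_rna, fixed = TRUE))
    stop("cannot fold sequences containing N")
  args <- c(sprintf("--dangles=%d", settings$dangles), "--noPS",
            "-P", locate_param_file(settings))
  if (settings$no_isolated_pairs) args <- c("--noLP", args)
  out <- system2(find_rnafold(), args, input = seq_rna, stdout = TRUE,
                 stderr = FALSE)
  hit <- regmatches(out, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
  hit <- hit[lengths(hit) == 3L]
  if (length(hit) == 0L)
    stop("could not parse RNAfold output:\n", paste(out, collapse = "\n"))
  db <- hit[[1L]][2L]
  dg <- as.numeric(hit[[1L]][3L])
  structure(list(sequence = seq_rna, dot_bracket = db, delta_g = dg,
                 pair_table = parse_dot_bracket(db), settings = settings,
                 engine = engine_version()),
            class = "hairpin_structure")
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(sprintf("<hairpin_structure> %d nt, dG = %.2f kcal/mol (%s)\n",
              nchar(x$sequence), x$delta_g, x$engine))
  cat(x$sequence, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Parse dot-bracket notation into a pair table
#'
#' @param dot_bracket String over `(`, `)` and `.`; brackets must balance
#'   (nested structures only, no pseudoknots).
#' @return data.frame with 0-based columns `i`, `j` (`i < j`), sorted by `i`.
#' @export
parse_dot_bracket <- function(dot_bracket) {
  ch <- strsplit(dot_bracket, "", fixed = TRUE)[[1L]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket may only contain '(', ')' and '.'")
  stack <- integer(0)
  i <- integer(0); j <- integer(0)
  for (k in seq_along(ch)) {
    if (ch[k] == "(") {
      stack <- c(stack, k)
    } else if (ch[k] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      i <- c(i, stack[length(stack)])
      j <- c(j, k)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  out <- data.frame(i = i - 1L, j = j - 1L)
  out <- out[order(out$i), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Segment a structure's base pairs into uninterrupted stems
#'
#' Walking the pair table in 5'-arm order, consecutive pairs `(i, j)` and
#' `(i', j')` stay in the same stem segment iff `i' - i <= 2` and
#' `j - j' <= 2`, i.e. the helix is interrupted by at most a 1x1 interior
#' loop. This is exactly how the central A-A mismatch of CAG self-pairing
#' appears in dot-bracket output, so a run of CAG:CAG duplex triplets reads
#' as one segment; bulges or loops larger than 1x1 split segments.
#'
#' @param structure A [fold()] result, or a pair-table data.frame.
#' @return The pair table with a `segment` column (1-based, in 5' order).
#' @export
stem_segments <- function(structure) {
  pairs <- if (inherits(structure, "hairpin_structure"))
    structure$pair_table else structure
  if (nrow(pairs) == 0L) return(cbind(pairs, segment = integer(0)))
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  di <- diff(pairs$i)
  dj <- -diff(pairs$j)
  new_seg <- c(TRUE, !(di <= 2L & dj <= 2L & dj >= 0L))
  pairs$segment <- cumsum(new_seg)
  rownames(pairs) <- NULL
  pairs
}

#' Count CAG units paired within each stem segment
#'
#' A CAG unit counts for a segment when a `CAG` triplet on the 5' arm has
#' both its C and its G paired inside that segment (the central A may sit
#' in a 1x1 mismatch); half-paired triplets never count. Triplets are found
#' by scanning the 5' arm in every reading frame.
#'
#' @param structure A [fold()] result.
#' @return data.frame with one row per segment: `segment`, `n_pairs`,
#'   `i_first`, `i_last`, `cag_units`.
#' @seealso [longest_uninterrupted_cag_stem()]
#' @export
segment_cag_units <- function(structure) {
  stopifnot(inherits(structure, "hairpin_structure"))
  pairs <- stem_segments(structure)
  ch <- strsplit(structure$sequence, "", fixed = TRUE)[[1L]]
  if (nrow(pairs) == 0L)
    return(data.frame(segment = integer(0), n_pairs = integer(0),
                      i_first = integer(0), i_last = integer(0),
                      cag_units = integer(0)))
  do.call(rbind, lapply(split(pairs, pairs$segment), function(seg) {
    left <- seg$i                     # 0-based 5'-arm positions
    span <- seq.int(min(left), max(left))
    units <- 0L
    for (c0 in span) {                # c0 = 0-based triplet start
      if (c0 + 2L > max(span)) break
      if (ch[c0 + 1L] == "C" && ch[c0 + 2L] == "A" && ch[c0 + 3L] == "G" &&
          (c0 %in% left) && ((c0 + 2L) %in% left))
        units <- units + 1L
    }
    data.frame(segment = seg$segment[1L], n_pairs = nrow(seg),
               i_first = min(left), i_last = max(left), cag_units = units)
  }))
}

#' Longest uninterrupted CAG-containing stem of a structure
#'
#' The maximum, over all stem segments, of the number of CAG units whose C
#' and G are both paired within the segment; 0 when no CAG triplet is
#' paired. This is the triplet-denominated "uninterrupted stem length" used
#' to compare repeat-variant hairpins.
#'
#' @param structure A [fold()] result.
#' @return Integer CAG-unit count.
#' @export
longest_uninterrupted_cag_stem <- function(structure) {
  seg <- segment_cag_units(structure)
  if (nrow(seg) == 0L) return(0L)
  max(seg$cag_units)
}

#' Fold and compare a panel of repeat variants
#'
#' Folds each sequence (or [variant_spec()]) under common settings and
#' tabulates length, free energy, the longest uninterrupted CAG stem and
#' the segment count, for side-by-side ordering of variant stability.
#'
#' @param variants Named character vector of sequences, or a list of
#'   [variant_spec()] objects (their names are used).
#' @param settings A [fold_settings()] object.
#' @return data.frame with one row per variant: `name`, `length_nt`,
#'   `delta_g`, `longest_cag_stem`, `n_segments`, `dot_bracket`; the folded
#'   structures are attached as attribute `structures`.
#' @export
compare_variants <- function(variants, settings = fold_settings()) {
  if (is.list(variants) && all(vapply(variants, inherits, TRUE, "variant_spec"))) {
    nms <- vapply(variants, `[[`, "", "name")
    variants <- stats::setNames(vapply(variants, build_variant, ""), nms)
  }
  if (length(variants) < 2L) stop("need at least two variants to compare")
  if (is.null(names(variants)) || any(!nzchar(names(variants))))
    stop("variants must be named")
  structures <- lapply(variants, fold, settings = settings)
  out <- data.frame(
    name = names(variants),
    length_nt = nchar(unname(variants)),
    delta_g = vapply(structures, `[[`, numeric(1), "delta_g"),
    longest_cag_stem = vapply(structures, longest_uninterrupted_cag_stem,
                              integer(1)),
    n_segments = vapply(structures, function(s)
      if (nrow(s$pair_table) == 0L) 0L
      else max(stem_segments(s)$segment), integer(1)),
    dot_bracket = vapply(structures, `[[`, character(1), "dot_bracket"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "structures") <- structures
  out
}

#' Fold the full huntingtin repeat-region constructs and report stem counts
#'
#' Builds the reference and LOI repeat-region constructs with the supplied
#' 15-nt genomic flanks, folds both, and reports the longest uninterrupted
#' CAG stem of each against the expected counts, under this package's 1x1
#' interior-loop stem-counting convention. Discrepancies are reported in
#' the returned table, never silently reconciled.
#'
#' @param flank5,flank3 15-nt flanking sequences around the repeat region
#'   (user-supplied; genomic context is not bundled with the package).
#' @param expected Named numeric vector of expected stem counts for `ref`
#'   and `loi` (literature-reported values 15 and 25 CAG units).
#' @param n_cag CAG count of the expansion (default 40).
#' @param settings A [fold_settings()] object.
#' @return data.frame with `variant`, `delta_g`, `longest_cag_stem`,
#'   `expected`, `matches_expected`.
#' @export
htt_stem_report <- function(flank5, flank3,
                            expected = c(ref = 15, loi = 25),
                            n_cag = 40L, settings = fold_settings()) {
  specs <- list(htt_repeat_spec("ref", n_cag, flank5, flank3),
                htt_repeat_spec("loi", n_cag, flank5, flank3))
  tab <- compare_variants(specs, settings = settings)
  variant <- c("ref", "loi")
  data.frame(variant = variant,
             delta_g = tab$delta_g,
             longest_cag_stem = tab$longest_cag_stem,
             expected = as.numeric(expected[variant]),
             matches_expected = tab$longest_cag_stem ==
               as.numeric(expected[variant]),
             stringsAsFactors = FALSE)
}
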
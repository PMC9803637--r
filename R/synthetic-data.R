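# Seeded generators producing planted-truth fixtures for every analysis
# stage. Each generator verifies its plantings with the production scanner
# before emitting, so the recorded truth is exact rather than probabilistic.

with_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_nt <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# a background string whose longest `unit` tract is < max_tract, by
# rejection sampling (uniform background rarely carries long tracts)
background_nt <- function(len, unit, max_tract = 9L) {
  repeat {
    s <- random_nt(1L, len)
    if (tract_lengths(s, unit) < max_tract) return(s)
  }
}

# embed a tract of exactly `len` nt into a background of total length
# `total`, at offset `at` (0-based), with boundary-breaking checks left to
# the caller's verification loop
plant_tract <- function(total, tract_len, unit, at = NULL) {
  tract <- periodic_sequence(unit, tract_len, phase = sample.int(3L, 1L) - 1L)
  if (tract_len >= total) return(substr(tract, 1L, total))
  if (is.null(at)) at <- sample.int(total - tract_len + 1L, 1L) - 1L
  left <- if (at > 0L) random_nt(1L, at) else ""
  right_len <- total - at - tract_len
  right <- if (right_len > 0L) random_nt(1L, right_len) else ""
  paste0(left, tract, right)
}

#' Synthesize a transcriptome with planted repeat tracts
#'
#' Generates genes as uniform-random region sequences (5'UTR, ORF, 3'UTR)
#' and plants perfect `unit` tracts of exactly the requested lengths, a
#' configurable fraction of them spanning the ORF/3'UTR junction so the
#' stitched-mRNA matching path is exercised. Backgrounds are resampled
#' until the production scanner confirms that each gene's longest tract
#' equals its planted length (background genes: < 10 nt), making the truth
#' table exact.
#'
#' @param n_genes Total genes, background included.
#' @param tract_plan Named integer vector, planted tract length (nt) ->
#'   number of genes (e.g. `c("15" = 3)`).
#' @param unit Trinucleotide unit to plant.
#' @param seed Integer seed (mandatory; generation is bit-reproducible).
#' @param region_len Named lengths of `utr5`, `orf`, `utr3` backgrounds.
#' @param junction_fraction Fraction of planted genes whose tract spans the
#'   ORF/3'UTR junction.
#' @return List with `regions` (gene_id/region/sequence data.frame, one row
#'   per region) and `truth` (gene_id, planted_len, spans_junction).
#' @export
synth_transcriptome <- function(n_genes = 50L, tract_plan = integer(0),
                                unit = "CTG", seed,
                                region_len = c(utr5 = 100L, orf = 300L,
                                               utr3 = 200L),
                                junction_fraction = 0.3) {
  if (missing(seed)) stop("seed is required")
  unit <- normalize_nt(unit)
  lens <- rep(as.integer(names(tract_plan)), as.integer(tract_plan))
  if (length(lens) > n_genes) stop("tract_plan exceeds n_genes")
  if (length(lens) && any(lens < 3L)) stop("planted tracts must be >= 3 nt")
  with_seed(seed, {
    ids <- sprintf("G%04d", seq_len(n_genes))
    planted <- c(lens, rep(0L, n_genes - length(lens)))
    junction <- logical(n_genes)
    if (length(lens))
      junction[seq_along(lens)] <-
        stats::runif(length(lens)) < junction_fraction
    rows <- vector("list", n_genes)
    truth <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      L <- planted[g]
      repeat {
        u5 <- background_nt(region_len[["utr5"]], unit)
        if (L == 0L) {
          orf <- background_nt(region_len[["orf"]], unit)
          u3 <- background_nt(region_len[["utr3"]], unit)
        } else if (junction[g]) {
          # split the tract across the ORF/3'UTR stitch point
          k <- sample(seq.int(1L, L - 1L), 1L)
          phase <- sample.int(3L, 1L) - 1L
          tract <- periodic_sequence(unit, L, phase = phase)
          orf <- paste0(background_nt(region_len[["orf"]] - k, unit),
                        substr(tract, 1L, k))
          u3 <- paste0(substr(tract, k + 1L, L),
                       background_nt(region_len[["utr3"]] - (L - k), unit))
        } else {
          orf <- plant_tract(region_len[["orf"]], L, unit)
          u3 <- background_nt(region_len[["utr3"]], unit)
        }
        mrna <- paste0(u5, orf, u3)
        got <- tract_lengths(mrna, unit)
        if ((L == 0L && got < 10L) || (L > 0L && got == L)) break
      }
      rows[[g]] <- data.frame(gene_id = ids[g],
                              region = c("utr5", "orf", "utr3"),
                              sequence = c(u5, orf, u3),
                              stringsAsFactors = FALSE)
      truth[[g]] <- data.frame(gene_id = ids[g], planted_len = L,
                               spans_junction = junction[g],
                               stringsAsFactors = FALSE)
    }
    list(regions = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Synthesize a ranked list with a planted score shift
#'
#' Non-target genes draw scores from `Normal(0, noise_sd)` and target
#' genes from `Normal(effect_size, noise_sd)`; a per-gene effect vector
#' can replace the single shift for graded designs (e.g. stronger
#' downregulation for genes with longer planted tracts).
#'
#' @param n_genes Number of genes (ignored when `gene_ids` is given).
#' @param gene_ids Optional explicit gene universe, e.g. the ids of a
#'   [synth_transcriptome()] truth table.
#' @param target_set Gene ids to shift; defaults to a random subset of
#'   size `set_size`.
#' @param set_size Size of the random target set when `target_set` is NULL.
#' @param effect_size Mean score shift of target genes.
#' @param noise_sd Score standard deviation.
#' @param seed Integer seed.
#' @param effect_by_gene Optional named vector of per-gene mean shifts,
#'   overriding `effect_size` for the named genes.
#' @return List with `table` (gene_id/logfc), `target_set`, and `ranked`
#'   (the [rank_by_logfc()] ranking of the table).
#' @export
synth_ranked_list <- function(n_genes = 2000L, target_set = NULL,
                              set_size = 100L, effect_size = -2,
                              noise_sd = 1, seed, effect_by_gene = NULL,
                              gene_ids = NULL) {
  if (missing(seed)) stop("seed is required")
  with_seed(seed, {
    ids <- if (is.null(gene_ids)) sprintf("G%05d", seq_len(n_genes))
      else as.character(gene_ids)
    n_genes <- length(ids)
    if (is.null(target_set)) target_set <- sample(ids, set_size)
    mu <- stats::setNames(rep(0, n_genes), ids)
    mu[intersect(target_set, ids)] <- effect_size
    if (!is.null(effect_by_gene)) {
      unknown <- setdiff(names(effect_by_gene), ids)
      if (length(unknown))
        stop("effect_by_gene names outside the gene universe: ",
             paste(utils::head(unknown, 3), collapse = ", "))
      mu[names(effect_by_gene)] <- effect_by_gene
    }
    tab <- data.frame(gene_id = ids,
                      logfc = stats::rnorm(n_genes, mean = mu, sd = noise_sd),
                      stringsAsFactors = FALSE)
    list(table = tab, target_set = target_set, ranked = rank_by_logfc(tab))
  })
}

#' Synthesize a read library with planted longest-tract lengths
#'
#' Fixed-length reads whose longest `unit` tract is exactly as planned;
#' every planting is verified with the production scanner before emission,
#' and optional substitution noise is applied only afterwards, with the
#' truth recorded pre-noise. Background reads carry no tract of 8 nt or
#' longer, so they never collide with the long-repeat listing threshold.
#'
#' @param tract_plan Named vector, tract length (nt) -> number of reads.
#' @param n_background Additional background reads.
#' @param read_len Read length in nt.
#' @param unit Trinucleotide unit.
#' @param error_rate Per-base substitution probability applied after
#'   verification.
#' @param seed Integer seed.
#' @return List with `reads` (read_id/sequence/count, count 1) and `truth`
#'   (data.frame `tract_len`/`n_reads`, the planted pre-noise histogram).
#' @export
synth_read_library <- function(tract_plan = integer(0), n_background = 0L,
                               read_len = 50L, unit = "CAG",
                               error_rate = 0, seed) {
  if (missing(seed)) stop("seed is required")
  unit <- normalize_nt(unit)
  lens <- rep(as.integer(names(tract_plan)), as.integer(tract_plan))
  if (length(lens) && any(lens > read_len))
    stop("planted tracts cannot exceed read_len")
  with_seed(seed, {
    seqs <- character(0)
    for (L in lens) {
      repeat {
        s <- plant_tract(read_len, L, unit)
        if (tract_lengths(s, unit) == L) break
      }
      seqs <- c(seqs, s)
    }
    if (n_background > 0L)
      seqs <- c(seqs, vapply(seq_len(n_background), function(i)
        background_nt(read_len, unit, max_tract = 8L), ""))
    if (error_rate > 0 && length(seqs)) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "", fixed = TRUE)[[1L]]
        flip <- stats::runif(length(ch)) < error_rate
        if (any(flip))
          ch[flip] <- vapply(ch[flip], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
        paste(ch, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    truth <- if (length(lens))
      data.frame(tract_len = as.integer(names(table(lens))),
                 n_reads = as.integer(table(lens)))
    else data.frame(tract_len = integer(0), n_reads = integer(0))
    list(reads = data.frame(read_id = sprintf("R%06d", seq_along(seqs)),
                            sequence = seqs, count = 1L,
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Synthesize RISC-bound Dicer-product libraries per construct
#'
#' Emulates Argonaute-pulldown libraries from cells expressing different
#' hairpin constructs: each library carries CAG-phase (group 1) Dicer
#' products of 21-22 nt, all beginning with the same 5' trinucleotide
#' phase, a small fixed proportion of CCG-phase (group 2) products, and
#' random background reads. The group-1 proportion scales with the
#' construct's abundance factor, so per-million-normalized group-1 counts
#' across libraries recover the abundance ratio.
#'
#' @param constructs Named numeric vector of relative group-1 abundance per
#'   construct (e.g. `c(Ref = 1, LOI = 4)`).
#' @param n_reads Reads per library.
#' @param group1_base_prop Group-1 read proportion at abundance factor 1.
#' @param group2_prop Fixed group-2 read proportion in every library.
#' @param dicer_lengths Named probability vector over product lengths in nt.
#' @param phase5 Leading trinucleotide of group-1 products.
#' @param seed Integer seed.
#' @return List with `libraries` (named list of read data.frames) and
#'   `truth` (per-library expected group proportions).
#' @export
synth_risc_library <- function(constructs = c(Ref = 1, LOI = 4),
                               n_reads = 50000L, group1_base_prop = 0.05,
                               group2_prop = 0.01,
                               dicer_lengths = c("21" = 0.5, "22" = 0.5),
                               phase5 = "AGC", seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(names(constructs))) stop("constructs must be named")
  phase5 <- normalize_nt(phase5)
  rot <- unit_rotations("CAG")
  g1_phase <- match(phase5, rot) - 1L
  if (is.na(g1_phase)) stop("phase5 must be a rotation of CAG")
  if (max(constructs) * group1_base_prop + group2_prop >= 1)
    stop("group proportions exceed 1 at the largest abundance factor")
  lens <- as.integer(names(dicer_lengths))
  defs <- group_definitions()
  with_seed(seed, {
    libraries <- lapply(names(constructs), function(nm) {
      p1 <- group1_base_prop * constructs[[nm]]
      grp <- sample(c("g1", "g2", "g3"), n_reads, replace = TRUE,
                    prob = c(p1, group2_prop, 1 - p1 - group2_prop))
      read_len <- sample(lens, n_reads, replace = TRUE,
                         prob = as.numeric(dicer_lengths))
      g1_species <- vapply(lens, function(L)
        periodic_sequence("CAG", L, phase = g1_phase), "")
      g2_species <- vapply(lens, function(L)
        periodic_sequence("CCG", L, phase = 0L), "")
      names(g1_species) <- names(g2_species) <- lens
      seqs <- character(n_reads)
      seqs[grp == "g1"] <- g1_species[as.character(read_len[grp == "g1"])]
      seqs[grp == "g2"] <- g2_species[as.character(read_len[grp == "g2"])]
      bg <- which(grp == "g3")
      while (length(bg) > 0L) {
        cand <- vapply(read_len[bg], function(L) random_nt(1L, L), "")
        ok <- assign_group(cand, defs) == "group3"
        seqs[bg[ok]] <- cand[ok]
        bg <- bg[!ok]
      }
      data.frame(read_id = sprintf("%s_%06d", nm, seq_len(n_reads)),
                 sequence = seqs, count = 1L, stringsAsFactors = FALSE)
    })
    names(libraries) <- names(constructs)
    truth <- data.frame(library = names(constructs),
                        abundance = as.numeric(constructs),
                        expected_group1_prop =
                          group1_base_prop * as.numeric(constructs),
                        expected_group2_prop = group2_prop,
                        stringsAsFactors = FALSE)
    list(libraries = libraries, truth = truth)
  })
}
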
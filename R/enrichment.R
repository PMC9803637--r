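#' Rank genes by log fold change
#'
#' Produces the descending ranked list used by preranked gene-set
#' enrichment. The sort is deterministic: ties in score are broken by gene
#' id, so a permuted input table yields an identical ranking.
#'
#' @param table data.frame with columns `gene_id` and a score column
#'   (`score` or `logfc`), or a named numeric vector.
#' @param metric_name Label recorded with the list.
#' @return data.frame of class `ranked_list` with columns `gene_id`,
#'   `score`, sorted descending.
#' @export
rank_by_logfc <- function(table, metric_name = "log_fold_change") {
  if (is.numeric(table) && !is.null(names(table)))
    table <- data.frame(gene_id = names(table), score = as.numeric(table),
                        stringsAsFactors = FALSE)
  score_col <- intersect(c("score", "logfc", "logFC"), names(table))[1L]
  if (is.na(score_col) || !"gene_id" %in% names(table))
    stop("table needs a gene_id column and a score/logfc column")
  gene_id <- as.character(table$gene_id)
  score <- as.numeric(table[[score_col]])
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(!is.finite(score))) stop("scores must be finite")
  ord <- order(-score, gene_id)
  out <- data.frame(gene_id = gene_id[ord], score = score[ord],
                    stringsAsFactors = FALSE)
  attr(out, "metric_name") <- metric_name
  class(out) <- c("ranked_list", class(out))
  out
}

# internal: ES from hit positions in a ranked list.
# absw: |score|^p in ranked order; returns the signed maximum deviation of
# the running sum (hit increments normalized to 1, miss decrement 1/(N-m)).
es_from_hits <- function(absw, hit, n, return_running = FALSE) {
  m <- sum(hit)
  if (m == 0L || m >= n)
    stop("gene set must hit at least one and not all ranked genes")
  incr <- rep.int(-1 / (n - m), n)
  wsum <- sum(absw[hit])
  incr[hit] <- if (wsum > 0) absw[hit] / wsum else 1 / m
  run <- cumsum(incr)
  hi <- max(run)
  lo <- min(run)
  # magnitude ties (to fp tolerance) resolve to the positive extreme
  es <- if (abs(hi) >= abs(lo) - 1e-12) hi else lo
  if (return_running) list(es = es, running_sum = run) else es
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The running-sum statistic of preranked GSEA: walking down the ranked
#' list, the sum increases by `|score|^weight / sum(|score|^weight over
#' hits)` at member genes and decreases by `1 / (N - m)` elsewhere; the
#' enrichment score is the signed maximum deviation from zero, with exact
#' magnitude ties between the positive and negative extremes resolved to
#' the positive one. All-zero hit weights fall back to equal hit
#' increments.
#'
#' @param ranked A [rank_by_logfc()] result.
#' @param members Character vector of gene ids.
#' @param weight Exponent on `|score|` (1 = the conventional "weighted"
#'   statistic).
#' @return List with `es` (in `[-1, 1]`), `running_sum` (length `N`) and
#'   `n_hits` (members present in the list).
#' @export
enrichment_score <- function(ranked, members, weight = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  hit <- ranked$gene_id %in% members
  if (!any(hit)) stop("no gene-set members present in the ranked list")
  absw <- abs(ranked$score)^weight
  res <- es_from_hits(absw, hit, nrow(ranked), return_running = TRUE)
  list(es = res$es, running_sum = res$running_sum, n_hits = sum(hit))
}

#' Gene-label permutation test for an enrichment score
#'
#' Builds a null distribution of enrichment scores from `n_perm` random
#' gene sets of the same size drawn without replacement from the ranked
#' list. Following the GSEA convention, the normalized score divides the
#' observed ES by the mean |null ES| of the same sign, and the nominal p is
#' the fraction of same-sign nulls at least as extreme, with a +1
#' correction so p is never 0. The caller-visible RNG state is left
#' untouched.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @param set_name Label carried into the result.
#' @return One-row data.frame of class `enrichment_result` with columns
#'   `set_name`, `set_size`, `es`, `nes`, `p_nominal`, `n_perm`, `seed`,
#'   `nes_defined`. When every null ES has the opposite sign, `nes` is `NA`,
#'   `nes_defined` is `FALSE` and `p_nominal` is floored at
#'   `1 / (n_perm + 1)`.
#' @export
permutation_test <- function(ranked, members, n_perm = 1000L, seed,
                             weight = 1, set_name = "set") {
  stopifnot(inherits(ranked, "ranked_list"), n_perm >= 1L)
  if (missing(seed)) stop("seed is required for reproducibility")
  hit <- ranked$gene_id %in% members
  if (!any(hit)) stop("no gene-set members present in the ranked list")
  n <- nrow(ranked)
  m <- sum(hit)
  absw <- abs(ranked$score)^weight
  es <- es_from_hits(absw, hit, n)

  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    h <- logical(n)
    h[sample.int(n, m)] <- TRUE
    es_from_hits(absw, h, n)
  }, numeric(1))

  same <- if (es >= 0) null_es >= 0 else null_es < 0
  n_same <- sum(same)
  if (n_same == 0L) {
    nes <- NA_real_
    p <- 1 / (n_perm + 1)
    defined <- FALSE
  } else {
    nes <- es / mean(abs(null_es[same]))
    p <- (1 + sum(abs(null_es[same]) >= abs(es))) / (1 + n_same)
    defined <- TRUE
  }
  out <- data.frame(set_name = set_name, set_size = m, es = es, nes = nes,
                    p_nominal = p, n_perm = as.integer(n_perm),
                    seed = as.integer(seed), nes_defined = defined,
                    stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Run preranked enrichment across a nested gene-set family
#'
#' One permutation test per threshold of the family; thresholds with no
#' members in the ranked list are dropped from the report. The seed for
#' threshold `t` is `seed + t` so each row is individually reproducible.
#'
#' @inheritParams permutation_test
#' @param family A [build_gene_set_family()] result or a named list of
#'   gene-id vectors (e.g. from [read_gmt()]).
#' @return data.frame with one `enrichment_result` row per reported set,
#'   plus a `threshold` column when the family carries thresholds.
#' @export
run_family <- function(ranked, family, n_perm = 1000L, seed, weight = 1) {
  if (missing(seed)) stop("seed is required for reproducibility")
  if (inherits(family, "gene_set_family")) {
    sets <- family$sets
    names(sets) <- sprintf("%s_GE_%sNT",
                           normalize_nt(family$unit, to = "RNA"),
                           names(family$sets))
    thresholds <- family$thresholds
  } else {
    sets <- family
    thresholds <- seq_along(sets)
  }
  rows <- list()
  for (k in seq_along(sets)) {
    members <- sets[[k]]
    if (!any(ranked$gene_id %in% members)) next
    row <- permutation_test(ranked, members, n_perm = n_perm,
                            seed = seed + thresholds[k], weight = weight,
                            set_name = names(sets)[k])
    row$threshold <- thresholds[k]
    rows[[length(rows) + 1L]] <- row
  }
  if (length(rows) == 0L) {
    warning("no gene set overlapped the ranked list")
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
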
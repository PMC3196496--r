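# Crossing gene age with expression bias: 2x2 Fisher tables, branch-wise
# binomial profiles, genomic cluster pooling (so linked neighbours are not
# counted as independent events), regulatory-feature proximity, and
# fold-enrichment arithmetic for annotation terms.

#' Age class x bias direction contingency test
#'
#' Builds the 2x2 table of (young, old) x the two bias directions among
#' biased genes only (unbiased genes are excluded) and applies a two-sided
#' Fisher exact test.
#'
#' @param calls data.frame with `gene_id` and `bias` (two direction labels
#'   plus optionally `"unbiased"`).
#' @param catalog gene catalog with `gene_id` and `age_class`.
#' @return list with `table` (2x2 matrix, rows young/old), `p`, and
#'   `proportions` (per-age-class share of the first direction).
#' @export
bias_table <- function(calls, catalog) {
  x <- calls[calls$bias != "unbiased", , drop = FALSE]
  if (nrow(x) == 0) stop("no biased genes")
  age <- catalog$age_class[match(x$gene_id, catalog$gene_id)]
  if (anyNA(age)) stop("biased genes missing from catalog")
  dirs <- sort(unique(x$bias))
  if (length(dirs) != 2) stop("expected exactly two bias directions, got: ",
                              paste(dirs, collapse = ","))
  tab <- table(factor(age, levels = c("young", "old")),
               factor(x$bias, levels = dirs))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("empty margin in bias table")
  list(table = unclass(tab),
       p = stats::fisher.test(tab)$p.value,
       proportions = tab[, 1] / rowSums(tab))
}

#' Branch-wise differential-expression profile
#'
#' For each origination branch: how many represented genes are up- or
#' down-biased, the proportions, and an exact binomial test of up versus
#' down against 0.5 among the biased genes (two-sided by summing outcome
#' probabilities at most the observed one; the one-sided upper-tail p is
#' reported alongside). Bonferroni correction is over the branches tested.
#'
#' @param calls data.frame with `gene_id`, `bias` (`up` direction label,
#'   `down` direction label, or `"unbiased"`).
#' @param catalog gene catalog with `gene_id` and `branch`.
#' @param n_branches terminal branch index B (branches 0..B).
#' @param up_label,down_label which bias labels count as up/down (defaults:
#'   the first/second sorted non-unbiased label).
#' @return data.frame, one row per branch: `branch`, `n`, `n_up`, `n_down`,
#'   `prop_up`, `prop_down`, `p` (two-sided), `p_one_sided`,
#'   `p_bonferroni`.
#' @export
branch_profile <- function(calls, catalog, n_branches,
                           up_label = NULL, down_label = NULL) {
  branch <- catalog$branch[match(calls$gene_id, catalog$gene_id)]
  if (anyNA(branch)) stop("called genes missing from catalog")
  dirs <- sort(setdiff(unique(calls$bias), "unbiased"))
  up_label <- up_label %||% dirs[1]
  down_label <- down_label %||% dirs[2]
  out <- lapply(0:n_branches, function(b) {
    sel <- branch == b
    n <- sum(sel)
    n_up <- sum(sel & calls$bias == up_label)
    n_down <- sum(sel & calls$bias == down_label)
    if (n_up + n_down > 0) {
      bt <- stats::binom.test(n_up, n_up + n_down, p = 0.5)
      p <- bt$p.value
      p1 <- stats::pbinom(n_up - 1, n_up + n_down, 0.5, lower.tail = FALSE)
    } else {
      p <- NA_real_; p1 <- NA_real_
    }
    data.frame(branch = b, n = n, n_up = n_up, n_down = n_down,
               prop_up = if (n > 0) n_up / n else NA_real_,
               prop_down = if (n > 0) n_down / n else NA_real_,
               p = p, p_one_sided = p1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  m <- sum(!is.na(out$p))
  out$p_bonferroni <- pmin(1, out$p * m)
  out
}

#' Pool neighbouring same-age same-bias genes into clusters
#'
#' Single-linkage chaining along each chromosome: genes are sorted by start
#' coordinate and successive genes merge into one cluster iff they share the
#' origination branch and bias direction and the gap from the end of the
#' previous gene to the start of the next (0-based half-open coordinates;
#' overlaps give gap <= 0) is at most `cutoff`. Clusters then replace genes
#' as the units of the age x bias Fisher test, so tandem duplicates are not
#' counted as independent observations.
#'
#' @param catalog data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `branch`, `age_class`, and `bias` (biased genes only; unbiased rows are
#'   dropped).
#' @param cutoff maximum gap in bases (the study uses 1e5 and 1e6).
#' @return list with `clusters` (one row per cluster: `chrom`, `branch`,
#'   `age_class`, `bias`, `n_genes`, `start`, `end`, `members`) and
#'   `bias_table` (cluster-level test from [bias_table()], or NULL when a
#'   margin is empty).
#' @export
pool_clusters <- function(catalog, cutoff) {
  if (cutoff < 0) stop("cutoff must be non-negative")
  x <- catalog[catalog$bias != "unbiased", , drop = FALSE]
  if (any(x$start >= x$end)) stop("invalid coordinates (start >= end)")
  x <- x[order(x$chrom, x$start, x$end, x$gene_id), , drop = FALSE]
  cl <- integer(nrow(x))
  cur <- 0L
  for (i in seq_len(nrow(x))) {
    new_cluster <- i == 1L ||
      x$chrom[i] != x$chrom[i - 1L] ||
      x$branch[i] != x$branch[i - 1L] ||
      x$bias[i] != x$bias[i - 1L] ||
      (x$start[i] - x$end[i - 1L]) > cutoff
    if (new_cluster) cur <- cur + 1L
    cl[i] <- cur
  }
  rows <- lapply(split(seq_len(nrow(x)), cl), function(idx) {
    data.frame(chrom = x$chrom[idx[1]], branch = x$branch[idx[1]],
               age_class = x$age_class[idx[1]], bias = x$bias[idx[1]],
               n_genes = length(idx),
               start = min(x$start[idx]), end = max(x$end[idx]),
               members = paste(x$gene_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, rows)
  rownames(clusters) <- NULL
  cbt <- tryCatch(
    bias_table(data.frame(gene_id = seq_len(nrow(clusters)),
                          bias = clusters$bias),
               data.frame(gene_id = seq_len(nrow(clusters)),
                          age_class = clusters$age_class)),
    error = function(e) NULL)
  list(clusters = clusters, bias_table = cbt)
}

#' Fraction of genes with a nearby genomic feature, by age and bias class
#'
#' Distance between a gene span and a feature interval is 0 when they
#' overlap, else the nearest-end gap; a gene is associated iff some feature
#' lies within `cutoff_bp` (inclusive). Intervals are 0-based half-open.
#'
#' @param catalog gene catalog with `gene_id`, `chrom`, `start`, `end`,
#'   `age_class`, and optionally `bias`.
#' @param features data.frame with `chrom`, `start`, `end` (BED-style).
#' @param cutoff_bp association cutoff in bases (>= 0).
#' @return data.frame of fractions per (age_class[, bias]) group, plus a
#'   logical `associated` vector attribute aligned with `catalog`.
#' @export
feature_association <- function(catalog, features, cutoff_bp) {
  if (cutoff_bp < 0) stop("cutoff must be non-negative")
  assoc <- logical(nrow(catalog))
  for (ch in unique(catalog$chrom)) {
    gi <- which(catalog$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    g <- IRanges::IRanges(start = catalog$start[gi] + 1L, end = catalog$end[gi])
    f <- IRanges::IRanges(start = features$start[fi] + 1L, end = features$end[fi])
    d <- IRanges::distanceToNearest(g, f)
    dd <- rep(NA_integer_, length(gi))
    dd[S4Vectors::queryHits(d)] <- S4Vectors::mcols(d)$distance
    assoc[gi] <- !is.na(dd) & dd <= cutoff_bp
  }
  byvars <- c("age_class", if ("bias" %in% names(catalog)) "bias")
  groups <- unique(catalog[, byvars, drop = FALSE])
  groups <- groups[do.call(order, groups), , drop = FALSE]
  frac <- vapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(catalog))
    for (v in byvars) sel <- sel & catalog[[v]] == groups[[v]][i]
    mean(assoc[sel])
  }, numeric(1))
  n <- vapply(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(catalog))
    for (v in byvars) sel <- sel & catalog[[v]] == groups[[v]][i]
    sum(sel)
  }, numeric(1))
  out <- cbind(groups, data.frame(n = n, fraction = frac))
  rownames(out) <- NULL
  attr(out, "associated") <- assoc
  out
}

#' Annotation-term fold enrichment with one-sided Fisher tests
#'
#' Fold enrichment = (hits in list / list size) / (hits in background /
#' background size); p from a one-sided (enrichment) Fisher exact test; BH
#' FDR across terms. Terms significant below `fdr` are flagged.
#'
#' @param gene_list character vector of genes of interest (subset of
#'   `background`).
#' @param background character vector of background genes.
#' @param term_map data.frame with columns `gene_id`, `term`.
#' @param fdr reporting threshold (default 0.05).
#' @return data.frame per term: `term`, `list_hits`, `bg_hits`,
#'   `fold_enrichment`, `p`, `q`, `significant`.
#' @export
term_enrichment <- function(gene_list, background, term_map, fdr = 0.05) {
  if (!all(gene_list %in% background)) stop("gene_list must be a subset of background")
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  terms <- sort(unique(tm$term))
  if (!length(terms)) stop("no terms represented in the background")
  ls <- length(gene_list); bs <- length(background)
  rows <- lapply(terms, function(t) {
    tg <- unique(tm$gene_id[tm$term == t])
    hl <- sum(gene_list %in% tg)
    hb <- length(tg)
    fold <- (hl / ls) / (hb / bs)
    tab <- matrix(c(hl, ls - hl, hb - hl, bs - ls - (hb - hl)), 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = t, list_hits = hl, bg_hits = hb,
               fold_enrichment = fold, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < fdr
  out[order(out$q, out$p), , drop = FALSE]
}
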
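# EST expression profiling: presence calls from library counts, young-gene
# proportions per tissue (and stage), Fisher tests with Bonferroni
# correction, and the two resampling controls (bootstrap error bars and
# between-species subsampling).

.est_cols <- c("library_id", "species", "tissue", "stage", "normal_flag",
               "gene_id", "est_count")

.check_est <- function(est) {
  if (!all(.est_cols %in% names(est)))
    stop("EST table must have columns: ", paste(.est_cols, collapse = ", "))
  if (any(est$est_count < 0)) stop("EST counts must be non-negative")
  invisible(est)
}

#' Call expression presence from EST counts
#'
#' A gene is called present in a (species, tissue) cell — optionally split
#' by developmental stage — when it is supported by at least `min_ests`
#' ESTs from normal-sample libraries. ESTs from non-normal libraries are
#' excluded before counting.
#'
#' @param est EST table: data.frame with columns `library_id`, `species`,
#'   `tissue`, `stage` (one of fetal/infant/adult/other/unknown),
#'   `normal_flag` (logical), `gene_id`, `est_count`.
#' @param min_ests minimum supporting ESTs (default 2).
#' @param by_stage also split cells by developmental stage.
#' @return data.frame with `gene_id`, `species`, `tissue` (and `stage` when
#'   `by_stage`), `est_total`, `expressed`.
#' @export
call_expression <- function(est, min_ests = 2, by_stage = FALSE) {
  .check_est(est)
  if (min_ests < 1) stop("min_ests must be >= 1")
  est <- est[as.logical(est$normal_flag), , drop = FALSE]
  if (by_stage) {
    known <- c("fetal", "infant", "adult", "other", "unknown")
    bad <- !est$stage %in% known
    if (any(bad)) {
      warning(sum(bad), " EST records with unknown stage labels routed to 'unknown'")
      est$stage[bad] <- "unknown"
    }
  }
  if (nrow(est) == 0) {
    out <- data.frame(gene_id = character(), species = character(),
                      tissue = character(), est_total = integer(),
                      expressed = logical(), stringsAsFactors = FALSE)
    if (by_stage) out$stage <- character()
    return(out)
  }
  keyvars <- c("gene_id", "species", "tissue", if (by_stage) "stage")
  agg <- stats::aggregate(est_count ~ ., data = est[, c(keyvars, "est_count")],
                          FUN = sum)
  names(agg)[names(agg) == "est_count"] <- "est_total"
  agg$expressed <- agg$est_total >= min_ests
  agg[order(agg$species, agg$tissue, agg$gene_id), , drop = FALSE]
}

#' Young-gene share of a tissue transcriptome
#'
#' Counts how many of the genes expressed in a (species, tissue[, stage])
#' cell are young, out of all genes expressed there.
#'
#' @param calls presence calls from [call_expression()].
#' @param catalog gene catalog with `gene_id` and `age_class`.
#' @param tissue tissue to profile.
#' @param species optional species filter.
#' @param stage optional stage filter (requires stage-split calls).
#' @return list with `young`, `total`, `proportion`.
#' @export
young_proportion <- function(calls, catalog, tissue, species = NULL, stage = NULL) {
  x <- calls[calls$expressed & calls$tissue == tissue, , drop = FALSE]
  if (!is.null(species)) x <- x[x$species == species, , drop = FALSE]
  if (!is.null(stage)) {
    if (!"stage" %in% names(x)) stop("calls were not made by stage")
    x <- x[x$stage == stage, , drop = FALSE]
  }
  genes <- unique(x$gene_id)
  miss <- setdiff(genes, catalog$gene_id)
  if (length(miss)) stop("genes missing from catalog: ", paste(utils::head(miss, 5), collapse = ","))
  if (length(genes) == 0) stop("no expressed genes in the requested cell")
  age <- catalog$age_class[match(genes, catalog$gene_id)]
  young <- sum(age == "young")
  list(young = young, total = length(genes), proportion = young / length(genes))
}

#' Compare two young-gene proportions by Fisher's exact test
#'
#' Gene-level 2x2: rows are the two groups (e.g. species), columns are
#' (young expressed, old expressed). Two-sided p with Bonferroni correction
#' for the number of cells tested in the run.
#'
#' @param a,b lists or vectors giving `(young, total)` for each group.
#' @param m_tests Bonferroni family size (default 1).
#' @return list with `p` and `p_bonferroni` (= `min(1, p * m_tests)`).
#' @export
compare_proportions <- function(a, b, m_tests = 1) {
  norm <- function(x) {
    if (is.list(x)) x <- unlist(x)
    if (!is.null(names(x)) && all(c("young", "total") %in% names(x)))
      x <- x[c("young", "total")]
    as.numeric(x[1:2])
  }
  a <- norm(a); b <- norm(b)
  if (a[2] < a[1] || b[2] < b[1]) stop("total must be >= young count")
  if (a[2] == 0 || b[2] == 0) stop("zero totals")
  tab <- matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  list(p = p, p_bonferroni = min(1, p * m_tests))
}

# expand a calls-style aggregation back to per-gene EST counts within a cell
.cell_counts <- function(est, species, tissue) {
  x <- est[as.logical(est$normal_flag) & est$species == species &
             est$tissue == tissue, , drop = FALSE]
  tapply(x$est_count, x$gene_id, sum)
}

#' Bootstrap error bars for per-tissue young proportions
#'
#' Within each (species, tissue) cell, each replicate resamples individual
#' ESTs with replacement to the original sequencing depth (a multinomial
#' draw over genes weighted by their observed EST counts), re-calls
#' presence at `min_ests`, and recomputes the young proportion. Returns the
#' mean and standard deviation across replicates (plotted as mean +/- 2 sd).
#'
#' @param est EST table (see [call_expression()]).
#' @param catalog gene catalog with `gene_id`, `age_class`.
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param min_ests presence threshold (default 2).
#' @return data.frame with `species`, `tissue`, `boot_mean`, `boot_sd`.
#' @export
bootstrap_background <- function(est, catalog, n_reps = 100, seed = 1,
                                 min_ests = 2) {
  .check_est(est)
  if (n_reps < 2) stop("n_reps must be >= 2")
  set.seed(stage_seed(seed, "bootstrap"))
  cells <- unique(est[as.logical(est$normal_flag), c("species", "tissue")])
  cells <- cells[order(cells$species, cells$tissue), , drop = FALSE]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    cnt <- .cell_counts(est, cells$species[i], cells$tissue[i])
    depth <- sum(cnt)
    if (depth == 0) stop("tissue with zero ESTs: ", cells$tissue[i])
    age <- catalog$age_class[match(names(cnt), catalog$gene_id)]
    props <- vapply(seq_len(n_reps), function(r) {
      res <- stats::rmultinom(1, depth, prob = cnt)[, 1]
      expr <- res >= min_ests
      if (!any(expr)) return(NA_real_)
      sum(expr & age == "young") / sum(expr)
    }, numeric(1))
    data.frame(species = cells$species[i], tissue = cells$tissue[i],
               boot_mean = mean(props, na.rm = TRUE),
               boot_sd = stats::sd(props, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Subsampling control for unequal EST depth between species
#'
#' Repeatedly draws `sample_size` ESTs without replacement from each of two
#' EST tables (e.g. human and mouse brain), re-calls presence, and compares
#' young proportions. The empirical p is the fraction of replicates in
#' which table `a`'s young proportion is less than or equal to table `b`'s
#' (ties count against `a`, the conservative direction); when no replicate
#' fails, the result is reported as `< 1/n_reps`.
#'
#' @param est_a,est_b EST tables for the two groups.
#' @param catalog gene catalog with `gene_id`, `age_class`.
#' @param sample_size ESTs to draw per replicate from each table.
#' @param n_reps replicates (default 1000).
#' @param seed integer seed.
#' @param min_ests presence threshold (default 2).
#' @return list with `p` (empirical), `p_label` (e.g. `"<0.001"` when no
#'   failures), `failures`, `n_reps`.
#' @export
subsample_control <- function(est_a, est_b, catalog, sample_size,
                              n_reps = 1000, seed = 1, min_ests = 2) {
  .check_est(est_a); .check_est(est_b)
  set.seed(stage_seed(seed, "subsample"))
  prep <- function(est) {
    est <- est[as.logical(est$normal_flag), , drop = FALSE]
    cnt <- tapply(est$est_count, est$gene_id, sum)
    if (sample_size > sum(cnt))
      stop("sample_size exceeds a table's EST total (", sum(cnt), ")")
    list(genes = names(cnt),
         pool = rep.int(seq_along(cnt), cnt),
         age = catalog$age_class[match(names(cnt), catalog$gene_id)])
  }
  A <- prep(est_a); B <- prep(est_b)
  prop_of <- function(pp) {
    draw <- sample(pp$pool, sample_size, replace = FALSE)
    cnt <- tabulate(draw, nbins = length(pp$genes))
    expr <- cnt >= min_ests
    if (!any(expr)) return(NA_real_)
    sum(expr & pp$age == "young") / sum(expr)
  }
  fail <- 0L
  for (r in seq_len(n_reps)) {
    pa <- prop_of(A); pb <- prop_of(B)
    if (is.na(pa) || is.na(pb) || pa <= pb) fail <- fail + 1L
  }
  p <- fail / n_reps
  list(p = p,
       p_label = if (fail == 0L) sprintf("<%g", 1 / n_reps) else sprintf("%g", p),
       failures = fail, n_reps = n_reps)
}

#' Per-tissue enrichment table comparing two species
#'
#' Builds the tissue-by-tissue comparison: for every tissue (optionally
#' tissue x stage cell) shared by the two species, young/total expressed
#' counts per species, the Fisher exact p, and Bonferroni correction over
#' the number of cells tested, plus bootstrap mean/sd for the first species.
#'
#' @param est EST table containing both species.
#' @param catalog gene catalog with `age_class`.
#' @param species_a,species_b the two species to compare.
#' @param min_ests presence threshold.
#' @param by_stage split by stage.
#' @param bootstrap_reps bootstrap replicates (0 skips the bootstrap).
#' @param seed integer seed.
#' @return data.frame, one row per tested cell.
#' @export
est_enrichment <- function(est, catalog, species_a, species_b, min_ests = 2,
                           by_stage = FALSE, bootstrap_reps = 0, seed = 1) {
  calls <- call_expression(est, min_ests = min_ests, by_stage = by_stage)
  keyvars <- c("tissue", if (by_stage) "stage")
  cells <- unique(calls[calls$species == species_a, keyvars, drop = FALSE])
  cells_b <- unique(calls[calls$species == species_b, keyvars, drop = FALSE])
  cells <- merge(cells, cells_b)
  m <- nrow(cells)
  rows <- lapply(seq_len(m), function(i) {
    st <- if (by_stage) cells$stage[i] else NULL
    a <- young_proportion(calls, catalog, cells$tissue[i], species_a, st)
    b <- young_proportion(calls, catalog, cells$tissue[i], species_b, st)
    cmp <- compare_proportions(a, b, m_tests = m)
    data.frame(tissue = cells$tissue[i],
               stage = if (by_stage) cells$stage[i] else NA_character_,
               young_a = a$young, total_a = a$total, prop_a = a$proportion,
               young_b = b$young, total_b = b$total, prop_b = b$proportion,
               p = cmp$p, p_bonferroni = cmp$p_bonferroni,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bootstrap_reps > 0) {
    bs <- bootstrap_background(est[est$species == species_a, ], catalog,
                               n_reps = bootstrap_reps, seed = seed,
                               min_ests = min_ests)
    out$boot_mean <- bs$boot_mean[match(out$tissue, bs$tissue)]
    out$boot_sd <- bs$boot_sd[match(out$tissue, bs$tissue)]
  }
  attr(out, "m_tests") <- m
  out
}
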
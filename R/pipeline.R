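# End-to-end orchestration: run the dating -> EST profiling ->
# quantification/DE -> age enrichment -> selection stages on a synthetic
# bundle (or user-supplied files), with input validation, a manifest of
# outputs, and a human-readable summary. Stages lacking inputs are skipped
# with a logged reason; truth files are never read by any stage.

#' Assemble a run configuration
#'
#' In synthetic mode a [sim_config()] drives the generators; in user mode
#' `paths` names the input files (`presence`, `catalog`, `est`, `counts`,
#' `transcripts`, `mk`). Thresholds default to the study's values: 2 ESTs,
#' k = 32, 30 bp minimum mappable length, FDR 0.05, positive-selection p
#' < 0.1, cluster cutoffs 100 kb and 1 Mb, 100 bootstrap and 1000
#' subsampling replicates.
#'
#' @param sim a [sim_config()] for synthetic mode (NULL in user mode).
#' @param paths named list of input paths for user mode.
#' @param out_dir output directory (created if missing).
#' @param min_ests,k,min_mappable,fdr,ps_threshold,cluster_cutoffs,bootstrap_reps,subsample_reps
#'   analysis thresholds.
#' @param seed integer seed (defaults to the sim config's seed).
#' @param reads_per_sample RNA-seq depth per sample in synthetic mode.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), paths = list(), out_dir = tempfile("genebirth_run_"),
                       min_ests = 2, k = 32, min_mappable = 30, fdr = 0.05,
                       ps_threshold = 0.1, cluster_cutoffs = c(1e5, 1e6),
                       bootstrap_reps = 100, subsample_reps = 1000,
                       seed = NULL, reads_per_sample = 100000) {
  if (is.null(sim) && !length(paths)) stop("need a sim config or input paths")
  if (!is.null(sim) && !inherits(sim, "sim_config")) stop("sim must be a sim_config")
  for (p in unlist(paths)) if (!file.exists(p)) stop("input file missing: ", p)
  structure(list(sim = sim, paths = paths, out_dir = out_dir,
                 min_ests = min_ests, k = k, min_mappable = min_mappable,
                 fdr = fdr, ps_threshold = ps_threshold,
                 cluster_cutoffs = cluster_cutoffs,
                 bootstrap_reps = bootstrap_reps,
                 subsample_reps = subsample_reps,
                 seed = seed %||% (if (!is.null(sim)) sim$seed else 1),
                 reads_per_sample = reads_per_sample),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; a `sim:` mapping is
#' passed to [sim_config()].
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(run_config, c(list(sim = sim), args))
}

#' Validate a synthetic or user input bundle
#'
#' Schema, coordinate, and cross-reference checks: catalog coordinates
#' half-open and positive-width, every gene in the EST table present in the
#' catalog, presence-matrix species covering the tree tips, EST columns
#' complete. Failures are collected into a report, never thrown.
#'
#' @param bundle list with any of `catalog`, `est`, `presence`, `stree`.
#' @return data.frame report with columns `check`, `detail` (zero rows when
#'   everything passes).
#' @export
validate_inputs <- function(bundle) {
  fail <- list()
  note <- function(check, detail)
    fail[[length(fail) + 1L]] <<- data.frame(check = check, detail = detail,
                                             stringsAsFactors = FALSE)
  if (!is.null(bundle$catalog)) {
    bad <- bundle$catalog$start >= bundle$catalog$end
    if (any(bad))
      note("coordinates", paste0("start >= end (1-based BED?): ",
                                 paste(utils::head(bundle$catalog$gene_id[bad], 5),
                                       collapse = ",")))
  }
  if (!is.null(bundle$est)) {
    missing_cols <- setdiff(.est_cols, names(bundle$est))
    if (length(missing_cols))
      note("est_schema", paste("missing columns:", paste(missing_cols, collapse = ",")))
    if (!is.null(bundle$catalog) && !length(missing_cols)) {
      orphan <- setdiff(unique(bundle$est$gene_id), bundle$catalog$gene_id)
      if (length(orphan))
        note("est_catalog_crossref",
             paste("genes absent from catalog:", paste(utils::head(orphan, 5), collapse = ",")))
    }
  }
  if (!is.null(bundle$presence) && !is.null(bundle$stree)) {
    if (!setequal(colnames(bundle$presence), bundle$stree$tree$tip.label))
      note("presence_species", "presence columns do not match tree tips")
  }
  if (!length(fail))
    return(data.frame(check = character(), detail = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, fail)
}

#' Run the full pipeline
#'
#' Synthetic mode generates the bundle from the sim config, then executes
#' dating, EST enrichment, RNA-seq quantification + DE, age x bias
#' enrichment (bias table, branch profile, cluster pooling at both
#' cutoffs), and MK/PRF selection, writing one TSV per result plus a
#' manifest with md5 digests. Stages without inputs are skipped with a
#' reason recorded in the manifest. Deterministic under a fixed seed.
#'
#' @param config a [run_config()].
#' @return list with all stage results, `manifest` (data.frame), and
#'   `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  emit <- function(stage, name, df) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tsv_table(df, path)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)), rows = nrow(df),
      note = "", stringsAsFactors = FALSE)
    invisible(path)
  }
  skip <- function(stage, why)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = "", md5 = "", rows = 0L, note = why,
      stringsAsFactors = FALSE)

  sim <- config$sim
  if (is.null(sim)) stop("user-mode file loading requires a sim config in this release; pass TSVs through the module functions directly")

  # --- generate bundle (truth kept aside, never passed to stages) ---
  pres <- gen_presence(sim)
  catalog <- gen_catalog(pres$truth, sim)
  est_h <- gen_est_table(catalog, sim, species = "human")
  est_m <- gen_est_table(catalog, sim, species = "mouse", enrichment = 1)
  tx <- gen_transcripts(catalog, sim)
  rs <- gen_rnaseq(catalog, tx$transcripts, sim,
                   reads_per_sample = config$reads_per_sample)
  truth <- list(branch = pres$truth, de = rs$truth, est = est_h$truth)

  vrep <- validate_inputs(list(catalog = catalog,
                               est = rbind(est_h$est, est_m$est),
                               presence = pres$presence, stree = pres$stree))
  if (nrow(vrep)) stop("input validation failed: ", vrep$check[1], " - ", vrep$detail[1])

  # --- dating ---
  dating <- date_genes(pres$stree, pres$presence)
  dating$age_class <- classify_age(dating$branch)
  results$dating <- dating
  emit("dating", "gene_branches", dating)

  # --- EST enrichment ---
  est_all <- rbind(est_h$est, est_m$est)
  enr <- est_enrichment(est_all, catalog, "human", "mouse",
                        min_ests = config$min_ests, by_stage = TRUE,
                        bootstrap_reps = 0, seed = config$seed)
  results$est_enrichment <- enr
  emit("est", "est_enrichment", enr)

  # --- RNA-seq quantification + DE ---
  kmap <- kmer_gene_map(tx$transcripts, tx$gene_of, k = config$k)
  el <- effective_length(tx$transcripts, tx$gene_of, k = config$k, map = kmap)
  keep <- filter_short_mappable(catalog, el, min_bp = config$min_mappable)
  counts <- sapply(rs$reads, function(rd)
    assign_reads(rd, tx$transcripts, tx$gene_of, k = config$k, map = kmap)$counts)
  counts <- counts[keep$retained, , drop = FALSE]
  de <- de_test(counts, rs$groups, fdr = config$fdr)
  names(de)[names(de) == "bias"] <- "bias"
  results$effective_length <- el
  results$de <- de
  emit("quant", "effective_length", el)
  emit("quant", "de_calls", de)

  # --- age x bias enrichment ---
  calls <- de[, c("gene_id", "bias")]
  bt <- tryCatch(bias_table(calls, catalog), error = function(e) NULL)
  if (is.null(bt)) skip("enrichment", "bias table empty margin")
  else {
    results$bias_table <- bt
    emit("enrichment", "bias_table",
         data.frame(cell = c("young_fetal", "young_adult", "old_fetal", "old_adult"),
                    count = as.vector(t(bt$table)), p = bt$p))
  }
  bp <- branch_profile(calls, catalog, n_branches = pres$stree$n_branches,
                       up_label = "fetal", down_label = "adult")
  results$branch_profile <- bp
  emit("enrichment", "branch_profile", bp)
  cat_bias <- merge(catalog, calls, by = "gene_id")
  clus <- lapply(config$cluster_cutoffs, function(cc)
    pool_clusters(cat_bias, cutoff = cc))
  names(clus) <- paste0("cutoff_", format(config$cluster_cutoffs, scientific = FALSE, trim = TRUE))
  results$clusters <- clus
  for (nm in names(clus)) emit("enrichment", paste0("clusters_", nm), clus[[nm]]$clusters)

  # --- selection ---
  mk_sim <- gen_mk_counts(rep(sim$gamma_values, length.out = 40),
                          theta_s = 20, theta_r = 20,
                          seed = config$seed)
  truth$mk <- mk_sim$truth
  sel <- mk_analyze(mk_sim$mk)
  sel_pos <- classify_positively_selected(sel, threshold = config$ps_threshold,
                                          p_col = "lrt_p")
  sel_pos <- sel_pos[!is.na(sel_pos$gamma) & sel_pos$gamma > 0, , drop = FALSE]
  results$selection <- sel
  results$positively_selected <- sel_pos
  emit("selection", "mk_results", sel)

  manifest <- do.call(rbind, manifest)
  results$manifest <- manifest
  results$truth <- truth
  results$catalog <- catalog
  results$out_dir <- config$out_dir
  write_tsv_table(manifest, file.path(config$out_dir, "run_manifest.tsv"))
  results
}

#' Summarise a pipeline run
#'
#' One row per analysis with its headline number, the test used, and the
#' multiple-testing family size.
#'
#' @param results output of [run_all()] (or an empty list).
#' @return data.frame with columns `analysis`, `statistic`, `value`,
#'   `test`, `family_size`.
#' @export
summarize_results <- function(results) {
  empty <- data.frame(analysis = character(), statistic = character(),
                      value = numeric(), test = character(),
                      family_size = integer(), stringsAsFactors = FALSE)
  if (!length(results)) return(empty)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  if (!is.null(results$est_enrichment)) {
    e <- results$est_enrichment
    bf <- e[e$tissue == "brain" & (is.na(e$stage) | e$stage == "fetal"), ]
    if (nrow(bf))
      add(analysis = "est_brain_fetal", statistic = "bonferroni_p",
          value = bf$p_bonferroni[1], test = "FET+Bonferroni",
          family_size = attr(e, "m_tests") %||% nrow(e))
  }
  if (!is.null(results$bias_table))
    add(analysis = "age_bias_2x2", statistic = "fet_p",
        value = results$bias_table$p, test = "FET", family_size = 1L)
  if (!is.null(results$de))
    add(analysis = "de_calls", statistic = "n_biased",
        value = sum(results$de$bias != "unbiased"), test = "binomial LRT + BH",
        family_size = nrow(results$de))
  if (!is.null(results$branch_profile)) {
    bp <- results$branch_profile
    add(analysis = "branch_profile", statistic = "n_significant_branches",
        value = sum(bp$p_bonferroni < 0.05, na.rm = TRUE),
        test = "exact binomial + Bonferroni",
        family_size = sum(!is.na(bp$p)))
  }
  if (!is.null(results$positively_selected))
    add(analysis = "selection", statistic = "n_positively_selected",
        value = nrow(results$positively_selected), test = "PRF LRT p<0.1",
        family_size = nrow(results$selection))
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
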
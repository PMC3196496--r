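# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: ortholog presence/absence with a
# true origination branch per gene, a gene catalog with coordinates and
# origination mechanisms, EST library tables with a planted young-gene
# fetal-brain enrichment, error-free 32-nt RNA-seq reads with planted
# differential expression and shared paralog sequence, PRF-distributed MK
# count tables, and pairwise codon alignments with exact difference counts.
# Truth is returned (and written) separately from the data; pipeline code
# never reads it. One global seed drives deterministic per-stage substreams.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data module. Defaults
#' describe the study conditions emulated throughout the test suite: a
#' 13-branch (0..12) vertebrate-to-human tree in which roughly 9% of genes
#' are primate-specific (branches 8..12), a fetal-brain expression advantage
#' for young genes, two developmental stages, and 32-nt error-free reads.
#'
#' @param seed global integer seed.
#' @param n_genes number of genes.
#' @param branch_origination_probs probability of originating on each branch
#'   0..B; must sum to 1 (within 1e-9).
#' @param young_fetal_enrichment odds multiplier (>= 1) on young genes'
#'   sampling weight in (brain, fetal) EST libraries.
#' @param n_tissues number of tissues (the first is always brain).
#' @param libraries_per_tissue_stage EST libraries per (tissue, stage).
#' @param mean_library_size ESTs per library.
#' @param de_effect_logfc log2 fold change planted in truly DE genes.
#' @param prop_de fraction of genes truly differentially expressed.
#' @param gamma_values selection intensities for simulated MK genes.
#' @param paralog_shared_bp identical-sequence block length shared between a
#'   duplicated gene and its parent.
#' @param loss_prob per-tip probability that a present ortholog is lost
#'   (Dollo: no regain).
#' @param read_length read/k-mer length (default 32).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 5000,
                       branch_origination_probs = c(0.56, rep(0.05, 7), rep(0.018, 5)),
                       young_fetal_enrichment = 3,
                       n_tissues = 6,
                       libraries_per_tissue_stage = 3,
                       mean_library_size = 10000,
                       de_effect_logfc = 2,
                       prop_de = 0.1,
                       gamma_values = c(-2, 0, 2, 5),
                       paralog_shared_bp = 40,
                       loss_prob = 0,
                       read_length = 32) {
  if (abs(sum(branch_origination_probs) - 1) > 1e-9)
    stop("branch origination probabilities must sum to 1")
  if (any(branch_origination_probs < 0)) stop("negative branch probability")
  if (young_fetal_enrichment < 1) stop("young_fetal_enrichment must be >= 1")
  if (n_genes < 1 || n_tissues < 1 || libraries_per_tissue_stage < 1 ||
      mean_library_size < 1)
    stop("counts must be positive")
  if (prop_de < 0 || prop_de > 1) stop("prop_de must be in [0, 1]")
  if (loss_prob < 0 || loss_prob >= 1) stop("loss_prob must be in [0, 1)")
  structure(list(seed = seed, n_genes = n_genes,
                 branch_origination_probs = branch_origination_probs,
                 young_fetal_enrichment = young_fetal_enrichment,
                 n_tissues = n_tissues,
                 libraries_per_tissue_stage = libraries_per_tissue_stage,
                 mean_library_size = mean_library_size,
                 de_effect_logfc = de_effect_logfc, prop_de = prop_de,
                 gamma_values = gamma_values,
                 paralog_shared_bp = paralog_shared_bp,
                 loss_prob = loss_prob, read_length = read_length),
            class = "sim_config")
}

#' Default 13-tip species tree with human as the focal tip
#'
#' A caterpillar topology whose root-to-human path defines branches 0..12:
#' branch 0 is shared by all vertebrates and branch 12 is the human terminal
#' branch; branches 8..12 are primate-specific under [classify_age()]'s
#' default young set.
#'
#' @return an [ape::phylo] object.
#' @export
default_species_tree <- function() {
  tips <- c("zebrafish", "frog", "chicken", "platypus", "opossum", "dog",
            "mouse", "galago", "marmoset", "rhesus", "gibbon", "chimp")
  nwk <- "human"
  for (t in rev(tips)) nwk <- sprintf("(%s,%s)", t, nwk)
  ape::read.tree(text = paste0(nwk, ";"))
}

#' Simulate an ortholog presence/absence matrix with known branch truth
#'
#' Each gene draws a true origination branch from the configured
#' probabilities. The gene is present in the focal tip and in every outgroup
#' clade that diverged at or after the origination branch; independent
#' per-tip Bernoulli loss (no regain) may then delete presences in non-focal
#' tips.
#'
#' @param tree rooted tree (default [default_species_tree()]).
#' @param config a [sim_config()].
#' @param focal focal tip name.
#' @return list with `presence` (logical gene x species matrix), `truth`
#'   (data.frame `gene_id`, `true_branch`), and `stree`.
#' @export
gen_presence <- function(config, tree = default_species_tree(), focal = "human") {
  stree <- species_tree(tree, focal)
  B <- stree$n_branches
  probs <- config$branch_origination_probs
  if (length(probs) != B + 1)
    stop("need one origination probability per branch 0..", B)
  set.seed(stage_seed(config$seed, "presence"))
  branch <- sample(0:B, config$n_genes, replace = TRUE, prob = probs)
  gene_id <- sprintf("g%05d", seq_len(config$n_genes))
  tips <- stree$tree$tip.label
  presence <- matrix(FALSE, config$n_genes, length(tips),
                     dimnames = list(gene_id, tips))
  presence[, focal] <- TRUE
  for (i in seq_len(B)) {   # outgroup clade O_{i-1} carries genes with branch <= i-1
    carriers <- branch <= (i - 1L)
    for (sp in stree$outgroups[[i]]) presence[carriers, sp] <- TRUE
  }
  if (config$loss_prob > 0) {
    nonfocal <- setdiff(tips, focal)
    loss <- matrix(stats::runif(config$n_genes * length(nonfocal)) < config$loss_prob,
                   config$n_genes, length(nonfocal))
    presence[, nonfocal] <- presence[, nonfocal] & !loss
  }
  list(presence = presence,
       truth = data.frame(gene_id = gene_id, true_branch = branch,
                          stringsAsFactors = FALSE),
       stree = stree)
}

#' Build a synthetic gene catalog from branch assignments
#'
#' Assigns chromosomes, 0-based half-open coordinates, strands, origination
#' mechanisms (duplicates get a parent gene from an older branch), and age
#' classes.
#'
#' @param truth data.frame with `gene_id`, `true_branch` (from
#'   [gen_presence()]).
#' @param config a [sim_config()].
#' @param young_branches young-branch set (default 8..12).
#' @return data.frame catalog: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `branch`, `age_class`, `mechanism`, `parent_gene`.
#' @export
gen_catalog <- function(truth, config, young_branches = 8:12) {
  set.seed(stage_seed(config$seed, "catalog"))
  n <- nrow(truth)
  chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
  start <- sample.int(5e7, n)
  len <- sample(2000:20000, n, replace = TRUE)
  mech <- sample(c("dna_duplicate", "retrogene", "de_novo", "unknown"),
                 n, replace = TRUE, prob = c(0.45, 0.2, 0.1, 0.25))
  branch <- truth$true_branch
  parent <- rep(NA_character_, n)
  dup <- mech %in% c("dna_duplicate", "retrogene")
  older <- function(b) which(branch < b)
  for (i in which(dup)) {
    cand <- older(branch[i])
    if (length(cand)) parent[i] <- truth$gene_id[sample(cand, 1)]
    else mech[i] <- "de_novo"
  }
  data.frame(gene_id = truth$gene_id, chrom = chrom, start = start,
             end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             branch = branch,
             age_class = classify_age(branch, young_branches),
             mechanism = mech, parent_gene = parent,
             stringsAsFactors = FALSE)
}

#' Simulate an EST library table with a planted fetal-brain enrichment
#'
#' Per-gene baseline expression weights are gamma-distributed, with young
#' genes' baseline scaled down by `young_weight_factor` to emulate the
#' narrow, weak expression typical of recently originated genes (so that
#' presence calls for young genes are informative rather than saturated).
#' In (brain, fetal) libraries the weight of young genes is multiplied by
#' `enrichment`; all other tissue x stage cells are unenriched. Each library
#' is a multinomial draw of exactly `mean_library_size` ESTs, so totals are
#' conserved exactly.
#'
#' @param catalog gene catalog (needs `gene_id`, `age_class`).
#' @param config a [sim_config()].
#' @param species species label for the table.
#' @param enrichment odds multiplier (default from config).
#' @param young_weight_factor baseline down-weighting of young genes
#'   (default 0.1).
#' @param seed optional seed override (default config seed).
#' @return list with `est` (long-format EST table; see [call_expression()])
#'   and `truth` (list with `enrichment`, `young_genes`).
#' @export
gen_est_table <- function(catalog, config, species = "human",
                          enrichment = config$young_fetal_enrichment,
                          young_weight_factor = 0.1, seed = config$seed) {
  if (config$mean_library_size < 1) stop("zero-size libraries")
  set.seed(stage_seed(seed, paste0("est-", species)))
  tissues <- c("brain", "heart", "liver", "kidney", "lung",
               "muscle", "testis", "skin")[seq_len(config$n_tissues)]
  stages <- c("fetal", "adult")
  n <- nrow(catalog)
  base_w <- stats::rgamma(n, shape = 0.5, rate = 1) + 1e-6
  young <- catalog$age_class == "young"
  base_w[young] <- base_w[young] * young_weight_factor
  out <- vector("list", length(tissues) * length(stages) *
                  config$libraries_per_tissue_stage)
  k <- 0L
  for (ti in tissues) for (st in stages) {
    w <- base_w
    if (ti == "brain" && st == "fetal") w[young] <- w[young] * enrichment
    for (l in seq_len(config$libraries_per_tissue_stage)) {
      cnt <- stats::rmultinom(1, config$mean_library_size, prob = w)[, 1]
      nz <- cnt > 0
      k <- k + 1L
      out[[k]] <- data.frame(
        library_id = sprintf("%s_%s_%s_L%d", species, ti, st, l),
        species = species, tissue = ti, stage = st, normal_flag = TRUE,
        gene_id = catalog$gene_id[nz], est_count = cnt[nz],
        stringsAsFactors = FALSE)
    }
  }
  list(est = do.call(rbind, out),
       truth = list(enrichment = enrichment,
                    young_genes = catalog$gene_id[young]))
}

#' Simulate transcripts, including duplicate pairs with shared sequence
#'
#' One transcript per gene of random sequence; genes with a recorded parent
#' copy a `paralog_shared_bp`-long block of the parent's transcript, so
#' reads from that block map to more than one gene and must be discarded by
#' [assign_reads()].
#'
#' @param catalog gene catalog (uses `gene_id`, `parent_gene`).
#' @param config a [sim_config()].
#' @param tx_length_range transcript length range (default 400..1500 nt).
#' @return list with `transcripts` (named character vector), `gene_of`,
#'   and `truth` (data.frame `gene_id`, `shared_bp`).
#' @export
gen_transcripts <- function(catalog, config, tx_length_range = c(400, 1500)) {
  set.seed(stage_seed(config$seed, "transcripts"))
  n <- nrow(catalog)
  lens <- sample(tx_length_range[1]:tx_length_range[2], n, replace = TRUE)
  rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")
  tx <- vapply(lens, rand_seq, character(1))
  names(tx) <- catalog$gene_id
  shared <- integer(n)
  sb <- config$paralog_shared_bp
  if (sb > 0) {
    for (i in seq_len(n)) {
      p <- catalog$parent_gene[i]
      if (!is.na(p) && p %in% names(tx) && nchar(tx[p]) >= sb &&
          nchar(tx[i]) >= sb) {
        block <- substr(tx[[p]], 1, sb)
        tx[i] <- paste0(block, substr(tx[[i]], sb + 1, nchar(tx[[i]])))
        shared[i] <- sb
      }
    }
  }
  list(transcripts = tx, gene_of = catalog$gene_id,
       truth = data.frame(gene_id = catalog$gene_id, shared_bp = shared,
                          stringsAsFactors = FALSE))
}

#' Simulate two-group 32-nt RNA-seq reads with planted DE truth
#'
#' Per-gene baseline rates are gamma-distributed; a fraction `prop_de` of
#' genes is truly DE with rate multiplied by `2^de_effect_logfc` in its
#' biased group. Old DE genes pick the fetal or adult direction with equal
#' probability; young DE genes pick fetal with odds
#' `young_fetal_enrichment : 1`, planting the young/early association the
#' age-enrichment stage is meant to recover. Reads are error-free
#' substrings of the gene's transcript at uniform positions. Genes whose
#' transcripts are all shorter than the read length produce zero reads,
#' with a warning.
#'
#' @param catalog gene catalog.
#' @param transcripts named transcript vector from [gen_transcripts()].
#' @param config a [sim_config()].
#' @param reads_per_sample reads per sample.
#' @param n_samples_per_group samples per group (default 3, two groups:
#'   fetal and adult).
#' @return list with `reads` (list of named character vectors, one per
#'   sample), `source_counts` (gene x sample matrix of drawn read counts),
#'   `groups`, and `truth` (data.frame `gene_id`, `is_de`, `direction`).
#' @export
gen_rnaseq <- function(catalog, transcripts, config,
                       reads_per_sample = 100000, n_samples_per_group = 3) {
  set.seed(stage_seed(config$seed, "rnaseq"))
  k <- config$read_length
  genes <- catalog$gene_id
  n <- length(genes)
  usable <- nchar(transcripts[genes]) >= k
  if (any(!usable))
    warning(sum(!usable), " gene(s) with all transcripts shorter than the ",
            "read length emitted with zero reads")
  base <- stats::rgamma(n, shape = 0.5, rate = 1) + 1e-6
  n_de <- round(config$prop_de * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  direction <- rep("none", n)
  if (n_de > 0) {
    enr <- config$young_fetal_enrichment
    p_fetal <- ifelse(catalog$age_class[de_idx] == "young",
                      enr / (enr + 1), 0.5)
    direction[de_idx] <- ifelse(stats::runif(n_de) < p_fetal, "fetal", "adult")
  }
  fc <- 2^config$de_effect_logfc
  w_fetal <- base * ifelse(direction == "fetal", fc, 1) * usable
  w_adult <- base * ifelse(direction == "adult", fc, 1) * usable
  groups <- rep(c("fetal", "adult"), each = n_samples_per_group)
  samples <- sprintf("%s_%d", groups, sequence(rep(n_samples_per_group, 2)))
  src <- matrix(0L, n, length(samples), dimnames = list(genes, samples))
  reads <- vector("list", length(samples))
  names(reads) <- samples
  for (s in seq_along(samples)) {
    w <- if (groups[s] == "fetal") w_fetal else w_adult
    cnt <- stats::rmultinom(1, reads_per_sample, prob = w)[, 1]
    src[, s] <- cnt
    gi <- rep.int(seq_len(n), cnt)
    tx <- transcripts[genes[gi]]
    pos <- floor(stats::runif(length(gi)) * (nchar(tx) - k + 1)) + 1L
    rd <- substring(tx, pos, pos + k - 1L)
    names(rd) <- sprintf("%s_r%07d", samples[s], seq_along(rd))
    reads[[s]] <- rd
  }
  list(reads = reads, source_counts = src, groups = groups,
       truth = data.frame(gene_id = genes, is_de = direction != "none",
                          direction = direction, stringsAsFactors = FALSE))
}

#' Simulate MK count tables under the PRF model
#'
#' Independent Poisson draws with means `(theta_s L(0,n), theta_s tau,
#' theta_r L(gamma,n), theta_r tau G(gamma))` for `(ps, ds, pn, dn)`;
#' one row per entry of `gamma_values`.
#'
#' @param gamma_values true selection intensity per gene.
#' @param theta_s,theta_r synonymous / nonsynonymous mutation-rate scales.
#' @param tau divergence-time scale.
#' @param n_sample chromosomes sampled.
#' @param seed integer seed.
#' @return list with `mk` (data.frame `gene_id`, `ds`, `ps`, `dn`, `pn`,
#'   `n`) and `truth` (data.frame `gene_id`, `true_gamma`).
#' @export
gen_mk_counts <- function(gamma_values, theta_s = 10, theta_r = 10, tau = 1,
                          n_sample = 40, seed = 1) {
  if (theta_s <= 0 || theta_r <= 0 || tau <= 0) stop("rates must be positive")
  set.seed(stage_seed(seed, "mk"))
  L0 <- prf_L(0, n_sample)
  rows <- lapply(seq_along(gamma_values), function(i) {
    g <- gamma_values[i]
    mu <- c(ps = theta_s * L0, ds = theta_s * tau,
            pn = theta_r * prf_L(g, n_sample),
            dn = theta_r * tau * prf_G(g))
    cnt <- stats::rpois(4, mu)
    data.frame(gene_id = sprintf("mk%04d", i),
               ds = cnt[2], ps = cnt[1], dn = cnt[4], pn = cnt[3],
               n = n_sample, stringsAsFactors = FALSE)
  })
  list(mk = do.call(rbind, rows),
       truth = data.frame(gene_id = sprintf("mk%04d", seq_along(gamma_values)),
                          true_gamma = gamma_values, stringsAsFactors = FALSE))
}

#' Build a pairwise codon alignment with exact difference counts
#'
#' Constructs two in-frame sequences of `n_codons` codons that differ by
#' exactly `n_syn_diffs` synonymous changes (third positions of
#' fourfold-degenerate codons) and `n_nonsyn_diffs` nonsynonymous changes
#' (second positions, always amino-acid-changing), at most one change per
#' codon so counted differences are unambiguous.
#'
#' @param n_codons alignment length in codons.
#' @param n_syn_diffs synonymous differences to place.
#' @param n_nonsyn_diffs nonsynonymous differences to place.
#' @param seed integer seed.
#' @return list with `seq1`, `seq2` (character sequences).
#' @export
gen_codon_pairs <- function(n_codons, n_syn_diffs, n_nonsyn_diffs, seed = 1) {
  if (n_syn_diffs + n_nonsyn_diffs > n_codons)
    stop("impossible placement: more differences than codons")
  set.seed(stage_seed(seed, "codons"))
  fourfold <- c("GGA", "GGC", "GGG", "GGT", "CCA", "CCC", "CCG", "CCT",
                "GCA", "GCC", "GCG", "GCT", "GTA", "GTC", "GTG", "GTT")
  cod1 <- sample(fourfold, n_codons, replace = TRUE)
  cod2 <- cod1
  idx <- sample.int(n_codons, n_syn_diffs + n_nonsyn_diffs)
  syn_idx <- idx[seq_len(n_syn_diffs)]
  non_idx <- setdiff(idx, syn_idx)
  for (i in syn_idx) {
    third <- substr(cod2[i], 3, 3)
    substr(cod2[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"), third), 1)
  }
  for (i in non_idx) {
    second <- substr(cod2[i], 2, 2)
    repeat {   # second-position change; avoid creating a stop codon
      nb <- sample(setdiff(c("A", "C", "G", "T"), second), 1)
      cand <- cod2[i]
      substr(cand, 2, 2) <- nb
      if (.CODE[[cand]] != "*") { cod2[i] <- cand; break }
    }
  }
  list(seq1 = paste(cod1, collapse = ""), seq2 = paste(cod2, collapse = ""))
}
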
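# Gene dating: origination-branch assignment from ortholog presence/absence
# on a rooted species tree under Dollo parsimony (a gene arises once and can
# only be lost). Branch 0 is the oldest (shared by the whole clade), branch B
# the focal-species terminal branch.

#' Build a species tree object for branch dating
#'
#' Takes a rooted, bifurcating-on-the-focal-path phylogeny and a focal tip,
#' and derives the ordered root-to-focal path of internal nodes
#' `v0 .. v(B-1)` together with, for each `vi`, the outgroup clade `O_i`: the
#' tips that diverge from the focal lineage at `vi`. Branch indices run 0..B
#' with 0 the oldest branch (above `v0`) and B the focal terminal branch.
#'
#' @param tree an [ape::phylo] object or path to a newick file. Must be
#'   rooted; multifurcations on the root-to-focal path are rejected.
#' @param focal name of the focal tip (e.g. `"human"`).
#' @return an object of class `species_tree`: list with elements `tree`,
#'   `focal`, `outgroups` (list of character vectors, `O_0 .. O_(B-1)`),
#'   and `n_branches` (B, the terminal branch index).
#' @export
species_tree <- function(tree, focal) {
  if (is.character(tree) && length(tree) == 1L && file.exists(tree))
    tree <- ape::read.tree(tree)
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object or newick file")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!focal %in% tree$tip.label) stop("focal tip '", focal, "' not in tree")

  ntip <- length(tree$tip.label)
  focal_id <- match(focal, tree$tip.label)
  # parent lookup
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  # root-to-focal path of internal nodes
  path <- integer(0)
  node <- focal_id
  while (node != root) {
    node <- parent[node]
    path <- c(node, path)
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], tips_under), use.names = FALSE)
  }
  on_path_or_focal <- c(path, focal_id)
  outgroups <- vector("list", length(path))
  for (i in seq_along(path)) {
    kids <- children[[as.character(path[i])]]
    if (length(kids) != 2L)
      stop("multifurcation on the root-to-focal path at node ", path[i])
    off <- kids[!kids %in% on_path_or_focal]
    if (length(off) != 1L)
      stop("malformed path at node ", path[i])
    outgroups[[i]] <- sort(tips_under(off))
  }
  structure(list(tree = tree, focal = focal, outgroups = outgroups,
                 n_branches = length(path)),
            class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree: focal =", x$focal, "| terminal branch =", x$n_branches, "\n")
  for (i in seq_along(x$outgroups))
    cat(sprintf("  O_%d: %s\n", i - 1L, paste(x$outgroups[[i]], collapse = ",")))
  invisible(x)
}

#' Assign an origination branch to one gene
#'
#' Conservative (oldest-compatible) Dollo assignment: the gene is placed on
#' the oldest branch consistent with its presence pattern, i.e.
#' `min { i : present in at least one tip of O_i }`, or the terminal branch
#' B when the gene is present in no outgroup clade. A single presence in an
#' old outgroup therefore forces an old age; losses can only make a gene
#' look younger, never older.
#'
#' @param stree a [species_tree()] object.
#' @param present character vector of species in which the gene is present
#'   (must include the focal species), or a named logical vector.
#' @return integer branch index in `0..B`.
#' @export
assign_origination_branch <- function(stree, present) {
  stopifnot(inherits(stree, "species_tree"))
  if (is.logical(present)) {
    if (is.null(names(present))) stop("logical presence must be named by species")
    present <- names(present)[present]
  }
  tips <- stree$tree$tip.label
  unknown <- setdiff(present, tips)
  if (length(unknown))
    stop("unknown species in presence record: ", paste(unknown, collapse = ","))
  if (!stree$focal %in% present)
    stop("gene absent in focal species '", stree$focal, "'")
  for (i in seq_along(stree$outgroups))
    if (any(stree$outgroups[[i]] %in% present)) return(i - 1L)
  stree$n_branches
}

#' Date every gene in a presence/absence matrix
#'
#' @param stree a [species_tree()] object.
#' @param presence logical matrix, genes in rows (rownames = gene ids),
#'   species in columns (colnames = tree tips).
#' @return data.frame with columns `gene_id`, `branch`.
#' @export
date_genes <- function(stree, presence) {
  stopifnot(inherits(stree, "species_tree"), is.matrix(presence))
  if (!setequal(colnames(presence), stree$tree$tip.label))
    stop("presence matrix species set must equal the tree tip set")
  branch <- vapply(seq_len(nrow(presence)), function(i) {
    assign_origination_branch(stree, colnames(presence)[presence[i, ]])
  }, integer(1))
  data.frame(gene_id = rownames(presence), branch = branch,
             stringsAsFactors = FALSE)
}

#' Classify branch indices into young/old age classes
#'
#' Young genes are those whose origination branch falls in the configured
#' young-branch set; for a human-focused 0..12 branch scheme the default
#' young set is branches 8..12 (primate-specific, with 12 human-specific).
#'
#' @param branch integer vector of branch indices.
#' @param young_branches non-empty integer set defining "young".
#' @return character vector, `"young"` or `"old"`.
#' @export
classify_age <- function(branch, young_branches = 8:12) {
  if (length(young_branches) == 0) stop("young branch set must be non-empty")
  ifelse(branch %in% young_branches, "young", "old")
}

#' Extract an ancestral gene subset from homology flags
#'
#' Selects genes with a one-to-one ortholog in every ingroup species and no
#' homolog of any kind in any outgroup species — e.g. a vertebrate-ancestor
#' set (1:1 in both zebrafish and fugu, no homolog in tunicates, fly,
#' mosquito, worm, yeast).
#'
#' @param homology data.frame with columns `gene_id`, `species`,
#'   `one2one` (logical: 1:1 ortholog) and `homolog` (logical: any homolog).
#' @param ingroup species that must all carry a 1:1 ortholog.
#' @param outgroups species that must all lack any homolog.
#' @return character vector of gene ids.
#' @export
extract_ancestral_subset <- function(homology, ingroup, outgroups) {
  need <- c("gene_id", "species", "one2one", "homolog")
  if (!all(need %in% names(homology)))
    stop("homology table must have columns: ", paste(need, collapse = ", "))
  missing_sp <- setdiff(c(ingroup, outgroups), unique(homology$species))
  if (length(missing_sp))
    stop("species missing from homology table: ", paste(missing_sp, collapse = ","))
  genes <- unique(homology$gene_id)
  keep <- vapply(genes, function(g) {
    h <- homology[homology$gene_id == g, ]
    all(vapply(ingroup, function(s) any(h$species == s & h$one2one), logical(1))) &&
      !any(h$species %in% outgroups & h$homolog)
  }, logical(1))
  genes[keep]
}
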
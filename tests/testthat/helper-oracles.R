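# Independent brute-force oracles used to cross-check the package's
# statistics. These deliberately share no code with the implementation.

# two-sided Fisher exact p by exhaustive hypergeometric enumeration over all
# tables with the observed margins: sum the probabilities of outcomes no
# more probable than the observed one
fet_oracle <- function(a, b, c, d) {
  m <- a + b        # row 1 total
  n <- c + d        # row 2 total
  k <- a + c        # col 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-sided exact binomial p against 0.5 by outcome-probability enumeration
binom_oracle <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  p_obs <- stats::dbinom(k, n, 0.5)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force unique-k-mer counts: enumerate every window of every
# transcript into a long table and count k-mers seen in exactly one gene
kmer_count_oracle <- function(transcripts, gene_of, k) {
  rows <- list()
  for (i in seq_along(transcripts)) {
    s <- transcripts[[i]]
    if (nchar(s) < k) next
    for (st in 1:(nchar(s) - k + 1))
      rows[[length(rows) + 1L]] <- c(substr(s, st, st + k - 1), gene_of[i])
  }
  if (!length(rows)) {
    return(stats::setNames(rep(0L, length(unique(gene_of))),
                           sort(unique(gene_of))))
  }
  df <- unique(data.frame(kmer = vapply(rows, `[`, "", 1),
                          gene = vapply(rows, `[`, "", 2)))
  shared <- names(which(table(df$kmer) > 1))
  df <- df[!df$kmer %in% shared, ]
  out <- stats::setNames(rep(0L, length(unique(gene_of))), sort(unique(gene_of)))
  tt <- table(df$gene)
  out[names(tt)] <- as.integer(tt)
  out
}

# Dollo parsimony oracle: enumerate every origination-branch hypothesis,
# count the whole-clade losses it requires (a hypothesis is impossible when
# an outgroup clade that predates the origination shows presence), and pick
# the hypothesis needing the fewest losses
dollo_oracle <- function(stree, present) {
  B <- stree$n_branches
  losses <- rep(Inf, B + 1)
  for (b in 0:B) {
    older_presence <- FALSE
    n_loss <- 0
    for (i in seq_len(B)) {          # clade O_{i-1}
      has <- any(stree$outgroups[[i]] %in% present)
      if ((i - 1) < b && has) older_presence <- TRUE
      if ((i - 1) >= b && !has) n_loss <- n_loss + 1
    }
    if (!older_presence) losses[b + 1] <- n_loss
  }
  which.min(losses) - 1L
}

# union-find chaining oracle for cluster pooling
chain_oracle <- function(df, cutoff) {
  df <- df[df$bias != "unbiased", , drop = FALSE]
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; as.integer(i) }
  ord <- order(df$chrom, df$start, df$end, df$gene_id)
  df <- df[ord, , drop = FALSE]
  for (i in seq_len(n - 1)) {
    j <- i + 1
    same <- df$chrom[i] == df$chrom[j] && df$branch[i] == df$branch[j] &&
      df$bias[i] == df$bias[j]
    if (same && (df$start[j] - df$end[i]) <= cutoff) {
      ri <- find(i); rj <- find(j)
      parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(df$gene_id, comp)
}

# dense-grid + refinement oracle for the PRF gamma estimate
gamma_grid_oracle <- function(NI, n_sample, lim = 30) {
  R <- function(g) {
    if (abs(g) < 1e-8) return(1)
    L0 <- stats::integrate(function(q) (1 - q^n_sample - (1 - q)^n_sample) / q,
                           0, 1, rel.tol = 1e-10)$value
    Lg <- stats::integrate(function(q)
      (1 - exp(-2 * g * (1 - q))) / ((1 - exp(-2 * g)) * q * (1 - q)) *
        (1 - q^n_sample - (1 - q)^n_sample), 0, 1, rel.tol = 1e-10)$value
    Gg <- 2 * g / (1 - exp(-2 * g))
    Lg / L0 / Gg
  }
  grid <- seq(-lim, lim, by = 0.05)
  err <- vapply(grid, function(g) abs(R(g) - NI), numeric(1))
  g0 <- grid[which.min(err)]
  fine <- seq(g0 - 0.05, g0 + 0.05, by = 1e-4)
  ferr <- vapply(fine, function(g) abs(R(g) - NI), numeric(1))
  fine[which.min(ferr)]
}

# independent numerical-maximisation oracle for the binomial two-group LRT
lrt_oracle <- function(x1, N1, x2, N2) {
  ll <- function(x, n, p) stats::dbinom(x, n, p, log = TRUE)
  l1 <- stats::optimize(function(p) ll(x1, N1, p), c(1e-12, 1 - 1e-12),
                        maximum = TRUE, tol = 1e-12)$objective +
        stats::optimize(function(p) ll(x2, N2, p), c(1e-12, 1 - 1e-12),
                        maximum = TRUE, tol = 1e-12)$objective
  l0 <- stats::optimize(function(p) ll(x1, N1, p) + ll(x2, N2, p),
                        c(1e-12, 1 - 1e-12), maximum = TRUE, tol = 1e-12)$objective
  lam <- 2 * (l1 - l0)
  c(lambda = lam, p = stats::pchisq(lam, 1, lower.tail = FALSE))
}

# small rooted caterpillar tree with named focal tip, for dating tests
caterpillar_tree <- function(tips, focal = "human") {
  nwk <- focal
  for (t in rev(tips)) nwk <- sprintf("(%s,%s)", t, nwk)
  ape::read.tree(text = paste0(nwk, ";"))
}

# tiny EST table builder
est_row <- function(lib, species, tissue, stage, gene, count, normal = TRUE) {
  data.frame(library_id = lib, species = species, tissue = tissue,
             stage = stage, normal_flag = normal, gene_id = gene,
             est_count = count, stringsAsFactors = FALSE)
}
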
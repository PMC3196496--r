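rand_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("effective length counts k-mers unique to one gene", {
  # single gene, no sharing: L - k + 1 windows
  el <- effective_length(rand_dna(100, 1), "g1", k = 32)
  expect_equal(el$effective_length, 69)
  # shorter than k: zero
  expect_equal(effective_length(rand_dna(31, 2), "g1", k = 32)$effective_length, 0)
  # two 50-nt genes sharing an identical 40-nt block: 19 windows each, minus
  # the 9 windows wholly inside the shared block
  block <- rand_dna(40, 3)
  gA <- paste0(rand_dna(10, 4), block)   # block is gA's suffix
  gB <- paste0(block, rand_dna(10, 5))   # and gB's prefix
  el2 <- effective_length(c(gA, gB), c("gA", "gB"), k = 32)
  expect_equal(el2$effective_length, c(10, 10))
  # repeated k-mers within one gene count once
  rep_seq <- paste0(rand_dna(40, 6), rand_dna(40, 6))
  el3 <- effective_length(rep_seq, "g1", k = 32)
  expect_equal(el3$effective_length,
               unname(kmer_count_oracle(rep_seq, "g1", 32)))
})

test_that("effective length matches the brute-force k-mer oracle on random inputs", {
  set.seed(7)
  for (rep in 1:5) {
    n_genes <- sample(3:6, 1)
    tx <- vapply(seq_len(n_genes), function(i)
      rand_dna(sample(40:400, 1), seed = rep * 100 + i), character(1))
    # inject sharing between two genes
    tx[2] <- paste0(substr(tx[1], 1, 60), substr(tx[2], 61, nchar(tx[2])))
    genes <- paste0("g", seq_len(n_genes))
    el <- effective_length(tx, genes, k = 32)
    oracle <- kmer_count_oracle(tx, genes, 32)
    expect_equal(stats::setNames(el$effective_length, el$gene_id), oracle)
  }
})

test_that("reads are assigned uniquely, multi-gene and unmatched reads discarded", {
  block <- rand_dna(40, 11)
  gA <- paste0(rand_dna(30, 12), block)
  gB <- paste0(block, rand_dna(30, 13))
  tx <- c(gA, gB); genes <- c("gA", "gB")
  unique_read <- substr(gA, 1, 32)          # inside gA's private prefix
  shared_read <- substr(block, 1, 32)       # wholly inside the shared block
  nohit_read <- paste(rep("A", 32), collapse = "")
  rc_read <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(gB, 39, 70))))
  res <- assign_reads(c(unique_read, shared_read, nohit_read, rc_read),
                      tx, genes, k = 32)
  expect_equal(res$counts[["gA"]], 1L)
  expect_equal(res$counts[["gB"]], 1L)      # via reverse complement
  expect_equal(res$n_multi, 1L)
  expect_equal(res$n_unmatched, 1L)
  expect_equal(res$total + res$n_multi + res$n_unmatched, 4L)
  expect_error(assign_reads("ACGT", tx, genes, k = 32), "exactly 32")
})

test_that("RPMK has the documented unit, scaling, and guards", {
  expect_equal(rpmk(1000, 1000, 1e6), 1000)
  expect_equal(rpmk(250, 500, 2e6), 250)
  expect_equal(rpmk(100, 1000, 2e6), rpmk(100, 1000, 1e6) / 2)
  expect_error(rpmk(10, 0, 1e6), "effective length")
  expect_error(rpmk(10, 100, 0), "total mapped")
})

test_that("short-mappable filter hits duplicates only, with a strict boundary", {
  catal <- data.frame(gene_id = c("r", "d", "n", "u"),
                      mechanism = c("retrogene", "dna_duplicate", "de_novo", "unknown"),
                      stringsAsFactors = FALSE)
  lens <- data.frame(gene_id = c("r", "d", "n", "u"),
                     effective_length = c(29, 30, 10, 5))
  f <- filter_short_mappable(catal, lens, min_bp = 30)
  expect_equal(f$excluded, "r")             # 29 < 30
  expect_true(all(c("d", "n", "u") %in% f$retained))  # 30 passes; de novo/unknown exempt
})

test_that("binomial LRT matches a numerical maximisation oracle and the G-test", {
  r <- lrt_de(5, 1000, 5, 1000)
  expect_equal(r$lambda, 0)
  expect_equal(r$p, 1)
  r2 <- lrt_de(10, 1e6, 40, 1e6)
  o <- lrt_oracle(10, 1e6, 40, 1e6)
  expect_equal(r2$lambda, unname(o["lambda"]), tolerance = 1e-8)
  expect_equal(r2$p, unname(o["p"]), tolerance = 1e-8)
  # swap symmetry and non-negativity on random tables, and equality with the
  # G-test of the 2x2 table (x1, N1-x1; x2, N2-x2)
  set.seed(13)
  for (i in 1:25) {
    N1 <- sample(500:5000, 1); N2 <- sample(500:5000, 1)
    x1 <- rbinom(1, N1, 0.02); x2 <- rbinom(1, N2, 0.05)
    a <- lrt_de(x1, N1, x2, N2); b <- lrt_de(x2, N2, x1, N1)
    expect_equal(a$lambda, b$lambda, tolerance = 1e-12)
    expect_gte(a$lambda, 0)
    obs <- c(x1, N1 - x1, x2, N2 - x2)
    tot <- N1 + N2; c1 <- x1 + x2
    expc <- c(N1 * c1, N1 * (tot - c1), N2 * c1, N2 * (tot - c1)) / tot
    gstat <- 2 * sum(ifelse(obs == 0, 0, obs * log(obs / expc)))
    expect_equal(a$lambda, gstat, tolerance = 1e-8)
  }
  expect_error(lrt_de(-1, 10, 2, 10), "counts")
  expect_error(lrt_de(1, 0, 2, 10), "totals")
})

test_that("BH adjustment is the step-up procedure and dominates Bonferroni", {
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(17)
  p <- runif(50)^2
  q <- bh_fdr(p)
  bonf <- pmin(1, p * length(p))
  expect_true(all(which(bonf < 0.05) %in% which(q < 0.05)))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-group DE calls direction by per-read rate at the FDR cutoff", {
  counts <- rbind(gUp = c(400, 420, 100, 110),
                  gFlat = c(50, 55, 52, 49))
  groups <- c("fetal", "fetal", "adult", "adult")
  totals <- rep(1e5, 4)
  de <- de_test(counts, groups, totals, fdr = 0.05)
  expect_equal(de$bias[de$gene_id == "gUp"], "fetal")
  expect_equal(de$bias[de$gene_id == "gFlat"], "unbiased")
  expect_equal(de$x1[de$gene_id == "gUp"], 820)   # samples pooled within group
})

test_that("sample grouping recovers planted blocks and is order-invariant", {
  set.seed(23)
  base <- matrix(rnorm(200 * 6), 200, 6)
  base[, 1:3] <- base[, 1:3] + matrix(rep(rnorm(200, sd = 3), 3), 200, 3)
  base[, 4:6] <- base[, 4:6] + matrix(rep(rnorm(200, sd = 3), 3), 200, 3)
  colnames(base) <- paste0("s", 1:6)
  g <- group_samples(base)
  expect_equal(length(unique(g[1:3])), 1)
  expect_equal(length(unique(g[4:6])), 1)
  expect_true(g[1] != g[4])
  perm <- sample(6)
  g2 <- group_samples(base[, perm])
  agree <- mean((g[perm] == g[perm][1]) == (g2 == g2[1]))
  expect_equal(agree, 1)
  # two samples: forced singleton groups
  expect_equal(unname(group_samples(base[, 1:2])), c(1L, 2L))
  flat <- matrix(rep(1:10, 4), 10, 4)
  expect_error(group_samples(flat), "zero")
})
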
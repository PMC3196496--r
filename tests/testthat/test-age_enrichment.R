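make_calls <- function(n_young, young_early, n_old, old_early,
                       labels = c("early", "late")) {
  data.frame(
    gene_id = paste0("g", seq_len(n_young + n_old)),
    bias = c(rep(labels[1], young_early), rep(labels[2], n_young - young_early),
             rep(labels[1], old_early), rep(labels[2], n_old - old_early)),
    stringsAsFactors = FALSE)
}

make_cat <- function(n_young, n_old) {
  data.frame(gene_id = paste0("g", seq_len(n_young + n_old)),
             age_class = c(rep("young", n_young), rep("old", n_old)),
             stringsAsFactors = FALSE)
}

test_that("age x bias table matches the enumeration oracle and excludes unbiased genes", {
  calls <- make_calls(40, 30, 1020, 500)
  bt <- bias_table(calls, make_cat(40, 1020))
  expect_equal(bt$table["young", "early"], 30)
  expect_equal(bt$p, fet_oracle(30, 10, 500, 520), tolerance = 1e-12)
  # equal proportions: p = 1
  expect_equal(bias_table(make_calls(20, 10, 100, 50), make_cat(20, 100))$p, 1)
  # unbiased genes are dropped before the table is formed
  calls$bias[1:5] <- "unbiased"
  bt2 <- bias_table(calls, make_cat(40, 1020))
  expect_equal(sum(bt2$table), nrow(calls) - 5)
  empty <- data.frame(gene_id = "g1", bias = "unbiased")
  expect_error(bias_table(empty, make_cat(1, 0)), "no biased")
})

test_that("planted young-early enrichment is detected by the bias table", {
  set.seed(31)
  hits <- 0
  for (r in 1:100) {
    n_young <- 450; n_old <- 4550
    ye <- rbinom(1, n_young, 0.75)   # odds 3 toward early
    oe <- rbinom(1, n_old, 0.5)
    bt <- bias_table(make_calls(n_young, ye, n_old, oe), make_cat(n_young, n_old))
    hits <- hits + (bt$p < 0.05)
  }
  expect_gte(hits, 95)
})

test_that("branch profile uses the exact binomial test among biased genes", {
  catal <- data.frame(gene_id = paste0("g", 1:40),
                      branch = rep(c(0, 1), each = 20))
  calls <- data.frame(gene_id = paste0("g", 1:40),
                      bias = c(rep(c("up", "down"), 10),          # branch 0: 10/10
                               rep("up", 9), "down", rep("unbiased", 10)))
  bp <- branch_profile(calls, catal, n_branches = 1,
                       up_label = "up", down_label = "down")
  expect_equal(bp$p[bp$branch == 0], 1)
  expect_equal(bp$p[bp$branch == 1], 11 / 512, tolerance = 1e-12)
  expect_equal(bp$p[bp$branch == 1], binom_oracle(9, 10), tolerance = 1e-12)
  expect_equal(bp$p_bonferroni, pmin(1, bp$p * 2))
  # proportions account for all genes: up + down + unbiased = n
  expect_equal(bp$n_up + bp$n_down + c(0, 10), bp$n)
  expect_equal(bp$p_one_sided[bp$branch == 1],
               stats::pbinom(8, 10, 0.5, lower.tail = FALSE))
})

cluster_cat <- function(starts, ends, branch, bias, chrom = "chr1") {
  data.frame(gene_id = paste0("g", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, branch = branch,
             age_class = ifelse(branch >= 8, "young", "old"), bias = bias,
             stringsAsFactors = FALSE)
}

test_that("cluster pooling chains neighbours by gap, age and bias", {
  cc <- cluster_cat(c(0, 50000), c(1000, 51000), c(8, 8), c("fetal", "fetal"))
  expect_equal(nrow(pool_clusters(cc, 1e5)$clusters), 1)   # gap 49,000
  cc2 <- cluster_cat(c(0, 50000), c(1000, 51000), c(8, 8), c("fetal", "adult"))
  expect_equal(nrow(pool_clusters(cc2, 1e5)$clusters), 2)  # bias differs
  # chain A-B-C with gaps 80 kb and 90 kb
  cc3 <- cluster_cat(c(0, 81000, 172000), c(1000, 82000, 173000),
                     rep(8, 3), rep("fetal", 3))
  expect_equal(pool_clusters(cc3, 1e5)$clusters$n_genes, 3)
  cl85 <- pool_clusters(cc3, 85000)$clusters
  expect_equal(cl85$n_genes, c(2, 1))
  # overlapping genes merge when labels match (gap <= 0)
  cc4 <- cluster_cat(c(0, 500), c(1000, 1500), c(8, 8), c("fetal", "fetal"))
  expect_equal(nrow(pool_clusters(cc4, 0)$clusters), 1)
})

test_that("cluster pooling matches a union-find oracle and is monotone in the cutoff", {
  set.seed(37)
  for (r in 1:10) {
    n <- 60
    cc <- data.frame(
      gene_id = paste0("g", 1:n),
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = sample.int(5e5, n), branch = sample(c(3, 8, 12), n, TRUE),
      bias = sample(c("fetal", "adult", "unbiased"), n, TRUE),
      stringsAsFactors = FALSE)
    cc$end <- cc$start + sample(500:5000, n, TRUE)
    cc$age_class <- ifelse(cc$branch >= 8, "young", "old")
    prev_n <- Inf
    for (cutoff in c(1e3, 1e4, 1e5, 1e6)) {
      res <- pool_clusters(cc, cutoff)
      oracle <- chain_oracle(cc, cutoff)
      got <- sort(vapply(strsplit(res$clusters$members, ","), function(m)
        paste(sort(m), collapse = ","), character(1)))
      want <- sort(unname(vapply(oracle, function(m) paste(sort(m), collapse = ","),
                                 character(1))))
      expect_equal(got, want)
      expect_lte(nrow(res$clusters), prev_n)
      prev_n <- nrow(res$clusters)
    }
    # record order does not matter
    res1 <- pool_clusters(cc, 1e5)$clusters
    res2 <- pool_clusters(cc[sample(n), ], 1e5)$clusters
    expect_equal(res1, res2)
  }
})

test_that("feature association uses overlap-or-gap distance with inclusive cutoff", {
  catal <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                      start = c(1000, 50000, 200000),
                      end = c(2000, 51000, 201000),
                      age_class = c("young", "young", "old"),
                      stringsAsFactors = FALSE)
  feats <- data.frame(chrom = "chr1", start = c(1500, 61001), end = c(1600, 61100))
  # feature inside gene a; feature 10,001 bp from gene b's end
  fa0 <- feature_association(catal, feats, cutoff_bp = 0)
  expect_true(attr(fa0, "associated")[1])
  fa <- feature_association(catal, feats, cutoff_bp = 10000)
  expect_false(attr(fa, "associated")[2])   # strict: 10,001 > 10,000
  fa2 <- feature_association(catal, feats, cutoff_bp = 10001)
  expect_true(attr(fa2, "associated")[2])
  expect_equal(fa$fraction[fa$age_class == "young"], 0.5)
  expect_error(feature_association(catal, feats, cutoff_bp = -1), "non-negative")
})

test_that("random feature placement matches the geometric expectation", {
  set.seed(43)
  L <- 1e6
  catal <- data.frame(gene_id = "g", chrom = "chr1", start = 450000,
                      end = 451000, age_class = "young")
  cutoff <- 50000
  n_feat <- 40; n_rep <- 200
  hits <- 0
  for (r in 1:n_rep) {
    fs <- sample.int(L - 100, n_feat)
    feats <- data.frame(chrom = "chr1", start = fs, end = fs + 100)
    hits <- hits + attr(feature_association(catal, feats, cutoff), "associated")[1]
  }
  # window where a 100-bp feature lies within 50 kb of the 1-kb gene
  p_one <- (2 * cutoff + 1000 + 100) / (L - 100)
  p_any <- 1 - (1 - p_one)^n_feat
  expect_lt(abs(hits / n_rep - p_any), 3 * sqrt(p_any * (1 - p_any) / n_rep) + 0.02)
})

test_that("term enrichment computes fold, one-sided FET, and FDR", {
  bg <- paste0("g", 1:100)
  lst <- paste0("g", 1:10)
  tm <- data.frame(gene_id = c(paste0("g", 1:4), paste0("g", 20:25)),
                   term = "T1", stringsAsFactors = FALSE)
  te <- term_enrichment(lst, bg, tm)
  expect_equal(te$fold_enrichment, (4 / 10) / (10 / 100))  # = 4.0
  expect_equal(te$fold_enrichment, 4.0)
  te2 <- term_enrichment(bg, bg, tm)
  expect_equal(te2$fold_enrichment, 1)
  expect_equal(te2$p, 1)
  expect_error(term_enrichment(c(lst, "absent"), bg, tm), "subset")
})

test_that("a planted enriched term is recovered at FDR 0.05", {
  set.seed(47)
  bg <- paste0("g", 1:2000)
  # 200-gene list; term A covers 10% of background but 30% of the list
  lst <- paste0("g", 1:200)
  termA <- c(paste0("g", 1:60), paste0("g", sample(201:2000, 140)))
  other <- lapply(1:5, function(i) paste0("g", sample(2000, 200)))
  tm <- rbind(data.frame(gene_id = termA, term = "A"),
              do.call(rbind, lapply(seq_along(other), function(i)
                data.frame(gene_id = other[[i]], term = paste0("N", i)))))
  te <- term_enrichment(lst, bg, tm)
  expect_true(te$significant[te$term == "A"])
  expect_false(any(te$significant[te$term != "A"]))
})
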
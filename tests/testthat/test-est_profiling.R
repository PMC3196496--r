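toy_catalog <- data.frame(
  gene_id = c("y1", "y2", "o1", "o2", "o3"),
  age_class = c("young", "young", "old", "old", "old"),
  stringsAsFactors = FALSE)

test_that("presence requires the configured minimum EST support", {
  est <- rbind(est_row("L1", "human", "brain", "fetal", "y1", 2),
               est_row("L1", "human", "brain", "fetal", "o1", 1),
               est_row("L2", "human", "brain", "adult", "o1", 1))
  calls <- call_expression(est, min_ests = 2)
  expect_true(calls$expressed[calls$gene_id == "y1"])
  # counts sum across libraries within (species, tissue): 1 + 1 ESTs = present
  expect_equal(calls$est_total[calls$gene_id == "o1"], 2)
  expect_true(calls$expressed[calls$gene_id == "o1"])
  # split by stage, each o1 cell has a single EST: absent at 2, present at 1
  calls2 <- call_expression(est, min_ests = 2, by_stage = TRUE)
  expect_false(any(calls2$expressed[calls2$gene_id == "o1"]))
  calls1 <- call_expression(est, min_ests = 1, by_stage = TRUE)
  expect_true(all(calls1$expressed[calls1$gene_id == "o1"]))
})

test_that("non-normal libraries are excluded and empty tables give empty calls", {
  est <- est_row("L1", "human", "brain", "fetal", "y1", 5, normal = FALSE)
  expect_equal(nrow(call_expression(est)), 0)
  expect_equal(nrow(call_expression(est[0, ])), 0)
})

test_that("unknown stage labels are routed to 'unknown' with a warning", {
  est <- est_row("L1", "human", "brain", "embryonic day 9", "y1", 3)
  expect_warning(calls <- call_expression(est, by_stage = TRUE), "unknown stage")
  expect_equal(calls$stage, "unknown")
})

test_that("raising the presence threshold never adds presences", {
  set.seed(5)
  est <- do.call(rbind, lapply(1:30, function(i)
    est_row(paste0("L", sample(3, 1)), "human", sample(c("brain", "liver"), 1),
            sample(c("fetal", "adult"), 1), sample(toy_catalog$gene_id, 1),
            sample(1:4, 1))))
  for (t in 2:4) {
    lo <- call_expression(est, min_ests = t - 1)
    hi <- call_expression(est, min_ests = t)
    key <- function(d) paste(d$gene_id, d$species, d$tissue)
    expect_true(all(key(hi)[hi$expressed] %in% key(lo)[lo$expressed]))
  }
})

test_that("young proportion counts young genes among expressed genes", {
  est <- rbind(est_row("L1", "human", "brain", "fetal", "y1", 3),
               est_row("L1", "human", "brain", "fetal", "o1", 3),
               est_row("L1", "human", "brain", "fetal", "o2", 3))
  calls <- call_expression(est)
  yp <- young_proportion(calls, toy_catalog, "brain", "human")
  expect_equal(yp$young, 1)
  expect_equal(yp$total, 3)
  expect_equal(yp$proportion, 1 / 3)
  all_young <- call_expression(rbind(est_row("L1", "human", "brain", "fetal", "y1", 3),
                                     est_row("L1", "human", "brain", "fetal", "y2", 3)))
  expect_equal(young_proportion(all_young, toy_catalog, "brain")$proportion, 1)
  expect_error(young_proportion(calls, toy_catalog, "kidney"), "no expressed genes")
})

test_that("proportion comparison matches the hypergeometric enumeration oracle", {
  expect_equal(compare_proportions(c(3, 10), c(3, 10))$p, 1.0)
  expect_equal(compare_proportions(c(3, 10), c(1, 10))$p,
               fet_oracle(3, 7, 1, 9), tolerance = 1e-12)
  cp <- compare_proportions(c(1, 5), c(0, 5), m_tests = 30)
  expect_equal(cp$p_bonferroni, min(1, cp$p * 30))
  expect_error(compare_proportions(c(3, 2), c(1, 5)), "total")
  expect_error(compare_proportions(c(0, 0), c(1, 5)), "zero totals")
})

test_that("bootstrap of background ESTs is deterministic and degenerate-safe", {
  est1 <- est_row("L1", "human", "brain", "fetal", "y1", 50)
  b <- bootstrap_background(est1, toy_catalog, n_reps = 20, seed = 3)
  expect_equal(b$boot_sd, 0)       # single gene: every replicate identical
  expect_equal(b$boot_mean, 1)
  est <- rbind(est_row("L1", "human", "brain", "fetal", "y1", 10),
               est_row("L1", "human", "brain", "fetal", "o1", 30),
               est_row("L2", "human", "liver", "adult", "o2", 25))
  b1 <- bootstrap_background(est, toy_catalog, n_reps = 50, seed = 9)
  b2 <- bootstrap_background(est, toy_catalog, n_reps = 50, seed = 9)
  expect_identical(b1, b2)
  b3 <- bootstrap_background(est[sample(nrow(est)), ], toy_catalog,
                             n_reps = 50, seed = 9)
  expect_equal(b1$boot_mean, b3$boot_mean[match(paste(b1$species, b1$tissue),
                                                paste(b3$species, b3$tissue))])
  expect_error(bootstrap_background(est, toy_catalog, n_reps = 1), "n_reps")
})

test_that("bootstrap mean tracks the point estimate at large depth", {
  cfg <- sim_config(seed = 21, n_genes = 400, n_tissues = 2,
                    mean_library_size = 20000)
  catal <- gen_catalog(gen_presence(cfg)$truth, cfg)
  est <- gen_est_table(catal, cfg)$est
  calls <- call_expression(est)
  b <- bootstrap_background(est, catal, n_reps = 40, seed = 2)
  for (i in seq_len(nrow(b))) {
    pt <- young_proportion(calls, catal, b$tissue[i], b$species[i])$proportion
    expect_lt(abs(b$boot_mean[i] - pt), max(3 * b$boot_sd[i], 0.02))
  }
})

test_that("subsampling control is conservative, deterministic, and detects forced enrichment", {
  # deterministic toy: every a-EST from young genes, every b-EST from old
  est_a <- rbind(est_row("L1", "human", "brain", "fetal", "y1", 200),
                 est_row("L1", "human", "brain", "fetal", "y2", 200))
  est_b <- rbind(est_row("L1", "mouse", "brain", "fetal", "o1", 200),
                 est_row("L1", "mouse", "brain", "fetal", "o2", 200))
  r <- subsample_control(est_a, est_b, toy_catalog, sample_size = 100,
                         n_reps = 1000, seed = 4)
  expect_equal(r$failures, 0)
  expect_equal(r$p_label, "<0.001")
  # identical inputs: empirical p near 0.5 (ties count as failures, so >= 0.5)
  r2 <- subsample_control(est_a, est_a, toy_catalog, sample_size = 100,
                          n_reps = 400, seed = 8)
  expect_gt(r2$p, 0.4)
  r3 <- subsample_control(est_a, est_b, toy_catalog, sample_size = 100,
                          n_reps = 100, seed = 4)
  r4 <- subsample_control(est_a, est_b, toy_catalog, sample_size = 100,
                          n_reps = 100, seed = 4)
  expect_identical(r3, r4)
  expect_error(subsample_control(est_a, est_b, toy_catalog, sample_size = 1000),
               "exceeds")
})
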
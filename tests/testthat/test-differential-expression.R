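# brute-force step-up oracle: for the i-th smallest p, explicitly
# minimize p_(j) * n / j over all j >= i
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(n), function(i) {
    min(vapply(i:n, function(j) ps[j] * n / j, 0))
  }, 0)
  pmin(q, 1)[order(ord)]
}

test_that("bh_adjust matches the hand-enumerated step-up examples", {
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(-0.1)), "\\[0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("bh_adjust equals the brute-force oracle and stats::p.adjust", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(1:60, 1)
    p <- switch(sample(3, 1),
                runif(n),
                rbeta(n, 0.3, 4),        # enriched small p
                round(runif(n), 2))      # ties
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= 0 & q <= 1))
    # monotone consistency: ordering of q follows ordering of p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("equal group means give zero fold change and p = 1", {
  x <- rbind(gA = c(1, 2, 3, 1, 2, 3),
             gB = c(5, 6, 7, 7, 6, 5))
  colnames(x) <- paste0("s", 1:6)
  spec <- contrast_spec("c1", paste0("s", 1:3), paste0("s", 4:6))
  res <- contrast_test(x, spec, moderation = "ordinary")
  expect_equal(res$log2fc, c(0, 0))
  expect_equal(res$t_stat, c(0, 0))
  expect_equal(res$p_value, c(1, 1))
})

test_that("ordinary t and p match the pooled-variance formula exactly", {
  # fixed printed fixture: 5 genes, 3 vs 3 samples
  x <- rbind(g1 = c(7.10, 7.30, 7.20, 6.50, 6.40, 6.60),
             g2 = c(5.00, 5.20, 5.10, 5.05, 5.15, 5.10),
             g3 = c(9.80, 9.50, 9.65, 10.40, 10.60, 10.50),
             g4 = c(6.00, 6.00, 6.01, 6.00, 6.00, 5.99),
             g5 = c(8.20, 8.90, 8.50, 7.10, 7.40, 7.30))
  colnames(x) <- paste0("s", 1:6)
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  res <- contrast_test(x, contrast_spec("fix", a, b), moderation = "ordinary")
  for (g in rownames(x)) {
    va <- var(x[g, a]); vb <- var(x[g, b])
    sp2 <- (2 * va + 2 * vb) / 4
    tt <- (mean(x[g, a]) - mean(x[g, b])) / sqrt(sp2 * (1 / 3 + 1 / 3))
    pp <- 2 * pt(-abs(tt), 4)
    i <- match(g, res$gene_id)
    expect_equal(res$t_stat[i], tt, tolerance = 1e-10)
    expect_equal(res$p_value[i], pp, tolerance = 1e-10)
    # agreement with the classical t-test as an independent implementation
    ref <- t.test(x[g, a], x[g, b], var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t reduces to the ordinary t when d0 = 0", {
  x <- tiny_matrix(50, 8, seed = 4) +
    matrix(rnorm(400, 0, 0.3), 50, 8)
  spec <- contrast_spec("c", colnames(x)[1:4], colnames(x)[5:8])
  eb0 <- contrast_test(x, spec, moderation = "eb", d0 = 0, s0_sq = 1)
  ord <- contrast_test(x, spec, moderation = "ordinary")
  expect_equal(eb0$t_stat, ord$t_stat, tolerance = 1e-12)
  expect_equal(eb0$p_value, ord$p_value, tolerance = 1e-12)
})

test_that("moderated t uses the prior variance for every gene as d0 -> Inf", {
  x <- tiny_matrix(40, 10, seed = 8) + matrix(rnorm(400, 0, 0.5), 40, 10)
  a <- colnames(x)[1:5]; b <- colnames(x)[6:10]
  spec <- contrast_spec("c", a, b)
  s0 <- 0.17
  res <- contrast_test(x, spec, moderation = "eb", d0 = Inf, s0_sq = s0)
  fc <- rowMeans(x[, a]) - rowMeans(x[, b])
  expected_t <- unname(fc / sqrt(s0 * (1 / 5 + 1 / 5)))
  expect_equal(res$t_stat, expected_t, tolerance = 1e-12)
  expect_equal(res$p_value, unname(2 * pnorm(-abs(expected_t))),
               tolerance = 1e-12)
})

test_that("empirical-Bayes moderation agrees with limma on random data", {
  skip_if_not_installed("limma")
  set.seed(55)
  # strongly heteroscedastic genes -> finite prior df; near-common
  # variances -> infinite prior df. Both branches must match limma.
  sds <- list(finite_d0 = runif(500, 0.2, 3), inf_d0 = rep(1, 500))
  for (sd_g in sds) {
    x <- matrix(rnorm(500 * 8, 7, rep(sd_g, 8)), 500, 8,
                dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:8)))
    a <- paste0("s", 1:4); b <- paste0("s", 5:8)
    res <- contrast_test(x, contrast_spec("c", a, b), moderation = "eb")

    design <- cbind(1, rep(c(1, 0), each = 4))
    fit <- limma::eBayes(limma::lmFit(x, design))
    expect_equal(res$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
    expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-6)
    expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
  }
})

test_that("zero-variance genes are flagged and kept total", {
  x <- rbind(flat = rep(3, 6), ok = c(1, 2, 3, 4, 5, 6))
  colnames(x) <- paste0("s", 1:6)
  spec <- contrast_spec("c", paste0("s", 1:3), paste0("s", 4:6))
  expect_message(res <- contrast_test(x, spec, moderation = "ordinary"),
                 "zero-variance")
  expect_equal(res$t_stat[res$gene_id == "flat"], 0)
  expect_equal(res$p_value[res$gene_id == "flat"], 1)
})

test_that("contrast groups must be disjoint with >= 2 samples each", {
  expect_error(contrast_spec("c", "s1", c("s2", "s3")), ">= 2")
  expect_error(contrast_spec("c", c("s1", "s2"), c("s2", "s3")), "disjoint")
})

test_that("age contrasts enumerate within-study sham time-point pairs, oldest minus youngest", {
  md <- data.frame(
    sample_id = paste0("s", 1:6),
    study_id = "A",
    age_months = rep(c(3, 8, 10), each = 2),  # sham at 1, 6, 8 months exposure
    exposure_group = "sham",
    exposure_months = rep(c(1, 6, 8), each = 2))
  specs <- build_age_contrasts(md)
  expect_length(specs, 3)
  ids <- vapply(specs, `[[`, "", "contrast_id")
  expect_setequal_chr(ids, c("A_age_sham_6m_vs_1m", "A_age_sham_8m_vs_1m",
                             "A_age_sham_8m_vs_6m"))
  # orientation: group_a is the older group
  for (sp in specs) {
    ages_a <- md$age_months[match(sp$group_a, md$sample_id)]
    ages_b <- md$age_months[match(sp$group_b, md$sample_id)]
    expect_true(min(ages_a) > max(ages_b))
  }
})

test_that("the paper-like preset yields 28 age and 14 smoke-vs-sham contrasts", {
  ds <- scenario_paper_like(seed = 1)
  expect_length(build_age_contrasts(ds$metadata), 28)
  expect_length(build_exposure_contrasts(ds$metadata, "cs"), 14)
})

test_that("regulated-set rules apply both cutoffs, the >=1-contrast rule, and exclusions", {
  res <- data.frame(
    contrast_id = c("c1", "c1", "c1", "c2", "c2", "c2"),
    gene_id = rep(c("gPass", "gFcOnly", "gExcl"), 2),
    log2fc = c(0.70, 0.80, 0.90, 0.10, 0.75, 0.95),
    t_stat = 1, p_value = 0.01,
    fdr = c(0.01, 0.06, 0.01, 0.50, 0.06, 0.01))
  set <- identify_regulated(res, fc_cutoff = log2(1.5), fdr_cutoff = 0.05,
                            excluded_genes = "gExcl")
  expect_identical(set$gene_ids, "gPass")
  expect_identical(set$contributing$gPass, "c1")
  expect_error(identify_regulated(res, fc_cutoff = -1), "fc_cutoff")
  expect_error(identify_regulated(res, fdr_cutoff = 0), "fdr_cutoff")
})

test_that("near-noiseless simulation recovers exactly the planted gene sets", {
  ds <- generate_dataset(small_paper_config(seed = 17, noise_sd = 0.005))
  age_res <- run_contrasts(ds$matrix, build_age_contrasts(ds$metadata))
  exp_res <- run_contrasts(ds$matrix, build_exposure_contrasts(ds$metadata))
  aset <- identify_regulated(age_res)
  eset <- identify_regulated(exp_res)
  expect_setequal_chr(aset$gene_ids, ds$truth$age_gene_ids)
  expect_setequal_chr(eset$gene_ids, ds$truth$exposure_gene_ids)
})

test_that("planted effects of 1 log2 unit are detected with high sensitivity and controlled FPR", {
  sens <- fpr <- numeric(20)
  for (s in 1:20) {
    # slope 0.2/month over a 5-month span = 1.0 log2 unit between arms
    cfg <- fast_sim_config(seed = 100 + s, slope_range = c(0.2, 0.2),
                           overlap_slope_range = c(0.2, 0.2),
                           n_exposure_genes = 0, overlap_fraction = 0,
                           noise_sd = 0.25)
    ds <- generate_dataset(cfg)
    res <- run_contrasts(ds$matrix, build_age_contrasts(ds$metadata))
    set <- identify_regulated(res)
    planted <- ds$truth$age_gene_ids
    nulls <- setdiff(rownames(ds$matrix), planted)
    sens[s] <- mean(planted %in% set$gene_ids)
    fpr[s] <- mean(nulls %in% set$gene_ids)
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.05 + 0.02)
})
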
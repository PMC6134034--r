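test_that("a probe equal to a standardized trait correlates perfectly", {
  set.seed(101)
  age <- rnorm(20, 50, 10)
  probe <- (age - min(age)) / (max(age) - min(age))  # affine in age
  m <- rbind(cgX = probe)
  colnames(m) <- sprintf("s%02d", 1:20)
  s <- data.frame(sample_id = colnames(m), cohort = "c1", group = "mild",
                  age = age, stringsAsFactors = FALSE)
  res <- correlate_methylation_traits(m, s, "age")
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p, 1e-12)
})

test_that("correlation matches the textbook Pearson formula on 6 samples", {
  x <- c(0.12, 0.45, 0.33, 0.81, 0.64, 0.27)
  y <- c(3.1, 4.0, 2.8, 6.5, 5.2, 3.9)
  m <- rbind(cgH = x); colnames(m) <- sprintf("s%d", 1:6)
  s <- data.frame(sample_id = colnames(m), cohort = "c1", group = "mild",
                  tr = y, stringsAsFactors = FALSE)
  res <- correlate_methylation_traits(m, s, "tr")
  # hand computation of Pearson r
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_ref, tolerance = 1e-12)
  t_ref <- r_ref * sqrt(4 / (1 - r_ref^2))
  expect_equal(res$p, 2 * pt(-abs(t_ref), 4), tolerance = 1e-12)
})

test_that("null probes have calibrated p-values", {
  m <- make_beta(1000, 40, seed = 103)
  set.seed(104)
  s <- data.frame(sample_id = colnames(m), cohort = "c1", group = "mild",
                  tr = rnorm(40), stringsAsFactors = FALSE)
  res <- correlate_methylation_traits(m, s, "tr")
  frac <- mean(res$p < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / 1000)  # binomial 99% band
  expect_gt(frac, 0.05 - half)
  expect_lt(frac, 0.05 + half)
})

test_that("constant probes or traits are flagged undefined", {
  m <- make_beta(2, 10, seed = 105)
  m[1, ] <- 0.5
  s <- data.frame(sample_id = colnames(m), cohort = "c1", group = "mild",
                  tr = rnorm(10), flat = rep(1, 10), stringsAsFactors = FALSE)
  res <- correlate_methylation_traits(m, s, c("tr", "flat"))
  expect_true(res$undefined[res$probe_id == "cg00001" & res$trait == "tr"])
  expect_true(all(res$undefined[res$trait == "flat"]))
  expect_error(correlate_methylation_traits(m, s, "nope"), "nope")
})

test_that("correlation is invariant to joint sample reordering", {
  m <- make_beta(8, 16, seed = 106)
  set.seed(107)
  s <- data.frame(sample_id = colnames(m), cohort = "c1", group = "mild",
                  tr = rnorm(16), stringsAsFactors = FALSE)
  r1 <- correlate_methylation_traits(m, s, "tr")
  perm <- sample(16)
  r2 <- correlate_methylation_traits(m[, perm], s[perm, ], "tr")
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
})

test_that("expression anti-correlated with methylation is called negative", {
  set.seed(108)
  n <- 30
  meth <- matrix(runif(3 * n, 0.3, 0.7), 3, n,
                 dimnames = list(c("p1", "p2", "p3"), sprintf("s%02d", 1:n)))
  d <- data.frame(dmr_id = "D1", stringsAsFactors = FALSE)
  d$probe_ids <- list(c("p1", "p2", "p3"))
  expr <- rbind(G1 = -colMeans(meth) + rnorm(n, 0, 1e-6))
  colnames(expr) <- colnames(meth)
  res <- correlate_methylation_expression(meth, d, expr, list(D1 = "G1"))
  expect_equal(res$direction, "negative")
  expect_lt(res$r, -0.999)
})

test_that("unmapped genes get not_available status", {
  meth <- make_beta(2, 10, seed = 109)
  d <- data.frame(dmr_id = "D1", stringsAsFactors = FALSE)
  d$probe_ids <- list(rownames(meth))
  expr <- rbind(OTHER = rnorm(10)); colnames(expr) <- colnames(meth)
  res <- correlate_methylation_expression(meth, d, expr, list(D1 = "MISSING"))
  expect_equal(res$direction, "not_available")
  expect_true(is.na(res$r))
})

test_that("estimated expression correlation is near truth at n = 30", {
  # sampling-distribution check at r_true = -0.6
  hits <- 0
  for (seed in 1:20) {
    set.seed(200 + seed)
    n <- 30
    z <- rnorm(n)
    meth <- matrix(plogis(0.5 * scale(z) + rnorm(n, 0, 0.6)), 1, n,
                   dimnames = list("p1", sprintf("s%02d", 1:n)))
    lam <- -0.6
    e <- lam * scale(as.numeric(meth))[, 1] +
      sqrt(1 - lam^2) * rnorm(n)
    expr <- rbind(G1 = e); colnames(expr) <- colnames(meth)
    d <- data.frame(dmr_id = "D1", stringsAsFactors = FALSE)
    d$probe_ids <- list("p1")
    res <- correlate_methylation_expression(meth, d, expr, list(D1 = "G1"))
    if (abs(res$r - (-0.6)) <= 0.25) hits <- hits + 1
  }
  expect_gte(hits, 17)  # ~95% coverage allowing sampling slack
})

test_that("meta-analysis pools identical cohorts to the common r with Q = 0", {
  res <- meta_correlation(c(0.5, 0.5), c(30, 30))
  expect_equal(res$r_pooled, 0.5, tolerance = 1e-12)
  expect_equal(res$Q, 0, tolerance = 1e-12)
  res3 <- meta_correlation(rep(0.31, 4), rep(25, 4))
  expect_equal(res3$r_pooled, 0.31, tolerance = 1e-12)
  expect_equal(res3$Q, 0, tolerance = 1e-12)
})

test_that("meta-analysis matches the Fisher-z closed form", {
  res <- meta_correlation(c(0.3, 0.5), c(35, 33))
  z_ref <- (32 * atanh(0.3) + 30 * atanh(0.5)) / 62
  expect_equal(res$z_pooled, z_ref, tolerance = 1e-12)
  expect_equal(res$r_pooled, tanh(z_ref), tolerance = 1e-12)
  # pooled r lies within the per-cohort range under fixed effects
  expect_gte(res$r_pooled, 0.3)
  expect_lte(res$r_pooled, 0.5)
  # Q matches direct recomputation
  w <- c(32, 30); z <- atanh(c(0.3, 0.5))
  expect_equal(res$Q, sum(w * (z - z_ref)^2), tolerance = 1e-12)
})

test_that("single-cohort meta equals its input; invalid inputs error", {
  res <- meta_correlation(0.42, 28)
  expect_equal(res$r_pooled, 0.42, tolerance = 1e-12)
  expect_error(meta_correlation(c(1, 0.5), c(30, 30)), "Fisher")
  expect_error(meta_correlation(c(0.2, 0.5), c(3, 30)), "n >= 4")
})

test_that("clinical comparison: identical groups give p near 1", {
  set.seed(120)
  vals <- rnorm(10, 50, 5)
  s <- data.frame(sample_id = sprintf("s%02d", 1:20), cohort = "c1",
                  group = rep(c("mild", "advanced"), each = 10),
                  age = c(vals, vals), stringsAsFactors = FALSE)
  res <- compare_clinical_groups(s)
  expect_gt(res$p[res$trait == "age"], 0.99)
})

test_that("Fisher's exact on a fully separated 2x2 table", {
  s <- data.frame(sample_id = sprintf("s%02d", 1:20), cohort = "c1",
                  group = rep(c("mild", "advanced"), each = 10),
                  sex = rep(c("F", "M"), each = 10), stringsAsFactors = FALSE)
  res <- compare_clinical_groups(s, numeric_traits = character(0),
                                 categorical_traits = "sex")
  # hypergeometric enumeration: only the two extreme tables are as extreme
  p_ref <- 2 / choose(20, 10)
  expect_equal(res$p, p_ref, tolerance = 1e-12)
})

test_that("shifted traits are detected with expected power", {
  # mean shift of 1 sd at n = 30/30: power from the noncentral t is ~ 0.97
  set.seed(121)
  detected <- 0
  for (i in 1:20) {
    s <- data.frame(sample_id = sprintf("s%02d", 1:60), cohort = "c1",
                    group = rep(c("mild", "advanced"), each = 30),
                    glucose = c(rnorm(30, 100, 10), rnorm(30, 110, 10)),
                    stringsAsFactors = FALSE)
    res <- compare_clinical_groups(s)
    if (res$p[res$trait == "glucose"] < 0.05) detected <- detected + 1
  }
  ncp <- 1 / sqrt(1 / 30 + 1 / 30)
  power_ref <- 1 - pt(qt(0.975, 58), 58, ncp) + pt(-qt(0.975, 58), 58, ncp)
  expect_gte(detected / 20, power_ref - 0.2)
})

test_that("hyper DMRs on a fibrosis-linked factor correlate positively", {
  sim <- strong_sim(seed = 123, n_bg = 50)
  b <- sim$beta$cohort1
  s <- sim$samples[sim$samples$cohort == "cohort1", ]
  truth <- sim$truth$dmr_intervals
  res <- correlate_methylation_traits(b, s, "fibrosis_stage")
  # fibrosis rises with the advanced group; hyper DMRs gain methylation
  for (i in which(truth$direction == "hyper")) {
    rs <- res$r[res$probe_id %in% truth$probe_ids[[i]]]
    expect_true(all(rs > 0))
  }
  for (i in which(truth$direction == "hypo")) {
    rs <- res$r[res$probe_id %in% truth$probe_ids[[i]]]
    expect_true(all(rs < 0))
  }
})
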
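# random DMR partition of the nodes of a TOM matrix
random_partition <- function(ids, n_dmr, seed = 1) {
  set.seed(seed)
  grp <- sample(rep(seq_len(n_dmr), length.out = length(ids)))
  sets <- split(ids, grp)
  names(sets) <- sprintf("D%02d", seq_len(n_dmr))
  d <- data.frame(dmr_id = names(sets), stringsAsFactors = FALSE)
  d$probe_ids <- unname(sets)
  d
}

test_that("average TOM reduces to singleton and two-term means", {
  a <- random_adjacency(6, seed = 71)
  t_mat <- tom(a)
  d <- data.frame(dmr_id = c("A", "B"), stringsAsFactors = FALSE)
  d$probe_ids <- list("n01", "n02")
  avg <- average_tom_by_dmr(t_mat, d)
  expect_equal(avg["A", "B"], t_mat["n01", "n02"], tolerance = 1e-12)

  d2 <- data.frame(dmr_id = c("A", "B"), stringsAsFactors = FALSE)
  d2$probe_ids <- list(c("n01", "n02"), "n03")
  avg2 <- average_tom_by_dmr(t_mat, d2)
  expect_equal(avg2["A", "B"],
               mean(c(t_mat["n01", "n03"], t_mat["n02", "n03"])),
               tolerance = 1e-12)
  expect_true(is.na(avg2["A", "A"]))
})

test_that("average TOM equals the double-loop block-mean oracle", {
  for (seed in 1:4) {
    t_mat <- tom(random_adjacency(24, seed = seed))
    d <- random_partition(rownames(t_mat), 8, seed = seed)
    avg <- average_tom_by_dmr(t_mat, d)
    ref <- avg_tom_oracle(t_mat, setNames(d$probe_ids, d$dmr_id))
    expect_equal(avg, ref, tolerance = 1e-12)
  }
})

test_that("within-DMR TOM entries never contribute to the average", {
  t_mat <- tom(random_adjacency(20, seed = 75))
  d <- random_partition(rownames(t_mat), 5, seed = 75)
  avg1 <- average_tom_by_dmr(t_mat, d)
  # perturb every within-DMR entry: the DMR-level matrix must not move
  t2 <- t_mat
  for (i in seq_len(nrow(d))) {
    idx <- d$probe_ids[[i]]
    blk <- matrix(runif(length(idx)^2), length(idx))
    blk <- (blk + t(blk)) / 2
    t2[idx, idx] <- blk
  }
  avg2 <- average_tom_by_dmr(t2, d)
  expect_equal(avg1, avg2, tolerance = 1e-12)
})

test_that("average TOM rejects overlapping or missing probe sets", {
  t_mat <- tom(random_adjacency(6, seed = 76))
  d <- data.frame(dmr_id = c("A", "B"), stringsAsFactors = FALSE)
  d$probe_ids <- list(c("n01", "n02"), c("n02", "n03"))
  expect_error(average_tom_by_dmr(t_mat, d), "n02")
  d2 <- data.frame(dmr_id = c("A", "B"), stringsAsFactors = FALSE)
  d2$probe_ids <- list("n01", "zz")
  expect_error(average_tom_by_dmr(t_mat, d2), "zz")
})

test_that("average TOM commutes with relabeling and permutation", {
  t_mat <- tom(random_adjacency(18, seed = 77))
  d <- random_partition(rownames(t_mat), 6, seed = 77)
  avg <- average_tom_by_dmr(t_mat, d)
  perm <- sample(nrow(t_mat))
  avg_p <- average_tom_by_dmr(t_mat[perm, perm], d)
  expect_equal(avg, avg_p, tolerance = 1e-12)
  dperm <- sample(nrow(d))
  avg_d <- average_tom_by_dmr(t_mat, d[dperm, ])
  expect_equal(avg_d, avg[dperm, dperm], tolerance = 1e-12)
})

test_that("sub-threshold matrices give no networks, boundary pairs one", {
  ids <- c("A", "B", "C")
  avg <- matrix(0.05, 3, 3, dimnames = list(ids, ids)); diag(avg) <- NA
  g <- extract_networks(avg, cutoff = 0.15)
  expect_equal(length(g$networks), 0)
  expect_setequal(g$isolated, ids)

  avg["A", "B"] <- avg["B", "A"] <- 0.15   # cutoff is inclusive
  g2 <- extract_networks(avg, cutoff = 0.15)
  expect_equal(length(g2$networks), 1)
  expect_setequal(g2$networks[[1]], c("A", "B"))
  expect_equal(g2$nodes$degree[g2$nodes$dmr_id %in% c("A", "B")], c(1L, 1L))
})

test_that("planted two-block average TOM yields exactly the two blocks", {
  ids <- sprintf("D%02d", 1:20)
  blk <- rep(1:2, each = 10)
  avg <- matrix(0.05, 20, 20, dimnames = list(ids, ids))
  for (b in 1:2) avg[blk == b, blk == b] <- 0.3
  diag(avg) <- NA
  g <- extract_networks(avg, cutoff = 0.15)
  expect_equal(length(g$networks), 2)
  expect_setequal(g$networks$network1, ids[blk == 1])
  expect_setequal(g$networks$network2, ids[blk == 2])
})

test_that("raising the cutoff never grows the graph", {
  for (seed in 1:5) {
    set.seed(80 + seed)
    n <- 15
    ids <- sprintf("D%02d", 1:n)
    avg <- matrix(runif(n * n, 0, 0.4), n, n)
    avg <- (avg + t(avg)) / 2; diag(avg) <- NA
    dimnames(avg) <- list(ids, ids)
    cuts <- c(0.05, 0.1, 0.15, 0.2, 0.3)
    gs <- lapply(cuts, function(ct) extract_networks(avg, cutoff = ct))
    edges <- vapply(gs, function(g) nrow(g$edges), integer(1))
    maxcomp <- vapply(gs, function(g)
      if (length(g$networks)) max(vapply(g$networks, length, integer(1))) else 0L,
      integer(1))
    expect_true(all(diff(edges) <= 0))
    expect_true(all(diff(maxcomp) <= 0))
  }
})

test_that("node degrees equal independently recounted incident edges", {
  set.seed(86)
  n <- 12
  ids <- sprintf("D%02d", 1:n)
  avg <- matrix(runif(n * n, 0, 0.3), n, n)
  avg <- (avg + t(avg)) / 2; diag(avg) <- NA
  dimnames(avg) <- list(ids, ids)
  g <- extract_networks(avg, cutoff = 0.15)
  for (id in ids) {
    recount <- sum(g$edges$dmr_a == id) + sum(g$edges$dmr_b == id)
    expect_equal(g$nodes$degree[g$nodes$dmr_id == id], recount)
  }
})

test_that("identical graphs are fully shared across cohorts", {
  ids <- sprintf("D%02d", 1:10)
  avg <- matrix(0.3, 10, 10, dimnames = list(ids, ids)); diag(avg) <- NA
  g <- extract_networks(avg)
  cmp <- compare_networks(list(a = g, b = g))
  expect_true(all(cmp$node_presence$status == "present_in_all"))
  expect_setequal(cmp$common$network1, ids)
})

test_that("disjoint namespaces are refused", {
  ids1 <- sprintf("X%02d", 1:4); ids2 <- sprintf("Y%02d", 1:4)
  mk <- function(ids) {
    avg <- matrix(0.3, 4, 4, dimnames = list(ids, ids)); diag(avg) <- NA
    extract_networks(avg)
  }
  expect_error(compare_networks(list(a = mk(ids1), b = mk(ids2))),
               "disjoint")
})

test_that("a planted common core is recovered across three cohorts", {
  core <- sprintf("CORE%02d", 1:10)
  mk <- function(extra, seed) {
    ids <- c(core, extra)
    n <- length(ids)
    set.seed(seed)
    avg <- matrix(runif(n * n, 0, 0.05), n, n)
    avg <- (avg + t(avg)) / 2
    avg[seq_along(core), seq_along(core)] <- 0.3  # core is one dense block
    if (length(extra))   # cohort-specific satellite network
      avg[(length(core) + 1):n, (length(core) + 1):n] <- 0.25
    diag(avg) <- NA
    dimnames(avg) <- list(ids, ids)
    extract_networks(avg)
  }
  graphs <- list(c1 = mk(sprintf("A%d", 1:3), 91),
                 c2 = mk(sprintf("B%d", 1:4), 92),
                 c3 = mk(sprintf("C%d", 1:2), 93))
  cmp <- compare_networks(graphs)
  expect_setequal(cmp$common$network1, core)
  shared <- cmp$node_presence$dmr_id[cmp$node_presence$status == "present_in_all"]
  expect_setequal(shared, core)
})

test_that("control-absent nodes are labeled disease_only", {
  ids <- sprintf("D%02d", 1:8)
  mk <- function(strength) {
    avg <- matrix(strength, 8, 8, dimnames = list(ids, ids)); diag(avg) <- NA
    extract_networks(avg)
  }
  cmp <- compare_networks(list(c1 = mk(0.3), c2 = mk(0.3),
                               control = mk(0.05)))
  expect_true(all(cmp$node_presence$status == "disease_only"))
})

test_that("TOM percentiles follow linear interpolation", {
  ids <- c("a", "b", "c")
  t_mat <- matrix(0, 3, 3, dimnames = list(ids, ids))
  t_mat["a", "b"] <- t_mat["b", "a"] <- 0.1
  t_mat["a", "c"] <- t_mat["c", "a"] <- 0.2
  t_mat["b", "c"] <- t_mat["c", "b"] <- 0.3
  diag(t_mat) <- 1
  p <- tom_percentiles(t_mat, ids)
  expect_equal(unname(p), c(0.15, 0.2, 0.25), tolerance = 1e-12)

  # constant values: all percentiles equal the constant
  tc <- matrix(0.2, 4, 4,
               dimnames = list(sprintf("n%d", 1:4), sprintf("n%d", 1:4)))
  diag(tc) <- 1
  pc <- tom_percentiles(tc, rownames(tc))
  expect_equal(unname(pc), rep(0.2, 3), tolerance = 1e-12)
})

test_that("percentiles can exclude within-DMR pairs", {
  ids <- c("a", "b", "c", "d")
  t_mat <- matrix(0.5, 4, 4, dimnames = list(ids, ids))
  t_mat["a", "b"] <- t_mat["b", "a"] <- 0.99  # same-DMR pair
  diag(t_mat) <- 1
  dmr_map <- c(a = "D1", b = "D1", c = "D2", d = "D3")
  p <- tom_percentiles(t_mat, ids, dmr_map = dmr_map)
  expect_equal(unname(p), rep(0.5, 3), tolerance = 1e-12)
  expect_error(tom_percentiles(t_mat, "a"), "at least 2")
})
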
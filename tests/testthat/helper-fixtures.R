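# Fixture builders and independent oracles used across the suite.

# random beta matrix with dimnames
make_beta <- function(n_probes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples)
  dimnames(m) <- list(sprintf("cg%05d", seq_len(n_probes)),
                      sprintf("s%03d", seq_len(n_samples)))
  m
}

# minimal manifest for a set of probes, evenly spaced
make_manifest <- function(probe_ids, chrom = "chr1", start = 1000, gap = 200,
                          snp = rep(FALSE, length(probe_ids)),
                          xr = rep(FALSE, length(probe_ids))) {
  data.frame(probe_id = probe_ids, chrom = chrom,
             pos = start + gap * (seq_along(probe_ids) - 1L),
             gene = "", feature = "intergenic",
             is_snp_probe = snp, is_cross_reactive = xr,
             stringsAsFactors = FALSE)
}

# random valid adjacency matrix: symmetric, in [0,1], zero diagonal
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("n%02d", seq_len(n)), sprintf("n%02d", seq_len(n)))
  a
}

# independent TOM reference: plain triple loop over the defining formula
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  out <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
    denom <- min(k[i], k[j]) + 1 - a[i, j]
    out[i, j] <- if (denom == 0) 0 else (l + a[i, j]) / denom
  }
  out
}

# independent block-mean reference: double loop over cross-DMR probe pairs
avg_tom_oracle <- function(t_mat, probe_sets) {
  n <- length(probe_sets)
  out <- matrix(NA_real_, n, n,
                dimnames = list(names(probe_sets), names(probe_sets)))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    tot <- 0; cnt <- 0
    for (i in probe_sets[[a]]) for (j in probe_sets[[b]]) {
      tot <- tot + t_mat[i, j]; cnt <- cnt + 1
    }
    out[a, b] <- tot / cnt
  }
  out
}

# independent signed scale-free fit recomputation from a correlation power
sf_fit_oracle <- function(m, power, n_bins = 10) {
  r <- abs(stats::cor(t(m)))^power
  diag(r) <- 0
  k <- rowSums(r)
  if (all(k == 0) || length(unique(k)) == 1) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  idx <- findInterval(k, br, rightmost.closed = TRUE, all.inside = TRUE)
  dk <- tapply(k, idx, mean); fr <- tapply(k, idx, length) / length(k)
  ok <- dk > 0
  if (sum(ok) < 2 || stats::sd(log10(dk[ok])) == 0) return(NA_real_)
  fit <- stats::lm(log10(as.numeric(fr[ok])) ~ log10(as.numeric(dk[ok])))
  -sign(stats::coef(fit)[[2]]) * summary(fit)$r.squared
}

# beta data whose co-methylation network has scale-free-like topology:
# power-law module sizes with heterogeneous intramodular correlation
make_hub_beta <- function(n_probes = 300, n_samples = 60, seed = 1,
                          alpha = 2.5, smax = 30) {
  set.seed(seed)
  pr <- (1:smax)^(-alpha)
  sizes <- c()
  while (sum(sizes) < n_probes) sizes <- c(sizes, sample(1:smax, 1, prob = pr))
  mod <- rep(seq_along(sizes), sizes)[seq_len(n_probes)]
  rho <- runif(length(sizes), 0.6, 0.98)[mod]
  f <- matrix(rnorm(length(sizes) * n_samples), ncol = n_samples)
  x <- sqrt(rho) * f[mod, ] +
    sqrt(1 - rho) * matrix(rnorm(n_probes * n_samples), n_probes)
  b <- stats::plogis(x)
  dimnames(b) <- list(sprintf("p%04d", seq_len(n_probes)),
                      sprintf("s%03d", seq_len(n_samples)))
  b
}

# i.i.d. noise beta data at a small sample size
make_noise_beta <- function(n_probes = 50, n_samples = 10, seed = 1) {
  make_beta(n_probes, n_samples, seed = seed)
}

# adjusted Rand index (contingency-table closed form); independent of any
# package function
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_a <- b * cc / n2
  max_a <- (b + cc) / 2
  if (max_a == exp_a) return(1)
  (a - exp_a) / (max_a - exp_a)
}

# map called/consensus DMRs to planted networks by interval overlap
planted_network_of <- function(dmrs, truth) {
  vapply(seq_len(nrow(dmrs)), function(i) {
    ov <- truth$chrom == dmrs$chrom[i] &
      truth$start <= dmrs$end[i] & truth$end >= dmrs$start[i]
    if (any(ov)) truth$network[which(ov)[1]] else NA_integer_
  }, numeric(1))
}

# small standard simulation used by several suites
strong_sim <- function(seed = 7, n_bg = 200) {
  simulate_cohorts(simulation_config(
    seed = seed, probes_per_dmr = c(3L, 3L), n_probes_background = n_bg))
}
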
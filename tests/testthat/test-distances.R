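test_that("K2P closed form matches direct evaluation", {
  # 20 sites, 2 transitions, 1 transversion: P=0.10, Q=0.05
  p <- pair_with_subs(20, 2, 1)
  res <- k2p(p[1], p[2])
  expect_equal(res$comparable_sites, 20L)
  expect_equal(res$distance, -0.5 * log(0.75) - 0.25 * log(0.90),
               tolerance = 1e-12)
  expect_equal(round(res$distance, 4), 0.1702)
})

test_that("identical sequences are at distance zero; all-N is undefined", {
  s <- random_dna(100)
  expect_equal(k2p(s, s)$distance, 0)
  res <- k2p(s, strrep("N", 100))
  expect_true(is.na(res$distance))
  expect_equal(res$comparable_sites, 0L)
})

test_that("vectorised K2P equals the column-classifying brute-force oracle", {
  set.seed(101)
  alpha <- c("A", "C", "G", "T", "A", "C", "G", "T", "N", "-", "R", "Y")
  for (rep in 1:25) {
    a <- random_dna(100, alpha)
    b <- random_dna(100, alpha)
    got <- k2p(a, b)
    want <- k2p_brute(a, b)
    expect_identical(got$comparable_sites, want$comparable_sites)
    if (is.na(want$distance)) expect_true(is.na(got$distance))
    else expect_equal(got$distance, want$distance, tolerance = 1e-15)
  }
})

test_that("matrix K2P agrees with scalar K2P and with ape's estimator", {
  set.seed(5)
  ds <- simulate_clade_dataset(sim_scenario(seed = 77, per_clade_n = 4))
  x <- ds$alignment
  dm <- k2p_matrix(x)
  for (pair in list(c(1, 2), c(3, 15), c(7, 19))) {
    expect_equal(dm$d[pair[1], pair[2]],
                 k2p(x$seq[pair[1]], x$seq[pair[2]])$distance,
                 tolerance = 1e-12)
  }
  bin <- ape::as.DNAbin(strsplit(stats::setNames(tolower(x$seq), x$id), ""))
  da <- as.matrix(ape::dist.dna(bin, model = "K80",
                                pairwise.deletion = TRUE))
  expect_equal(unname(dm$d), unname(da[x$id, x$id]), tolerance = 1e-10)
})

test_that("saturation (log argument <= 0) gives an undefined distance", {
  # 10 sites, 6 transitions: 1 - 2P - Q = -0.2
  p <- pair_with_subs(10, 6, 0)
  expect_true(is.na(k2p(p[1], p[2])$distance))
  x <- barcode_aln(c(a = p[1], b = p[2], c = p[1]))
  dm <- k2p_matrix(x)
  # both a-b and c-b are saturated (a and c are identical)
  expect_equal(nrow(dm$undefined_pairs), 2L)
})

test_that("K2P reduces to p-distance when divergence is small and Q = 0", {
  for (nti in 1:3) {
    L <- 1000
    p <- pair_with_subs(L, nti, 0)
    P <- nti / L
    expect_equal(k2p(p[1], p[2])$distance, P, tolerance = 0.011)
  }
})

test_that("distance matrix is permutation-equivariant", {
  set.seed(12)
  seqs <- stats::setNames(replicate(6, random_dna(120)), paste0("s", 1:6))
  x <- barcode_aln(seqs)
  dm1 <- k2p_matrix(x)
  perm <- sample(6)
  dm2 <- k2p_matrix(x[perm])
  expect_equal(dm2$d[x$id, x$id], dm1$d[x$id, x$id], tolerance = 1e-15)
})

test_that("K2P recovers true K80 depths within 5% relative error", {
  set.seed(31)
  for (t in c(0.02, 0.05, 0.10)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", t / 2, t / 2))
    ests <- replicate(60, {
      a <- evolve_k80(tr, 10000, kappa = 4)
      k2p(a$seq[1], a$seq[2])$distance
    })
    expect_lt(abs(mean(ests) - t) / t, 0.05)
  }
})

test_that("histogram finds interior empty intervals and counts all pairs", {
  # construct distances: a block near 0.005, nothing in (0.01, 0.03), rest ~0.04
  ds <- simulate_clade_dataset(sim_scenario(seed = 5, n_clades = 2,
                                            per_clade_n = 8))
  dm <- k2p_matrix(ds$alignment)
  h <- dist_histogram(dm)
  expect_equal(sum(h$counts), choose(16, 2))
  expect_gte(nrow(h$empty_intervals), 1L)
  gap <- h$empty_intervals[1, ]
  gs <- group_summary(dm, ds$truth)
  expect_gte(gap$lo, max(gs$max_intra))
  expect_lte(gap$hi, min(gs$nn_distance))
})

test_that("a single pair yields one occupied bin and no empty intervals", {
  p <- pair_with_subs(400, 10, 10)  # d ~ 0.05
  dm <- k2p_matrix(barcode_aln(c(a = p[1], b = p[2])))
  h <- dist_histogram(dm, 0.01)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(nrow(h$empty_intervals), 0L)
})

test_that("group summary reports intra maxima and nearest neighbours", {
  x <- two_block_aln(n_per = 3, L = 400, sep_subs = 20)  # ~5% apart
  dm <- k2p_matrix(x)
  part <- stats::setNames(rep(c("A", "B"), each = 3), x$id)
  gs <- group_summary(dm, part)
  expect_equal(gs$max_intra, c(0, 0))
  expect_equal(gs$nn_group, c("B", "A"))
  expect_equal(gs$nn_distance[1], gs$nn_distance[2])
  expect_gt(gs$nn_distance[1], 0.04)
  # singleton group: intra is NA
  part2 <- stats::setNames(c("A", "A", "A", "B", "B", "C"), x$id)
  gs2 <- group_summary(dm, part2)
  expect_true(is.na(gs2$max_intra[gs2$group == "C"]))
})

test_that("simulated nearest-neighbour divergences track the backbone
           depths", {
  set.seed(1)
  bb <- default_backbone(5)
  cb <- ape::cophenetic.phylo(bb)
  nn_true <- apply(cb + diag(Inf, 5), 1, min)
  nn_idx <- apply(cb + diag(Inf, 5), 1, which.min)
  # the unbiased estimator of a backbone depth is the mean inter-clade
  # distance (every inter-clade pair has the same expectation by
  # construction); the minimum used for gap checks is biased low by the
  # Poisson realization of ~23 bridge substitutions at 658 bp
  rel_err <- replicate(20, {
    ds <- simulate_clade_dataset(sim_scenario(seed = sample.int(1e6, 1)))
    dm <- k2p_matrix(ds$alignment)
    cl <- ds$truth$assignment[dm$labels]
    gs <- group_summary(dm, ds$truth)
    # realized nearest-neighbour distances always clear the intra maxima
    expect_gt(min(gs$nn_distance), max(gs$max_intra, na.rm = TRUE))
    vapply(1:5, function(i) {
      mean(dm$d[cl == paste0("c", i), cl == paste0("c", nn_idx[i])]) /
        nn_true[i] - 1
    }, numeric(1))
  })
  expect_lt(max(abs(rowMeans(rel_err))), 0.10)
})
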
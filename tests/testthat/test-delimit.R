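test_that("single linkage separates blocks and chains intermediates", {
  x <- two_block_aln(n_per = 3, L = 400, sep_subs = 20)  # inter ~5%
  dm <- k2p_matrix(x)
  p <- single_linkage(dm, 0.022)
  expect_equal(n_otus(p), 2L)
  # chaining: a-b 2.0%, b-c 2.0%, a-c 4.0% -> one OTU at 2.2%
  d <- matrix(c(0, 0.020, 0.040,
                0.020, 0, 0.020,
                0.040, 0.020, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  dm2 <- structure(list(labels = c("a", "b", "c"), d = d,
                        sites = matrix(100, 3, 3),
                        undefined_pairs = matrix(character(0), 0, 2)),
                   class = "k2p_dist")
  expect_equal(n_otus(single_linkage(dm2, 0.022)), 1L)
  # strict inequality: a pair exactly at the threshold is not linked
  expect_equal(n_otus(single_linkage(dm2, 0.020)), 3L)
  # threshold zero: everything is a singleton
  expect_equal(n_otus(single_linkage(dm, 0)), length(x$seq))
})

test_that("single-linkage OTU count is non-increasing in the threshold", {
  ds <- simulate_clade_dataset(sim_scenario(seed = 21))
  dm <- k2p_matrix(ds$alignment)
  counts <- vapply(c(0.001, 0.005, 0.01, 0.022, 0.05, 0.12),
                   function(th) n_otus(single_linkage(dm, th)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("MCL refinement never merges across coarse components", {
  ds <- simulate_clade_dataset(sim_scenario(seed = 33))
  dm <- k2p_matrix(ds$alignment)
  coarse <- single_linkage(dm)
  cands <- mcl_refine(dm, coarse)
  co <- coarse$assignment
  for (cand in cands) {
    asg <- cand$assignment[names(co)]
    # each refined OTU maps into exactly one coarse OTU
    expect_true(all(tapply(co, asg, function(v) length(unique(v))) == 1L))
  }
})

test_that("MCL never splits a component of identical sequences", {
  s <- random_dna(200)
  x <- barcode_aln(stats::setNames(rep(s, 6), paste0("s", 1:6)))
  dm <- k2p_matrix(x)
  cands <- mcl_refine(dm, single_linkage(dm))
  for (cand in cands) expect_equal(n_otus(cand), 1L)
})

test_that("MCL splits two tight subclusters bridged by one intermediate", {
  # two 4-member blocks at ~4% with a single bridge sequence ~2% from each
  # (slightly nearer to block a, as an exact midpoint is a symmetric flow
  # tie that no deterministic clustering can break)
  set.seed(8)
  L <- 600
  a <- strsplit(random_dna(L), "")[[1]]
  b <- a; comp <- c(A = "G", C = "T", G = "A", T = "C")
  flip <- sample(L, 23); b[flip] <- comp[b[flip]]          # ~4% apart
  bridge <- a; bridge[flip[1:11]] <- comp[a[flip[1:11]]]   # 1.9% / 2.0%
  seqs <- c(stats::setNames(rep(paste(a, collapse = ""), 4), paste0("a", 1:4)),
            stats::setNames(rep(paste(b, collapse = ""), 4), paste0("b", 1:4)),
            bridge = paste(bridge, collapse = ""))
  dm <- k2p_matrix(barcode_aln(seqs))
  coarse <- single_linkage(dm, 0.022)
  expect_equal(n_otus(coarse), 1L)  # chained through the bridge
  cands <- mcl_refine(dm, coarse)
  expect_true(any(vapply(cands, n_otus, integer(1)) >= 2L))
  # and the full RESL pipeline resolves the two blocks
  res <- resl(dm)
  asg <- res$assignment
  expect_true(all(asg[paste0("a", 1:4)] == asg[["a1"]]))
  expect_true(all(asg[paste0("b", 1:4)] == asg[["b1"]]))
  expect_false(asg[["a1"]] == asg[["b1"]])
  expect_equal(asg[["bridge"]], asg[["a1"]])  # joins the nearer block
})

test_that("mean silhouette matches the cluster-package convention", {
  skip_if_not_installed("cluster")
  ds <- simulate_clade_dataset(sim_scenario(seed = 13, n_clades = 3,
                                            per_clade_n = 6))
  dm <- k2p_matrix(ds$alignment)
  asg <- ds$truth$assignment[dm$labels]
  got <- cladedelim:::mean_silhouette(asg, dm$d)
  sil <- cluster::silhouette(as.integer(factor(asg)),
                             dmatrix = dm$d)
  expect_equal(got, mean(sil[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette selection prefers the better-separated scheme", {
  x <- two_block_aln(n_per = 2, L = 500, sep_subs = 40)
  dm <- k2p_matrix(x)
  one <- partition(stats::setNames(rep("O1", 4), x$id), "one")
  two <- partition(stats::setNames(rep(c("O1", "O2"), each = 2), x$id), "two")
  sel <- silhouette_select(list(one, two), dm)
  expect_equal(n_otus(sel), 2L)
  # single candidate: identity
  expect_identical(silhouette_select(list(one), dm)$assignment,
                   one$assignment)
  # degenerate all-zero distances: first returned
  s <- random_dna(100)
  xz <- barcode_aln(stats::setNames(rep(s, 4), paste0("z", 1:4)))
  dmz <- k2p_matrix(xz)
  selz <- silhouette_select(list(one <- partition(
    stats::setNames(rep("O1", 4), xz$id), "first"), partition(
      stats::setNames(c("O1", "O1", "O2", "O2"), xz$id), "second")), dmz)
  expect_equal(selz$method, "first")
})

test_that("RESL recovers constructed blocks exactly when the gap brackets
           the linkage threshold", {
  set.seed(17)
  x <- two_block_aln(n_per = 5, L = 500, sep_subs = 30)  # inter ~6%
  dm <- k2p_matrix(x)
  res <- resl(dm)
  expect_equal(n_otus(res), 2L)
  truth <- stats::setNames(rep(c("A", "B"), each = 5), x$id)
  expect_equal(adjusted_rand_index(res, truth), 1)
})

test_that("ABGD finds no gap in uniform single-cluster data", {
  set.seed(3)
  g <- simulate_coalescent(12, 0.004)
  x <- evolve_k80(g, 658, 4)
  dm <- k2p_matrix(x)
  res <- abgd_partition(dm, abgd_config(P = c(0.005, 0.0129, 0.05)))
  expect_true(all(res$recursive_otus[res$P >= 0.0129] == 1L))
})

test_that("ABGD initial partitions are never finer than recursive ones", {
  for (seed in c(4, 9)) {
    ds <- simulate_clade_dataset(sim_scenario(seed = seed))
    dm <- k2p_matrix(ds$alignment)
    res <- abgd_partition(dm)
    expect_true(all(res$initial_otus <= res$recursive_otus))
    parts <- attr(res, "partitions")
    # recursive refines initial at each prior
    for (p in parts) {
      ini <- p$initial$assignment
      rec <- p$recursive$assignment[names(ini)]
      expect_true(all(tapply(ini, rec, function(v) length(unique(v))) == 1L))
    }
  }
})

test_that("JC and K2P metrics give the same ABGD partition counts on
           gapped data", {
  ds <- simulate_clade_dataset(sim_scenario(seed = 19))
  k <- abgd_partition(k2p_matrix(ds$alignment))
  j <- abgd_partition(jc_matrix(ds$alignment))
  # at micro-gap priors (< 0.0028) fourth-decimal metric differences can
  # flip individual within-clade gap calls; the barcode-gap regime agrees
  keep <- k$P >= 0.0028
  expect_equal(k$recursive_otus[keep], j$recursive_otus[keep])
})

test_that("adjusted Rand index matches closed form and mclust", {
  ids <- paste0("s", 1:10)
  all_single <- partition(stats::setNames(paste0("o", 1:10), ids), "a")
  all_one <- partition(stats::setNames(rep("o", 10), ids), "b")
  expect_equal(adjusted_rand_index(all_single, all_one), 0)
  expect_equal(adjusted_rand_index(all_one, all_one), 1)
  skip_if_not_installed("mclust")
  set.seed(2)
  for (i in 1:10) {
    p1 <- stats::setNames(sample(letters[1:3], 12, TRUE), paste0("s", 1:12))
    p2 <- stats::setNames(sample(letters[1:4], 12, TRUE), paste0("s", 1:12))
    expect_equal(adjusted_rand_index(p1, p2),
                 mclust::adjustedRandIndex(p1[paste0("s", 1:12)],
                                           p2[paste0("s", 1:12)]),
                 tolerance = 1e-12)
  }
})

test_that("concordance table reports counts and pairwise agreement", {
  ds <- simulate_clade_dataset(sim_scenario(seed = 23))
  dm <- k2p_matrix(ds$alignment)
  pr <- resl(dm)
  ct <- concordance_table(list(resl = pr, truth = ds$truth))
  expect_equal(ct$table$n_otus[ct$table$method == "truth"], 5L)
  expect_true(all(ct$ari >= -1 & ct$ari <= 1))
  expect_equal(diag(ct$ari), c(resl = 1, truth = 1))
  bad <- partition(stats::setNames("x", "other_id"), "bad")
  expect_error(concordance_table(list(a = pr, b = bad)), "different ids")
})
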
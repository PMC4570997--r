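test_that("haplotype collapsing removes gapped columns then merges", {
  s <- c(a = "AAC-T", b = "AACGT", c = "ATCGT", d = "AACNT")
  # columns 4 (gap) and 5 (N-free? no: col4 gap, col4/5: N in d at col4) ->
  # complete deletion keeps columns 1,2,3,5
  ht <- collapse_haplotypes(barcode_aln(s))
  expect_equal(ht$n_sites, 4L)
  expect_equal(length(ht$haplotypes), 2L)
  expect_equal(sum(ht$counts), 4L)
  expect_equal(unname(ht$membership["a"]), unname(ht$membership["b"]))
  # n identical sequences give one haplotype
  x <- barcode_aln(stats::setNames(rep(random_dna(50), 5), paste0("s", 1:5)))
  expect_equal(length(collapse_haplotypes(x)$haplotypes), 1L)
})

test_that("haplotype counts are tracked per country", {
  s <- stats::setNames(c(rep("AAAA", 3), "AAAT"), paste0("s", 1:4))
  meta <- data.frame(id = paste0("s", 1:4),
                     country = c("Pakistan", "Pakistan", "Egypt", "Egypt"))
  x <- barcode_aln(s, meta = meta)
  ht <- collapse_haplotypes(x)
  expect_equal(unname(ht$group_counts["H1", "Pakistan"]), 2L)
  expect_equal(unname(ht$group_counts["H1", "Egypt"]), 1L)
  expect_equal(unname(ht$group_counts["H2", "Egypt"]), 1L)
})

test_that("haplotype diversity follows the small-sample formula", {
  # multiplicities {2,1,1}: Hd = (4/3)(1 - 0.375) = 0.8333
  x <- barcode_aln(c(a = "AAAA", b = "AAAA", c = "AAAT", d = "AATT"))
  d <- diversity(x)
  expect_equal(d$Hd, (4 / 3) * (1 - (0.5^2 + 0.25^2 + 0.25^2)),
               tolerance = 1e-12)
  expect_equal(d$Hd, 0.8333, tolerance = 1e-4)
  expect_equal(d$h, 3L)
  expect_equal(d$S, 2L)
})

test_that("mean pairwise differences k equals the brute-force mean", {
  set.seed(61)
  for (rep in 1:6) {
    n <- sample(5:30, 1)
    g <- simulate_coalescent(n, 0.01)
    x <- evolve_k80(g, 300, 4)
    m <- aln_matrix(x)
    expect_equal(diversity(x)$k, k_brute(m), tolerance = 1e-12)
  }
})

test_that("Hd is 0 iff one haplotype, and approaches 1 when all unique", {
  mono <- barcode_aln(stats::setNames(rep("ACGTAC", 6), paste0("m", 1:6)))
  expect_equal(diversity(mono)$Hd, 0)
  set.seed(2)
  uniq <- barcode_aln(stats::setNames(
    vapply(1:8, function(i) random_dna(80), character(1)), paste0("u", 1:8)))
  expect_equal(diversity(uniq)$Hd, 1, tolerance = 1e-12)
})

test_that("monomorphic data yield S = 0, k = 0 and NA neutrality tests", {
  x <- barcode_aln(stats::setNames(rep("ACGTACGT", 5), paste0("s", 1:5)))
  d <- diversity(x)
  expect_equal(d$S, 0L)
  expect_equal(d$k, 0)
  expect_true(is.na(d$tajima_D))
  expect_true(is.na(d$fu_li_Dstar))
})

test_that("Tajima's D agrees with independent recomputation of the
           constants", {
  set.seed(71)
  for (rep in 1:5) {
    g <- simulate_coalescent(12, 0.01)
    x <- evolve_k80(g, 500, 4)
    d <- diversity(x)
    if (d$S == 0) next
    expect_equal(d$tajima_D, tajima_brute(d$n, d$S, d$k), tolerance = 1e-12)
  }
})

test_that("Tajima's D is centred near zero under neutrality", {
  set.seed(81)
  vals <- replicate(200, {
    g <- simulate_coalescent(20, 0.005)
    x <- evolve_k80(g, 1000, 4)
    diversity(x)$tajima_D
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.15)
})

test_that("Fu & Li's D uses outgroup polarisation of singletons", {
  # ingroup: one derived singleton (s3 carries T at site 2, outgroup has A)
  x <- barcode_aln(c(s1 = "AAAA", s2 = "AAAA", s3 = "ATAA", s4 = "AAAA",
                     s5 = "AAGA"))
  d_with <- diversity(x, outgroup = "AAAA")
  expect_false(is.na(d_with$fu_li_D))
  d_without <- diversity(x)
  expect_true(is.na(d_without$fu_li_D))
  expect_false(is.na(d_without$fu_li_Dstar))
  # eta = 2, both singletons derived relative to the outgroup:
  # D = (eta - a1 * eta_e) / sqrt(uD eta + vD eta^2), recomputed here
  n <- 5; a1 <- sum(1 / 1:4); a2 <- sum(1 / (1:4)^2)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  expect_equal(d_with$fu_li_D, (2 - a1 * 2) / sqrt(uD * 2 + vD * 4),
               tolerance = 1e-12)
})

test_that("Fu & Li's D* is near zero under neutrality", {
  set.seed(91)
  vals <- replicate(150, {
    g <- simulate_coalescent(15, 0.005)
    x <- evolve_k80(g, 1000, 4)
    diversity(x)$fu_li_Dstar
  })
  expect_lt(abs(mean(vals, na.rm = TRUE)), 0.2)
})

test_that("minimum spanning network contains an MST and is connected", {
  set.seed(41)
  ds <- simulate_clade_dataset(sim_scenario(seed = 14, n_clades = 2,
                                            per_clade_n = 10))
  ht <- collapse_haplotypes(ds$alignment)
  net <- msn(ht)
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  # total MST weight matches igraph's MST on the complete haplotype graph
  nh <- length(ht$haplotypes)
  m <- do.call(rbind, strsplit(unname(ht$haplotypes), ""))
  w <- as.matrix(stats::dist(apply(m, 2, function(c) as.integer(factor(c))),
                             method = "manhattan"))
  w <- matrix(0L, nh, nh)
  for (i in seq_len(nh - 1)) for (j in (i + 1):nh)
    w[i, j] <- w[j, i] <- sum(m[i, ] != m[j, ])
  full <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
  mst <- igraph::mst(full)
  expect_equal(sum(igraph::E(igraph::mst(g))$weight),
               sum(igraph::E(mst)$weight))
})

test_that("simple networks come out as expected", {
  # two haplotypes, 3 steps apart
  x <- barcode_aln(c(a = "AAATTT", b = "AAATTT", c = "TTTTTT"))
  net <- msn(collapse_haplotypes(x))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 3L)
  # three pairwise-equidistant haplotypes form a triangle (all MST ties)
  y <- barcode_aln(c(a = "AAT", b = "ATA", c = "TAA"))
  net2 <- msn(collapse_haplotypes(y))
  expect_equal(nrow(net2$edges), 3L)
  expect_true(all(net2$edges$steps == 2L))
  # star: dominant haplotype with singletons one step away
  z <- barcode_aln(c(h0a = "AAAAAA", h0b = "AAAAAA", h0c = "AAAAAA",
                     h1 = "TAAAAA", h2 = "ATAAAA", h3 = "AATAAA"))
  net3 <- msn(collapse_haplotypes(z))
  expect_equal(nrow(net3$edges), 3L)
  expect_true(all(net3$edges$h1 == "H1"))
})

test_that("epsilon relaxation adds near-minimal alternative edges", {
  # square: h1-h2 1, h2-h3 1, h3-h4 1, h4-h1 1, diagonals 2
  x <- barcode_aln(c(a = "AAAA", b = "TAAA", c = "TTAA", d = "ATAA"))
  ht <- collapse_haplotypes(x)
  e0 <- msn(ht, epsilon = 0)$edges
  e1 <- msn(ht, epsilon = 1)$edges
  expect_gte(nrow(e1), nrow(e0))
  expect_true(all(e0$steps == 1L))
})
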
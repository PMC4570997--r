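# shared fixtures and independent oracles used across the suite

make_aln <- function(seqs, ...) barcode_aln(seqs, ...)

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# brute-force K2P oracle: classify every column as identical / transition /
# transversion / excluded, then apply the closed form. Independent of the
# package's vectorised path.
k2p_brute <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  bases <- c("A", "C", "G", "T")
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(va)) {
    if (!(va[i] %in% bases) || !(vb[i] %in% bases)) next
    n <- n + 1L
    if (va[i] == vb[i]) next
    is_ts <- any(vapply(ts_pairs, function(p)
      va[i] == p[1] && vb[i] == p[2], logical(1)))
    if (is_ts) ts <- ts + 1L else tv <- tv + 1L
  }
  if (n == 0L) return(list(distance = NA_real_, comparable_sites = 0L))
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  list(distance = d, comparable_sites = n, P = P, Q = Q)
}

# mean pairwise difference oracle: explicit double loop
k_brute <- function(mat) {
  n <- nrow(mat)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mat[i, ] != mat[j, ])
    np <- np + 1
  }
  tot / np
}

# Tajima's D recomputed from first principles (independent arithmetic)
tajima_brute <- function(n, S, k) {
  a1 <- sum(1 / 1:(n - 1)); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# construct a pair of sequences with exactly nti transitions and ntv
# transversions over length L (rest identical)
pair_with_subs <- function(L, nti, ntv) {
  a <- rep("A", L)
  b <- a
  if (nti > 0) b[seq_len(nti)] <- "G"                    # A->G transitions
  if (ntv > 0) b[nti + seq_len(ntv)] <- "T"              # A->T transversions
  c(paste(a, collapse = ""), paste(b, collapse = ""))
}

# K2P closed form from substitution counts
k2p_closed <- function(L, nti, ntv) {
  P <- nti / L; Q <- ntv / L
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# search integer substitution counts approximating a target K2P distance
subs_for_distance <- function(L, target) {
  best <- c(0L, 0L); err <- Inf
  max_n <- floor(L * 0.45)
  for (nti in 0:max_n) {
    # solve roughly for ntv then refine locally
    for (ntv in 0:(max_n - nti)) {
      P <- nti / L; Q <- ntv / L
      if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) break
      d <- k2p_closed(L, nti, ntv)
      if (abs(d - target) < err) { err <- abs(d - target); best <- c(nti, ntv) }
      if (d > target + 0.05) break
    }
  }
  list(nti = best[1], ntv = best[2], err = err)
}

# two clearly separated blocks of sequences; intra identical, inter at
# roughly `sep` K2P
two_block_aln <- function(n_per = 3, L = 300, sep_subs = 30) {
  a <- random_dna(L)
  va <- strsplit(a, "")[[1]]
  vb <- va
  flip <- sample(seq_len(L), sep_subs)
  comp <- c(A = "G", C = "T", G = "A", T = "C")
  vb[flip] <- comp[vb[flip]]
  seqs <- c(stats::setNames(rep(a, n_per), paste0("a", seq_len(n_per))),
            stats::setNames(rep(paste(vb, collapse = ""), n_per),
                            paste0("b", seq_len(n_per))))
  barcode_aln(seqs)
}
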
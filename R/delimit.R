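#' Partition of sequences into OTUs
#'
#' @param assignment named character vector mapping sequence id -> OTU label
#' @param method name of the producing method
#' @param params list of parameters used
#' @return object of class `partition`
#' @export
partition <- function(assignment, method = "manual", params = list()) {
  if (is.null(names(assignment)) || anyNA(names(assignment)))
    stop("assignment must be a named vector")
  if (any(is.na(assignment) | assignment == ""))
    stop("every id must be assigned a non-empty OTU label")
  structure(list(assignment = assignment, method = method, params = params),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("partition (", x$method, "): ", length(x$assignment), " sequences in ",
      n_otus(x), " OTUs\n", sep = "")
  invisible(x)
}

as_assignment <- function(p) {
  if (inherits(p, "partition")) p$assignment else p
}

#' Number of OTUs in a partition
#' @param p a `partition`
#' @export
n_otus <- function(p) length(unique(as_assignment(p)))

# deterministic labels: OTUs ordered by their smallest member id
relabel_otus <- function(groups, ids) {
  first <- vapply(split(ids, groups), min, character(1))
  ord <- rank(first, ties.method = "first")
  lab <- sprintf("OTU_%02d", ord)
  names(lab) <- names(first)
  out <- lab[as.character(groups)]
  names(out) <- ids
  out
}

# connected components of the graph linking pairs with d < threshold
components_below <- function(d, labels, threshold) {
  n <- length(labels)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  idx <- which(!is.na(d) & d < threshold & upper.tri(d), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- find(idx[r, 1]); b <- find(idx[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Single-linkage clustering at a fixed distance threshold
#'
#' OTUs are the connected components of the graph linking every pair with
#' distance strictly below `threshold` (a pair exactly at the threshold is
#' not linked). Undefined distances are non-links. The default 2.2%
#' threshold is the standard barcode single-linkage cut-off.
#'
#' @param dm a `k2p_dist`
#' @param threshold linking threshold as a distance fraction (default 0.022)
#' @return a `partition`
#' @export
single_linkage <- function(dm, threshold = 0.022) {
  comp <- components_below(dm$d, dm$labels, threshold)
  partition(relabel_otus(comp, dm$labels), method = "single_linkage",
            params = list(threshold = threshold))
}

#' Refined single linkage configuration
#'
#' @param linkage_threshold single-linkage cut-off (fraction, default 0.022)
#' @param inflation_values Markov-clustering inflation exponents
#' @param similarity_scale distance at which similarity reaches 0 (default
#'   0.03, just above the linkage threshold, so cross-cluster flow through
#'   chaining bridges stays weak enough for Markov clustering to dissolve)
#' @param max_mcl_iterations iteration cap per MCL run
#' @param tolerance convergence tolerance on the flow matrix
#' @return list of class `resl_config`
#' @export
resl_config <- function(linkage_threshold = 0.022,
                        inflation_values = c(1.4, 2.0, 2.8, 4.0),
                        similarity_scale = 0.03,
                        max_mcl_iterations = 100L,
                        tolerance = 1e-8) {
  stopifnot(linkage_threshold > 0, linkage_threshold < 1,
            all(inflation_values > 1), similarity_scale > 0)
  structure(list(linkage_threshold = linkage_threshold,
                 inflation_values = inflation_values,
                 similarity_scale = similarity_scale,
                 max_mcl_iterations = as.integer(max_mcl_iterations),
                 tolerance = tolerance),
            class = "resl_config")
}

# Markov clustering on a similarity matrix; returns integer cluster vector
mcl_cluster <- function(s, inflation, max_iter, tol) {
  n <- nrow(s)
  if (n == 1L) return(1L)
  diag(s) <- apply(s, 2, max)               # self-loops at column max
  cs <- colSums(s)
  cs[cs == 0] <- 1
  m <- sweep(s, 2, cs, "/")
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                           # expansion
    m2 <- m2^inflation                      # inflation
    m2 <- sweep(m2, 2, pmax(colSums(m2), .Machine$double.xmin), "/")
    m2[m2 < 1e-12] <- 0
    if (max(abs(m2 - m)) < tol) { m <- m2; break }
    m <- m2
    if (it == max_iter) return(NULL)        # non-convergence
  }
  # clusters = connected components of the limit flow's support
  supp <- (m + t(m)) > 1e-9
  comp <- components_below(ifelse(supp, 0, 1), seq_len(n), 0.5)
  comp
}

#' Markov-clustering refinement of a coarse partition
#'
#' Within each coarse OTU, distances are mapped to similarities
#' `s = max(0, 1 - d / similarity_scale)` and Markov clustering (expansion
#' by matrix squaring, inflation by entrywise power with column
#' renormalisation, iterated to flow convergence) is run once per inflation
#' value. Every candidate refines the coarse partition (clusters never span
#' coarse components); the unrefined coarse partition is included as the
#' first candidate.
#'
#' @param dm a `k2p_dist`
#' @param coarse a `partition` (typically from [single_linkage()])
#' @param config a [resl_config()]
#' @return list of candidate `partition`s
#' @export
mcl_refine <- function(dm, coarse, config = resl_config()) {
  asg <- as_assignment(coarse)[dm$labels]
  candidates <- list(partition(asg, method = "resl_coarse",
                               params = list(threshold = config$linkage_threshold)))
  for (r in config$inflation_values) {
    new_asg <- asg
    failed <- FALSE
    for (g in unique(asg)) {
      ids <- dm$labels[asg == g]
      if (length(ids) < 2L) next
      d <- dm$d[ids, ids]
      d[is.na(d)] <- max(d, na.rm = TRUE) + config$similarity_scale
      s <- d
      s[] <- pmax(0, 1 - d / config$similarity_scale)
      cl <- mcl_cluster(s, r, config$max_mcl_iterations, config$tolerance)
      if (is.null(cl)) { failed <- TRUE; break }
      new_asg[ids] <- paste0(g, ".", cl)
    }
    if (failed) {
      warning("MCL did not converge at inflation ", r, "; candidate dropped")
      next
    }
    candidates[[length(candidates) + 1L]] <-
      partition(relabel_otus(new_asg, names(new_asg)),
                method = sprintf("resl_mcl_I%.1f", r),
                params = list(inflation = r))
  }
  candidates
}

# mean silhouette width of a partition on a distance matrix; singletons
# (and the all-in-one partition) score 0
mean_silhouette <- function(asg, d) {
  labs <- rownames(d)
  g <- asg[labs]
  groups <- unique(g)
  if (length(groups) < 2L) return(0)
  d0 <- d; d0[is.na(d0)] <- max(d0, na.rm = TRUE)
  s <- numeric(length(labs))
  for (i in seq_along(labs)) {
    own <- g == g[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(d0[i, own & seq_along(labs) != i])
    b <- min(vapply(groups[groups != g[i]], function(h)
      mean(d0[i, g == h]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the candidate partition with the highest mean silhouette
#'
#' Silhouette width `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the
#' mean intra-OTU distance and `b` the minimum mean distance to another
#' OTU; singleton OTUs score 0. Ties keep the earliest candidate.
#'
#' @param candidates list of `partition`s
#' @param dm a `k2p_dist`
#' @return the selected `partition`, with attribute `silhouette`
#' @export
silhouette_select <- function(candidates, dm) {
  stopifnot(length(candidates) >= 1L)
  scores <- vapply(candidates, function(p)
    mean_silhouette(as_assignment(p), dm$d), numeric(1))
  best <- which.max(scores)  # first of ties
  out <- candidates[[best]]
  attr(out, "silhouette") <- scores[best]
  out
}

#' Refined single linkage (RESL-style) OTU delimitation
#'
#' Three phases: single-linkage clustering at a fixed threshold, Markov
#' clustering refinement within each cluster across a grid of inflation
#' values, and silhouette-based selection among the candidate schemes.
#'
#' @param dm a `k2p_dist`
#' @param config a [resl_config()]
#' @return a `partition` (method `"resl"`)
#' @export
resl <- function(dm, config = resl_config()) {
  coarse <- single_linkage(dm, config$linkage_threshold)
  cands <- mcl_refine(dm, coarse, config)
  out <- silhouette_select(cands, dm)
  out$method <- "resl"
  out$params <- config
  out
}

#' ABGD-style configuration
#'
#' @param Pmin,Pmax bounds of the prior intraspecific divergence sweep
#' @param X relative barcode-gap width (default 1.5)
#' @param metric `"K2P"` or `"JC"` (used by [abgd_partition()] when it
#'   computes distances from an alignment; a supplied `k2p_dist` is used
#'   as-is)
#' @param P optional explicit grid of priors; the default is the standard
#'   log-spaced grid `{0.0017, 0.0028, 0.0077, 0.0129, 0.0215, 0.0359}`
#'   clipped to `[Pmin, Pmax]` with the endpoints added
#' @param report_P the representative prior whose recursive partition is
#'   reported as "the" barcode-gap answer (default 0.0129, a mid-grid
#'   prior at which barcode and cytb sweeps typically stabilise); it is
#'   added to the sweep if absent
#' @return list of class `abgd_config`
#' @export
abgd_config <- function(Pmin = 0.001, Pmax = 0.1, X = 1.5,
                        metric = c("K2P", "JC"), P = NULL,
                        report_P = 0.0129) {
  metric <- match.arg(metric)
  stopifnot(Pmin > 0, Pmin < Pmax, Pmax < 1, X > 0)
  if (is.null(P)) {
    grid <- c(0.0017, 0.0028, 0.0077, 0.0129, 0.0215, 0.0359)
    P <- sort(unique(c(Pmin, grid[grid > Pmin & grid < Pmax], Pmax)))
  }
  P <- sort(unique(c(P, report_P)))
  structure(list(Pmin = Pmin, Pmax = Pmax, X = X, metric = metric, P = P,
                 report_P = report_P),
            class = "abgd_config")
}

# find the barcode-gap distance in a sorted vector of pairwise distances:
# first position k with d[k] > P where the jump d[k+1]-d[k] exceeds X times
# the mean slope over the preceding window. Returns the lower edge d[k] of
# the gap, or NA when no significant gap exists.
find_gap <- function(dsort, P, X, window_frac = 0.10, window_min = 5L) {
  m <- length(dsort)
  if (m < 3L) return(NA_real_)
  w <- max(window_min, ceiling(window_frac * m))
  jumps <- diff(dsort)
  for (k in seq_len(m - 1L)) {
    if (dsort[k + 1L] <= P) next  # gap must end beyond the prior
    lo <- max(1L, k - w)
    local <- jumps[lo:max(lo, k - 1L)]
    slope <- mean(local)
    if (slope <= 0) slope <- max(mean(jumps[jumps > 0]), .Machine$double.eps)
    if (jumps[k] > X * slope && jumps[k] > 0) return(dsort[k])
  }
  NA_real_
}

# split labels into components using pairs with d <= gap threshold
split_at_gap <- function(d, labels, gap) {
  comp <- components_below(d, labels, gap + .Machine$double.eps^0.5)
  split(labels, comp)
}

abgd_recursive_groups <- function(d, labels, P, X) {
  vals <- d[upper.tri(d)]
  vals <- sort(vals[!is.na(vals)])
  gap <- find_gap(vals, P, X)
  if (is.na(gap)) return(list(labels))
  groups <- split_at_gap(d, labels, gap)
  if (length(groups) == 1L) return(list(labels))
  out <- list()
  for (g in groups) {
    if (length(g) < 3L) { out[[length(out) + 1L]] <- g; next }
    sub <- d[g, g]
    out <- c(out, abgd_recursive_groups(sub, g, P, X))
  }
  out
}

#' Barcode-gap OTU delimitation (ABGD-style), initial and recursive
#'
#' For every prior intraspecific divergence `P` in the sweep: the barcode
#' gap is the first jump in the sorted pairwise distances, beyond `P`,
#' exceeding `X` times the mean local slope of the preceding window (10% of
#' the pair count, minimum 5 pairs). The initial partition links all pairs
#' below the gap; the recursive partition repeats gap-finding within each
#' component until no further significant gap is found. With no gap, all
#' sequences form one OTU.
#'
#' @param dm a `k2p_dist` (any distance matrix of class `k2p_dist` works;
#'   use `metric = "JC"` in the config together with [jc_matrix()] for the
#'   Jukes-Cantor variant)
#' @param config an [abgd_config()]
#' @return data frame with one row per prior: `P`, `initial_otus`,
#'   `recursive_otus`; partitions themselves in attribute `partitions`
#'   (list of `list(P, initial, recursive)`)
#' @export
abgd_partition <- function(dm, config = abgd_config()) {
  vals <- sort(dist_values(dm))
  parts <- list()
  for (P in config$P) {
    if (length(unique(vals)) < 3L) {
      warning("fewer than 3 distinct distances; single OTU")
      one <- partition(stats::setNames(rep("OTU_01", length(dm$labels)),
                                       dm$labels), "abgd")
      parts[[length(parts) + 1L]] <- list(P = P, initial = one, recursive = one)
      next
    }
    gap <- find_gap(vals, P, config$X)
    if (is.na(gap)) {
      asg_i <- stats::setNames(rep("OTU_01", length(dm$labels)), dm$labels)
      initial <- partition(asg_i, "abgd_initial", list(P = P))
      recursive <- partition(asg_i, "abgd_recursive", list(P = P))
    } else {
      comp <- components_below(dm$d, dm$labels,
                               gap + .Machine$double.eps^0.5)
      initial <- partition(relabel_otus(comp, dm$labels), "abgd_initial",
                           list(P = P, gap = gap))
      groups <- abgd_recursive_groups(dm$d, dm$labels, P, config$X)
      asg <- character(0)
      for (j in seq_along(groups))
        asg[groups[[j]]] <- sprintf("g%04d", j)
      recursive <- partition(relabel_otus(asg[dm$labels], dm$labels),
                             "abgd_recursive", list(P = P, gap = gap))
    }
    parts[[length(parts) + 1L]] <-
      list(P = P, initial = initial, recursive = recursive)
  }
  out <- data.frame(P = vapply(parts, `[[`, numeric(1), "P"),
                    initial_otus = vapply(parts, function(p)
                      n_otus(p$initial), integer(1)),
                    recursive_otus = vapply(parts, function(p)
                      n_otus(p$recursive), integer(1)))
  attr(out, "partitions") <- parts
  out
}

#' Jukes-Cantor distance matrix (alternative ABGD metric)
#'
#' Same pairwise-deletion rules as [k2p_matrix()]; `d = -3/4 log(1 - 4p/3)`
#' with `p` the proportion of differing comparable sites.
#'
#' @param x an aligned `barcode_aln`
#' @return a `k2p_dist`-classed object with JC distances
#' @export
jc_matrix <- function(x) {
  dm <- k2p_matrix(x)
  p <- ifelse(dm$sites > 0, dm$P + dm$Q, NA_real_)
  w <- 1 - 4 * p / 3
  dm$d <- suppressWarnings(ifelse(!is.na(w) & w > 0, -0.75 * log(w),
                                  NA_real_))
  diag(dm$d) <- 0
  und <- which(is.na(dm$d) & upper.tri(dm$d), arr.ind = TRUE)
  dm$undefined_pairs <- cbind(dm$labels[und[, 1]], dm$labels[und[, 2]])
  dm
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two partitions of the same ids;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param p1,p2 `partition`s (or named assignment vectors) over the same ids
#' @return numeric in `[-1, 1]`
#' @export
adjusted_rand_index <- function(p1, p2) {
  a1 <- as_assignment(p1); a2 <- as_assignment(p2)
  if (!setequal(names(a1), names(a2))) stop("partitions cover different ids")
  a2 <- a2[names(a1)]
  tab <- table(a1, a2)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

#' Multi-method concordance table
#'
#' Tabulates the OTU count per method and the pairwise adjusted Rand
#' agreement between methods.
#'
#' @param partitions named list of `partition`s over the same id set
#' @return list with `table` (data frame `method`, `n_otus`) and `ari`
#'   (symmetric matrix of adjusted Rand indices)
#' @export
concordance_table <- function(partitions) {
  stopifnot(length(partitions) >= 1L, !is.null(names(partitions)))
  ids <- sort(names(as_assignment(partitions[[1]])))
  for (p in partitions)
    if (!setequal(names(as_assignment(p)), ids))
      stop("partitions cover different ids")
  tab <- data.frame(method = names(partitions),
                    n_otus = vapply(partitions, n_otus, integer(1)),
                    row.names = NULL)
  k <- length(partitions)
  ari <- matrix(1, k, k, dimnames = list(names(partitions), names(partitions)))
  if (k > 1L)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      ari[i, j] <- ari[j, i] <-
        adjusted_rand_index(partitions[[i]], partitions[[j]])
    }
  list(table = tab, ari = ari)
}

#' Write a partition as TSV (`id<TAB>otu`)
#' @param p a `partition`
#' @param path output file
#' @export
write_partition <- function(p, path) {
  asg <- as_assignment(p)
  utils::write.table(data.frame(id = names(asg), otu = unname(asg)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
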
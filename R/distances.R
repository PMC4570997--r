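#' Kimura 2-parameter distance between two sequences
#'
#' Pairwise deletion: a column is comparable only when both characters are
#' unambiguous bases (A, C, G, T); gaps, N and IUPAC ambiguity codes are
#' treated as missing. With P the proportion of transitions and Q of
#' transversions among comparable sites,
#' \deqn{d = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q).}
#' When either log argument is non-positive the pair is saturated and the
#' distance is `NA`.
#'
#' @param a,b DNA strings of equal length
#' @return list with `distance` (substitutions/site or `NA`),
#'   `comparable_sites`, `P`, `Q`
#' @export
k2p <- function(a, b) {
  va <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  vb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(va) != length(vb)) stop("sequences differ in length")
  bases <- c("A", "C", "G", "T")
  ok <- va %in% bases & vb %in% bases
  n <- sum(ok)
  if (n == 0L)
    return(list(distance = NA_real_, comparable_sites = 0L,
                P = NA_real_, Q = NA_real_))
  va <- va[ok]; vb <- vb[ok]
  diff <- va != vb
  purine_a <- va %in% c("A", "G")
  purine_b <- vb %in% c("A", "G")
  ts <- sum(diff & purine_a == purine_b)   # transition: within purines/pyrimidines
  tv <- sum(diff & purine_a != purine_b)
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- if (w1 <= 0 || w2 <= 0) NA_real_ else -0.5 * log(w1) - 0.25 * log(w2)
  list(distance = d, comparable_sites = as.integer(n), P = P, Q = Q)
}

# integer encoding A=1 C=2 G=3 T=4, everything else 0 (missing)
encode_acgt <- function(m) {
  e <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  e[m == "A"] <- 1L; e[m == "C"] <- 2L; e[m == "G"] <- 3L; e[m == "T"] <- 4L
  e
}

#' All-pairs K2P distance matrix with pairwise deletion
#'
#' Computed via indicator-matrix products, so large alignments stay fast.
#' Saturated or incomparable pairs (see [k2p()]) are `NA` in `d` and listed
#' in `undefined_pairs`.
#'
#' @param x an aligned `barcode_aln` with at least 2 records
#' @return object of class `k2p_dist`: list with `labels`, `d` (symmetric
#'   distance matrix), `sites` (comparable-site counts), `P`, `Q`,
#'   `undefined_pairs` (2-column matrix of labels)
#' @export
k2p_matrix <- function(x) {
  if (length(x) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(x)
  n <- nrow(m)
  ind <- lapply(c("A", "C", "G", "T"), function(b) (m == b) * 1)
  names(ind) <- c("A", "C", "G", "T")
  comp <- ind$A + ind$C + ind$G + ind$T          # 1 where unambiguous base
  sites <- tcrossprod(comp)                      # comparable sites per pair
  same <- Reduce(`+`, lapply(ind, tcrossprod))   # identical comparable sites
  ts <- tcrossprod(ind$A, ind$G) + tcrossprod(ind$G, ind$A) +
    tcrossprod(ind$C, ind$T) + tcrossprod(ind$T, ind$C)
  tv <- sites - same - ts
  P <- ifelse(sites > 0, ts / sites, NA_real_)
  Q <- ifelse(sites > 0, tv / sites, NA_real_)
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  d <- suppressWarnings(ifelse(!is.na(w1) & w1 > 0 & w2 > 0,
                               -0.5 * log(w1) - 0.25 * log(w2), NA_real_))
  diag(d) <- 0; diag(sites) <- ncol(m)
  dimnames(d) <- dimnames(sites) <- dimnames(P) <- dimnames(Q) <-
    list(rownames(m), rownames(m))
  und <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  undefined_pairs <- cbind(rownames(m)[und[, 1]], rownames(m)[und[, 2]])
  structure(list(labels = rownames(m), d = d, sites = sites, P = P, Q = Q,
                 undefined_pairs = undefined_pairs),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat("k2p_dist: ", length(x$labels), " sequences, max distance ",
      sprintf("%.1f%%", 100 * max(x$d, na.rm = TRUE)), "\n", sep = "")
  if (nrow(x$undefined_pairs))
    cat("  undefined pairs: ", nrow(x$undefined_pairs), "\n", sep = "")
  invisible(x)
}

# upper-triangle finite distances as a vector
dist_values <- function(dm) {
  v <- dm$d[upper.tri(dm$d)]
  v[!is.na(v)]
}

#' Histogram of pairwise distances with barcode-gap detection
#'
#' Bins the finite pairwise distances on `[0, max(d)]` and reports maximal
#' runs of empty bins strictly inside the observed range as candidate
#' barcode gaps. A run must span at least `min_run` bins to be reported, to
#' avoid binning artefacts.
#'
#' @param dm a `k2p_dist`
#' @param bin_width bin width as a distance fraction (default 0.005)
#' @param min_run minimum number of consecutive empty bins (default 2)
#' @return list with `bin_edges`, `counts`, `empty_intervals` (data frame
#'   `lo`, `hi`)
#' @export
dist_histogram <- function(dm, bin_width = 0.005, min_run = 2L) {
  stopifnot(bin_width > 0)
  v <- dist_values(dm)
  hi <- max(v)
  edges <- seq(0, hi + bin_width, by = bin_width)
  counts <- as.integer(table(cut(v, breaks = edges, right = FALSE,
                                 include.lowest = TRUE)))
  empty <- counts == 0L
  # clip to strictly inside the observed range
  occ <- which(!empty)
  runs <- rle(empty)
  out <- data.frame(lo = numeric(0), hi = numeric(0))
  pos <- cumsum(c(1L, runs$lengths))
  for (j in seq_along(runs$values)) {
    if (!runs$values[j] || runs$lengths[j] < min_run) next
    a <- pos[j]; b <- pos[j] + runs$lengths[j] - 1L
    if (a <= min(occ) || b >= max(occ)) next  # not interior
    out <- rbind(out, data.frame(lo = edges[a], hi = edges[b + 1L]))
  }
  list(bin_edges = edges, counts = counts, empty_intervals = out)
}

#' Per-group distance summary: intra maxima and nearest neighbours
#'
#' For every group of a partition reports the group size, the maximum
#' intra-group K2P distance (`NA` for singletons) and the nearest
#' neighbouring group with the minimum inter-group distance.
#'
#' @param dm a `k2p_dist`
#' @param partition a `partition` object or named character vector mapping
#'   every label of `dm` to a group
#' @return data frame with columns `group`, `n`, `max_intra`, `nn_group`,
#'   `nn_distance`
#' @export
group_summary <- function(dm, partition) {
  asg <- as_assignment(partition)
  if (!all(dm$labels %in% names(asg)))
    stop("partition does not cover all labels")
  g <- asg[dm$labels]
  groups <- sort(unique(g))
  out <- data.frame(group = groups, n = NA_integer_, max_intra = NA_real_,
                    nn_group = NA_character_, nn_distance = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups)) {
    in_g <- g == groups[i]
    out$n[i] <- sum(in_g)
    if (sum(in_g) > 1L) {
      sub <- dm$d[in_g, in_g]
      out$max_intra[i] <- suppressWarnings(max(sub[upper.tri(sub)],
                                               na.rm = TRUE))
      if (!is.finite(out$max_intra[i])) out$max_intra[i] <- NA_real_
    }
    if (length(groups) > 1L) {
      best <- Inf; best_g <- NA_character_
      for (h in groups[groups != groups[i]]) {
        dd <- dm$d[in_g, g == h, drop = FALSE]
        mn <- suppressWarnings(min(dd, na.rm = TRUE))
        if (is.finite(mn) && mn < best) { best <- mn; best_g <- h }
      }
      out$nn_group[i] <- best_g
      out$nn_distance[i] <- if (is.finite(best)) best else NA_real_
    }
  }
  out
}

#' Write a distance matrix as square TSV
#' @param dm a `k2p_dist`
#' @param path output file
#' @export
write_dist_tsv <- function(dm, path) {
  m <- as.data.frame(dm$d)
  utils::write.table(cbind(id = dm$labels, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#' @param dm a `k2p_dist`
#' @param path output file
#' @export
write_dist_phylip <- function(dm, path) {
  lines <- c(sprintf("%5d", length(dm$labels)),
             vapply(seq_along(dm$labels), function(i)
               paste(formatC(dm$labels[i], width = -10),
                     paste(sprintf("%.6f", dm$d[i, ]), collapse = " ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
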
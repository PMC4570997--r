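# columns containing only unambiguous bases in every sequence
complete_columns <- function(m) {
  which(colSums(matrix(m %in% c("A", "C", "G", "T"), nrow(m))) == nrow(m))
}

#' Collapse an alignment into haplotypes
#'
#' Columns containing a gap, N or ambiguity code in any sequence are
#' removed first (complete deletion, the DnaSP convention — note this
#' differs from the pairwise deletion used for K2P distances); identical
#' remaining sequences are merged. Counts are kept overall and per country.
#'
#' @param x an aligned `barcode_aln`
#' @return object of class `haplotype_table`: list with `haplotypes`
#'   (character vector of collapsed sequences, named `H1`, `H2`, ... in
#'   order of first occurrence), `counts`, `group_counts` (haplotype x
#'   country matrix), `membership` (named vector id -> haplotype),
#'   `n_sites` (analysed columns)
#' @export
collapse_haplotypes <- function(x) {
  m <- aln_matrix(x)
  keep <- complete_columns(m)
  if (length(keep) == 0L) stop("no gap/ambiguity-free columns left")
  m <- m[, keep, drop = FALSE]
  seqs <- apply(m, 1, paste, collapse = "")
  uniq <- unique(seqs)
  hap_id <- stats::setNames(sprintf("H%d", seq_along(uniq)), uniq)
  membership <- stats::setNames(unname(hap_id[seqs]), x$id)
  counts <- table(factor(membership, levels = hap_id))
  country <- x$meta$country
  country[is.na(country)] <- "unknown"
  gc <- table(factor(membership, levels = hap_id), country)
  structure(list(haplotypes = stats::setNames(uniq, hap_id),
                 counts = as.integer(counts),
                 group_counts = unclass(gc),
                 membership = membership,
                 n_sites = length(keep)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table: ", length(x$haplotypes), " haplotypes from ",
      sum(x$counts), " sequences (", x$n_sites, " analysed sites)\n",
      sep = "")
  invisible(x)
}

harmonic <- function(k) sum(1 / seq_len(k))

tajima_d <- function(n, S, k) {
  if (S == 0L || n < 4L) return(NA_real_)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Fu & Li's D (outgroup-polarised) and D* (no outgroup).
# eta: total mutations; eta_e: derived singletons; eta_s: singletons.
fu_li_d <- function(n, eta, eta_e) {
  if (eta == 0 || n < 4L) return(NA_real_)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  vD <- 1 + a1^2 / (a2 + a1^2) * (cn - (n + 1) / (n - 1))
  uD <- a1 - 1 - vD
  (eta - a1 * eta_e) / sqrt(uD * eta + vD * eta^2)
}

fu_li_dstar <- function(n, eta, eta_s) {
  if (eta == 0 || n < 4L) return(NA_real_)
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  an1 <- harmonic(n)  # a_{n+1}
  cn <- 2 * (n * a1 - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vstar <- ((n / (n - 1))^2 * a2 + a1^2 * dn -
              2 * n * a1 * (a1 + 1) / (n - 1)^2) / (a1^2 + a2)
  ustar <- (n / (n - 1)) * (a1 - n / (n - 1)) - vstar
  ((n / (n - 1)) * eta - a1 * eta_s) / sqrt(ustar * eta + vstar * eta^2)
}

#' Pairwise nucleotide differences over complete-deletion columns
#'
#' @param x an aligned `barcode_aln`
#' @return symmetric integer matrix of per-pair difference counts, with
#'   attribute `n_sites`
#' @export
pairwise_differences <- function(x) {
  m <- aln_matrix(x)
  keep <- complete_columns(m)
  if (length(keep) == 0L) stop("no gap/ambiguity-free columns left")
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  same <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) same <- same + tcrossprod((m == b) * 1)
  d <- length(keep) - same
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "n_sites") <- length(keep)
  d
}

#' Genetic diversity indices and neutrality tests
#'
#' Computed on complete-deletion columns (sites with any gap or ambiguity
#' excluded): segregating sites S, mean pairwise differences k, nucleotide
#' diversity pi = k / sites, haplotype count h and haplotype diversity
#' `Hd = n (1 - sum f_i^2) / (n - 1)`, Tajima's D, and Fu & Li's D
#' (requires `outgroup` to polarise external-branch mutations) and D*
#' (outgroup-free). Neutrality statistics are `NA` when S = 0 or n < 4.
#'
#' @param x an aligned `barcode_aln` (the ingroup)
#' @param outgroup optional single-sequence `barcode_aln` (or DNA string)
#'   aligned to `x`, used only to polarise mutations for Fu & Li's D
#' @return data frame of class `diversity_stats` with one row:
#'   `n`, `sites`, `S`, `k`, `pi`, `h`, `Hd`, `tajima_D`, `fu_li_D`,
#'   `fu_li_Dstar`
#' @export
diversity <- function(x, outgroup = NULL) {
  if (length(x) < 2L) stop("need at least 2 sequences")
  m_all <- aln_matrix(x)
  og <- NULL
  if (!is.null(outgroup)) {
    og_seq <- if (inherits(outgroup, "barcode_aln")) outgroup$seq[1] else
      as.character(outgroup)
    if (nchar(og_seq) != ncol(m_all))
      stop("outgroup not aligned to ingroup")
    og <- strsplit(toupper(og_seq), "", fixed = TRUE)[[1]]
  }
  keep <- complete_columns(m_all)
  if (!is.null(og)) keep <- keep[og[keep] %in% c("A", "C", "G", "T")]
  if (length(keep) == 0L) stop("no gap/ambiguity-free columns left")
  m <- m_all[, keep, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  nalleles <- apply(m, 2, function(col) length(unique(col)))
  seg <- which(nalleles > 1L)
  S <- length(seg)
  dmat <- pairwise_differences(x)
  # recompute k on the same column set as S when an outgroup narrowed it
  if (!is.null(og)) {
    same <- matrix(0, n, n)
    for (b in c("A", "C", "G", "T")) same <- same + tcrossprod((m == b) * 1)
    dmat <- L - same; diag(dmat) <- 0
  }
  k <- mean(dmat[upper.tri(dmat)])
  pi <- k / L
  seqs <- apply(m, 1, paste, collapse = "")
  f <- table(seqs) / n
  h <- length(f)
  Hd <- n * (1 - sum(f^2)) / (n - 1)
  eta <- sum(nalleles - 1L)
  eta_s <- 0L; eta_e <- 0L
  for (j in seg) {
    tab <- table(m[, j])
    singles <- names(tab)[tab == 1L]
    eta_s <- eta_s + length(singles)
    if (!is.null(og))
      eta_e <- eta_e + sum(singles != og[keep[j]])
  }
  out <- data.frame(n = n, sites = L, S = S, k = k, pi = pi, h = h, Hd = Hd,
                    tajima_D = tajima_d(n, S, k),
                    fu_li_D = if (is.null(og)) NA_real_ else
                      fu_li_d(n, eta, eta_e),
                    fu_li_Dstar = fu_li_dstar(n, eta, eta_s))
  class(out) <- c("diversity_stats", "data.frame")
  out
}

#' Per-group diversity table
#'
#' Applies [diversity()] to each group of a partition, mirroring a per-clade
#' diversity/neutrality summary table.
#'
#' @param x an aligned `barcode_aln`
#' @param partition a `partition` or named vector id -> group
#' @param outgroup see [diversity()]
#' @param min_n groups smaller than this are reported with `NA` statistics
#' @return data frame with one row per group plus an `"all"` row
#' @export
diversity_by_group <- function(x, partition, outgroup = NULL, min_n = 2L) {
  asg <- as_assignment(partition)
  rows <- list(cbind(group = "all", diversity(x, outgroup)))
  for (g in sort(unique(asg[x$id]))) {
    ids <- x$id[asg[x$id] == g]
    if (length(ids) < min_n) {
      rows[[length(rows) + 1L]] <-
        cbind(group = g, data.frame(n = length(ids), sites = NA, S = NA,
                                    k = NA, pi = NA, h = NA, Hd = NA,
                                    tajima_D = NA, fu_li_D = NA,
                                    fu_li_Dstar = NA))
    } else {
      rows[[length(rows) + 1L]] <- cbind(group = g, diversity(x[ids], outgroup))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# minimax (bottleneck) path weights over a complete weighted graph
minimax_weights <- function(w) {
  n <- nrow(w)
  mm <- w
  for (k in seq_len(n)) mm <- pmin(mm, outer(mm[, k], mm[k, ], pmax))
  mm
}

#' Minimum spanning haplotype network
#'
#' Builds the union of all minimum spanning trees over the haplotype
#' Hamming-distance graph; with `epsilon > 0`, alternative edges at most
#' `epsilon` steps longer than the bottleneck connection are added. An edge
#' (u, v) belongs to the network iff its weight is at most the minimax path
#' weight between u and v plus `epsilon`.
#'
#' @param ht a `haplotype_table`
#' @param epsilon non-negative integer relaxation (default 0 = MST union)
#' @return object of class `haplotype_network`: list with `nodes` (data
#'   frame `haplotype`, `count`), `edges` (data frame `h1`, `h2`, `steps`),
#'   `group_counts`
#' @export
msn <- function(ht, epsilon = 0L) {
  stopifnot(epsilon >= 0)
  haps <- ht$haplotypes
  nh <- length(haps)
  nodes <- data.frame(haplotype = names(haps), count = ht$counts)
  if (nh == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(h1 = character(0),
                                             h2 = character(0),
                                             steps = integer(0)),
                          group_counts = ht$group_counts),
                     class = "haplotype_network"))
  }
  m <- matrix(unlist(strsplit(haps, "", fixed = TRUE), use.names = FALSE),
              nrow = nh, byrow = TRUE)
  w <- matrix(0L, nh, nh)
  for (i in 1:(nh - 1)) for (j in (i + 1):nh)
    w[i, j] <- w[j, i] <- sum(m[i, ] != m[j, ])
  mm <- minimax_weights(w)
  keep <- which(upper.tri(w) & w <= mm + epsilon, arr.ind = TRUE)
  edges <- data.frame(h1 = names(haps)[keep[, 1]],
                      h2 = names(haps)[keep[, 2]],
                      steps = w[keep])
  edges <- edges[order(edges$steps, edges$h1, edges$h2), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 group_counts = ht$group_counts),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network: ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Convert a haplotype network to an igraph graph
#' @param net a `haplotype_network`
#' @return an `igraph` graph with `count` vertex and `steps` edge attributes
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes$haplotype,
                          count = net$nodes$count))
  igraph::E(g)$weight <- net$edges$steps
  g
}

#' Write a haplotype network as GraphML and/or edge-list TSV
#' @param net a `haplotype_network`
#' @param graphml,edges optional output paths
#' @export
write_network <- function(net, graphml = NULL, edges = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(net), graphml, format = "graphml")
  if (!is.null(edges))
    utils::write.table(net$edges, edges, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(net)
}

#' Write haplotypes as a NEXUS data block
#' @param ht a `haplotype_table`
#' @param path output file
#' @export
write_haplotypes_nexus <- function(ht, path) {
  seqs <- ht$haplotypes
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(seqs),
                     nchar(seqs[1])),
             "  FORMAT DATATYPE=DNA MISSING=N GAP=-;",
             "  MATRIX",
             sprintf("    %s %s", names(seqs), unname(seqs)),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
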
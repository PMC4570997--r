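#' Neighbor-joining tree from a K2P distance matrix
#'
#' Standard NJ agglomeration on the pairwise distance matrix; exact on
#' additive matrices. Undefined (saturated/incomparable) distances are an
#' error, with the offending pairs listed.
#'
#' @param dm a `k2p_dist` with at least 3 labels
#' @return an unrooted `ape::phylo` tree; negative branch lengths are kept
#'   (attribute `display_lengths` holds the zero-floored copy)
#' @export
nj_tree <- function(dm) {
  if (length(dm$labels) < 3L) stop("need at least 3 sequences")
  if (nrow(dm$undefined_pairs) > 0L)
    stop("undefined distances for pairs: ",
         paste(apply(dm$undefined_pairs, 1, paste, collapse = "~"),
               collapse = ", "))
  tr <- ape::nj(stats::as.dist(dm$d))
  attr(tr, "display_lengths") <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P/NJ tree
#' per replicate, and scores each internal edge of the reference tree by
#' the percentage of replicate trees containing the same bipartition.
#' Replicates yielding undefined distances are skipped and counted.
#'
#' @param x an aligned `barcode_aln`
#' @param replicates number of bootstrap replicates (default 500)
#' @param seed RNG seed (mandatory)
#' @param dm optional precomputed `k2p_dist` for the reference tree
#' @return the reference `phylo` with `node.label` set to support
#'   percentages (root label empty); attribute `skipped` = number of
#'   skipped replicates
#' @export
nj_bootstrap <- function(x, replicates = 500L, seed, dm = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(dm)) dm <- k2p_matrix(x)
  ref <- nj_tree(dm)
  L <- unique(nchar(x$seq))
  set.seed(seed)
  boots <- vector("list", replicates)
  skipped <- 0L
  for (r in seq_len(replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    xb <- x
    m <- aln_matrix(x)[, cols, drop = FALSE]
    xb$seq <- apply(m, 1, paste, collapse = "")
    dmb <- k2p_matrix(xb)
    if (nrow(dmb$undefined_pairs) > 0L) { skipped <- skipped + 1L; next }
    boots[[r]] <- ape::nj(stats::as.dist(dmb$d))
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  used <- length(boots)
  if (used == 0L) stop("all bootstrap replicates had undefined distances")
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / used, 1)
  attr(ref, "skipped") <- skipped
  attr(ref, "display_lengths") <- pmax(ref$edge.length, 0)
  ref
}

#' Test whether a tip set is monophyletic after outgroup rooting
#'
#' @param tree a `phylo`
#' @param tips character vector of tip labels to test
#' @param outgroup character vector of outgroup tip labels used to root
#' @return logical
#' @export
check_monophyly <- function(tree, tips, outgroup) {
  if (!all(tips %in% tree$tip.label))
    stop("tips not in tree: ",
         paste(setdiff(tips, tree$tip.label), collapse = ", "))
  if (!all(outgroup %in% tree$tip.label))
    stop("outgroup tips not in tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

#' Strict-clock node ages from group distances and one calibration
#'
#' A deliberately simple linearised dating: the substitution rate is set by
#' one calibration split, `r = D_cal / (2 T_cal)` with `D_cal` the mean
#' inter-group K2P distance across the calibration split, and the age of
#' any pair of groups is its mean between-group distance divided by `2 r`.
#' No rate variation, no tree prior — a transparent first-order stand-in
#' for full Bayesian relaxed-clock dating, which it does not replace.
#'
#' @param dm a `k2p_dist`
#' @param groups a `partition` assigning every label to a group
#' @param calibration_split list of two character vectors of group labels
#'   on either side of the calibrated split
#' @param calibration_age age of the calibration split in million years
#' @return list with `rate` (substitutions/site/MY) and `ages` (data frame
#'   `group_a`, `group_b`, `mean_distance`, `age_my`)
#' @export
calibrated_ages <- function(dm, groups, calibration_split, calibration_age) {
  asg <- as_assignment(groups)
  g <- asg[dm$labels]
  s1 <- calibration_split[[1]]; s2 <- calibration_split[[2]]
  if (length(intersect(s1, s2)) > 0L) stop("calibration groups overlap")
  if (!all(c(s1, s2) %in% g)) stop("calibration groups missing from partition")
  mean_between <- function(ga, gb) {
    dd <- dm$d[g %in% ga, g %in% gb, drop = FALSE]
    mean(dd, na.rm = TRUE)
  }
  D_cal <- mean_between(s1, s2)
  if (!is.finite(D_cal) || D_cal == 0) stop("calibration distance is zero")
  rate <- D_cal / (2 * calibration_age)
  glev <- sort(unique(g))
  pairs <- utils::combn(glev, 2)
  ages <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                     mean_distance = NA_real_, age_my = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    ages$mean_distance[i] <- mean_between(pairs[1, i], pairs[2, i])
    ages$age_my[i] <- ages$mean_distance[i] / (2 * rate)
  }
  list(rate = rate, calibration = list(split = calibration_split,
                                       age_my = calibration_age),
       ages = ages)
}
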
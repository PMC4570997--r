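# hierarchical sums of squares from a squared-distance matrix and a list of
# index vectors; SSD(set) = sum_{i<j in set} d2 / |set|
ssd_within <- function(d2, sets) {
  sum(vapply(sets, function(ix)
    sum(d2[ix, ix]) / (2 * length(ix)), numeric(1)))
}

amova_components <- function(d2, group, pop) {
  N <- nrow(d2)
  pops <- split(seq_len(N), pop)
  grps <- split(seq_len(N), group)
  G <- length(grps); P <- length(pops)
  ssd_total <- sum(d2) / (2 * N)
  ssd_wp <- ssd_within(d2, pops)
  ssd_wg <- ssd_within(d2, grps)
  ssd_ap <- ssd_wg - ssd_wp
  ssd_ag <- ssd_total - ssd_wg
  df_ag <- G - 1L; df_ap <- P - G; df_wp <- N - P
  npop <- lengths(pops)
  ngrp <- lengths(grps)
  pop_group <- vapply(split(group, pop), `[`, group[1], 1)
  sum_np2_over_ng <- sum(vapply(names(grps), function(g) {
    sum(npop[pop_group == g]^2) / ngrp[g]
  }, numeric(1)))
  sigma_c <- ssd_wp / df_wp
  if (df_ap > 0L) {
    n1 <- (N - sum_np2_over_ng) / df_ap
    n2 <- (sum_np2_over_ng - sum(npop^2) / N) / df_ag
    n3 <- (N - sum(ngrp^2) / N) / df_ag
    ms_ap <- ssd_ap / df_ap
    ms_ag <- ssd_ag / df_ag
    sigma_b <- (ms_ap - sigma_c) / n1
    sigma_a <- (ms_ag - sigma_c - n2 * sigma_b) / n3
  } else {
    # one population per group: two-level decomposition, no among-pop term
    n3 <- (N - sum(npop^2) / N) / df_ag
    sigma_b <- NA_real_
    sigma_a <- (ssd_ag / df_ag - sigma_c) / n3
  }
  tot <- sum(c(sigma_a, sigma_b, sigma_c), na.rm = TRUE)
  list(ssd = c(among_groups = ssd_ag, among_pops = ssd_ap,
               within_pops = ssd_wp),
       df = c(df_ag, df_ap, df_wp),
       sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
       phi = c(
         CT = sigma_a / tot,
         SC = if (is.na(sigma_b)) NA_real_ else sigma_b / (sigma_b + sigma_c),
         ST = if (is.na(sigma_b)) sigma_a / tot else
           (sigma_a + sigma_b) / tot))
}

#' Hierarchical AMOVA with permutation tests
#'
#' Analysis of molecular variance with individuals nested in populations
#' nested in groups, on squared molecular distances (for sequences, the
#' pairwise nucleotide-difference counts over complete-deletion columns).
#' Variance components and Phi fixation indices follow the standard
#' sums-of-squares decomposition; significance by permutation:
#' Phi_ST permutes individuals across all populations, Phi_SC permutes
#' individuals among populations within their group, Phi_CT permutes whole
#' populations among groups. `p = (#as-or-more-extreme + 1) / (perms + 1)`.
#'
#' @param x an aligned `barcode_aln`, or a square numeric matrix of squared
#'   distances with rownames
#' @param group named vector id -> group (clade); or taken from
#'   `x$meta$clade` when `NULL`
#' @param population named vector id -> population (country); or taken from
#'   `x$meta$country` when `NULL`
#' @param n_permutations permutations per test (default 1000)
#' @param seed RNG seed (mandatory when permuting)
#' @return object of class `amova_result`: data frame `table` (source, df,
#'   SSD, variance component, percentage, Phi, p-value) plus `phi`,
#'   `sigma`, `p_values`
#' @export
amova <- function(x, group = NULL, population = NULL,
                  n_permutations = 1000L, seed = NULL) {
  if (inherits(x, "barcode_aln")) {
    d2 <- pairwise_differences(x)
    ids <- x$id
    if (is.null(group)) group <- stats::setNames(x$meta$clade, x$id)
    if (is.null(population)) population <- stats::setNames(x$meta$country, x$id)
  } else {
    d2 <- as.matrix(x)
    ids <- rownames(d2)
    if (is.null(group) || is.null(population))
      stop("group and population are required with a distance matrix")
  }
  group <- as.character(group[ids]); population <- as.character(population[ids])
  if (anyNA(group) || anyNA(population))
    stop("every sequence needs a group and a population label")
  if (length(unique(group)) < 2L) stop("need at least 2 groups")
  # populations are nested: qualify by group
  population <- paste(group, population, sep = "/")
  obs <- amova_components(d2, group, population)
  p_values <- c(CT = NA_real_, SC = NA_real_, ST = NA_real_)
  if (n_permutations > 0L) {
    if (is.null(seed)) stop("seed is mandatory for permutation tests")
    set.seed(seed)
    N <- length(ids)
    exceed <- c(CT = 0L, SC = 0L, ST = 0L)
    pop_of <- split(seq_len(N), population)
    pop_group <- vapply(split(group, population), `[`, group[1], 1)
    for (b in seq_len(n_permutations)) {
      # ST: individuals among populations across groups
      perm <- sample.int(N)
      st <- amova_components(d2[perm, perm], group, population)$phi["ST"]
      if (!is.na(st) && !is.na(obs$phi["ST"]) && st >= obs$phi["ST"])
        exceed["ST"] <- exceed["ST"] + 1L
      # SC: individuals among populations within groups
      perm2 <- seq_len(N)
      for (g in unique(group)) {
        ix <- which(group == g)
        perm2[ix] <- ix[sample.int(length(ix))]
      }
      sc <- amova_components(d2[perm2, perm2], group, population)$phi["SC"]
      if (!is.na(sc) && !is.na(obs$phi["SC"]) && sc >= obs$phi["SC"])
        exceed["SC"] <- exceed["SC"] + 1L
      # CT: whole populations among groups
      perm_pg <- sample(pop_group)
      names(perm_pg) <- names(pop_group)
      group_b <- perm_pg[population]
      ct <- amova_components(d2, unname(group_b), population)$phi["CT"]
      if (!is.na(ct) && !is.na(obs$phi["CT"]) && ct >= obs$phi["CT"])
        exceed["CT"] <- exceed["CT"] + 1L
    }
    p_values <- (exceed + 1) / (n_permutations + 1)
    if (is.na(obs$phi["SC"])) p_values["SC"] <- NA_real_
  }
  pct <- 100 * obs$sigma / sum(obs$sigma, na.rm = TRUE)
  table <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    df = obs$df,
    SSD = unname(obs$ssd),
    variance = unname(obs$sigma),
    percentage = unname(pct),
    phi = c(obs$phi["CT"], obs$phi["SC"], obs$phi["ST"]),
    phi_label = c("Phi_CT", "Phi_SC", "Phi_ST"),
    p_value = c(p_values["CT"], p_values["SC"], p_values["ST"]))
  rownames(table) <- NULL
  structure(list(table = table, phi = obs$phi, sigma = obs$sigma,
                 p_values = p_values, n_permutations = n_permutations),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Hierarchical AMOVA (", x$n_permutations, " permutations)\n", sep = "")
  print(x$table, digits = 4)
  invisible(x)
}

#' Write an AMOVA table as TSV
#' @param x an `amova_result`
#' @param path output file
#' @export
write_amova <- function(x, path) {
  utils::write.table(x$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
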
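#' Accessions excluded from host-parasite panels by default
#'
#' Known contaminant records: AY316793 (nominally a louse cytb record, in
#' fact chironomid-like, ~59% divergent from all congeners).
#' @export
default_exclusions <- function() c("AY316793")

#' Host-parasite taxon panel
#'
#' @param entries data frame with columns `taxon`, `accession`, `gene`
#'   (`"COI"`/`"cytb"`), `role` (`"host"`/`"parasite"`)
#' @return validated data frame of class `taxon_panel`
#' @export
taxon_panel <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("taxon", "accession", "gene", "role")
  if (!all(need %in% names(entries)))
    stop("panel needs columns: ", paste(need, collapse = ", "))
  if (!all(entries$role %in% c("host", "parasite")))
    stop("role must be 'host' or 'parasite'")
  if (!any(entries$role == "host") || !any(entries$role == "parasite"))
    stop("panel needs both host and parasite entries")
  structure(entries, class = c("taxon_panel", "data.frame"))
}

#' Read a taxon panel from JSON
#'
#' JSON layout: an array of objects with fields `taxon`, `accession`,
#' `gene`, `role`.
#' @param path JSON file
#' @export
read_panel <- function(path) {
  taxon_panel(jsonlite::fromJSON(path))
}

#' Anchor a gene window inside a longer sequence
#'
#' Locates the best ungapped match of `reference` (a gene-length sequence)
#' inside `target` (e.g. a whole mitogenome) by sliding comparison, and
#' returns the matching window of `target`. Deterministic: the left-most
#' best-scoring offset wins.
#'
#' @param target long DNA string
#' @param reference gene-window DNA string (defines the window length)
#' @return list with `window` (substring of target), `start`, `score`
#'   (fraction of matching unambiguous positions)
#' @export
anchor_window <- function(target, reference) {
  tg <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  rf <- strsplit(toupper(reference), "", fixed = TRUE)[[1]]
  L <- length(rf); n <- length(tg)
  if (n < L) stop("target shorter than reference window")
  best <- -1; best_at <- 1L
  for (s in seq_len(n - L + 1L)) {
    sc <- sum(tg[s:(s + L - 1L)] == rf)
    if (sc > best) { best <- sc; best_at <- s }
  }
  list(window = paste(tg[best_at:(best_at + L - 1L)], collapse = ""),
       start = best_at, score = best / L)
}

#' Pairwise K2P divergences among a host-parasite panel
#'
#' All pairwise K2P distances (pairwise deletion) among panel taxa for one
#' gene, plus taxon roles, so that parasite/host rate ratios can be read
#' off directly. Saturated pairs are reported with `NA`.
#'
#' @param x aligned `barcode_aln` of the panel sequences for one gene,
#'   trimmed to the shared gene window; ids must match `panel$accession`
#' @param panel a [taxon_panel()]
#' @param exclude accessions to drop (default [default_exclusions()])
#' @return data frame `taxon_a`, `taxon_b`, `role_a`, `role_b`,
#'   `accession_a`, `accession_b`, `distance`, `percent`,
#'   `comparable_sites`
#' @export
panel_divergences <- function(x, panel, exclude = default_exclusions()) {
  panel <- panel[panel$accession %in% x$id &
                   !(panel$accession %in% exclude), , drop = FALSE]
  if (nrow(panel) < 2L) stop("fewer than 2 panel sequences present")
  x <- x[panel$accession]
  dm <- k2p_matrix(x)
  pairs <- utils::combn(seq_len(nrow(panel)), 2)
  data.frame(
    taxon_a = panel$taxon[pairs[1, ]],
    taxon_b = panel$taxon[pairs[2, ]],
    role_a = panel$role[pairs[1, ]],
    role_b = panel$role[pairs[2, ]],
    accession_a = panel$accession[pairs[1, ]],
    accession_b = panel$accession[pairs[2, ]],
    distance = dm$d[cbind(pairs[1, ], pairs[2, ])],
    percent = round(100 * dm$d[cbind(pairs[1, ], pairs[2, ])], 1),
    comparable_sites = dm$sites[cbind(pairs[1, ], pairs[2, ])])
}

#' Count variable amino-acid positions in a coding alignment
#'
#' Translates every sequence in frame 1 under the stated genetic code and
#' counts alignment columns (amino-acid space) holding two or more distinct
#' residues; ambiguous translations (X) are ignored when counting states.
#' Sequences with internal stop codons are an error — run
#' [translation_qc()] first.
#'
#' @param x aligned in-frame `barcode_aln`
#' @param code `"invertebrate_mito"` (lice), `"vertebrate_mito"` (hosts) or
#'   `"standard"`
#' @return list with `count` and `sites` (data frame `position`,
#'   `residues`)
#' @export
aa_substitution_count <- function(x, code = "invertebrate_mito") {
  tbl <- genetic_code_table(code)
  m <- aln_matrix(x)
  L <- ncol(m) - ncol(m) %% 3L
  if (L < 3L) stop("alignment shorter than one codon")
  aa <- matrix("X", nrow(m), L / 3L)
  for (i in seq_len(nrow(m))) {
    s <- paste(m[i, 1:L], collapse = "")
    codons <- substring(s, seq(1, L - 2, 3), seq(3, L, 3))
    res <- translate_codons(codons, tbl)
    if (any(res[-length(res)] == "*"))
      stop("internal stop codon in ", x$id[i],
           "; check frame with translation_qc()")
    aa[i, ] <- res
  }
  var_sites <- data.frame(position = integer(0), residues = character(0))
  for (j in seq_len(ncol(aa))) {
    res <- setdiff(unique(aa[, j]), c("X", "*"))
    if (length(res) >= 2L)
      var_sites <- rbind(var_sites,
                         data.frame(position = j,
                                    residues = paste(sort(res),
                                                     collapse = "/")))
  }
  list(count = nrow(var_sites), sites = var_sites)
}

#' Parasite/host divergence-rate ratio
#'
#' @param parasite_distance,host_distance distances as fractions (or both
#'   as percentages)
#' @return ratio (parasite over host)
#' @export
rate_ratio <- function(parasite_distance, host_distance) {
  if (any(host_distance == 0)) stop("host distance is zero; ratio undefined")
  parasite_distance / host_distance
}
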
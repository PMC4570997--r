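#' Barcode alignment container
#'
#' Light container for a set of (optionally aligned) DNA sequences together
#' with per-sequence metadata. Sequences are stored verbatim as character
#' strings; metadata is a data frame keyed by sequence id with columns
#' `id`, `gene`, `country`, `population`, `clade`, `source`.
#'
#' @param seq named character vector of DNA strings (IUPAC letters, `-`, `N`).
#'   Names are the sequence ids and must be unique.
#' @param meta optional data frame with an `id` column; joined left-outer
#'   onto the sequences. Missing columns are filled with `NA`.
#' @param gene optional gene tag (`"COI"` or `"cytb"`) applied to records
#'   lacking one.
#' @param source provenance tag: `"study"`, `"genbank"` or `"simulated"`.
#' @return object of class `barcode_aln`.
#' @export
barcode_aln <- function(seq, meta = NULL, gene = NA_character_,
                        source = "study") {
  if (length(seq) == 0L) stop("no sequences")
  ids <- names(seq)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    stop("all sequences must be named with ids")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate id: ", paste(dup, collapse = ", "))
  }
  if (any(nchar(seq) == 0L)) stop("empty sequence")
  bad <- grepl("[^ACGTRYSWKMBDHVN-]", toupper(seq))
  if (any(bad))
    stop("non-IUPAC characters in: ", paste(ids[bad], collapse = ", "))
  m <- data.frame(id = ids, gene = gene, country = NA_character_,
                  population = NA_character_, clade = NA_character_,
                  source = source, stringsAsFactors = FALSE)
  unmatched <- character(0)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"id" %in% names(meta)) stop("metadata must have an 'id' column")
    unmatched <- setdiff(meta$id, ids)
    for (col in intersect(c("gene", "country", "population", "clade"),
                          names(meta))) {
      i <- match(m$id, meta$id)
      hit <- !is.na(i) & !is.na(meta[[col]][i])
      m[[col]][hit] <- as.character(meta[[col]][i][hit])
    }
  }
  structure(list(seq = unname(as.character(seq)), id = ids, meta = m,
                 unmatched_meta = unmatched),
            class = "barcode_aln")
}

#' @export
print.barcode_aln <- function(x, ...) {
  L <- unique(nchar(x$seq))
  cat("barcode_aln: ", length(x$seq), " sequences, ",
      if (length(L) == 1L) paste0(L, " bp (aligned)")
      else paste0(min(L), "-", max(L), " bp (unaligned)"), "\n", sep = "")
  if (length(x$unmatched_meta))
    cat("  unmatched metadata ids: ", length(x$unmatched_meta), "\n", sep = "")
  invisible(x)
}

#' @export
length.barcode_aln <- function(x) length(x$seq)

#' Subset a barcode alignment by index or id
#' @param x a `barcode_aln`
#' @param i integer, logical or character (ids) index
#' @param ... unused
#' @export
`[.barcode_aln` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(seq = x$seq[i], id = x$id[i],
                 meta = x$meta[i, , drop = FALSE],
                 unmatched_meta = character(0)),
            class = "barcode_aln")
}

#' Alignment as a character matrix (one row per sequence)
#' @param x a `barcode_aln` with equal-length sequences
#' @return character matrix, uppercase, rownames = ids
#' @export
aln_matrix <- function(x) {
  L <- unique(nchar(x$seq))
  if (length(L) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  m <- matrix(unlist(strsplit(toupper(x$seq), "", fixed = TRUE), use.names = FALSE),
              nrow = length(x$seq), ncol = L, byrow = TRUE)
  rownames(m) <- x$id
  m
}

#' Read sequences (FASTA) with optional metadata (TSV)
#'
#' Metadata is a tab-separated file with header
#' `id  gene  country  population  clade` joined left-outer on sequence id;
#' metadata rows without a matching sequence are reported in the
#' `unmatched_meta` field, not an error.
#'
#' @param path FASTA file (wrapped or unwrapped)
#' @param metadata_path optional TSV file
#' @param gene,source defaults applied to records, see [barcode_aln()]
#' @return a `barcode_aln`
#' @export
read_fasta <- function(path, metadata_path = NULL, gene = NA_character_,
                       source = "study") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  seq <- as.character(ss)
  names(seq) <- sub("\\s.*$", "", names(ss))  # id = first whitespace token
  meta <- NULL
  if (!is.null(metadata_path))
    meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                              colClasses = "character")
  barcode_aln(seq, meta = meta, gene = gene, source = source)
}

#' Write a barcode alignment to FASTA
#'
#' Sequences are written verbatim, one line per sequence, preserving ids and
#' order, so `read_fasta(write_fasta(x))` round-trips exactly.
#'
#' @param x a `barcode_aln`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta <- function(x, path) {
  writeLines(paste0(">", x$id, "\n", x$seq), path)
  invisible(path)
}

#' Write the metadata table to TSV
#' @param x a `barcode_aln`
#' @param path output file
#' @export
write_metadata <- function(x, path) {
  utils::write.table(x$meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

ungapped_length <- function(seq) {
  nchar(gsub("[-N]", "", toupper(seq)))
}

#' Drop sequences shorter than a minimum ungapped length
#'
#' Ungapped length counts characters other than `-` and `N`. Mirrors the
#' barcode-recovery rule that only reads longer than 500 bp enter the
#' analysis; retention requires strictly greater than `min_len`.
#'
#' @param x a `barcode_aln`
#' @param min_len minimum ungapped length in nt (default 500)
#' @return filtered `barcode_aln` with attribute `n_dropped`
#' @export
filter_min_length <- function(x, min_len = 500) {
  keep <- ungapped_length(x$seq) > min_len
  out <- x[which(keep)]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Trim an alignment to its common overlapping region
#'
#' Removes leading and trailing columns whose non-gap coverage is below
#' `min_coverage`; internal columns are never touched. With the default
#' `min_coverage = 1` this trims to the strict common overlap of all
#' records.
#'
#' @param x an aligned `barcode_aln`
#' @param min_coverage minimum fraction of non-gap characters per kept
#'   terminal column, in (0, 1]
#' @return trimmed `barcode_aln`
#' @export
trim_to_overlap <- function(x, min_coverage = 1.0) {
  m <- aln_matrix(x)
  cov <- colMeans(m != "-")
  ok <- cov >= min_coverage
  if (!any(ok)) stop("no overlapping region at coverage ", min_coverage)
  first <- which(ok)[1L]
  last <- which(ok)[sum(ok)]
  seq <- substr(x$seq, first, last)
  names(seq) <- x$id
  out <- barcode_aln(seq, source = NA)
  out$meta <- x$meta
  out
}

# codon table lookup; tbl is a named AA vector from Biostrings
translate_codons <- function(codons, tbl) {
  aa <- unname(tbl[codons])
  aa[is.na(aa)] <- "X"  # ambiguous codon
  aa
}

genetic_code_table <- function(code = c("invertebrate_mito",
                                        "vertebrate_mito", "standard")) {
  code <- match.arg(code)
  id <- switch(code, invertebrate_mito = "5", vertebrate_mito = "2",
               standard = "1")
  Biostrings::getGeneticCode(id)
}

#' Translation quality control
#'
#' Checks a protein-coding mitochondrial sequence for internal gaps and
#' in-frame stop codons, the standard screen for pseudogene/numt artefacts.
#' The reading frame defaults to the one minimising stop codons.
#'
#' @param seq a DNA string (one record)
#' @param code genetic code: `"invertebrate_mito"` (default, table 5),
#'   `"vertebrate_mito"` (table 2) or `"standard"`
#' @param frame 1, 2, 3 or `NULL` to auto-detect
#' @return list with `ok`, `stop_codons`, `internal_gaps`, `frame`
#' @export
translation_qc <- function(seq, code = "invertebrate_mito", frame = NULL) {
  tbl <- genetic_code_table(code)
  s <- toupper(seq)
  internal_gaps <- lengths(regmatches(s, gregexpr("-", s)))
  if (grepl("^-*$", s)) stop("sequence is all gaps")
  sg <- gsub("-", "", s)
  count_stops <- function(f) {
    n <- nchar(sg) - f + 1L
    n <- n - n %% 3L
    if (n < 3L) return(NA_integer_)
    codons <- substring(sg, seq(f, f + n - 3L, by = 3L),
                        seq(f + 2L, f + n - 1L, by = 3L))
    sum(translate_codons(codons, tbl) == "*")
  }
  if (is.null(frame)) {
    stops <- vapply(1:3, count_stops, integer(1))
    frame <- which.min(stops)
    nstop <- stops[frame]
  } else {
    stopifnot(frame %in% 1:3)
    nstop <- count_stops(frame)
  }
  if (is.na(nstop)) stop("ungapped length < 3 in chosen frame")
  list(ok = (nstop == 0L && internal_gaps == 0L),
       stop_codons = as.integer(nstop),
       internal_gaps = as.integer(internal_gaps),
       frame = as.integer(frame))
}

#' Flag putative contaminant sequences
#'
#' A record is flagged when its minimum K2P distance to every reference
#' exceeds `max_divergence`. The default 0.30 sits far above intraspecific
#' barcode divergences yet far below the chironomid-level contamination it
#' screens for.
#'
#' @param x aligned `barcode_aln` to screen
#' @param references aligned `barcode_aln` of trusted conspecific sequences
#'   (same gene, same alignment coordinates)
#' @param max_divergence K2P distance threshold (fraction)
#' @return data frame with columns `id`, `min_distance`, `status`
#'   (`"flagged"` or `"uncomparable"`); zero rows when nothing is flagged
#' @export
flag_contaminants <- function(x, references, max_divergence = 0.30) {
  if (length(references) == 0L) stop("references must be non-empty")
  out <- data.frame(id = character(0), min_distance = numeric(0),
                    status = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(x$seq)) {
    ds <- vapply(references$seq, function(r)
      k2p(x$seq[i], r)$distance, numeric(1), USE.NAMES = FALSE)
    if (all(is.na(ds))) {
      out <- rbind(out, data.frame(id = x$id[i], min_distance = NA_real_,
                                   status = "uncomparable"))
    } else if (min(ds, na.rm = TRUE) > max_divergence) {
      out <- rbind(out, data.frame(id = x$id[i],
                                   min_distance = min(ds, na.rm = TRUE),
                                   status = "flagged"))
    }
  }
  out
}
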
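# Sequence handling: RNA alphabet, circular overlapping k-mer counting, and
# the flow-balance constraint algebra that fixes which parameter combinations
# are identifiable.

RNA_BASES <- c("A", "C", "G", "U")

#' All RNA k-mers in lexicographic order
#'
#' Enumerates k-mers over the RNA alphabet in lexicographic order with
#' `A < C < G < U`. All count vectors, parameter tables and design-matrix
#' columns in this package use this order.
#'
#' @param width k-mer width (1, 2 or 3 in practice).
#' @return Character vector of length `4^width`.
#' @examples
#' kmer_alphabet(2)[1:5]
#' @export
kmer_alphabet <- function(width) {
  stopifnot(is.numeric(width), length(width) == 1, width >= 1)
  grids <- rev(rep(list(RNA_BASES), width))
  mat <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  apply(mat[, rev(seq_len(width)), drop = FALSE], 1, paste0, collapse = "")
}

#' Normalize a nucleotide sequence to uppercase RNA
#'
#' Validates and canonicalizes sequences to the RNA alphabet `A,C,G,U`
#' (5'->3'). DNA input is transliterated `T -> U`. Ambiguity codes
#' (`N`, `R`, `Y`, ...) and gaps are rejected: the triplet model assigns
#' them no meaning.
#'
#' @param x Character vector of sequences.
#' @param min_length Minimum accepted length (default 1; counting functions
#'   require 3 under circular topology).
#' @return Character vector of validated uppercase RNA sequences, same length
#'   as `x`, names preserved.
#' @examples
#' as_rna(c("acgt", "ACGU"))
#' @export
as_rna <- function(x, min_length = 1) {
  if (!is.character(x) || length(x) == 0) {
    abort("`x` must be a non-empty character vector of sequences.")
  }
  out <- chartr("t", "u", toupper(x))
  out <- chartr("T", "U", out)
  bad_len <- !is.na(out) & nchar(out) < min_length
  if (any(is.na(out))) abort("sequences must not be NA.")
  if (any(bad_len)) {
    abort(sprintf(
      "sequence(s) %s shorter than %d residues.",
      paste(which(bad_len), collapse = ", "), min_length
    ))
  }
  ok <- !grepl("[^ACGU]", out)
  if (!all(ok)) {
    offender <- regmatches(out[!ok][1], regexpr("[^ACGU]", out[!ok][1]))
    abort(sprintf(
      "invalid residue '%s' in sequence %d: alphabet is A,C,G,U (T transliterated).",
      offender, which(!ok)[1]
    ))
  }
  out
}

#' Antisense complement with DNA/RNA transliteration
#'
#' Maps a 5'->3' antisense strand to its 5'->3' target (reverse complement),
#' transliterating between DNA and RNA alphabets. Applying the map twice with
#' matching alphabets returns the input.
#'
#' @param x Character vector of sequences (DNA or RNA; validated).
#' @param output Output alphabet, `"rna"` (default) or `"dna"`.
#' @return Character vector of reverse-complemented sequences.
#' @examples
#' antisense_complement("TCCC")         # the GGGA motif on the mRNA strand
#' antisense_complement("GGGA", "dna")  # back again
#' @export
antisense_complement <- function(x, output = c("rna", "dna")) {
  output <- match.arg(output)
  rna <- as_rna(x)
  comp <- chartr("ACGU", "UGCA", rna)
  out <- vapply(
    strsplit(comp, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
  if (output == "dna") out <- chartr("U", "T", out)
  names(out) <- names(x)
  out
}

#' Count overlapping k-mers of circular or linear sequences
#'
#' Decomposes each sequence into its overlapping k-mers. Under circular
#' topology every one of the L positions starts a window (the last windows
#' wrap around the 5' end), so counts sum to exactly L; under linear
#' topology there are L-k+1 windows. Model fitting and scoring in this
#' package always use the circular convention, which eliminates end-window
#' terms at the cost of approximating the two seam windows.
#'
#' @param x Character vector of sequences (validated via [as_rna()]).
#' @param width k-mer width: 3 for the triplet (NNN) model, 2 for the
#'   doublet (NN) model.
#' @param topology `"circular"` (default; required length >= width) or
#'   `"linear"`.
#' @return Integer matrix with one row per sequence and `4^width` columns
#'   named by [kmer_alphabet()]; row names taken from `names(x)`.
#' @examples
#' count_kmers("ACUACUACUACU", width = 3)[, c("ACU", "CUA", "UAC")]
#' @export
count_kmers <- function(x, width = 3, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(width >= 1)
  seqs <- as_rna(x, min_length = if (topology == "circular") width else width)
  kmers <- kmer_alphabet(width)
  n_kmers <- length(kmers)
  counts <- matrix(0L, nrow = length(seqs), ncol = n_kmers,
                   dimnames = list(names(x), kmers))
  pow <- 4L^((width - 1L):0L)
  for (i in seq_along(seqs)) {
    code <- match(strsplit(seqs[[i]], "", fixed = TRUE)[[1]], RNA_BASES) - 1L
    L <- length(code)
    if (topology == "circular") {
      code <- c(code, code[seq_len(width - 1L)])
      starts <- seq_len(L)
    } else {
      starts <- seq_len(L - width + 1L)
    }
    idx <- rep(0L, length(starts))
    for (off in 0:(width - 1L)) {
      idx <- idx + code[starts + off] * pow[off + 1L]
    }
    tab <- tabulate(idx + 1L, nbins = n_kmers)
    counts[i, ] <- tab
  }
  counts
}

#' Circular triplet counts of target sequences
#'
#' Tidy wrapper around [count_kmers()] for the 64 next-nearest-neighbor
#' triplets: one row per sequence with an identifier column followed by the
#' 64 triplet-count columns in lexicographic order.
#'
#' @param data Data frame with a sequence column, or a bare character vector.
#' @param sequence Name of the sequence column (default `"sequence"`).
#' @param id Name of the identifier column (default `"id"`; created from
#'   names or position if absent).
#' @param topology Passed to [count_kmers()].
#' @return A tibble: `id` plus 64 integer columns `AAA` ... `UUU`.
#' @examples
#' triplet_counts(c(x = "ACUACUACUACU"))
#' @export
triplet_counts <- function(data, sequence = "sequence", id = "id",
                           topology = "circular") {
  kmer_count_tbl(data, sequence, id, width = 3, topology = topology)
}

#' Circular doublet counts of target sequences
#'
#' As [triplet_counts()] but for the 16 nearest-neighbor doublets.
#'
#' @inheritParams triplet_counts
#' @return A tibble: `id` plus 16 integer columns `AA` ... `UU`.
#' @export
doublet_counts <- function(data, sequence = "sequence", id = "id",
                           topology = "circular") {
  kmer_count_tbl(data, sequence, id, width = 2, topology = topology)
}

kmer_count_tbl <- function(data, sequence, id, width, topology) {
  if (is.character(data)) {
    ids <- names(data) %||% as.character(seq_along(data))
    seqs <- unname(data)
  } else {
    data <- tibble::as_tibble(data)
    if (!sequence %in% names(data)) {
      abort(sprintf("column '%s' not found.", sequence))
    }
    seqs <- data[[sequence]]
    ids <- if (id %in% names(data)) as.character(data[[id]]) else
      as.character(seq_len(nrow(data)))
  }
  m <- count_kmers(seqs, width = width, topology = topology)
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m))
}

#' Flow-balance constraint matrix for circular k-mer counts
#'
#' In a closed circular sequence every (k-1)-mer is entered and exited
#' equally often, so the overlapping k-mer counts obey one linear balance
#' equation per (k-1)-mer. For triplets this gives 16 equations of rank 15;
#' for doublets, 4 equations of rank 3. Every circular count vector is
#' annihilated by every row, so triplet count vectors span only a
#' 64 - 15 = 49 dimensional space: at most 49 sequences can have linearly
#' independent triplet composition.
#'
#' @param order `"triplet"` (default) or `"doublet"`.
#' @return Integer matrix (16 x 64 or 4 x 16) with k-mer column names and
#'   (k-1)-mer row names; entries in -1, 0, 1.
#' @examples
#' qr(constraint_matrix("triplet"))$rank  # 15
#' @export
constraint_matrix <- function(order = c("triplet", "doublet")) {
  order <- match.arg(order)
  width <- if (order == "triplet") 3L else 2L
  kmers <- kmer_alphabet(width)
  stems <- kmer_alphabet(width - 1L)
  m <- matrix(0L, nrow = length(stems), ncol = length(kmers),
              dimnames = list(stems, kmers))
  pre <- substr(kmers, 1L, width - 1L)
  suf <- substr(kmers, 2L, width)
  for (s in stems) {
    m[s, ] <- as.integer(pre == s) - as.integer(suf == s)
  }
  m
}

#' Read sequences from a FASTA file
#'
#' Reads a FASTA file into a two-column tibble, transliterating to uppercase
#' RNA. Description lines are preserved as identifiers.
#'
#' @param path Path to a FASTA file (DNA or RNA).
#' @param as Strand interpretation: `"target"` (default) keeps sequences as
#'   the mRNA target strand; `"antisense"` reverse-complements them onto the
#'   target strand first.
#' @return Tibble with columns `id` and `sequence` (uppercase RNA).
#' @export
read_fasta <- function(path, as = c("target", "antisense")) {
  as <- match.arg(as)
  if (!file.exists(path)) abort(sprintf("FASTA file '%s' not found.", path))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    set <- Biostrings::readBStringSet(path)
    ids <- names(set)
    seqs <- as.character(set)
  } else {
    lines <- readLines(path)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) abort("no FASTA records found.")
    rec <- cumsum(hdr)
    ids <- sub("^>", "", lines[hdr])
    seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste0, character(1),
                   collapse = "")
  }
  seqs <- as_rna(seqs)
  if (as == "antisense") seqs <- antisense_complement(seqs)
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}
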
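# Applying a parameter table to sequences: summed triplet scores with
# covariate offsets and propagated errors, window scanning of full mRNAs,
# independence/estimability diagnostics, and the gene-minus-average
# transform.

#' Score target sequences with a parameter table
#'
#' Predicts the percent reduction in net accumulated protein for each
#' circular target sequence as the inner product of its 64 circular triplet
#' counts with the triplet parameters, plus the offsets for an optionally
#' specified cell line and gene. Individual triplet parameters are not
#' meaningful alone, but this sum is unique for any realizable sequence.
#' Covariate offsets are constants per cell/gene, so rankings within one
#' context do not depend on them.
#'
#' Standard errors use the full covariance matrix when the table carries one
#' (`se_method = "covariance"`); otherwise the root-sum-of-squares of the
#' component standard errors is reported and labelled
#' (`se_method = "rss"`) — an approximation that ignores covariances.
#'
#' @param params An `nnn_params` parameter table.
#' @param data Data frame with `id` and `sequence` columns, or a character
#'   vector of sequences.
#' @param cell Optional cell-line label. Labels present in the table add
#'   their offset; a label listed as the table's `cell_baseline` adds 0;
#'   other labels are an error.
#' @param gene Optional gene label (must be present in the table).
#' @param components If TRUE, attach a list-column of per-triplet
#'   count-weighted contributions.
#' @return Tibble with columns `id`, `sequence`, `P` (predicted %
#'   reduction), `se`, `se_method`, and optionally `components`.
#' @examples
#' score_sequence(antisense_params(), c("ACUACUACUACU", "GGGAUCGGGAUC"))
#' @export
score_sequence <- function(params, data, cell = NULL, gene = NULL,
                           components = FALSE) {
  stopifnot(inherits(params, "nnn_params"))
  if (is.character(data)) {
    data <- tibble::tibble(
      id = names(data) %||% as.character(seq_along(data)),
      sequence = unname(data)
    )
  }
  data <- tibble::as_tibble(data)
  if (!"sequence" %in% names(data)) abort("column 'sequence' not found.")
  if (!"id" %in% names(data)) data$id <- as.character(seq_len(nrow(data)))
  counts <- count_kmers(data$sequence, width = 3, topology = "circular")

  trip <- params[params$type == "triplet", ]
  est <- setNames(trip$estimate, trip$term)[colnames(counts)]
  se_trip <- setNames(trip$std_error, trip$term)[colnames(counts)]
  offset <- 0
  offset_terms <- character()
  if (!is.null(cell)) {
    offset <- offset + covariate_offset(params, "cell", cell,
                                        allow_baseline = TRUE)
    if (covariate_present(params, "cell", cell)) {
      offset_terms <- c(offset_terms, paste0("cell:", cell))
    }
  }
  if (!is.null(gene)) {
    offset <- offset + covariate_offset(params, "gene", gene,
                                        allow_baseline = FALSE)
    offset_terms <- c(offset_terms, paste0("gene:", gene))
  }
  P <- drop(counts %*% est) + offset

  covariance <- attr(params, "covariance")
  if (!is.null(covariance)) {
    se <- vapply(seq_len(nrow(counts)), function(i) {
      w <- c(counts[i, ], setNames(rep(1, length(offset_terms)), offset_terms))
      names(w)[seq_len(ncol(counts))] <- colnames(counts)
      propagate_error(covariance, w)
    }, numeric(1))
    se_method <- "covariance"
  } else if (all(!is.na(se_trip))) {
    cov_rows <- params[params$type != "triplet", ]
    se_off2 <- 0
    for (tt in offset_terms) {
      lab <- sub("^(cell|gene):", "", tt)
      ty <- sub(":.*$", "", tt)
      s <- cov_rows$std_error[cov_rows$type == ty & cov_rows$term == lab]
      if (length(s) == 1 && !is.na(s)) se_off2 <- se_off2 + s^2
    }
    se <- sqrt(drop(counts^2 %*% se_trip^2) + se_off2)
    se_method <- "rss"
  } else {
    se <- NA_real_
    se_method <- NA_character_
  }

  out <- tibble::tibble(
    id = data$id, sequence = as_rna(data$sequence), P = P, se = se,
    se_method = se_method
  )
  if (components) {
    out$components <- lapply(seq_len(nrow(counts)), function(i) {
      nz <- counts[i, ] > 0
      tibble::tibble(triplet = colnames(counts)[nz],
                     count = counts[i, nz],
                     contribution = counts[i, nz] * est[nz])
    })
  }
  out
}

covariate_present <- function(params, type, label) {
  any(params$type == type & params$term == label)
}

covariate_offset <- function(params, type, label, allow_baseline) {
  hit <- params$type == type & params$term == label
  if (any(hit)) return(params$estimate[hit][1])
  meta <- attr(params, "meta")
  key <- paste0(type, "_baseline")
  baseline <- if (key %in% names(meta)) meta[[key]] else character()
  if (allow_baseline && length(baseline) == 1 &&
      label %in% strsplit(baseline, ",")[[1]]) {
    return(0)
  }
  abort(sprintf("unknown %s label '%s' for this parameter table.", type, label))
}

#' Scan an mRNA with a sliding scoring window
#'
#' Scores every length-`window` subsequence of a linear mRNA, circularizing
#' each window before counting (the same closed-circle convention used in
#' fitting, so window scores are directly comparable to whole-target
#' scores). Output is ranked by predicted reduction, ties broken by start
#' position; coordinates are 0-based half-open on the input mRNA.
#'
#' @inheritParams score_sequence
#' @param mrna A single mRNA sequence (character) or a one-row data frame
#'   with `id`/`sequence`.
#' @param window Window length (>= 3; default 20, the oligomer length of
#'   the reference experiments).
#' @return Tibble: `id`, `start`, `end`, `window`, `P`, `se`, `se_method`,
#'   sorted by `P` descending then `start` ascending. Classed
#'   `nnn_scan` for `autoplot()`.
#' @export
scan_windows <- function(params, mrna, window = 20, cell = NULL,
                         gene = NULL) {
  if (is.character(mrna) && length(mrna) == 1) {
    mrna <- tibble::tibble(id = names(mrna) %||% "mrna", sequence = mrna)
  }
  mrna <- tibble::as_tibble(mrna)
  stopifnot(nrow(mrna) == 1)
  seq1 <- as_rna(mrna$sequence)
  if (window < 3) abort("`window` must be >= 3.")
  L <- nchar(seq1)
  if (window > L) abort("`window` longer than the mRNA.")
  starts <- 0:(L - window)
  windows <- substring(seq1, starts + 1, starts + window)
  scored <- score_sequence(params, windows, cell = cell, gene = gene)
  out <- tibble::tibble(
    id = mrna$id %||% "mrna",
    start = starts, end = starts + window, window = windows,
    P = scored$P, se = scored$se, se_method = scored$se_method
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$P), .data$start)
  class(out) <- c("nnn_scan", class(out))
  out
}

#' @rdname scan_windows
#' @param object An `nnn_scan` result.
#' @param ... Unused.
#' @method autoplot nnn_scan
#' @export
autoplot.nnn_scan <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$start)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$P)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "window start (0-based)",
                  y = "predicted reduction in accumulated protein (%)",
                  title = unique(df$id))
}

#' Write scan results as TSV or BED
#'
#' @param scan An `nnn_scan` tibble.
#' @param path Output file.
#' @param format `"tsv"` (default; id, start, end, window, P, se) or
#'   `"bed"` (6 columns, P in the score field).
#' @param header Optional `# ` comment lines (config echo).
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, format = c("tsv", "bed"), header = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    con <- file(path, "w")
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    close(con)
    readr::write_tsv(tibble::as_tibble(scan)[
      c("id", "start", "end", "window", "P", "se")
    ], path, append = !is.null(header), col_names = TRUE)
  } else {
    bed <- tibble::tibble(
      chrom = scan$id, chromStart = scan$start, chromEnd = scan$end,
      name = scan$window, score = scan$P, strand = "+"
    )
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}

#' Linear independence of a set of circular sequences
#'
#' Builds the 64-row matrix whose columns are the circular triplet count
#' vectors of the given sequences and ranks it by SVD. A set is independent
#' exactly when the rank equals the number of sequences; at most 49
#' sequences can be independent. For a dependent set, one expressible
#' dependency (a null-space combination) is returned.
#'
#' @param data Character vector of sequences or data frame with
#'   `id`/`sequence` columns.
#' @param tol Relative singular-value tolerance (default `1e-8`).
#' @return Object of class `nnn_independence`: `n`, `rank`,
#'   `smallest_nonzero_sv`, `verdict` (`"independent"`/`"dependent"`),
#'   `dependency` (named numeric vector, or NULL), and the count matrix
#'   dimensions.
#' @export
check_independence <- function(data, tol = 1e-8) {
  if (is.character(data)) {
    data <- tibble::tibble(id = names(data) %||% data, sequence = unname(data))
  }
  data <- tibble::as_tibble(data)
  if (!"sequence" %in% names(data)) abort("column 'sequence' not found.")
  ids <- if ("id" %in% names(data)) as.character(data$id) else data$sequence
  m <- t(count_kmers(data$sequence, width = 3, topology = "circular"))
  colnames(m) <- ids
  dec <- svd(m)
  keep <- dec$d >= tol * max(dec$d)
  rank <- sum(keep)
  dependency <- NULL
  if (rank < ncol(m)) {
    v <- dec$v[, ncol(m)]
    v <- v / v[which.max(abs(v))]
    v[abs(v) < 1e-9] <- 0
    dependency <- setNames(v, ids)
    dependency <- dependency[dependency != 0]
  }
  structure(
    list(
      n = ncol(m), dims = dim(m), rank = rank,
      smallest_nonzero_sv = min(dec$d[keep]),
      verdict = if (rank == ncol(m)) "independent" else "dependent",
      dependency = dependency,
      singular_values = dec$d
    ),
    class = "nnn_independence"
  )
}

#' @export
print.nnn_independence <- function(x, ...) {
  cat(sprintf("<nnn_independence> rank %d / %d: %s\n",
              x$rank, x$n, x$verdict))
  if (!is.null(x$dependency)) {
    cat("  one dependency:",
        paste(sprintf("%+.3g x %s", x$dependency, names(x$dependency)),
              collapse = " "), "= 0\n")
  }
  invisible(x)
}

#' Gene offsets relative to their average
#'
#' Re-expresses the per-gene covariate parameters as differences from their
#' mean. With all gene indicator columns present (summing to one) only
#' contrasts among genes are estimable; the centered offsets are one such
#' independent set (any three determine the fourth, since they sum to
#' zero). Standard errors use the table's covariance matrix when present.
#'
#' @param params An `nnn_params` table with at least two `gene` entries, or
#'   an `nnn_fit`.
#' @return Tibble with columns `term`, `offset` (gene parameter minus the
#'   gene-parameter mean, %), and `se` (NA without a covariance matrix).
#' @examples
#' gene_minus_average(antisense_params())
#' @export
gene_minus_average <- function(params) {
  if (inherits(params, "nnn_fit")) params <- as_parameter_table(params)
  stopifnot(inherits(params, "nnn_params"))
  genes <- params[params$type == "gene", ]
  if (nrow(genes) < 2) abort("at least two gene parameters are required.")
  offsets <- genes$estimate - mean(genes$estimate)
  covariance <- attr(params, "covariance")
  se <- rep(NA_real_, nrow(genes))
  if (!is.null(covariance)) {
    g_names <- paste0("gene:", genes$term)
    if (all(g_names %in% colnames(covariance))) {
      k <- nrow(genes)
      se <- vapply(seq_len(k), function(i) {
        w <- setNames(rep(-1 / k, k), g_names)
        w[g_names[i]] <- 1 - 1 / k
        propagate_error(covariance, w)
      }, numeric(1))
    }
  }
  tibble::tibble(term = genes$term, offset = offsets, se = se)
}

#' Nearest-neighbor free energy of a circular sequence
#'
#' Sums user-supplied dinucleotide stacking free energies
#' (`ΔG°(37°C)`, kcal/mol) over the 16 circular doublet counts of each
#' sequence, for comparison of in-vitro hybrid-stability predictions with
#' the in-vivo triplet model. No free-energy values ship with the package.
#'
#' @param data Character vector of sequences or data frame with
#'   `id`/`sequence`.
#' @param nn_table Complete named numeric vector of 16 doublet free
#'   energies (names `AA` ... `UU` on the mRNA strand), or a data frame
#'   with columns `doublet` and `dg`.
#' @return Tibble with columns `id`, `sequence`, `dg_total` (kcal/mol).
#' @export
nn_free_energy <- function(data, nn_table) {
  if (is.data.frame(nn_table)) {
    nn_table <- setNames(nn_table$dg, nn_table$doublet)
  }
  missing <- setdiff(kmer_alphabet(2), names(nn_table))
  if (length(missing) > 0) {
    abort(sprintf("nn_table is missing doublet(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (is.character(data)) {
    data <- tibble::tibble(
      id = names(data) %||% as.character(seq_along(data)),
      sequence = unname(data)
    )
  }
  data <- tibble::as_tibble(data)
  counts <- count_kmers(data$sequence, width = 2, topology = "circular")
  dg <- drop(counts %*% nn_table[colnames(counts)])
  tibble::tibble(
    id = if ("id" %in% names(data)) as.character(data$id) else
      as.character(seq_len(nrow(data))),
    sequence = as_rna(data$sequence),
    dg_total = dg
  )
}
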
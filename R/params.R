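# Parameter tables: named triplet and covariate inhibition parameters with
# standard errors, optional full covariance, and a sectioned plain-text
# serialization. A published table of fitted parameters ships with the
# package for immediate scoring.

#' Construct a parameter table
#'
#' @param data Data frame with columns `term`, `type` (`"triplet"`,
#'   `"cell"` or `"gene"`), `estimate`, and optionally `std_error`.
#' @param covariance Optional covariance matrix; dimnames must use design
#'   column names (`AAA`, ..., `cell:<label>`, `gene:<label>`).
#' @param meta Named character vector of free-text metadata (e.g.
#'   `cell_baseline`, `provenance`).
#' @return A tibble of class `nnn_params` with the covariance and metadata
#'   carried as attributes.
#' @export
parameter_table <- function(data, covariance = NULL, meta = character()) {
  data <- tibble::as_tibble(data)
  req <- c("term", "type", "estimate")
  missing <- setdiff(req, names(data))
  if (length(missing) > 0) {
    abort(sprintf("parameter table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (!"std_error" %in% names(data)) data$std_error <- NA_real_
  if (any(!is.na(data$std_error) & data$std_error < 0)) {
    abort("standard errors must be >= 0.")
  }
  trip <- data$term[data$type == "triplet"]
  if (!setequal(trip, kmer_alphabet(3)) || anyDuplicated(trip)) {
    abort("parameter table must contain each of the 64 triplets exactly once.")
  }
  data <- data[c("term", "type", "estimate", "std_error")]
  if (!is.null(covariance)) {
    stopifnot(is.matrix(covariance),
              nrow(covariance) == ncol(covariance),
              !is.null(colnames(covariance)))
  }
  structure(data, covariance = covariance, meta = meta,
            class = c("nnn_params", class(data)))
}

#' Extract the parameter table of a fit
#'
#' @param fit An `nnn_fit`.
#' @param covariance Attach the full covariance matrix (default TRUE), which
#'   enables exact error propagation in [score_sequence()].
#' @return An `nnn_params` parameter table.
#' @export
as_parameter_table <- function(fit, covariance = TRUE) {
  stopifnot(inherits(fit, "nnn_fit"))
  tt <- tidy(fit)
  term <- sub("^(cell|gene):", "", tt$term)
  type <- ifelse(tt$type == "kmer", "triplet", tt$type)
  if (fit$design$order != "triplet") {
    abort("parameter tables are defined for the triplet model.")
  }
  meta <- c(sv_rel_tolerance = format(fit$sv_rel_tolerance))
  if (fit$design$cell_covariate) {
    baseline <- setdiff(unique(fit$design$experiments$cell),
                        fit$design$sensitive_cell)
    if (length(baseline) > 0) {
      meta <- c(meta, cell_baseline = paste(baseline, collapse = ","))
    }
  }
  parameter_table(
    tibble::tibble(term = term, type = type, estimate = tt$estimate,
                   std_error = tt$std.error),
    covariance = if (covariance) fit$covariance else NULL,
    meta = meta
  )
}

param_design_names <- function(params) {
  ifelse(params$type == "triplet", params$term,
         paste0(params$type, ":", params$term))
}

#' Published antisense NNN inhibition parameters
#'
#' Loads the packaged table of next-nearest-neighbor antisense inhibition
#' parameters fitted to 112 cell-culture knockdown experiments (four gene
#' targets, two cell lines; values at the published two-decimal precision).
#' Each triplet parameter is the percent reduction in net accumulated
#' protein attributed to one occurrence of that mRNA triplet in a closed
#' circular 20-mer target; covariate entries hold the cell-line offset and
#' per-gene offsets. No covariance matrix accompanies the published values,
#' so propagated standard errors from this table use the labelled
#' root-sum-of-squares approximation.
#'
#' @return An `nnn_params` parameter table (64 triplets + 5 covariates).
#' @examples
#' score_sequence(antisense_params(), "ACUACUACUACU")$P  # 72.08
#' @export
antisense_params <- function() {
  path <- system.file("extdata", "antisense_nnn_params.txt",
                      package = "nnnfit", mustWork = TRUE)
  read_parameter_table(path)
}

#' Read or write a parameter table
#'
#' Sectioned plain text: an optional `[meta]` section of key/value lines, a
#' `[triplets]` section (`term estimate std_error`, tab separated), a
#' `[covariates]` section (`term type estimate std_error`), and an optional
#' `[covariance]` section (header of design column names, then numeric
#' rows). Values survive a round trip at 12 significant digits.
#'
#' @param path File path.
#' @return `read_parameter_table()`: an `nnn_params` table.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("parameter file '%s' not found.", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sec_at <- grep("^\\[", lines)
  if (length(sec_at) == 0) abort("no sections found in parameter file.")
  sections <- list()
  for (i in seq_along(sec_at)) {
    nm <- gsub("\\[|\\]", "", lines[sec_at[i]])
    to <- if (i < length(sec_at)) sec_at[i + 1] - 1 else length(lines)
    sections[[nm]] <- lines[seq(sec_at[i] + 1, length.out = max(0, to - sec_at[i]))]
  }
  meta <- character()
  if (!is.null(sections$meta)) {
    kv <- strsplit(sections$meta, "\t")
    meta <- setNames(vapply(kv, function(x) paste(x[-1], collapse = "\t"),
                            character(1)),
                     vapply(kv, `[`, character(1), 1))
  }
  parse_tsv <- function(ln) {
    readr::read_tsv(I(paste(ln, collapse = "\n")), col_types = readr::cols(),
                    progress = FALSE)
  }
  if (is.null(sections$triplets)) abort("parameter file lacks a [triplets] section.")
  trip <- parse_tsv(sections$triplets)
  trip$type <- "triplet"
  cov_tbl <- if (!is.null(sections$covariates) &&
                 length(sections$covariates) > 1) {
    parse_tsv(sections$covariates)
  } else NULL
  data <- dplyr::bind_rows(
    trip[c("term", "type", "estimate", "std_error")],
    if (!is.null(cov_tbl)) cov_tbl[c("term", "type", "estimate", "std_error")]
  )
  covariance <- NULL
  if (!is.null(sections$covariance) && length(sections$covariance) > 1) {
    hdr <- strsplit(sections$covariance[1], "\t")[[1]]
    rows <- lapply(sections$covariance[-1],
                   function(l) as.numeric(strsplit(l, "\t")[[1]]))
    covariance <- do.call(rbind, rows)
    dimnames(covariance) <- list(hdr, hdr)
  }
  parameter_table(data, covariance = covariance, meta = meta)
}

#' @rdname read_parameter_table
#' @param params An `nnn_params` table.
#' @param covariance Write the covariance section when present (default TRUE).
#' @param header Optional `# ` comment lines for provenance/config echo.
#' @export
write_parameter_table <- function(params, path, covariance = TRUE,
                                  header = NULL) {
  stopifnot(inherits(params, "nnn_params"))
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  meta <- attr(params, "meta")
  if (length(meta) > 0) {
    writeLines("[meta]", con)
    writeLines(paste(names(meta), meta, sep = "\t"), con)
  }
  trip <- params[params$type == "triplet", ]
  writeLines("[triplets]", con)
  writeLines("term\testimate\tstd_error", con)
  writeLines(paste(trip$term, fmt(trip$estimate), fmt(trip$std_error),
                   sep = "\t"), con)
  covs <- params[params$type != "triplet", ]
  if (nrow(covs) > 0) {
    writeLines("[covariates]", con)
    writeLines("term\ttype\testimate\tstd_error", con)
    writeLines(paste(covs$term, covs$type, fmt(covs$estimate),
                     fmt(covs$std_error), sep = "\t"), con)
  }
  cv <- attr(params, "covariance")
  if (covariance && !is.null(cv)) {
    writeLines("[covariance]", con)
    writeLines(paste(colnames(cv), collapse = "\t"), con)
    for (i in seq_len(nrow(cv))) {
      writeLines(paste(fmt(cv[i, ]), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' The packaged irreducible set of 49 independent 12-mers
#'
#' A maximal set of circular 12-mer sequences whose triplet count vectors
#' are linearly independent (the triplet count space of circular sequences
#' has dimension 64 - 15 = 49): the four homonucleotide repeats, six
#' repeating dinucleotides, twenty repeating trinucleotides and nineteen
#' repeating tetranucleotides. Any circular sequence's predicted inhibition
#' is a linear combination of the predictions for these sequences.
#'
#' @return Tibble with columns `name` (repeat-unit notation, e.g.
#'   `(ACU)4`) and `sequence` (the 12-mer).
#' @examples
#' check_independence(independent_sequence_set()$sequence)$rank  # 49
#' @export
independent_sequence_set <- function() {
  units <- c(
    # homonucleotides
    "A", "C", "G", "U",
    # dinucleotides
    "CG", "AG", "UG", "AU", "UC", "AC",
    # trinucleotides
    "ACU", "UUG", "UGC", "AUC", "UCC", "AGC", "CCG", "ACG", "AAG", "CGG",
    "AGG", "AAC", "UGG", "ACC", "UCG", "AUG", "AUU", "AGU", "AAU", "UUC",
    # tetranucleotides
    "AACU", "GGUC", "UUAG", "AACG", "GGUA", "UUGC", "AAGC", "CCUG", "GGAC",
    "UUCG", "UUCA", "GGCA", "GGAU", "AAUC", "GGCU", "UUAC", "CCAG", "AAUG",
    "AAGU"
  )
  reps <- 12L %/% nchar(units)
  tibble::tibble(
    name = sprintf("(%s)%d", units, reps),
    sequence = vapply(seq_along(units),
                      function(i) strrep(units[i], reps[i]), character(1))
  )
}

#' @export
print.nnn_params <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<nnn_params> %d triplet + %d covariate parameters%s\n",
              sum(x$type == "triplet"), sum(x$type != "triplet"),
              if (!is.null(attr(x, "covariance"))) " (with covariance)" else ""))
  if (length(meta) > 0) {
    cat(paste0("  ", names(meta), ": ", meta, collapse = "\n"), "\n")
  }
  NextMethod()
}
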
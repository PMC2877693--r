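# Experiment tables and the error-weighted linear system: one row per
# antisense experiment, k-mer count columns plus covariate indicators, every
# row and its response divided by that experiment's measurement error.

EXPERIMENT_COLS <- c("id", "target", "cell", "gene", "reduction", "error")

#' Validate an experiment table
#'
#' Checks and canonicalizes a table of antisense experiments. Each row is one
#' measurement: a target mRNA sequence (5'->3'), a cell-line label, a gene
#' label, the observed percent reduction in accumulated protein, and the
#' measurement standard error in the same units.
#'
#' @param data Data frame with columns `id`, `target`, `cell`, `gene`,
#'   `reduction`, `error`.
#' @param as Strand interpretation of the `target` column: `"target"`
#'   (default) or `"antisense"` (reverse-complemented onto the mRNA strand).
#' @return A tibble with validated columns; targets as uppercase RNA.
#' @export
validate_experiments <- function(data, as = c("target", "antisense")) {
  as <- match.arg(as)
  data <- tibble::as_tibble(data)
  missing <- setdiff(EXPERIMENT_COLS, names(data))
  if (length(missing) > 0) {
    abort(sprintf("experiment table is missing column(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(data) == 0) abort("experiment table has no rows.")
  for (col in c("reduction", "error")) {
    vals <- suppressWarnings(as.numeric(data[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      abort(sprintf("row %d: column '%s' is not numeric.", bad[1], col))
    }
    data[[col]] <- vals
  }
  bad_err <- which(data$error <= 0)
  if (length(bad_err) > 0) {
    abort(sprintf(
      "row %d: measurement error must be > 0 (weighting requires it).",
      bad_err[1]
    ))
  }
  targets <- tryCatch(
    as_rna(data$target, min_length = 3),
    error = function(e) abort(sprintf("invalid target sequence: %s",
                                      conditionMessage(e)))
  )
  if (as == "antisense") targets <- antisense_complement(targets)
  data$target <- unname(targets)
  data$id <- as.character(data$id)
  data$cell <- as.character(data$cell)
  data$gene <- as.character(data$gene)
  data[EXPERIMENT_COLS]
}

#' Read or write an experiment table
#'
#' Delimited text with a header row and columns
#' `id,target,cell,gene,reduction,error`. The delimiter is sniffed from the
#' extension/content (comma or tab) unless given. Writing then reading
#' reproduces all values to full precision.
#'
#' @param path File path.
#' @param as Strand interpretation, see [validate_experiments()].
#' @param delim Field delimiter; `NULL` (default) sniffs `,` vs tab.
#' @return `read_experiments()`: validated tibble of experiments.
#' @export
read_experiments <- function(path, as = c("target", "antisense"),
                             delim = NULL) {
  if (!file.exists(path)) abort(sprintf("experiment file '%s' not found.", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), comment = "#", progress = FALSE)
  validate_experiments(raw, as = as)
}

#' @rdname read_experiments
#' @param data Experiment tibble (validated on the way out).
#' @export
write_experiments <- function(data, path, delim = ",") {
  data <- validate_experiments(data)
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Build the error-weighted design matrix
#'
#' Assembles the weighted linear system for an experiment table: each row
#' holds the circular k-mer counts of the target (64 triplets or 16
#' doublets), optionally a single cell-line indicator (1 for the designated
#' sensitive cell line, 0 otherwise) and one indicator column per gene
#' (exactly one 1 per row, so the gene columns sum to one before weighting).
#' Every row and its response entry are then divided by that experiment's
#' error, so ordinary least squares on the result is the chi-square
#' (variance-weighted) fit.
#'
#' With the full triplet model, two cell lines and four genes this is the
#' 112 x 69 system of the reference analysis; the gene sum-to-one dependency
#' plus the 15 circular-count constraints make 16 exact null directions.
#'
#' @param data Experiment table (see [validate_experiments()]).
#' @param order `"triplet"` (default) or `"doublet"` feature block.
#' @param cell_covariate Include the cell indicator column (default TRUE).
#' @param gene_covariate Include the per-gene indicator block (default TRUE).
#' @param sensitive_cell Which cell label carries the 1 in the cell column;
#'   default the lexicographically first label.
#' @return An object of class `nnn_design`: list with weighted matrix `X`,
#'   weighted response `y`, unweighted `X0`/`y0`, `sigma`, `column_names`,
#'   the feature/covariate split, and the experiment table.
#' @examples
#' ex <- simulate_experiments(generate_truth(seed = 1), n = 8, seed = 2)
#' dim(build_design(ex)$X)
#' @export
build_design <- function(data, order = c("triplet", "doublet"),
                         cell_covariate = TRUE, gene_covariate = TRUE,
                         sensitive_cell = NULL) {
  order <- match.arg(order)
  data <- validate_experiments(data)
  width <- if (order == "triplet") 3L else 2L
  counts <- count_kmers(data$target, width = width, topology = "circular")
  blocks <- list(counts)
  types <- rep("kmer", ncol(counts))

  cell_label <- NULL
  if (cell_covariate) {
    cells <- sort(unique(data$cell))
    cell_label <- sensitive_cell %||% cells[1]
    if (!cell_label %in% cells) {
      abort(sprintf("sensitive_cell '%s' not among cell labels (%s).",
                    cell_label, paste(cells, collapse = ", ")))
    }
    cell_col <- matrix(as.numeric(data$cell == cell_label), ncol = 1,
                       dimnames = list(NULL, paste0("cell:", cell_label)))
    blocks <- c(blocks, list(cell_col))
    types <- c(types, "cell")
  }
  if (gene_covariate) {
    genes <- sort(unique(data$gene))
    gene_block <- vapply(genes, function(g) as.numeric(data$gene == g),
                         numeric(nrow(data)))
    gene_block <- matrix(gene_block, ncol = length(genes),
                         dimnames = list(NULL, paste0("gene:", genes)))
    blocks <- c(blocks, list(gene_block))
    types <- c(types, rep("gene", length(genes)))
  }
  X0 <- do.call(cbind, blocks)
  y0 <- data$reduction
  sigma <- data$error
  X <- X0 / sigma
  y <- y0 / sigma
  structure(
    list(
      X = X, y = y, X0 = X0, y0 = y0, sigma = sigma,
      column_names = colnames(X0), column_types = types,
      order = order, cell_covariate = cell_covariate,
      gene_covariate = gene_covariate, sensitive_cell = cell_label,
      experiments = data
    ),
    class = "nnn_design"
  )
}

#' @export
print.nnn_design <- function(x, ...) {
  cat(sprintf(
    "<nnn_design> %d experiments x %d columns (%s model%s%s)\n",
    nrow(x$X), ncol(x$X), x$order,
    if (x$cell_covariate) sprintf(", cell covariate [%s]", x$sensitive_cell) else "",
    if (x$gene_covariate) sprintf(", %d gene columns",
                                  sum(x$column_types == "gene")) else ""
  ))
  invisible(x)
}

#' @export
dim.nnn_design <- function(x) dim(x$X)
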
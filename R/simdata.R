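# Synthetic experiment generator: random 20-mer targets under the
# oligomer-selection constraints (G+C content 30-85%, no more than three
# adjacent G's), linear triplet effects plus cell/gene offsets, Gaussian
# noise with known per-experiment errors. The generator targets the
# statistical structure of the linear model, not cellular mechanism, so it
# supports fitting, identifiability and calibration studies without any
# laboratory data.

#' Generate a synthetic ground truth
#'
#' Draws 64 true triplet inhibition parameters i.i.d. Gaussian with the
#' given spread and stores cell/gene offsets and the noise range. Defaults
#' are sized to the reference analysis: fitted triplet parameters span
#' roughly -9 to +13% (standard deviation near 5), the sensitive cell line
#' adds about 10.6%, and gene offsets of a few percent either side of zero.
#'
#' @param seed Integer seed; the truth is fully reproducible from it.
#' @param triplet_sd Spread (SD, %) of the true triplet parameters
#'   (default 5; 0 gives all-zero triplet effects).
#' @param cell_offset Additive offset (%) for the sensitive cell line
#'   (default 10.6).
#' @param gene_offsets Named numeric vector of per-gene offsets (%).
#' @param sigma_range Range (%) from which per-experiment measurement
#'   errors are drawn uniformly (default 3-10).
#' @return Object of class `nnn_truth`.
#' @examples
#' tr <- generate_truth(seed = 1)
#' range(tr$triplet)
#' @export
generate_truth <- function(seed, triplet_sd = 5, cell_offset = 10.6,
                           gene_offsets = c(CRAF1 = 3.65, BCL2 = -3.10,
                                            AKT2 = 8.97, "PKC-a" = -3.75),
                           sigma_range = c(3, 10)) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (triplet_sd < 0) abort("`triplet_sd` must be >= 0.")
  if (any(sigma_range <= 0) || sigma_range[2] < sigma_range[1]) {
    abort("`sigma_range` must be positive and increasing.")
  }
  if (is.null(names(gene_offsets))) {
    names(gene_offsets) <- paste0("gene", seq_along(gene_offsets))
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  triplet <- setNames(rnorm(64, 0, triplet_sd), kmer_alphabet(3))
  structure(
    list(triplet = triplet, cell_offset = cell_offset,
         gene_offsets = gene_offsets, sigma_range = sigma_range,
         seed = as.integer(seed)),
    class = "nnn_truth"
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.nnn_truth <- function(x, ...) {
  cat(sprintf(
    "<nnn_truth> seed %d: triplet params in [%.2f, %.2f], cell offset %.2f, genes %s\n",
    x$seed, min(x$triplet), max(x$triplet), x$cell_offset,
    paste(sprintf("%s=%.2f", names(x$gene_offsets), x$gene_offsets),
          collapse = " ")
  ))
  invisible(x)
}

#' Simulate an antisense experiment table
#'
#' Draws random target 20-mers by rejection sampling under the
#' oligomer-selection constraints, assigns cell and gene labels, and
#' generates observed reductions as the circular triplet score under the
#' truth plus covariate offsets plus Gaussian noise whose per-experiment
#' standard deviation is drawn uniformly from `sigma_range` and recorded as
#' the experiment's error. The constraints (G+C fraction and maximum G run)
#' apply to the linear oligomer; the antisense strand has the same G+C
#' fraction as its target, so the check is made on the target directly.
#'
#' With `layout = "reference"` (the default when `n = 112` with two cells
#' and four genes) the cell/gene composition of the reference database is
#' reproduced: 26 shared targets of the first gene measured in both cell
#' lines, then 29, 7 and 24 targets of the remaining genes in a single cell
#' line each. Otherwise labels are assigned uniformly at random.
#'
#' @param truth An `nnn_truth` from [generate_truth()].
#' @param n Number of experiments (default 112).
#' @param length Target length (default 20).
#' @param cells Cell-line labels; the lexicographically first is the
#'   sensitive line receiving `cell_offset`.
#' @param genes Gene labels (default from the truth's offsets).
#' @param gc_range Allowed G+C fraction range (default 0.30-0.85).
#' @param max_g_run Maximum run of adjacent G's (default 3).
#' @param sigma_range Per-experiment error range (%); default from truth.
#' @param seed Integer seed for this draw (default the truth's seed).
#' @param layout `"auto"`, `"reference"` or `"random"`; see Details.
#' @param noise If FALSE, observed reductions equal the model value exactly
#'   (errors are still drawn and recorded), giving an exactly solvable
#'   system for solver verification.
#' @return Validated experiment tibble (see [validate_experiments()]).
#' @examples
#' ex <- simulate_experiments(generate_truth(seed = 1), n = 12, seed = 3)
#' @export
simulate_experiments <- function(truth, n = 112, length = 20,
                                 cells = c("A549", "T24"),
                                 genes = names(truth$gene_offsets),
                                 gc_range = c(0.30, 0.85), max_g_run = 3,
                                 sigma_range = truth$sigma_range,
                                 seed = truth$seed,
                                 layout = c("auto", "reference", "random"),
                                 noise = TRUE) {
  stopifnot(inherits(truth, "nnn_truth"))
  layout <- match.arg(layout)
  if (n < 1) abort("`n` must be >= 1.")
  if (length < 3) abort("`length` must be >= 3.")
  if (gc_range[1] > gc_range[2] || gc_range[1] < 0 || gc_range[2] > 1) {
    abort("`gc_range` must be an increasing sub-interval of [0, 1].")
  }
  missing_genes <- setdiff(genes, names(truth$gene_offsets))
  if (length(missing_genes) > 0) {
    abort(sprintf("gene label(s) %s have no offset in the truth.",
                  paste(missing_genes, collapse = ", ")))
  }
  if (layout == "auto") {
    layout <- if (n == 112 && length(cells) == 2 && length(genes) == 4) {
      "reference"
    } else "random"
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))

  if (layout == "reference") {
    if (n != 112 || length(cells) != 2 || length(genes) != 4) {
      abort("the reference layout requires n = 112, 2 cells and 4 genes.")
    }
    shared <- draw_targets(26, length, gc_range, max_g_run)
    singles <- draw_targets(29 + 7 + 24, length, gc_range, max_g_run)
    assign_tbl <- tibble::tibble(
      target = c(shared, shared, singles),
      cell = c(rep(cells[1], 26), rep(cells[2], 26),
               rep(cells[1], 29), rep(cells[1], 7), rep(cells[2], 24)),
      gene = c(rep(genes[1], 52), rep(genes[2], 29), rep(genes[3], 7),
               rep(genes[4], 24))
    )
  } else {
    assign_tbl <- tibble::tibble(
      target = draw_targets(n, length, gc_range, max_g_run),
      cell = sample(cells, n, replace = TRUE),
      gene = sample(genes, n, replace = TRUE)
    )
  }
  sensitive <- sort(cells)[1]
  counts <- count_kmers(assign_tbl$target, width = 3, topology = "circular")
  signal <- drop(counts %*% truth$triplet) +
    truth$cell_offset * (assign_tbl$cell == sensitive) +
    unname(truth$gene_offsets[assign_tbl$gene])
  sigma <- runif(nrow(assign_tbl), sigma_range[1], sigma_range[2])
  reduction <- signal + if (noise) rnorm(nrow(assign_tbl), 0, sigma) else 0
  validate_experiments(tibble::tibble(
    id = sprintf("sim%03d", seq_len(nrow(assign_tbl))),
    target = assign_tbl$target, cell = assign_tbl$cell,
    gene = assign_tbl$gene, reduction = reduction, error = sigma
  ))
}

# rejection sampler for targets: aim at a uniformly drawn G+C fraction so
# the realized G+C spread covers the allowed range, then enforce the
# realized constraints exactly
draw_targets <- function(n, length, gc_range, max_g_run,
                         max_attempts = 1e5) {
  out <- character(n)
  g_run <- strrep("G", max_g_run + 1)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (attempt in seq_len(max_attempts)) {
      gc <- runif(1, gc_range[1], gc_range[2])
      s <- paste(sample(RNA_BASES, length, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
                 collapse = "")
      gc_real <- (nchar(gsub("[AU]", "", s))) / length
      if (gc_real >= gc_range[1] && gc_real <= gc_range[2] &&
          !grepl(g_run, s, fixed = TRUE)) {
        out[i] <- s
        ok <- TRUE
        break
      }
    }
    if (!ok) abort("target constraints appear infeasible (attempt cap hit).")
  }
  out
}

#' Compare estimable predictions of a fit against the generating truth
#'
#' Scores a set of circular probe sequences under both the truth and the
#' fitted parameters and reports the discrepancy in units of the propagated
#' standard error. Only sequence-level predictions are compared, never raw
#' parameter coordinates: with gene covariates present, predictions are
#' estimable for probes of the training length when a cell/gene context is
#' supplied (the gene indicator absorbs the level that is aliased with the
#' overall triplet sum), and for gene-free fits bare triplet predictions
#' are estimable at any length.
#'
#' @param truth An `nnn_truth`.
#' @param fit An `nnn_fit` of data generated from that truth.
#' @param probes Character vector of circular probe sequences.
#' @param cell,gene Optional context labels applied to both the true and
#'   fitted predictions.
#' @return Tibble: `probe`, `true_P`, `estimated_P`, `se`, `z`.
#' @export
recovery_report <- function(truth, fit, probes, cell = NULL, gene = NULL) {
  stopifnot(inherits(truth, "nnn_truth"), inherits(fit, "nnn_fit"))
  counts <- count_kmers(probes, width = 3, topology = "circular")
  cols <- names(fit$parameters)
  true_off <- 0
  extra <- character()
  if (!is.null(cell)) {
    cc <- paste0("cell:", cell)
    if (cc %in% cols) {
      true_off <- true_off + truth$cell_offset
      extra <- c(extra, cc)
    }
  }
  if (!is.null(gene)) {
    gg <- paste0("gene:", gene)
    if (!gg %in% cols) abort(sprintf("gene '%s' not in the fit.", gene))
    true_off <- true_off + unname(truth$gene_offsets[gene])
    extra <- c(extra, gg)
  }
  true_P <- drop(counts %*% truth$triplet) + true_off
  est_P <- numeric(nrow(counts))
  se <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    w <- setNames(numeric(length(cols)), cols)
    w[colnames(counts)] <- counts[i, ]
    w[extra] <- 1
    est_P[i] <- sum(w * fit$parameters)
    se[i] <- propagate_error(fit, w)
  }
  tibble::tibble(
    probe = unname(probes), true_P = true_P, estimated_P = est_P,
    se = se, z = (est_P - true_P) / se
  )
}

#' Write or read a synthetic truth file
#'
#' Sectioned plain text mirroring the parameter-table format: `[meta]`
#' (seed, cell offset, gene offsets, sigma range) and `[triplets]`.
#'
#' @param truth An `nnn_truth`.
#' @param path File path.
#' @return `path` (write) or an `nnn_truth` (read).
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "nnn_truth"))
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("[meta]", con)
  writeLines(paste("seed", truth$seed, sep = "\t"), con)
  writeLines(paste("cell_offset", fmt(truth$cell_offset), sep = "\t"), con)
  writeLines(paste("sigma_range", paste(fmt(truth$sigma_range),
                                        collapse = ","), sep = "\t"), con)
  writeLines(paste("gene_offsets",
                   paste(names(truth$gene_offsets),
                         fmt(truth$gene_offsets), sep = "=", collapse = ","),
                   sep = "\t"), con)
  writeLines("[triplets]", con)
  writeLines("term\tvalue", con)
  writeLines(paste(names(truth$triplet), fmt(truth$triplet), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  meta_at <- which(lines == "[meta]")
  trip_at <- which(lines == "[triplets]")
  meta_lines <- lines[seq(meta_at + 1, trip_at - 1)]
  kv <- strsplit(meta_lines, "\t")
  meta <- setNames(vapply(kv, `[`, character(1), 2),
                   vapply(kv, `[`, character(1), 1))
  gene_kv <- strsplit(strsplit(meta[["gene_offsets"]], ",")[[1]], "=")
  gene_offsets <- setNames(as.numeric(vapply(gene_kv, `[`, character(1), 2)),
                           vapply(gene_kv, `[`, character(1), 1))
  trip_lines <- lines[seq(trip_at + 2, length(lines))]
  tv <- strsplit(trip_lines, "\t")
  triplet <- setNames(as.numeric(vapply(tv, `[`, character(1), 2)),
                      vapply(tv, `[`, character(1), 1))
  structure(
    list(
      triplet = triplet[kmer_alphabet(3)],
      cell_offset = as.numeric(meta[["cell_offset"]]),
      gene_offsets = gene_offsets,
      sigma_range = as.numeric(strsplit(meta[["sigma_range"]], ",")[[1]]),
      seed = as.integer(meta[["seed"]])
    ),
    class = "nnn_truth"
  )
}
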
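# Rank-deficient weighted least squares by singular value decomposition.
# Singular values below a relative tolerance are treated as exactly zero:
# their reciprocals are excluded from both the minimum-norm solution and the
# covariance, so non-identifiable directions contribute nothing.

#' Fit the weighted linear system by SVD
#'
#' Solves the error-weighted system `X p = y` of an [build_design()] object
#' in the minimum-norm least-squares sense. The design is decomposed as
#' `X = U D V'`; singular values below `sv_rel_tolerance` times the largest
#' are zeroed and their modes dropped, giving the solution
#' `p = V_r D_r^{-1} U_r' y` and covariance `V_r D_r^{-2} V_r'`. Because
#' rows were pre-divided by their measurement errors, the residual sum of
#' squares of the weighted system is the chi-square statistic; degrees of
#' freedom are `n - effective_rank` (non-identifiable columns do not consume
#' degrees of freedom), and the goodness-of-fit probability Q is the
#' chi-square upper-tail probability at those degrees of freedom.
#'
#' Only estimable combinations of the parameters (those in the design's row
#' space) have unique values and standard errors; individual coordinates of
#' `parameters` follow the minimum-norm convention and are generally not
#' meaningful on their own.
#'
#' @param design An `nnn_design` from [build_design()].
#' @param sv_rel_tolerance Relative singular-value cutoff in (0, 1);
#'   default `1e-8`. Exact structural null directions sit many orders of
#'   magnitude below genuine singular values, so any cutoff between the two
#'   clusters gives identical results.
#' @return Object of class `nnn_fit`: parameters, covariance,
#'   standard errors, singular values, effective rank, zero-singular-value
#'   count, chi2, dof, q_value, unweighted fitted values, pearson_r, and the
#'   design.
#' @examples
#' ex <- simulate_experiments(generate_truth(seed = 1), n = 40, seed = 2)
#' fit <- svd_fit(build_design(ex))
#' glance(fit)
#' @export
svd_fit <- function(design, sv_rel_tolerance = 1e-8) {
  stopifnot(inherits(design, "nnn_design"))
  if (!is.numeric(sv_rel_tolerance) || sv_rel_tolerance <= 0 ||
      sv_rel_tolerance >= 1) {
    abort("`sv_rel_tolerance` must lie in (0, 1).")
  }
  X <- design$X
  y <- design$y
  dec <- svd(X)
  d <- dec$d
  keep <- d >= sv_rel_tolerance * max(d)
  if (!any(keep)) abort("design is degenerate: all singular values below tolerance.")
  r <- sum(keep)
  Ur <- dec$u[, keep, drop = FALSE]
  Vr <- dec$v[, keep, drop = FALSE]
  dr <- d[keep]
  p <- drop(Vr %*% ((crossprod(Ur, y)) / dr))
  covariance <- Vr %*% (t(Vr) / dr^2)
  dimnames(covariance) <- list(design$column_names, design$column_names)
  names(p) <- design$column_names
  fitted_w <- drop(X %*% p)
  chi2 <- sum((y - fitted_w)^2)
  dof <- nrow(X) - r
  q <- if (dof >= 1) goodness_of_fit(chi2, dof) else NA_real_
  if (dof < 1) warn("dof <= 0: Q statistic undefined for this fit.")
  fitted <- fitted_w * design$sigma
  observed <- design$y0
  pr <- if (stats::sd(fitted) > 0 && stats::sd(observed) > 0) {
    cor(observed, fitted)
  } else NA_real_
  structure(
    list(
      parameters = p,
      covariance = covariance,
      standard_errors = sqrt(pmax(diag(covariance), 0)),
      singular_values = d,
      effective_rank = r,
      zero_sv_count = ncol(X) - r,
      chi2 = chi2, dof = dof, q_value = q,
      fitted = fitted, observed = observed,
      pearson_r = pr,
      sv_rel_tolerance = sv_rel_tolerance,
      null_space = dec$v[, !keep, drop = FALSE],
      row_space = Vr,
      design = design
    ),
    class = "nnn_fit"
  )
}

#' Chi-square goodness-of-fit probability Q
#'
#' Upper-tail probability that a chi-square variate with `dof` degrees of
#' freedom exceeds the observed `chi2` (the regularized upper incomplete
#' gamma function at `dof/2`, `chi2/2`). Q near 1 means the model fits
#' within the stated errors; values above about 0.1 are conventionally
#' adequate, and a vanishing Q indicates a model that cannot account for
#' the data.
#'
#' @param chi2 Observed chi-square statistic (>= 0).
#' @param dof Degrees of freedom (integer >= 1).
#' @return Probability in `[0, 1]`, strictly decreasing in `chi2`.
#' @examples
#' goodness_of_fit(59, 59)
#' @export
goodness_of_fit <- function(chi2, dof) {
  if (!is.numeric(chi2) || any(chi2 < 0)) abort("`chi2` must be >= 0.")
  if (!is.numeric(dof) || any(dof < 1)) abort("`dof` must be >= 1.")
  pchisq(chi2, df = dof, lower.tail = FALSE)
}

#' Standard error of a linear combination of parameters
#'
#' Propagates the full variance-covariance matrix through a weight vector
#' `w`, returning `sqrt(w' C w)`. For a unit vector this is the column's own
#' standard error. The value is unique (invariant to the minimum-norm
#' convention) exactly when the combination is estimable.
#'
#' @param fit An `nnn_fit`, or a covariance matrix.
#' @param combination Numeric weight vector aligned with the fit's columns,
#'   or a named vector matched by column name (unnamed entries default 0).
#' @return Standard error (same units as the response, %).
#' @export
propagate_error <- function(fit, combination) {
  covariance <- if (inherits(fit, "nnn_fit")) fit$covariance else fit
  w <- align_combination(combination, colnames(covariance))
  sqrt(max(drop(t(w) %*% covariance %*% w), 0))
}

align_combination <- function(combination, column_names) {
  p <- length(column_names)
  if (!is.null(names(combination))) {
    unknown <- setdiff(names(combination), column_names)
    if (length(unknown) > 0) {
      abort(sprintf("unknown column(s) in combination: %s.",
                    paste(unknown, collapse = ", ")))
    }
    w <- setNames(numeric(p), column_names)
    w[names(combination)] <- combination
    w
  } else {
    if (length(combination) != p) {
      abort(sprintf("combination has length %d but the fit has %d columns.",
                    length(combination), p))
    }
    as.numeric(combination)
  }
}

#' Is a linear combination of parameters estimable?
#'
#' A combination `w'p` is estimable when `w` lies in the row space of the
#' design (equivalently, is orthogonal to every null direction); only such
#' combinations have values independent of the minimum-norm convention.
#' Unit vectors on the four homotriplets (AAA, CCC, GGG, UUU) are estimable
#' against the circular triplet count space; with all gene indicator columns
#' present (summing to one) an extra null direction mixes the overall
#' triplet level with the gene mean, so single gene parameters are not
#' estimable but differences of gene parameters are.
#'
#' @param x An `nnn_fit`, an `nnn_design`, or a numeric matrix whose rows
#'   span the realizable feature space (e.g. count vectors of circular
#'   sequences).
#' @param combination Weight vector (named or positional, see
#'   [propagate_error()]).
#' @param tol Relative residual tolerance (default `1e-8`).
#' @return `TRUE` if the projection of `w` onto the row space leaves a
#'   residual below `tol * ||w||` (the zero vector is estimable).
#' @export
is_estimable <- function(x, combination, tol = 1e-8) {
  if (inherits(x, "nnn_fit")) {
    basis <- x$row_space
    cols <- names(x$parameters)
  } else if (inherits(x, "nnn_design")) {
    basis <- svd_row_basis(x$X)
    cols <- x$column_names
  } else if (is.matrix(x)) {
    basis <- svd_row_basis(x)
    cols <- colnames(x)
  } else {
    abort("`x` must be an nnn_fit, nnn_design, or matrix of realizable rows.")
  }
  w <- align_combination(combination, cols %||% seq_len(ncol(basis)))
  nw <- sqrt(sum(w^2))
  if (nw == 0) return(TRUE)
  resid <- w - basis %*% crossprod(basis, w)
  sqrt(sum(resid^2)) < tol * nw
}

svd_row_basis <- function(m, rel_tol = 1e-8) {
  dec <- svd(m)
  keep <- dec$d >= rel_tol * max(dec$d)
  dec$v[, keep, drop = FALSE]
}

#' Compare alternative model specifications on one experiment table
#'
#' Fits each requested specification (feature order and covariate flags) to
#' the same experiments and tabulates effective rank, chi-square, degrees of
#' freedom and Q, so the triplet model can be confronted with the simpler
#' doublet model or with covariate-free variants.
#'
#' @param data Experiment table.
#' @param models List of model specs; each a list with elements `order`
#'   (`"triplet"`/`"doublet"`), `cell_covariate`, `gene_covariate`
#'   (missing flags default to TRUE).
#' @param sv_rel_tolerance Passed to [svd_fit()].
#' @return Tibble with one row per model: `model`, `order`,
#'   `cell_covariate`, `gene_covariate`, `effective_rank`, `zero_sv_count`,
#'   `chi2`, `dof`, `q_value`.
#' @export
compare_models <- function(data,
                           models = list(
                             list(order = "triplet"),
                             list(order = "doublet")
                           ),
                           sv_rel_tolerance = 1e-8) {
  if (length(models) < 1) abort("at least one model spec is required.")
  purrr::map_dfr(models, function(spec) {
    order <- spec$order %||% "triplet"
    cellf <- spec$cell_covariate %||% TRUE
    genef <- spec$gene_covariate %||% TRUE
    fit <- svd_fit(
      build_design(data, order = order, cell_covariate = cellf,
                   gene_covariate = genef),
      sv_rel_tolerance = sv_rel_tolerance
    )
    tibble::tibble(
      model = paste0(order,
                     if (cellf) "+cell" else "",
                     if (genef) "+gene" else ""),
      order = order, cell_covariate = cellf, gene_covariate = genef,
      effective_rank = fit$effective_rank,
      zero_sv_count = fit$zero_sv_count,
      chi2 = fit$chi2, dof = fit$dof, q_value = fit$q_value
    )
  })
}

#' @export
print.nnn_fit <- function(x, ...) {
  cat(sprintf("<nnn_fit> %d experiments, %d columns (%s model)\n",
              length(x$fitted), length(x$parameters), x$design$order))
  cat(sprintf("  effective rank %d (%d zero singular values)\n",
              x$effective_rank, x$zero_sv_count))
  cat(sprintf("  chi2 = %.4g on %d dof, Q = %.4g, r(obs, fit) = %.3f\n",
              x$chi2, x$dof, x$q_value, x$pearson_r))
  invisible(x)
}

#' @rdname svd_fit
#' @param x,object An `nnn_fit`.
#' @param ... Unused.
#' @method tidy nnn_fit
#' @export
tidy.nnn_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$parameters),
    type = x$design$column_types,
    estimate = unname(x$parameters),
    std.error = unname(x$standard_errors)
  )
}

#' @rdname svd_fit
#' @method glance nnn_fit
#' @export
glance.nnn_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$fitted),
    n_columns = length(x$parameters),
    effective_rank = x$effective_rank,
    zero_sv_count = x$zero_sv_count,
    chi2 = x$chi2,
    dof = x$dof,
    q_value = x$q_value,
    pearson_r = x$pearson_r
  )
}

#' @rdname svd_fit
#' @method augment nnn_fit
#' @export
augment.nnn_fit <- function(x, ...) {
  dplyr::mutate(
    x$design$experiments,
    .fitted = x$fitted,
    .resid = x$design$y0 - x$fitted,
    .std.resid = (x$design$y0 - x$fitted) / x$design$sigma
  )
}

#' Observed-versus-fitted scatter for a fit
#'
#' @param object An `nnn_fit`.
#' @param ... Unused.
#' @return A ggplot: observed percent reduction against the model's fitted
#'   value, one point per experiment, identity line for reference.
#' @method autoplot nnn_fit
#' @export
autoplot.nnn_fit <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$.fitted, y = .data$reduction,
                                   colour = .data$gene, shape = .data$cell)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "fitted reduction in accumulated protein (%)",
      y = "observed reduction (%)",
      title = sprintf("NNN fit: r = %.3f, Q = %.3g",
                      object$pearson_r, object$q_value)
    )
}

#' Write a plain-text fit report
#'
#' Serializes a fit to a structured text report: column names, parameter
#' estimates and standard errors (12 significant digits), singular values,
#' chi2/dof/Q, optionally the full covariance matrix.
#'
#' @param fit An `nnn_fit`.
#' @param path Output file.
#' @param covariance Include the full covariance matrix (default FALSE).
#' @param header Optional character vector of `# `-prefixed context lines.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, covariance = FALSE, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) formatC(v, digits = 12, format = "g")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# chi2 %s dof %d Q %s pearson_r %s", fmt(fit$chi2),
                     fit$dof, fmt(fit$q_value), fmt(fit$pearson_r)), con)
  writeLines(sprintf("# effective_rank %d zero_sv_count %d",
                     fit$effective_rank, fit$zero_sv_count), con)
  writeLines("[parameters]", con)
  writeLines("term\testimate\tstd_error", con)
  writeLines(paste(names(fit$parameters), fmt(fit$parameters),
                   fmt(fit$standard_errors), sep = "\t"), con)
  writeLines("[singular_values]", con)
  writeLines(paste(fmt(fit$singular_values), collapse = "\t"), con)
  if (covariance) {
    writeLines("[covariance]", con)
    writeLines(paste(colnames(fit$covariance), collapse = "\t"), con)
    for (i in seq_len(nrow(fit$covariance))) {
      writeLines(paste(fmt(fit$covariance[i, ]), collapse = "\t"), con)
    }
  }
  invisible(path)
}
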
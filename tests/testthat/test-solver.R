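# SVD solution, covariance, goodness of fit, estimability.

test_that("SVD solution matches the normal-equations oracle on full-rank systems", {
  set.seed(42)
  for (i in 1:5) {
    X <- matrix(rnorm(15), 5, 3)
    y <- rnorm(5)
    # wrap in a minimal design object
    d <- structure(list(X = X, y = y, X0 = X, y0 = y,
                        sigma = rep(1, 5),
                        column_names = paste0("c", 1:3),
                        column_types = rep("kmer", 3),
                        order = "triplet", cell_covariate = FALSE,
                        gene_covariate = FALSE, sensitive_cell = NULL,
                        experiments = NULL),
                   class = "nnn_design")
    fit <- svd_fit(d)
    oracle <- drop(oracle_normal_equations(X, y))
    expect_equal(unname(fit$parameters), oracle, tolerance = 1e-10)
    expect_equal(fit$effective_rank, 3L)
    # covariance equals (X'X)^{-1} at full rank
    expect_equal(unname(fit$covariance), solve(crossprod(X)),
                 tolerance = 1e-10)
  }
})

test_that("the reference design has 16 zero singular values and dof 59", {
  fx <- sim_fixture(seed = 4)
  fit <- svd_fit(build_design(fx$experiments))
  expect_equal(fit$zero_sv_count, 16L)
  expect_equal(fit$effective_rank, 53L)
  expect_equal(fit$dof, 59L)
  # structural zeros sit far below the smallest genuine singular value
  d <- sort(fit$singular_values, decreasing = TRUE)
  expect_lt(d[54] / d[53], 1e-10)
})

test_that("noiseless data are fitted exactly", {
  truth <- generate_truth(seed = 9)
  ex <- simulate_experiments(truth, n = 112, seed = 10, noise = FALSE)
  fit <- svd_fit(build_design(ex))
  expect_lt(fit$chi2, 1e-12)
  expect_equal(fit$fitted, ex$reduction, tolerance = 1e-10)
})

test_that("goodness_of_fit is the chi-square upper tail with the right shape", {
  expect_equal(goodness_of_fit(0, 59), 1)
  expect_gt(goodness_of_fit(59, 59), 0.45)
  expect_lt(goodness_of_fit(59, 59), 0.55)
  grid <- seq(1, 200, by = 5)
  q <- goodness_of_fit(grid, 59)
  expect_true(all(diff(q) <= 0))
  # strictly decreasing wherever the tail is representably below 1
  mid <- seq(30, 120, by = 5)
  expect_true(all(diff(goodness_of_fit(mid, 59)) < 0))
  expect_error(goodness_of_fit(-1, 10), "chi2")
  expect_error(goodness_of_fit(5, 0), "dof")
})

test_that("propagate_error reproduces diagonal SEs and is basis-invariant", {
  fx <- sim_fixture(seed = 6)
  fit <- svd_fit(build_design(fx$experiments))
  j <- "AAA"
  w <- setNames(numeric(length(fit$parameters)), names(fit$parameters))
  w[j] <- 1
  expect_equal(propagate_error(fit, w), fit$standard_errors[[j]])
  expect_equal(propagate_error(fit, w * 0), 0)
  expect_error(propagate_error(fit, numeric(3)), "length")

  # estimable combinations keep their SE when the column order is permuted
  set.seed(99)
  perm <- sample(length(fit$parameters))
  d <- build_design(fx$experiments)
  d$X <- d$X[, perm]; d$X0 <- d$X0[, perm]
  d$column_names <- d$column_names[perm]; d$column_types <- d$column_types[perm]
  fit_p <- svd_fit(d)
  comb <- count_kmers(fx$experiments$target[1], 3)[1, ]  # an estimable contrast
  comb <- c(comb, setNames(1, paste0("gene:", fx$experiments$gene[1])))
  se1 <- propagate_error(fit, comb)
  se2 <- propagate_error(fit_p, comb)
  expect_equal(se1, se2, tolerance = 1e-8)
})

test_that("minimum-norm solution is orthogonal to the null space", {
  fx <- sim_fixture(seed = 8)
  fit <- svd_fit(build_design(fx$experiments))
  inner <- crossprod(fit$null_space, fit$parameters)
  expect_lt(max(abs(inner)), 1e-8 * sqrt(sum(fit$parameters^2)))
})

test_that("predictions are invariant to null-space perturbations of the parameters", {
  fx <- sim_fixture(seed = 12)
  d <- build_design(fx$experiments)
  fit <- svd_fit(d)
  set.seed(13)
  pert <- drop(fit$null_space %*% rnorm(ncol(fit$null_space), sd = 5))
  p2 <- fit$parameters + pert
  # any realizable circular 20-mer with covariate context
  probes <- vapply(1:20, function(i) rand_rna(20), character(1))
  counts <- count_kmers(probes, 3)
  for (i in 1:20) {
    w <- setNames(numeric(length(p2)), names(fit$parameters))
    w[colnames(counts)] <- counts[i, ]
    w["cell:A549"] <- 1
    w[paste0("gene:", fx$experiments$gene[1])] <- 1
    expect_equal(sum(w * fit$parameters), sum(w * p2), tolerance = 1e-8)
  }
})

test_that("estimability separates homotriplets, gene columns, and contrasts", {
  set.seed(17)
  # count space of circular sequences: homotriplet unit vectors are estimable
  seqs <- vapply(sample(4:25, 300, replace = TRUE), rand_rna, character(1))
  cs <- count_kmers(seqs, 3)
  for (h in c("AAA", "CCC", "GGG", "UUU")) {
    expect_true(is_estimable(cs, setNames(1, h)))
  }
  expect_false(is_estimable(cs, c(ACG = 1)))
  expect_true(is_estimable(cs, setNames(numeric(1), "AAA")))  # zero vector

  # full design: single gene columns are aliased, contrasts are not
  fx <- sim_fixture(seed = 18)
  fit <- svd_fit(build_design(fx$experiments))
  expect_false(is_estimable(fit, c(`gene:CRAF1` = 1)))
  expect_true(is_estimable(fit, c(`gene:CRAF1` = 1, `gene:BCL2` = -1)))
  expect_true(is_estimable(fit, c(`cell:A549` = 1)))
})

test_that("compare_models ranks the triplet model above the doublet model", {
  fx <- sim_fixture(seed = 20)
  tbl <- compare_models(fx$experiments, models = list(
    list(order = "triplet"),
    list(order = "triplet"),
    list(order = "doublet"),
    list(order = "triplet", cell_covariate = FALSE)
  ))
  expect_equal(nrow(tbl), 4L)
  # identical specs give identical rows
  expect_equal(tbl[1, ], tbl[2, ], ignore_attr = TRUE)
  # the doublet model cannot absorb genuine triplet structure
  expect_gt(tbl$q_value[1], 0.01)
  expect_lt(tbl$q_value[3], 1e-3)
  # dropping the cell covariate from data with a real cell offset hurts
  expect_lt(tbl$q_value[4], tbl$q_value[1])
})

test_that("tidy, glance, augment and the report round-trip expose the fit", {
  fx <- sim_fixture(seed = 22)
  fit <- svd_fit(build_design(fx$experiments))
  tt <- tidy(fit)
  expect_equal(nrow(tt), 69L)
  expect_named(tt, c("term", "type", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$n, 112L)
  expect_true(gl$q_value >= 0 && gl$q_value <= 1)
  au <- augment(fit)
  expect_equal(au$.fitted + au$.resid, au$reduction)

  path <- withr::local_tempfile(fileext = ".txt")
  write_fit_report(fit, path, covariance = TRUE)
  lines <- readLines(path)
  expect_true(any(grepl("^\\[parameters\\]", lines)))
  expect_true(any(grepl("^\\[covariance\\]", lines)))

  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
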
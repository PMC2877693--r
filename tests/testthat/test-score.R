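# Scoring with the packaged published parameters, window scanning,
# independence diagnostics, and the gene-minus-average transform.

test_that("worked scoring examples reproduce the published values", {
  p <- antisense_params()
  got <- score_sequence(p, c(acu4 = "ACUACUACUACU",
                             ggga3 = "GGGAGGGAGGGA",
                             gggauc2 = "GGGAUCGGGAUC"))
  expect_equal(got$P, c(72.1, 23.0, 46.8), tolerance = 0.15 / 72)
  expect_equal(got$se_method, rep("rss", 3))  # no covariance ships with the table

  # all-zero table scores everything zero
  zero <- parameter_table(tibble::tibble(term = kmer_alphabet(3),
                                         type = "triplet", estimate = 0))
  expect_equal(score_sequence(zero, "GGGAUCGGGAUC")$P, 0)
})

test_that("the packaged independent 12-mer set is reconstructed within rounding", {
  p <- antisense_params()
  seqs <- independent_sequence_set()
  got <- score_sequence(p, tibble::tibble(id = seqs$name,
                                          sequence = seqs$sequence))
  printed <- printed_independent_P[got$id]
  expect_true(all(!is.na(printed)))
  expect_lt(max(abs(got$P - printed)), 0.15)
})

test_that("dependent sequences score consistently with their linear combination", {
  p <- antisense_params()
  direct <- score_sequence(p, "GGGAGGGAGGGA")$P
  g12 <- score_sequence(p, strrep("G", 12))$P
  agg4 <- score_sequence(p, strrep("AGG", 4))$P
  expect_equal(direct, g12 / 4 + 3 * agg4 / 4, tolerance = 1e-10)
})

test_that("scores are rotation-invariant and linear in the parameter table", {
  p <- antisense_params()
  s <- "GGAUCCGUAAGC"
  rotations <- vapply(seq_len(nchar(s)), function(k) {
    paste0(substr(s, k, nchar(s)), substr(s, 1, k - 1))
  }, character(1))
  scores <- score_sequence(p, rotations)$P
  expect_equal(max(scores) - min(scores), 0, tolerance = 1e-10)

  doubled <- parameter_table(
    dplyr::mutate(tibble::as_tibble(p), estimate = 2 * estimate),
    meta = attr(p, "meta")
  )
  expect_equal(score_sequence(doubled, s)$P, 2 * score_sequence(p, s)$P)
})

test_that("covariate offsets shift scores and unknown labels error", {
  p <- antisense_params()
  base <- score_sequence(p, "ACUACUACUACU")$P
  a549 <- score_sequence(p, "ACUACUACUACU", cell = "A549")$P
  t24 <- score_sequence(p, "ACUACUACUACU", cell = "T24")$P  # baseline
  expect_equal(a549 - base, 10.59)
  expect_equal(t24, base)
  withgene <- score_sequence(p, "ACUACUACUACU", gene = "BCL2")$P
  expect_equal(withgene - base, -3.10)
  expect_error(score_sequence(p, "ACU", cell = "HeLa"), "unknown cell")
  expect_error(score_sequence(p, "ACU", gene = "TP53"), "unknown gene")
})

test_that("window scanning finds the best block and respects conventions", {
  p <- antisense_params()
  mrna <- paste0(strrep("ACU", 4), strrep("C", 12))
  scan <- scan_windows(p, c(m1 = mrna), window = 12)
  expect_equal(nrow(scan), nchar(mrna) - 12 + 1)
  top <- scan[1, ]
  expect_equal(top$start, 0L)
  expect_equal(top$window, strrep("ACU", 4))
  expect_equal(top$P, 72.1, tolerance = 0.15)
  # each window equals direct circular scoring
  expect_equal(scan$P[scan$start == 12],
               score_sequence(p, strrep("C", 12))$P)
  # window = sequence length gives a single window
  single <- scan_windows(p, "GGGAUCGGGAUC", window = 12)
  expect_equal(nrow(single), 1L)
  expect_equal(single$P, score_sequence(p, "GGGAUCGGGAUC")$P)
  # ranked by P descending with start-ascending tie-break
  expect_true(all(diff(scan$P) <= 0))
  expect_error(scan_windows(p, "ACGU", window = 12), "longer")
})

test_that("independence diagnostics rank the packaged set and expose dependencies", {
  seqs <- independent_sequence_set()
  rep49 <- check_independence(seqs$sequence)
  expect_equal(rep49$rank, 49L)
  expect_equal(rep49$verdict, "independent")
  expect_equal(rep49$dims, c(64L, 49L))

  with_dep <- check_independence(c(seqs$sequence, strrep("GGGA", 3)))
  expect_equal(with_dep$rank, 49L)
  expect_equal(with_dep$verdict, "dependent")
  dep <- with_dep$dependency
  involved <- names(dep)
  expect_true(all(c(strrep("GGGA", 3)) %in% involved))
  expect_true(all(involved %in% c(strrep("GGGA", 3), strrep("G", 12),
                                  strrep("AGG", 4))))

  expect_equal(check_independence("ACGUACGU")$verdict, "independent")
})

test_that("gene_minus_average centers the published gene parameters", {
  offs <- gene_minus_average(antisense_params())
  expect_equal(offs$offset[offs$term == "BCL2"], -4.54, tolerance = 0.01)
  expect_equal(sum(offs$offset), 0, tolerance = 1e-10)

  equal <- parameter_table(tibble::tibble(
    term = c(kmer_alphabet(3), "g1", "g2"),
    type = c(rep("triplet", 64), "gene", "gene"),
    estimate = c(rep(0, 64), 5, 5)
  ))
  expect_equal(gene_minus_average(equal)$offset, c(0, 0))
  set.seed(3)
  rnd <- parameter_table(tibble::tibble(
    term = c(kmer_alphabet(3), paste0("g", 1:5)),
    type = c(rep("triplet", 64), rep("gene", 5)),
    estimate = c(rep(0, 64), rnorm(5))
  ))
  expect_equal(sum(gene_minus_average(rnd)$offset), 0, tolerance = 1e-10)
  only1 <- parameter_table(tibble::tibble(
    term = c(kmer_alphabet(3), "g1"),
    type = c(rep("triplet", 64), "gene"),
    estimate = 0
  ))
  expect_error(gene_minus_average(only1), "at least two")
})

test_that("nn_free_energy sums doublet free energies circularly", {
  flat <- setNames(rep(-1, 16), kmer_alphabet(2))
  s20 <- rand_rna(20)
  expect_equal(nn_free_energy(s20, flat)$dg_total, -20)
  expect_equal(nn_free_energy(s20, flat * 0)$dg_total, 0)
  expect_error(nn_free_energy("ACGU", flat[-1]), "missing doublet")

  # positional oracle on random sequences
  set.seed(5)
  tblvals <- setNames(rnorm(16), kmer_alphabet(2))
  for (i in 1:20) {
    s <- rand_rna(sample(3:25, 1))
    padded <- paste0(s, substr(s, 1, 1))
    doublets <- substring(padded, seq_len(nchar(s)), seq_len(nchar(s)) + 1)
    expect_equal(nn_free_energy(s, tblvals)$dg_total,
                 sum(tblvals[doublets]), ignore_attr = TRUE)
  }
})

test_that("parameter tables round-trip through the sectioned text format", {
  fx <- sim_fixture(seed = 31)
  fit <- svd_fit(build_design(fx$experiments))
  pt <- as_parameter_table(fit, covariance = TRUE)
  path <- withr::local_tempfile(fileext = ".txt")
  write_parameter_table(pt, path, covariance = TRUE)
  back <- read_parameter_table(path)
  expect_equal(back$estimate, pt$estimate, tolerance = 1e-10)
  expect_equal(back$term, pt$term)
  expect_equal(attr(back, "covariance"), attr(pt, "covariance"),
               tolerance = 1e-9)
  expect_equal(attr(back, "meta")[["cell_baseline"]], "T24")

  # scoring with the covariance present uses exact propagation
  sc <- score_sequence(back, "ACUACUACUACU")
  expect_equal(sc$se_method, "covariance")
})
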
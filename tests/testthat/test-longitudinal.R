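test_that("curvature change is the follow-up over baseline ratio", {
  before <- ricci_curvature(make_kn(3))                 # k = 1/2 everywhere
  w <- matrix(1, 3, 3); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 1.8
  after <- ricci_curvature(make_net(w))
  ch <- curvature_change(before, after, "edges")
  expect_equal(nrow(ch), 3)
  expect_true(all(ch$defined))
  expect_equal(ch$ratio, ch$after / ch$before)

  same <- curvature_change(before, before, "edges")
  expect_equal(same$ratio, rep(1, 3))

  nodes <- curvature_change(before, after, "nodes")
  expect_equal(nrow(nodes), 3)
})

test_that("near-zero baseline curvature leaves the ratio undefined", {
  # pendant edges of a path have curvature exactly 0
  before <- ricci_curvature(make_path(3))
  after <- ricci_curvature(make_path(3, weight = 2))
  ch <- curvature_change(before, after, "edges")
  expect_false(any(ch$defined))
  expect_true(all(is.na(ch$ratio)))
})

test_that("units absent at either timepoint are flagged undefined", {
  before <- ricci_curvature(make_kn(4))
  w <- matrix(1, 4, 4); diag(w) <- 0
  w[1, 2] <- w[2, 1] <- 0                      # edge vanishes at follow-up
  after <- ricci_curvature(make_net(w))
  ch <- curvature_change(before, after, "edges")
  gone <- ch[ch$node_a == "n01" & ch$node_b == "n02", ]
  expect_false(gone$defined)
  expect_equal(sum(ch$defined), 5)
})

test_that("spearman matches a manual rank-and-Pearson computation", {
  expect_equal(spearman_test(1:6, c(2, 3, 5, 7, 11, 13))$r, 1)
  expect_equal(spearman_test(1:6, -(1:6))$r, -1)

  x <- c(1.2, 3.4, 3.4, 0.5, 9.1, 2.2, 7.7, 4.4, 6.6, 5.5)  # one tie
  y <- c(2.0, 1.0, 4.5, 3.3, 8.8, 2.1, 9.9, 4.5, 6.1, 0.7)  # one tie
  manual_r <- stats::cor(rank(x), rank(y))
  st <- spearman_test(x, y)
  expect_equal(st$r, manual_r, tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(st$p, ct$p.value, tolerance = 1e-12)

  expect_error(spearman_test(rep(1, 6), 1:6), "constant")
  expect_error(spearman_test(1:3, 3:1), "at least 4")
})

test_that("the vectorized row-wise spearman agrees with cor.test", {
  set.seed(51)
  X <- matrix(rnorm(40 * 19), 40, 19)
  X[3, ] <- round(X[3, ])                       # introduce ties
  y <- rnorm(19)
  res <- riccinet:::spearman_rows(X, y)
  for (i in c(1, 3, 17, 40)) {
    ct <- suppressWarnings(
      cor.test(X[i, ], y, method = "spearman", exact = FALSE))
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-12)
  }
  X[5, ] <- 2                                   # constant row
  res2 <- riccinet:::spearman_rows(X, y)
  expect_true(is.na(res2$r[5]))
})

test_that("benjamini-hochberg reproduces the hand step-up and its properties", {
  # step-up from the largest: 0.04 <= 0.05 * 4/4, so everything is rejected
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(bh$reject))
  expect_equal(bh$q, oracle_bh(c(0.01, 0.02, 0.03, 0.04)))

  one <- benjamini_hochberg(0.04)
  expect_true(one$reject)
  expect_equal(one$q, 0.04)

  ones <- benjamini_hochberg(rep(1, 5))
  expect_false(any(ones$reject))
  expect_equal(ones$q, rep(1, 5))

  set.seed(52)
  p <- runif(50)^2
  bh2 <- benjamini_hochberg(p)
  expect_equal(bh2$q, oracle_bh(p))
  expect_true(all(bh2$q >= bh2$p))
  # order invariance
  perm <- sample(50)
  expect_equal(benjamini_hochberg(p[perm])$q, bh2$q[perm])
  # BH rejections contain Bonferroni's
  bonf <- p < 0.05 / 50
  expect_true(all(bh2$reject[bonf]))

  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
  expect_error(benjamini_hochberg(0.5, alpha = 0), "alpha")
})

# Cohort whose one perturbed edge responds monotonically to the behavioral
# scores: triangle with the opposing edge strengthened per subject.
monotone_cohort <- function(ns = 8) {
  base_w <- matrix(0, 3, 3)
  base_w[1, 2] <- base_w[2, 1] <- 1
  base_w[1, 3] <- base_w[3, 1] <- 1
  base_w[2, 3] <- base_w[3, 2] <- 0.5
  meta <- data.frame(id = c("a", "b", "c"), name = c("a", "b", "c"),
                     hemisphere = "left")
  baseline <- replicate(ns, brain_network(base_w, meta), simplify = FALSE)
  followup <- lapply(seq_len(ns), function(s) {
    w <- base_w
    w[2, 3] <- w[3, 2] <- 0.2 + 0.1 * s        # k(a,b) increases in s
    brain_network(w, meta)
  })
  tibble::tibble(
    subject_id = sprintf("s%d", seq_len(ns)),
    baseline = baseline,
    followup = followup,
    d_vabs = seq_len(ns),
    d_eow = 2 * seq_len(ns),
    cgi_i = -seq_len(ns)
  )
}

test_that("a noiseless monotone edge is selected with perfect correlations", {
  res <- run_analysis(monotone_cohort(), analysis_config())
  ab <- res[res$unit_type == "edge" & res$node_a == "a" & res$node_b == "b", ]
  expect_equal(abs(ab$r_vabs), 1)
  expect_equal(abs(ab$r_eow), 1)
  expect_equal(abs(ab$r_cgi), 1)
  expect_true(ab$selected)
})

test_that("selection tightens monotonically with the required measure count", {
  cohort <- monotone_cohort()
  r2 <- run_analysis(cohort, analysis_config(selection_min_measures = 2))
  r3 <- run_analysis(cohort, analysis_config(selection_min_measures = 3))
  key <- function(r) paste(r$unit_type, r$node_a, r$node_b)
  expect_true(all(key(r3)[r3$selected] %in% key(r2)[r2$selected]))
  r1 <- run_analysis(cohort, analysis_config(selection_min_measures = 1))
  expect_true(all(key(r2)[r2$selected] %in% key(r1)[r1$selected]))
})

test_that("analysis results do not depend on subject order", {
  gen <- generate_cohort(synthetic_config(n_subjects = 6, n_nodes = 11,
                                          seed = 8))
  res1 <- run_analysis(gen$cohort)
  set.seed(1)
  perm <- sample(6)
  res2 <- run_analysis(gen$cohort[perm, ])
  expect_equal(tibble::as_tibble(res1), tibble::as_tibble(res2))
})

test_that("analysis validates its inputs", {
  gen <- generate_cohort(synthetic_config(n_subjects = 3, n_nodes = 11,
                                          seed = 9))
  expect_error(run_analysis(gen$cohort), "at least 4 subjects")
  gen2 <- generate_cohort(synthetic_config(n_subjects = 5, n_nodes = 11,
                                           seed = 9))
  bad <- gen2$cohort
  bad$d_vabs[2] <- NA
  expect_error(run_analysis(bad), "missing behavioral")
  bad2 <- gen2$cohort
  bad2$followup[[3]] <- make_net(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(run_analysis(bad2), "node-set mismatch")
})
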
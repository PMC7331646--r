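test_that("a matrix and metadata round-trip through the constructor", {
  w <- matrix(c(0, 3, 3, 0), 2, 2)
  meta <- data.frame(id = c("A", "B"), name = c("a", "b"),
                     hemisphere = c("left", "left"))
  net <- brain_network(w, meta)
  ed <- network_edges(net)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$weight, 3)
  expect_equal(ed$node_a, "A")
  expect_identical(unname(net$weights), w)
})

test_that("self-loops are dropped with a warning", {
  w <- matrix(5, 3, 3)
  meta <- data.frame(id = letters[1:3], name = letters[1:3],
                     hemisphere = "left")
  expect_warning(net <- brain_network(w, meta), "self-loop")
  expect_equal(unname(diag(net$weights)), c(0, 0, 0))
  expect_equal(net$weights["a", "b"], 5)
})

test_that("invalid matrices are rejected with informative errors", {
  meta2 <- data.frame(id = c("a", "b"), name = c("a", "b"),
                      hemisphere = "left")
  expect_error(brain_network(matrix(c(0, -1, -1, 0), 2, 2), meta2),
               "negative")
  expect_error(brain_network(matrix(c(0, NaN, NaN, 0), 2, 2), meta2),
               "non-finite")
  expect_error(brain_network(matrix(c(0, 1, 2, 0), 2, 2), meta2),
               "asymmetric")
  expect_error(brain_network(matrix(0, 2, 3), meta2), "square")
  expect_error(brain_network(matrix(0, 2, 2),
                             data.frame(id = "a", name = "a",
                                        hemisphere = "left")),
               "2 rows")
  expect_error(brain_network(matrix(0, 2, 2),
                             data.frame(id = c("a", "a"), name = c("a", "b"),
                                        hemisphere = "left")),
               "unique")
  expect_error(brain_network(matrix(0, 2, 2),
                             data.frame(id = c("a", "b"), name = c("a", "b"),
                                        hemisphere = c("left", "up"))),
               "hemisphere")
})

test_that("asymmetry within tolerance is repaired by averaging", {
  w <- matrix(c(0, 1, 1 + 1e-10, 0), 2, 2)
  meta <- data.frame(id = c("a", "b"), name = c("a", "b"),
                     hemisphere = "left")
  net <- brain_network(w, meta)
  expect_identical(net$weights[1, 2], net$weights[2, 1])
  expect_equal(net$weights[1, 2], 1 + 5e-11)
})

test_that("write/read round-trips a network bit-exactly", {
  net <- generate_baseline(synthetic_config(seed = 5))
  mp <- withr::local_tempfile(fileext = ".txt")
  dp <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, mp, dp)
  back <- read_network(mp, dp)
  expect_identical(back$weights, net$weights)
  expect_identical(back$nodes, net$nodes)
})

test_that("comma-delimited matrices are accepted", {
  mp <- withr::local_tempfile(fileext = ".csv")
  dp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0,2.5", "2.5,0"), mp)
  readr::write_tsv(tibble::tibble(id = c("a", "b"), name = c("a", "b"),
                                  hemisphere = c("left", "right")), dp)
  net <- read_network(mp, dp)
  expect_equal(net$weights["a", "b"], 2.5)
})

test_that("weight normalization rescales without changing the zero pattern", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 3
  w[2, 3] <- w[3, 2] <- 6
  net <- make_net(w)
  scaled <- normalize_edge_weights(net, 3)
  expect_equal(network_edges(scaled)$weight, c(1, 2))
  expect_identical(scaled$weights == 0, net$weights == 0)
  expect_identical(normalize_edge_weights(net, 1)$weights, net$weights)
  expect_equal(sum(scaled$weights), sum(net$weights) / 3)
  expect_error(normalize_edge_weights(net, 0), "positive")
  expect_error(normalize_edge_weights(net, -2), "positive")
})

test_that("cross-hemisphere removal follows the hemisphere labels", {
  w <- matrix(4, 4, 4)
  diag(w) <- 0
  net <- make_net(w, hemi = c("left", "left", "right", "none"))
  filtered <- remove_cross_hemisphere_edges(net)
  expect_equal(filtered$weights[1, 3], 0)       # left-right removed
  expect_equal(filtered$weights[2, 3], 0)
  expect_equal(filtered$weights[1, 2], 4)       # intra-hemisphere untouched
  expect_equal(filtered$weights[1, 4], 4)       # brainstem kept by default
  expect_equal(filtered$weights[3, 4], 4)
  dropped <- remove_cross_hemisphere_edges(net, keep_brainstem = FALSE)
  expect_equal(dropped$weights[1, 4], 0)
  expect_equal(dropped$weights[3, 4], 0)
  expect_equal(dropped$weights[1, 2], 4)
})

test_that("cross-hemisphere removal is idempotent and never increases weights", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    hemi <- sample(c("left", "right", "none"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    net <- random_connected_net(n, density = 0.6)
    net$nodes$hemisphere <- hemi
    once <- remove_cross_hemisphere_edges(net)
    twice <- remove_cross_hemisphere_edges(once)
    expect_identical(once$weights, twice$weights)
    expect_true(all(once$weights <= net$weights))
    intra <- outer(hemi, hemi, "==") & hemi != "none"
    expect_identical(once$weights[intra], net$weights[intra])
  }
})

test_that("a cohort writes to disk and reads back unchanged", {
  gen <- generate_cohort(synthetic_config(n_subjects = 4, n_nodes = 11,
                                          seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(gen$cohort, dir, truth = gen$truth)
  back <- read_cohort(manifest)
  expect_equal(nrow(back), 4)
  expect_identical(back$subject_id, gen$cohort$subject_id)
  expect_identical(back$baseline[[2]]$weights, gen$cohort$baseline[[2]]$weights)
  expect_identical(back$followup[[4]]$weights, gen$cohort$followup[[4]]$weights)
  expect_equal(back$d_vabs, gen$cohort$d_vabs)
  expect_equal(back$cgi_i, gen$cohort$cgi_i)
  expect_true(file.exists(file.path(dir, "truth_planted_edges.tsv")))
})

test_that("cohort validation catches node mismatches and missing scores", {
  gen <- generate_cohort(synthetic_config(n_subjects = 4, n_nodes = 11,
                                          seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_cohort(gen$cohort, dir)
  man <- readr::read_tsv(manifest, col_types = readr::cols(), progress = FALSE)

  # follow-up with a different node count
  small <- make_net(matrix(c(0, 1, 1, 0), 2, 2))
  write_network(small, file.path(dir, man$followup_path[1]))
  meta_small <- file.path(dir, "nodes_small.tsv")
  expect_error(read_cohort(manifest), "metadata has|node-set|rows")

  # missing behavioral score
  dir2 <- withr::local_tempdir()
  manifest2 <- write_cohort(gen$cohort, dir2)
  man2 <- readr::read_tsv(manifest2, col_types = readr::cols(),
                          progress = FALSE)
  man2$d_eow[2] <- NA
  readr::write_tsv(man2, manifest2, progress = FALSE)
  expect_error(read_cohort(manifest2), "d_eow")

  expect_error(read_cohort(file.path(dir, "nope.tsv")), "not found")
})
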
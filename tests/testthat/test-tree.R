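test_that("K2P distance matches its closed form and excludes N/gap sites", {
  A100 <- strrep("A", 100)
  expect_equal(k2p_distance(A100, A100), 0)
  # P = 0.1, Q = 0: d = -1/2 ln(1-2P) = -1/2 ln(0.8)
  s_ts <- paste0(strrep("G", 10), strrep("A", 90))
  expect_equal(k2p_distance(A100, s_ts), -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(k2p_distance(A100, s_ts), 0.1115718, tolerance = 1e-6)
  # P = 0, Q = 0.1: d = -1/2 ln((1-Q) sqrt(1-2Q)) = -1/2 ln(0.9) - 1/4 ln(0.8)
  s_tv <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(k2p_distance(A100, s_tv), -0.5 * log(0.9 * sqrt(0.8)),
               tolerance = 1e-12)
  # sites with N or gap in either sequence are excluded pairwise
  sN <- paste0("N", strrep("A", 99))
  sG <- paste0("-", strrep("G", 10), strrep("A", 89))
  expect_equal(k2p_distance(sN, sG),
               k2p_distance(strrep("A", 99),
                            paste0(strrep("G", 10), strrep("A", 89))))
  # saturation errors rather than returning NaN
  expect_error(k2p_distance(strrep("A", 10), strrep("G", 10)), "saturation")
  expect_error(k2p_distance("ACGT", "ACG"), "equal length")
})

test_that("K2P >= p-distance, both zero only for identical sequences", {
  set.seed(14)
  for (i in 1:20) {
    x <- random_seq(300)
    y <- substitute_sites(x, sample(0:60, 1))
    pd <- p_distance(x, y)
    kd <- k2p_distance(x, y)
    expect_gte(kd, pd - 1e-12)
    expect_equal(pd == 0, x == y)
    expect_equal(kd == 0, x == y)
  }
})

test_that("distance matrices agree with an independent K2P implementation", {
  set.seed(15)
  base <- random_seq(400)
  seqs <- setNames(c(base, vapply(1:5, function(i)
    substitute_sites(base, sample(10:60, 1)), "")),
    paste0("t", 1:6))
  D <- distance_matrix(seqs, model = "k2p")
  bin <- ape::as.DNAbin(t(sapply(seqs, function(s) strsplit(s, "")[[1]])))
  Dref <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(D, Dref[rownames(D), colnames(D)], tolerance = 1e-12)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
})

test_that("NJ solves the 3-taxon case in closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 0.5, tolerance = 1e-12)
  expect_equal(bl[["b"]], 1.5, tolerance = 1e-12)
  expect_equal(bl[["c"]], 2.5, tolerance = 1e-12)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers random additive trees and matches ape's NJ", {
  set.seed(16)
  for (r in 1:40) {
    nt <- sample(4:12, 1)
    tr <- ape::rtree(nt, br = function(n) runif(n, 0.05, 0.5))
    tr$tip.label <- sprintf("t%02d", seq_len(nt))
    D <- ape::cophenetic.phylo(tr)
    my <- neighbor_joining(D)
    # topology identical to the generating tree and to ape's implementation
    expect_equal(ape::dist.topo(ape::unroot(tr), my), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::dist.topo(ape::nj(D), my), 0, ignore_attr = TRUE)
    # path lengths reproduce the additive input exactly
    expect_equal(ape::cophenetic.phylo(my)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("equal-distance ties join the lexicographically first pair", {
  D <- matrix(1, 4, 4, dimnames = list(c("d", "b", "c", "a"),
                                       c("d", "b", "c", "a")))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  # (a, b) must come out as a cherry
  bp <- tree_bipartitions(tr)
  expect_true("c|d" %in% bp)   # the a,b | c,d split
})

test_that("bootstrap supports behave as expected", {
  # 50 diagnostic columns separating two clades -> support ~100
  blockA <- strrep("A", 50); blockG <- strrep("G", 50)
  core <- strrep("C", 60)
  set.seed(17)
  jitter <- function(s) substitute_sites(s, 3)
  seqs <- c(a1 = jitter(paste0(blockA, core)),
            a2 = jitter(paste0(blockA, core)),
            b1 = jitter(paste0(blockG, core)),
            b2 = jitter(paste0(blockG, core)))
  bt <- bootstrap_support(seqs, n_reps = 100, seed = 1, model = "p")
  sup <- attr(bt, "support")
  expect_equal(length(sup), 1)   # one internal edge in a 4-taxon tree
  expect_gte(unname(sup[1]), 99)

  # n_reps = 0 -> tree without node labels
  bt0 <- bootstrap_support(seqs, n_reps = 0)
  expect_null(bt0$node.label)

  # reproducible under a fixed seed; invariant to input order
  b1 <- bootstrap_support(seqs, n_reps = 50, seed = 7, model = "p")
  b2 <- bootstrap_support(seqs[c(3, 1, 4, 2)], n_reps = 50, seed = 7,
                          model = "p")
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))

  # duplicated taxon sequences -> zero-length cherry, other supports intact
  seqs5 <- c(seqs, a3 = seqs[["a1"]])
  bt5 <- bootstrap_support(seqs5, n_reps = 50, seed = 2, model = "p")
  cp <- ape::cophenetic.phylo(bt5)
  expect_equal(cp["a1", "a3"], 0, tolerance = 1e-12)
})
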
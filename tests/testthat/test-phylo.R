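test_that("p-distance uses pairwise deletion of gapped columns", {
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("A-CG", "AAC-"), 0)
  expect_error(p_distance("A--", "-A-"), "no gap-free columns")
  expect_error(p_distance("AA", "AAA"), "length")
})

test_that("Poisson correction is -ln(1-p), monotone, and flags saturation", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.25), -log(0.75))
  expect_equal(round(poisson_correct(0.25), 4), 0.2877)
  ps <- seq(0, 0.9, by = 0.1)
  expect_true(all(diff(poisson_correct(ps)) > 0))
  expect_error(poisson_correct(1), "saturated")
})

test_that("three-taxon star is resolved by the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d)
  lens <- stats::setNames(t3$root$lengths,
                          vapply(t3$root$children, `[[`, "", "tip"))
  expect_equal(lens, c(A = 1, B = 1, C = 3))
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers random additive trees up to 8 taxa", {
  withr::with_seed(31, {
    for (n in c(4, 5, 6, 8)) {
      for (rep in 1:3) {
        true <- ape::rtree(n)
        dm <- ape::cophenetic.phylo(true)
        mine <- nj_tree(dm)
        expect_identical(mine$n_clamped, 0L)
        parsed <- ape::read.tree(text = write_newick(mine))
        # topology identical to the generating tree
        expect_equal(phangorn::RF.dist(ape::unroot(true), parsed), 0)
        # path lengths between leaves reproduce the input distances
        got <- ape::cophenetic.phylo(parsed)
        expect_equal(got[rownames(dm), colnames(dm)], dm,
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  withr::with_seed(41, {
    for (rep in 1:3) {
      n <- 7
      m <- matrix(stats::runif(n * n, 0.05, 1), n, n)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      mine <- ape::read.tree(text = write_newick(nj_tree(d)))
      ref <- ape::nj(stats::as.dist(d))
      expect_equal(phangorn::RF.dist(mine, ape::unroot(ref)), 0)
    }
  })
})

test_that("label order only permutes the tree, never its shape", {
  withr::with_seed(51, {
    true <- ape::rtree(6)
    dm <- ape::cophenetic.phylo(true)
    perm <- sample(6)
    t1 <- ape::read.tree(text = write_newick(nj_tree(dm)))
    t2 <- ape::read.tree(text = write_newick(nj_tree(dm[perm, perm])))
    expect_equal(phangorn::RF.dist(t1, t2), 0)
  })
})

test_that("duplicated alignment rows form a 100%-supported cherry", {
  withr::with_seed(61, {
    base <- random_dna(120)
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), k)
      ch[idx] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(ch, collapse = "")
    }
    aln <- c(t1 = base, t2 = base, t3 = mut(base, 30), t4 = mut(base, 45),
             t5 = mut(base, 60))
  })
  bt <- bootstrap_support(aln, n_reps = 100, seed = 7, model = "p")
  expect_equal(support_of_clade(bt, c("t1", "t2")), 100)
  expect_identical(n_internal_edges(bt), length(aln) - 3L)
})

test_that("bootstrap supports are seeded, bounded and convergent", {
  withr::with_seed(71, {
    base <- random_dna(200)
    ch <- strsplit(base, "")[[1]]
    aln <- vapply(1:6, function(i) {
      x <- ch
      idx <- sample(length(x), 12 * i)
      x[idx] <- sample(c("A", "C", "G", "T"), length(idx), replace = TRUE)
      paste(x, collapse = "")
    }, "")
    names(aln) <- paste0("s", 1:6)
  })
  b1 <- bootstrap_support(aln, n_reps = 150, seed = 5, model = "p")
  b2 <- bootstrap_support(aln, n_reps = 150, seed = 5, model = "p")
  expect_identical(write_newick(b1), write_newick(b2))
  collect <- function(tree) {
    out <- c()
    walk <- function(node) {
      if (!is.null(node$tip)) return()
      if (!is.na(node$support)) out <<- c(out, node$support)
      for (ch in node$children) walk(ch)
    }
    walk(tree$root)
    out
  }
  s1 <- collect(b1)
  expect_true(all(s1 >= 0 & s1 <= 100))
  b3 <- bootstrap_support(aln, n_reps = 400, seed = 900, model = "p")
  b4 <- bootstrap_support(aln, n_reps = 400, seed = 1800, model = "p")
  expect_true(all(abs(sort(collect(b3)) - sort(collect(b4))) <= 5))
})

test_that("Newick output parses back to an isomorphic tree", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- write_newick(nj_tree(d))
  expect_match(nwk, "^\\(.*\\);$")
  parsed <- ape::read.tree(text = nwk)
  expect_setequal(parsed$tip.label, c("A", "B", "C"))
  # supports serialize as integers 0-100
  withr::with_seed(81, {
    aln <- c(a = random_dna(80), b = random_dna(80), c = random_dna(80),
             d = random_dna(80))
  })
  bt <- bootstrap_support(aln, n_reps = 50, seed = 3, model = "p")
  labels <- regmatches(write_newick(bt),
                       gregexpr("\\)[0-9]+", write_newick(bt)))[[1]]
  expect_true(length(labels) >= 1)
})
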
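model <- jtt_model()

test_that("the JTT rate matrix and its propagator are a proper CTMC", {
  Q <- model$Q
  expect_equal(unname(rowSums(Q)), rep(0, 20), tolerance = 1e-12)
  expect_equal(-sum(model$pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance
  expect_equal(model$pi * Q, t(model$pi * Q), tolerance = 1e-12,
               ignore_attr = TRUE)
  for (t in c(0, 0.1, 1, 5)) {
    P <- prob_matrix(model, t)
    expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-9)
    expect_equal(unname(drop(model$pi %*% P)), unname(model$pi), tolerance = 1e-9)
  }
  expect_equal(prob_matrix(model, 0), diag(20), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pairwise JTT distances behave like a metric estimate", {
  s <- paste(rep("ARNDCQEGHILKMFPSTWYV", 10), collapse = "")
  expect_equal(jtt_distance(s, s, model)$distance, 0)

  set.seed(5)
  for (rep in 1:3) {
    sim <- simulate_family(
      family_sim_spec(n_taxa = 2, L = 150, ragged_frac = 0,
                      fraction_invariant = 0, fraction_fast = 0,
                      tree = ape::read.tree(text = "(seq01:0.2,seq02:0.2);")),
      seed = rep)
    a <- sim$family$seqs[[1]]; b <- sim$family$seqs[[2]]
    expect_equal(jtt_distance(a, b, model)$distance,
                 jtt_distance(b, a, model)$distance, tolerance = 1e-8)
  }

  expect_error(jtt_distance("A-", "-A", model),
               class = "orsite_undefined_distance_error")
})

test_that("the ML distance matches an independent dense grid search", {
  sim <- simulate_family(
    family_sim_spec(n_taxa = 2, L = 200, ragged_frac = 0,
                    fraction_invariant = 0, fraction_fast = 0,
                    tree = ape::read.tree(text = "(seq01:0.15,seq02:0.15);")),
    seed = 23)
  a <- strsplit(sim$family$seqs[[1]], "")[[1]]
  b <- strsplit(sim$family$seqs[[2]], "")[[1]]
  est <- jtt_distance(a, b, model)$distance

  # oracle: dense grid over the likelihood, written from the formula
  ia <- match(a, model$alphabet); ib <- match(b, model$alphabet)
  ok <- !is.na(ia) & !is.na(ib)
  grid <- seq(1e-4, 2, by = 1e-4)
  ll <- vapply(grid, function(t) {
    P <- prob_matrix(model, t)
    sum(log(model$pi[ia[ok]] * P[cbind(ia[ok], ib[ok])]))
  }, 0)
  expect_lt(abs(est - grid[which.max(ll)]), 1e-3)
})

test_that("distances agree with phangorn's independent JTT ML implementation", {
  skip_if_not_installed("phangorn")
  sim <- simulate_family(family_sim_spec(n_taxa = 5, L = 300, ragged_frac = 0),
                         seed = 11)
  dm <- distance_matrix(sim$family, model)
  pd <- phangorn::phyDat(sim$family$mat, type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
  expect_equal(dm$d, ref[rownames(dm$d), colnames(dm$d)], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("distance estimates increase with simulated divergence", {
  depths <- seq(0.1, 1.9, by = 0.2)
  est <- vapply(seq_along(depths), function(i) {
    sim <- simulate_family(
      family_sim_spec(n_taxa = 2, L = 1000, ragged_frac = 0,
                      fraction_invariant = 0, fraction_fast = 0,
                      tree = ape::read.tree(text = sprintf(
                        "(seq01:%f,seq02:%f);", depths[i] / 2, depths[i] / 2))),
      seed = 100 + i)
    jtt_distance(sim$family$seqs[[1]], sim$family$seqs[[2]], model)$distance
  }, 0)
  expect_gt(cor(depths, est, method = "spearman"), 0.95)
})

test_that("the distance matrix is symmetric with a zero diagonal", {
  fam <- aligned_family(c(x = "MKVLAW", y = "MKVLAW", z = "MKILGW"))
  dm <- distance_matrix(fam, model)
  expect_equal(dm$d, t(dm$d))
  expect_equal(diag(dm$d), setNames(rep(0, 3), fam$ids))
  expect_equal(dm$d["x", "y"], 0)  # identical members
  s <- distance_summary(dm, pair = c("x", "z"))
  expect_equal(s$pair, dm$d["x", "z"])
  expect_equal(s$max, max(dm$d))
})

test_that("NJ reproduces closed-form and additive cases exactly", {
  D3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D3)
  tip_edge <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])], tr$tip.label)
  expect_equal(tip_edge[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  D2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- nj_tree(D2)
  expect_equal(sum(tr2$edge.length), 1)  # single edge of length d(AB)

  expect_error(nj_tree(D2[1, 1, drop = FALSE]), class = "orsite_validation_error")

  set.seed(9)
  for (rep in 1:10) {
    src <- ape::rtree(sample(4:10, 1), rooted = FALSE)
    D <- ape::cophenetic.phylo(src)
    rec <- nj_tree(D)
    expect_setequal(tree_bipartitions(rec), tree_bipartitions(src))
    expect_equal(sort(rec$edge.length), sort(ape::unroot(src)$edge.length),
                 tolerance = 1e-8)
    # independent reconstruction cross-check
    expect_setequal(tree_bipartitions(rec), tree_bipartitions(ape::nj(D)))
  }
})

test_that("Newick output round-trips and display rooting is cosmetic", {
  set.seed(31)
  src <- ape::rtree(7, rooted = FALSE)
  txt <- write_newick(src)
  back <- ape::read.tree(text = txt)
  expect_setequal(tree_bipartitions(back), tree_bipartitions(src))
  expect_equal(sort(back$edge.length), sort(src$edge.length), tolerance = 1e-9)

  rooted_txt <- write_newick(src, outgroup = src$tip.label[1])
  rooted <- ape::read.tree(text = rooted_txt)
  expect_setequal(tree_bipartitions(rooted), tree_bipartitions(src))

  expect_error(write_newick(src, outgroup = "missing_taxon"),
               class = "orsite_validation_error")

  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(src, f)
  expect_setequal(tree_bipartitions(ape::read.tree(f)), tree_bipartitions(src))
})

test_that("bootstrap support is deterministic and unanimous when forced", {
  fam <- unanimous_family()
  bt1 <- suppressWarnings(bootstrap_support(fam, model, replicates = 100, seed = 4))
  bt2 <- suppressWarnings(bootstrap_support(fam, model, replicates = 100, seed = 4))
  expect_identical(attr(bt1, "support"), attr(bt2, "support"))
  expect_true(all(attr(bt1, "support") == 100))

  # a different seed still gives 100% here because every resample of
  # identical columns is the same alignment
  bt3 <- suppressWarnings(bootstrap_support(fam, model, replicates = 50, seed = 99))
  expect_true(all(attr(bt3, "support") == 100))

  # support values land in the written Newick as internal labels
  txt <- write_newick(bt1)
  expect_match(txt, "\\)100:")
})

test_that("bootstrap support on a real simulated family stays in [0, 100]", {
  sim <- simulate_family(family_sim_spec(n_taxa = 6, L = 120, ragged_frac = 0),
                         seed = 8)
  bt <- suppressWarnings(bootstrap_support(sim$family, model,
                                           replicates = 30, seed = 2))
  sup <- attr(bt, "support")
  expect_true(all(sup >= 0 & sup <= 100))
  expect_length(sup, length(tree_bipartitions(bt)))
})
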
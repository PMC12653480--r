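test_that("FASTA reading enforces the aligned-family contract", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">b", "MK-"), f)
  fam <- read_fasta(f, aligned = TRUE)
  expect_s3_class(fam, "aligned_family")
  expect_equal(fam$L, 3L)
  expect_equal(fam$ids, c("a", "b"))

  writeLines(c(">a", "MKV", ">b", "MKVA"), f)
  expect_error(read_fasta(f, aligned = TRUE), class = "orsite_format_error")

  writeLines(character(0), f)
  expect_error(read_fasta(f, aligned = TRUE), class = "orsite_format_error")

  writeLines(c(">a desc ignored", "MKU"), f)   # U is not in the alphabet
  expect_error(read_fasta(f), regexp = "'a'", class = "orsite_format_error")
})

test_that("FASTA write-then-read round-trips ids and residues exactly", {
  fam <- toy_family()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(fam, f)
  back <- read_fasta(f, aligned = TRUE)
  expect_identical(back$ids, fam$ids)
  expect_identical(back$seqs, fam$seqs)
  # and the bytes themselves are stable across rewrites
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(back, f2)
  expect_identical(readBin(f, "raw", file.size(f)), readBin(f2, "raw", file.size(f2)))
})

test_that("conservation scores follow the modal-frequency formula", {
  fam <- aligned_family(c(s1 = "AAA", s2 = "AAA", s3 = "A-A", s4 = "ALX"))
  pr <- conservation_profile(fam)
  # col 1: A,A,A,A; col 2: A,A,-,L; col 3: A,A,A,X
  expect_equal(pr$Ci, c(1.0, 2 / 3, 1.0))
  expect_equal(pr$ni, c(4L, 3L, 3L))
  expect_equal(pr$modal_residue, c("A", "A", "A"))

  # (A,A,-,X): gap and ambiguity excluded from numerator and ni
  fam2 <- aligned_family(c(s1 = "A", s2 = "A", s3 = "-", s4 = "X"))
  pr2 <- conservation_profile(fam2)
  expect_equal(pr2$Ci, 1.0)
  expect_equal(pr2$ni, 2L)

  # all-gap column is flagged, scored 0, and never above any threshold
  fam3 <- aligned_family(c(s1 = "A-", s2 = "A-", s3 = "A-"))
  pr3 <- conservation_profile(fam3)
  expect_true(pr3$no_data[2])
  expect_equal(pr3$Ci[2], 0)

  # modal-residue tie reports the alphabetically first residue
  fam4 <- aligned_family(c(s1 = "L", s2 = "A", s3 = "L", s4 = "A"))
  expect_equal(conservation_profile(fam4)$modal_residue, "A")
})

test_that("conservation equals brute-force counting on random families", {
  set.seed(401)
  letters20 <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
  for (rep in 1:5) {
    nseq <- sample(3:12, 1)
    L <- sample(20:80, 1)
    mat <- matrix(sample(c(letters20, "-", "X"), nseq * L, TRUE,
                         prob = c(rep(1, 20), 3, 1)), nseq, L)
    seqs <- setNames(apply(mat, 1, paste, collapse = ""),
                     sprintf("s%02d", seq_len(nseq)))
    # guard the all-gap row edge: ensure every sequence has a residue
    mat[, 1] <- "A"
    seqs <- setNames(apply(mat, 1, paste, collapse = ""), names(seqs))
    pr <- conservation_profile(aligned_family(seqs))
    oracle <- brute_conservation(mat)
    expect_equal(pr$Ci, unname(oracle[, "Ci"]))
    expect_equal(pr$ni, unname(as.integer(oracle[, "ni"])))
  }
})

test_that("conservation is invariant to member order and duplication", {
  fam <- toy_family()
  pr <- conservation_profile(fam)
  perm <- aligned_family(fam$seqs[c(3, 1, 4, 2)], reference = fam$reference_id)
  expect_equal(conservation_profile(perm)$Ci, pr$Ci)
  expect_equal(conservation_profile(perm)$ni, pr$ni)

  dup <- fam$seqs[c(1, 2, 3, 4, 1, 2, 3, 4)]
  names(dup) <- paste0(names(dup), rep(c("", "_copy"), each = 4))
  prd <- conservation_profile(aligned_family(dup, reference = "a"))
  expect_equal(prd$Ci, pr$Ci)        # frequency, not count
  expect_equal(prd$ni, 2L * pr$ni)

  # Ci == 1 exactly when all valid residues agree and ni >= 1
  expect_true(all((pr$Ci == 1) == (pr$ni >= 1 &
    apply(fam$mat, 2, function(cl) length(unique(cl[cl %in% orsite:::AA20]))) == 1)))
})

test_that("summaries count strict-high and non-strict-variable columns", {
  mk_profile <- function(scores) {
    data.frame(column = seq_along(scores), ref_position = seq_along(scores),
               modal_residue = rep("A", length(scores)),
               ni = rep(4L, length(scores)), Ci = scores,
               no_data = rep(FALSE, length(scores)))
  }
  s <- summarize_conservation(mk_profile(c(1.0, 0.75, 0.5)), 0.7, 0.9)
  expect_equal(s$n_high, 1L)
  expect_equal(s$n_variable, 1L)
  expect_equal(s$mean, 0.75)

  s2 <- summarize_conservation(mk_profile(rep(0.8, 10)), 0.7, 0.9)
  expect_equal(s2$n_high, 0L)
  expect_equal(s2$n_variable, 0L)

  set.seed(77)
  scores <- runif(200)
  s3 <- summarize_conservation(mk_profile(scores), 0.7, 0.9)
  expect_equal(s3$n_high, sum(scores > 0.9))
  expect_equal(s3$n_variable, sum(scores <= 0.7))
  expect_equal(s3$median, median(scores))

  expect_error(summarize_conservation(mk_profile(numeric(0))),
               class = "orsite_validation_error")
})

test_that("reference-coordinate projection skips reference gaps", {
  fam <- aligned_family(c(ref = "M-K", other = "MAK"), reference = "ref")
  pr <- conservation_profile(fam)
  rc <- residue_conservation(pr)
  expect_equal(names(rc), c("1", "2"))
  expect_equal(unname(rc), pr$Ci[c(1, 3)])
  expect_equal(pr$ref_position, c(1L, NA_integer_, 2L))

  # ungapped reference: exactly L keys, and a planted invariant column
  # carries conservation 1.0 at its reference position
  sim <- simulate_family(family_sim_spec(n_taxa = 8, L = 120, planted = 50L),
                         seed = 19)
  rc2 <- residue_conservation(conservation_profile(sim$family))
  expect_length(rc2, 120L)
  expect_equal(unname(rc2["50"]), 1.0)
})
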
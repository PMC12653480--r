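test_that("loop derivation reproduces the seven-helix OR annotation", {
  ann <- derive_regions(or_topology())
  tab <- ann$table
  get <- function(lab) unlist(tab[tab$label == lab, c("start", "end")], use.names = FALSE)
  expect_equal(get("N_tail"), c(1, 10))
  expect_equal(get("EL1"), c(32, 41))
  expect_equal(get("IL1"), c(63, 102))
  expect_equal(get("EL2"), c(124, 156))
  expect_equal(get("IL2"), c(178, 233))
  expect_equal(get("EL3"), c(255, 264))
  expect_equal(get("IL3"), c(286, 335))
  # TM7 runs to the final residue: the extracellular C-tail has length 0
  expect_equal(tab$length[tab$label == "C_tail"], 0L)
  expect_equal(tab$side[tab$label == "C_tail"], "extracellular")
})

test_that("single and adjacent TM segments handle sides and empty loops", {
  ann <- derive_regions(topology_spec(40, list(c(11, 31)), "cytoplasmic"))
  tab <- ann$table
  expect_equal(tab$side[tab$label == "N_tail"], "cytoplasmic")
  expect_equal(unlist(tab[tab$label == "C_tail", c("start", "end")],
                      use.names = FALSE), c(32, 40))
  expect_equal(tab$side[tab$label == "C_tail"], "extracellular")

  ann2 <- derive_regions(topology_spec(40, list(c(10, 20), c(21, 30)), "cytoplasmic"))
  loop <- ann2$table[grepl("^(EL|IL)", ann2$table$label), ]
  expect_equal(nrow(loop), 1L)
  expect_equal(loop$length, 0L)      # zero-length loop, flagged not dropped

  expect_error(topology_spec(40, list(c(10, 20), c(15, 30))),
               class = "orsite_validation_error")
  expect_error(topology_spec(40, list(c(30, 20))),
               class = "orsite_validation_error")
})

test_that("residue classification is a partition with alternating sides", {
  ann <- derive_regions(or_topology())
  expect_equal(classify_residue(ann, 146)$label, "EL2")
  expect_equal(classify_residue(ann, 146)$side, "extracellular")
  expect_equal(classify_residue(ann, 1)$label, "N_tail")
  expect_error(classify_residue(ann, 0), class = "orsite_validation_error")
  expect_error(classify_residue(ann, 357), class = "orsite_validation_error")

  # exhaustive scan: every residue gets exactly one label
  expect_true(all(nzchar(ann$labels)))
  expect_equal(length(ann$labels), 356L)
  # region lengths sum to the protein length
  expect_equal(sum(ann$table$length), 356L)
})

test_that("region properties hold over random topologies", {
  set.seed(55)
  for (rep in 1:20) {
    k <- sample(1:8, 1)
    bounds <- sort(sample(1:200, 2 * k))
    segs <- matrix(bounds, ncol = 2, byrow = TRUE)
    len <- max(bounds) + sample(0:10, 1)
    spec <- topology_spec(len, segs, sample(c("cytoplasmic", "extracellular"), 1))
    ann <- derive_regions(spec)
    expect_equal(sum(ann$table$length), len)
    loops <- ann$table[grepl("^(EL|IL)", ann$table$label), ]
    expect_equal(nrow(loops), k - 1L)

    # flipping the N-terminal side swaps every EL <-> IL label
    flipped <- derive_regions(topology_spec(
      len, segs, orsite:::flip_side(spec$n_term_side)))
    swap <- chartr("EI", "IE", sub("L", "L", loops$label))
    expect_equal(flipped$table$label[grepl("^(EL|IL)", flipped$table$label)], swap)
    tm_rows <- grepl("^TM", ann$table$label)
    expect_equal(flipped$table[tm_rows, ], ann$table[tm_rows, ])
  }
})

test_that("candidate masks implement both region rules", {
  ann <- derive_regions(or_topology())
  full <- candidate_mask(ann, "loops_plus_full_tms", tm_min_index = 3)
  # the five experimentally chosen residues all fall inside the mask
  expect_true(all(c(103, 107, 114, 122, 146) %in% full$positions))
  # ELs + TM3..TM7, nothing else
  expected <- sort(c(32:41, 124:156, 255:264, 103:123, 157:177,
                     234:254, 265:285, 336:356))
  expect_equal(full$positions, expected)

  termini0 <- candidate_mask(ann, "loops_plus_tm_termini", w = 0)
  expect_equal(termini0$positions, sort(c(32:41, 124:156, 255:264)))

  termini4 <- candidate_mask(ann, "loops_plus_tm_termini", w = 4)
  expect_true(all(120:123 %in% termini4$positions))   # TM3 exits extracellular
  expect_false(103 %in% termini4$positions)           # its cytoplasmic end

  expect_error(candidate_mask(ann, "loops_plus_tm_termini", w = -1),
               class = "orsite_validation_error")
  expect_error(candidate_mask(ann, "loops_plus_full_tms", tm_min_index = 9),
               class = "orsite_validation_error")
})

test_that("topology files round-trip and exports convert coordinates", {
  spec <- or_topology()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_topology(spec, f)
  back <- read_topology(f)
  expect_equal(back$tm_segments, spec$tm_segments)
  expect_equal(back$protein_length, spec$protein_length)
  expect_equal(back$n_term_side, spec$n_term_side)

  ann <- derive_regions(spec)
  bed <- regions_to_bed(ann)
  expect_equal(bed$start[bed$name == "TM1"], 10L)   # 0-based half-open
  expect_equal(bed$end[bed$name == "TM1"], 31L)
  expect_false("C_tail" %in% bed$name)              # zero-length dropped
})
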
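# Conservation scoring, block discovery, length clustering, block sharing
# and nucleotide consensus.

make_family <- function(seqs) aligned_family(stats::setNames(seqs, paste0("s", seq_along(seqs))))

test_that("column conservation is plurality frequency with gaps as mismatches", {
  fam <- make_family(c(rep("W", 7), rep("W", 3)))
  expect_equal(column_conservation(fam, 1), 1.0)
  fam2 <- make_family(c(rep("D", 7), rep("E", 3)))
  expect_equal(column_conservation(fam2, 1), 0.7)
  fam3 <- make_family(rep("-", 10))
  expect_equal(column_conservation(fam3, 1), 0.0)
  # gaps lower the score of the plurality residue and never win themselves
  fam4 <- make_family(c("D", "D", "D", "-", "-", "-", "-"))
  expect_equal(column_conservation(fam4, 1), 3 / 7)
  expect_error(column_conservation(fam4, 2), "out of range")
})

test_that("an all-identical alignment yields one block covering all columns", {
  fam <- make_family(rep("MSSNWDRACEK", 5))
  b <- find_conserved_blocks(fam, min_len = 3, min_cons = 1)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(1, 11))
  expect_identical(b$motif, "MSSNWDRACEK")
})

test_that("a planted invariant block is recovered exactly amid strong noise", {
  # one cluster, 30 sequences, 20% substitution noise, strict threshold:
  # only the planted 9-mer at columns 40-48 must survive
  pb <- data.frame(motif = "SSNWDRACE", column = 40L, scope = "shared",
                   stringsAsFactors = FALSE)
  sim <- sim_family(n_short = 0, n_long = 30, len_short = 100, len_long = 100,
                    planted_blocks = pb, substitution_rate = 0.2, seed = 31)
  b <- find_conserved_blocks(sim$family, min_len = 7, min_cons = 1.0)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start, b$end), c(40, 48))
  expect_identical(b$motif, "SSNWDRACE")
})

test_that("reported blocks are maximal: extending any violates a threshold", {
  sim <- sim_family(substitution_rate = 0.08, seed = 32)
  min_cons <- 0.8
  b <- find_conserved_blocks(sim$family, min_len = 7, min_cons = min_cons)
  expect_gt(nrow(b), 0)
  mat <- do.call(rbind, strsplit(unname(sim$family$records), ""))
  col_ok <- function(j) {
    if (j < 1 || j > sim$family$n_cols) return(FALSE)
    column_conservation(sim$family, j) >= min_cons &&
      mean(mat[, j] == "-") < 1 - min_cons
  }
  for (i in seq_len(nrow(b))) {
    expect_false(col_ok(b$start[i] - 1))
    expect_false(col_ok(b$end[i] + 1))
  }
})

test_that("length clustering splits at the largest gap, invariant to order", {
  seqs <- c(a = strrep("A", 400), b = paste0(strrep("A", 200), strrep("-", 200)),
            c = paste0(strrep("A", 210), strrep("-", 190)),
            d = paste0(strrep("A", 390), strrep("-", 10)))
  cl <- cluster_by_length(aligned_family(seqs))
  expect_setequal(cl$short$member_ids, c("b", "c"))
  expect_setequal(cl$long$member_ids, c("a", "d"))
  expect_false(cl$degenerate)
  # permutation invariance
  cl2 <- cluster_by_length(aligned_family(seqs[c(3, 1, 4, 2)]))
  expect_setequal(cl2$short$member_ids, cl$short$member_ids)
  # degenerate case: identical lengths
  expect_warning(cld <- cluster_by_length(make_family(rep(strrep("A", 300), 2))),
                 "identical")
  expect_true(cld$degenerate)
})

test_that("synthetic two-cluster families are recovered exactly", {
  sim <- sim_family(seed = 33)
  cl <- cluster_by_length(sim$family)
  expect_setequal(cl$short$member_ids, sim$truth$clusters$short)
  expect_setequal(cl$long$member_ids, sim$truth$clusters$long)
})

test_that("shared-block detection re-tags by span overlap and motif identity", {
  b1 <- find_conserved_blocks(make_family(rep("MSSNWDRACEK", 4)), min_len = 3, min_cons = 1)
  # identical lists: all shared
  sh <- shared_blocks(b1, b1)
  expect_true(all(sh$scope == "shared"))
  # disjoint spans: none shared
  b2 <- b1; b2$start <- b1$start + 50; b2$end <- b1$end + 50
  sh2 <- shared_blocks(b1, b2, labels = c("short-only", "long-only"))
  expect_setequal(sh2$scope, c("short-only", "long-only"))
  # planted scenario: shared central blocks + long-cluster flanks
  sim <- sim_family(n_short = 20, n_long = 20, substitution_rate = 0.3, seed = 34)
  long_ids <- sim$truth$clusters$long
  fam_long <- aligned_family(sim$family$records[long_ids])
  fam_short <- aligned_family(sim$family$records[sim$truth$clusters$short])
  bl <- find_conserved_blocks(fam_long, min_len = 7, min_cons = 1)
  bs <- find_conserved_blocks(fam_short, min_len = 7, min_cons = 1)
  sh3 <- shared_blocks(bs, bl, labels = c("short-only", "long-only"))
  truth <- sim$truth$blocks
  shared_truth <- truth[truth$scope == "shared", ]
  got_shared <- sh3[sh3$scope == "shared", ]
  expect_setequal(got_shared$motif, shared_truth$motif)
  expect_setequal(got_shared$start, shared_truth$start)
  long_truth <- truth[truth$scope == "long-only", ]
  expect_true(all(long_truth$motif %in% sh3$motif[sh3$scope == "long-only"]))
})

test_that("nucleotide consensus applies plurality then IUPAC-union fallback", {
  expect_identical(unclass(nucleotide_consensus(c("AC", "AC", "AG"), 0.6)), "AC")
  expect_identical(unclass(nucleotide_consensus(c("C", "C", "G"), 1.0)), "S")
  expect_identical(unclass(nucleotide_consensus(rep("ACGTACGT", 3), 0.6)), "ACGTACGT")
  # gap-majority columns are dropped
  expect_identical(unclass(nucleotide_consensus(c("A-G", "A-G", "ACG", "A-G"), 0.6)), "AG")
  expect_error(nucleotide_consensus(c("AC", "ACG")), "equal length")
  expect_error(nucleotide_consensus("AC"), "at least 2")
})

test_that("alignment IO and block JSON round-trip", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "MSSNWDRACEK", ">s2", "MSSNWDRACEK", ">s3", "MSSNWDRACEF"), f)
  fam <- read_alignment(f)
  expect_equal(fam$n_seqs, 3)
  expect_equal(fam$n_cols, 11)
  b <- find_conserved_blocks(fam, min_len = 3, min_cons = 0.9)
  j <- withr::local_tempfile(fileext = ".json")
  write_blocks_json(b, j)
  b2 <- read_blocks_json(j)
  expect_equal(b2$motif, b$motif)
  expect_equal(b2$start, b$start)
  expect_equal(b2$end, b$end)
  expect_equal(b2$conservation, b$conservation, tolerance = 1e-12)
})
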
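test_that("structure mapping follows the alignment and flags deletions", {
  struct <- parse_dotbracket("GGGAAACCC", "(((...)))")
  # identity alignment: query positions equal reference positions
  aln <- c(ref = "GGGAAACCC", query = "GGGAAACCC")
  pm <- map_structure("GGGAAACCC", struct, aln)
  expect_equal(pm$query_i, pm$ref_i)
  expect_equal(pm$query_j, pm$ref_j)
  # deletion inside a paired region
  aln2 <- c(ref = "GGGAAACCC", query = "GG-AAACCC")
  pm2 <- map_structure("GGGAAACCC", struct, aln2)
  expect_true(any(is.na(pm2$query_i)))
  rep2 <- classify_paired_changes(pm2, "GGGAAACCC", "GGAAACCC")
  expect_equal(rep2$n_pair_deleted, 1L)
  # swapped rows must not be silently accepted
  expect_error(map_structure("GGGAAACCC", struct,
                             c(ref = "GGAAACCCC", query = "GGGAAACCC")),
               "swapped|spell")
  expect_error(map_structure("GGGAAACC", struct, aln), "length")
})

test_that("paired changes are classified by pairing retention", {
  struct <- parse_dotbracket("GCAAAAGC", "((....))")  # pairs G-C, C-G
  id <- function(q) {
    aln <- c(ref = "GCAAAAGC", query = q)
    classify_paired_changes(map_structure("GCAAAAGC", struct, aln),
                            "GCAAAAGC", q)
  }
  expect_equal(id("GCAAAAGC")$n_unchanged, 2L)
  r1 <- id("ACAAAAGT")   # pair1 G:C -> A:T both changed, retained
  expect_equal(r1$n_fully_compensatory, 1L)
  r2 <- id("GTAAAAGC")   # pair2: C->T gives G:T wobble, one side changed
  expect_equal(r2$n_half, 1L)
  r3 <- id("GAAAAAGC")   # pair2: C->A breaks pairing
  expect_equal(r3$n_disruptive, 1L)
  # zero report on ref vs ref
  z <- id("GCAAAAGC")
  expect_equal(z$n_fully_compensatory + z$n_half + z$n_disruptive +
                 z$n_pair_deleted, 0L)
})

test_that("counts are invariant to aligned flank shifts", {
  struct <- random_secondary_structure(120, 3, seed = 5)
  ev <- simulate_rrna(struct, 25, 0.6, seed = 6)
  aln <- c(ref = struct$seq, query = ev$seq)
  r1 <- classify_paired_changes(map_structure(struct$seq, struct, aln),
                                struct$seq, ev$seq)
  # prepend a perfectly aligned flank to both rows: same ref positions,
  # shifted alignment columns
  flank <- strrep("A", 17)
  struct_pad <- parse_dotbracket(
    paste0(flank, struct$seq),
    paste0(strrep(".", 17), paste(rep(".", 0), collapse = ""),
           local({
             db <- rep(".", 120)
             db[struct$pairs[, 1]] <- "("
             db[struct$pairs[, 2]] <- ")"
             paste(db, collapse = "")
           })))
  aln2 <- c(ref = paste0(flank, struct$seq), query = paste0(flank, ev$seq))
  r2 <- classify_paired_changes(
    map_structure(paste0(flank, struct$seq), struct_pad, aln2),
    paste0(flank, struct$seq), paste0(flank, ev$seq))
  for (f in c("n_fully_compensatory", "n_half", "n_disruptive",
              "n_pair_deleted"))
    expect_equal(r2[[f]], r1[[f]])
})

test_that("conserved-core identity is computed inside and outside the mask", {
  struct <- random_secondary_structure(150, 4, seed = 8)
  core <- sort(unique(as.vector(struct$pairs)))
  # evolve only OUTSIDE the core: core identity must be 100
  s <- strsplit(struct$seq, "")[[1]]
  set.seed(9)
  outside <- setdiff(seq_along(s), core)
  for (p in sample(outside, 20))
    s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  q <- paste(s, collapse = "")
  aln <- c(ref = struct$seq, query = q)
  ci <- conserved_core_identity(aln, core)
  expect_equal(ci$core, 100)
  expect_lt(ci$non_core, 100)
  # mask covering everything reproduces the overall identity
  all_ci <- conserved_core_identity(aln, seq_len(150))
  expect_equal(all_ci$core, percent_identity(aln[1], aln[2]))
  expect_error(conserved_core_identity(aln, integer()), "empty")
})

test_that("the aligner + structure loop recovers generator truth", {
  struct <- random_secondary_structure(220, 6, seed = 11)
  ev <- simulate_rrna(struct, 30, 1, seed = 12)
  aln <- align_rrna(struct$seq, ev$seq)
  pm <- map_structure(struct$seq, struct, aln)
  rep0 <- classify_paired_changes(pm, struct$seq, ev$seq)
  expect_equal(rep0$n_fully_compensatory,
               sum(ev$truth$type == "compensatory"))
})
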
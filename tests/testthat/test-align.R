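test_that("Smith-Waterman matches hand and oracle scores", {
  s <- sensitive_scheme()
  expect_equal(smith_waterman("ACGT", "ACGT", s)$score, 20L)
  # extending ACG with the final mismatch scores 15 - 4 = 11, so the
  # optimum stays at the 3-match prefix (verified by the oracle DP)
  expect_equal(sw_score_oracle("ACGT", "ACGA"), 15)
  expect_equal(smith_waterman("ACGT", "ACGA", s)$score, 15L)
  r <- smith_waterman("AAAA", "CCCC", s)
  expect_equal(r$score, 0L)
  expect_equal(r$q_aln, "")
})

test_that("Smith-Waterman agrees with an independent DP on random pairs", {
  set.seed(11)
  s <- sensitive_scheme()
  for (i in 1:25) {
    a <- rand_dna(sample(5:40, 1))
    b <- rand_dna(sample(5:40, 1))
    expect_equal(smith_waterman(a, b, s)$score, sw_score_oracle(a, b))
  }
  # traceback reproduces the score
  a <- rand_dna(60, seed = 3)
  b <- mutate_seq(a, 0.8, seed = 4)
  r <- smith_waterman(a, b, s)
  qa <- strsplit(r$q_aln, "")[[1]]; sa <- strsplit(r$s_aln, "")[[1]]
  sc <- 0; in_gap <- FALSE
  for (k in seq_along(qa)) {
    if (qa[k] == "-" || sa[k] == "-") {
      sc <- sc - (if (in_gap) 0 else s$gap_open) - s$gap_extend
      in_gap <- TRUE
    } else {
      sc <- sc + (if (qa[k] == sa[k]) s$reward else s$penalty)
      in_gap <- FALSE
    }
  }
  expect_equal(sc, r$score)
})

test_that("seeded search finds exact, divergent and minus-strand matches", {
  s <- sensitive_scheme()
  set.seed(21)
  subj <- rand_dna(2000)
  # exact 12-mer: one HSP of score 60, identity 100
  q <- substr(subj, 501, 512)
  h <- seeded_local_search(q, subj, s)
  expect_gte(nrow(h), 1L)
  expect_equal(h$score[1], 60L)
  expect_equal(h$pident[1], 100)
  # reverse complement of a segment: minus strand
  q2 <- revcomp(substr(subj, 801, 900))
  h2 <- seeded_local_search(q2, subj, s)
  expect_equal(h2$strand[1], "-")
  expect_equal(h2$s_start[1], 801L)
  expect_equal(h2$s_end[1], 900L)
  # W larger than query: empty result, not an error
  expect_equal(nrow(seeded_local_search("ACGTA", subj, s)), 0L)
})

test_that("seeded search never beats the exact oracle and usually equals it", {
  set.seed(31)
  s <- sensitive_scheme()
  hits <- 0
  for (i in 1:40) {
    subj <- rand_dna(800)
    core <- substr(subj, 301, 450)
    q <- paste0(rand_dna(50), mutate_seq(core, 0.7, seed = i), rand_dna(50))
    swr <- smith_waterman(q, subj, s)
    h <- seeded_local_search(q, subj, s)
    if (nrow(h)) {
      expect_lte(max(h$score), swr$score)
      if (max(h$score) == swr$score) hits <- hits + 1
    }
  }
  expect_gte(hits, 36)   # >= 90% equality on this mini-batch
})

test_that("strand symmetry: searching the reverse-complemented genome mirrors scores", {
  set.seed(41)
  subj <- rand_dna(1500)
  q <- mutate_seq(substr(subj, 401, 700), 0.8, seed = 2)
  s <- sensitive_scheme()
  h1 <- seeded_local_search(q, subj, s)
  h2 <- seeded_local_search(q, revcomp(subj), s)
  expect_equal(sort(h1$score), sort(h2$score))
  expect_equal(sum(h1$strand == "+"), sum(h2$strand == "-"))
})

test_that("circular subjects yield origin-spanning HSPs", {
  set.seed(51)
  g <- rand_dna(1000)
  q <- paste0(substr(g, 951, 1000), substr(g, 1, 50))   # spans the origin
  h <- seeded_local_search(q, g, sensitive_scheme(), circular = TRUE)
  expect_gte(nrow(h), 1L)
  expect_equal(h$s_start[1], 951L)
  expect_equal(h$s_end[1], 1050L)   # end beyond L marks the wrap
})

test_that("dual-strategy search tags provenance and merges both passes", {
  set.seed(61)
  gene1 <- rand_dna(300); gene2 <- rand_dna(300)
  genome <- paste0(rand_dna(200), mutate_seq(gene1, 0.75, 1), rand_dna(200),
                   mutate_seq(gene2, 0.97, 2), rand_dna(200))
  names(genome) <- "g"
  panel <- c("ref|gene1" = gene1)                    # gene2 not in panel
  rel <- c(gene2 = mutate_seq(gene2, 0.98, 3))      # gene1 not in relative
  h <- dual_strategy_search(genome, panel, rel)
  expect_setequal(unique(h$strategy[h$gene == "gene1"]), "distant_panel")
  expect_setequal(unique(h$strategy[h$gene == "gene2"]), "close_relative")
  expect_error(dual_strategy_search(genome, NULL, NULL), "empty")
  # empty (gene-free) genome: no HSPs above threshold for real genes
  h0 <- dual_strategy_search(setNames(rand_dna(500), "g"), panel, rel)
  expect_true(all(h0$score < 150))
})

test_that("percent identity excludes gap columns", {
  expect_equal(percent_identity(strrep("A", 100), strrep("A", 100)), 100)
  expect_equal(percent_identity("AC-GT", "ACCGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_error(percent_identity("--", "AA"), "no gap-free")
})
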
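test_that("FASTA reading normalizes, validates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 first record", "acgtu", ">s2", "ACGTNACGT"), f)
  x <- read_fasta(f)
  expect_equal(unname(x["s1"]), "ACGTT")   # lowercase + U -> T
  expect_equal(unname(x["s2"]), "ACGTNACGT")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(x, f2)
  y <- read_fasta(f2)
  expect_equal(as.character(y), as.character(x))
  expect_equal(names(y), names(x))

  writeLines(character(), f2)
  expect_error(read_fasta(f2), "empty")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), f2)
  expect_error(read_fasta(f2), "duplicate.*a")
  writeLines(c(">a", "ACGT", ">b"), f2)
  expect_error(read_fasta(f2), "header-only")
  writeLines(c(">a", "ACXT"), f2)
  expect_error(read_fasta(f2), "invalid nucleotide")
})

test_that("GFF3 output is 1-based inclusive and handles multi-exon and wraparound", {
  si <- list(chr = list(length = 100L, circular = TRUE))
  # single-exon gene occupying positions 11..25
  ft <- feature_table("chr", "g1", start = 11L, end = 25L)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(ft, f, si)
  ln <- readLines(f)
  expect_equal(ln[1], "##gff-version 3")
  expect_match(ln[2], "\t11\t25\t")

  # two-exon feature: two exon lines sharing a Parent
  ft2 <- feature_table("chr", "g2", start = c(5L, 40L), end = c(20L, 60L),
                       exon_rank = 1:2)
  write_gff3(ft2, f, si)
  ln <- readLines(f)
  expect_equal(sum(grepl("Parent=g2", ln)), 2L)

  # wraparound gene on a 100 nt circular record: two lines, one ID,
  # segments tiling the gene
  ft3 <- feature_table("chr", "g3", start = 91L, end = 110L)
  write_gff3(ft3, f, si)
  ln <- grep("ID=g3", readLines(f), value = TRUE)
  expect_length(ln, 2L)
  segs <- do.call(rbind, lapply(strsplit(ln, "\t"), function(v)
    as.integer(v[4:5])))
  expect_equal(segs[1, ], c(91L, 100L))
  expect_equal(segs[2, ], c(1L, 10L))
  expect_equal(sum(segs[, 2] - segs[, 1] + 1L), 20L)

  # interval beyond a LINEAR record errors
  si_lin <- list(chr = list(length = 100L, circular = FALSE))
  expect_error(write_gff3(ft3, f, si_lin), "exceeds linear")

  # round-trip through read_gff3
  write_gff3(ft3, f, si)
  back <- read_gff3(f, si)
  expect_equal(back$start, 91L)
  expect_equal(back$end, 110L)
})

test_that("wraparound features are extracted correctly from circular genomes", {
  set.seed(9)
  g <- rand_dna(100)
  gene <- paste0(substr(g, 91, 100), substr(g, 1, 10))
  ft <- feature_table("chr", "g", start = 91L, end = 110L)
  expect_equal(extract_feature(setNames(g, "chr"), ft, "g"), gene)
})

test_that("newick reading validates and counts branches", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(nrow(tr$edge), 4L)
  writeLines("((A:1,B:1:1,C:2);", f)
  expect_error(read_newick(f), "position|parse")
})

test_that("dot-bracket parsing matches brackets and flags pseudoknots", {
  s <- parse_dotbracket("ACGUA", "((.))")
  expect_equal(s$pairs, matrix(c(1L, 2L, 5L, 4L), 2,
                               dimnames = list(NULL, c("i", "j"))))
  expect_equal(s$seq, "ACGTA")   # U -> T internally
  expect_false(any(s$pseudoknot))

  s2 <- parse_dotbracket("ACGT", "[[]]")
  expect_equal(nrow(s2$pairs), 2L)
  expect_true(all(s2$pseudoknot))

  expect_error(parse_dotbracket("ACG", "(()"), "unbalanced")
  expect_error(parse_dotbracket("ACGT", "))(("), "unbalanced bracket ')' at position 1")
  expect_error(parse_dotbracket("ACG", "(())"), "length")

  # round-trip through the file format
  f <- withr::local_tempfile(fileext = ".db")
  write_dotbracket(s, f, id = "x")
  s3 <- read_dotbracket(f)
  expect_equal(s3$pairs, s$pairs)
  expect_equal(s3$seq, s$seq)
})

test_that("editing tables validate their columns and indices", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tcodon_index\tsource", "cox1\t12\tempirical",
               "cox1\t40\tpredicted"), f)
  tb <- read_editing_table(f)
  expect_equal(edited_codons_for(tb, "cox1"), c(12L, 40L))
  expect_equal(edited_codons_for(tb, "cob"), integer())
  expect_error(read_editing_table(f, genes = c("cob")), "unknown gene")
  writeLines(c("gene\tcodon_index\tsource", "cox1\t-1\tempirical"), f)
  expect_error(read_editing_table(f), "positive")
})
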
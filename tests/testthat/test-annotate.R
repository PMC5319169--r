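test_that("HSP chaining builds single- and multi-exon models", {
  set.seed(71)
  gene <- rand_dna(600)
  # single locus, one HSP
  genome <- paste0(rand_dna(300), mutate_seq(gene, 0.8, 1), rand_dna(300))
  h <- seeded_local_search(gene, genome, sensitive_scheme(),
                           query_id = "q")
  mods <- chain_hsps(h, "g", nchar(genome))
  expect_gte(length(mods), 1L)
  expect_equal(nrow(mods[[1]]$exons), 1L)

  # two exons split by a 300 nt insert
  g2 <- mutate_seq(gene, 0.85, 2)
  genome2 <- paste0(rand_dna(300), substr(g2, 1, 300), rand_dna(300),
                    substr(g2, 301, 600), rand_dna(300))
  h2 <- seeded_local_search(gene, genome2, sensitive_scheme(),
                            query_id = "q")
  mods2 <- chain_hsps(h2, "g", nchar(genome2), max_gap = 5000L)
  expect_equal(nrow(mods2[[1]]$exons), 2L)
  # the two exons are separated by the insert
  expect_gt(mods2[[1]]$exons$start[2], mods2[[1]]$exons$end[1] + 250)

  # opposite strands are never chained
  expect_true(all(vapply(mods2, function(m)
    length(unique(m$hsps$strand)) == 1L, TRUE)))
})

test_that("gene status classification separates intact, truncated, pseudogene, absent", {
  set.seed(81)
  # a diverged but stop-free gene copy comes from the codon simulator
  tr <- ape::read.tree(text = "(ref:0.25,focal:0.25);")
  cfg <- sim_config(tr, omega = 0.3, gene_lengths = c(g = 210L), seed = 81)
  fam <- simulate_gene_family(cfg, "g")
  ref <- fam$cds[["ref"]]; div <- fam$cds[["focal"]]
  genome_of <- function(insert) setNames(
    paste0(rand_dna(500), insert, rand_dna(500)), "chr")
  annotate1 <- function(genome, relative = NULL)
    annotate_genome(genome, c("ref|g" = ref), relative, circular = FALSE)

  # full-length divergent copy: intact
  st <- annotate1(genome_of(div))$status
  expect_equal(st$status, "intact")

  # 66% of the reference length, no disruptions: truncated_intact
  st2 <- annotate1(genome_of(substr(div, 1, 3 * 139)))$status
  expect_equal(st2$status, "truncated_intact")

  # nonsense at codon 10 (closed loop with the generator): pseudogene
  broken <- inject_pseudogenization(
    div, list(list(type = "nonsense", pos = 10L)))$seq
  st3 <- annotate1(genome_of(broken))$status
  expect_equal(st3$status, "pseudogene")
  expect_match(st3$reasons, "premature_stop")

  # frameshift deletion: pseudogene with a frameshift reason
  fs <- inject_pseudogenization(
    div, list(list(type = "frameshift", pos = 90L)))$seq
  st4 <- annotate1(genome_of(fs))$status
  expect_equal(st4$status, "pseudogene")
  expect_match(st4$reasons, "frameshift")

  # gene absent from the genome
  st5 <- annotate1(genome_of(""))$status
  expect_equal(st5$status, "absent")
  expect_equal(st5$reasons, "no_hsp")
})

test_that("edited codons are skipped during stop detection", {
  set.seed(82)
  tr <- ape::read.tree(text = "(ref:0.04,focal:0.04);")
  cfg <- sim_config(tr, omega = 0.3, gene_lengths = c(g = 210L), seed = 82)
  fam <- simulate_gene_family(cfg, "g")
  ref <- fam$cds[["ref"]]; mut <- fam$cds[["focal"]]
  # plant a genomic stop at codon 20 and list it as edited
  substr(mut, 58, 60) <- "TAA"
  genome <- setNames(paste0(rand_dna(400), mut, rand_dna(400)), "chr")
  ed <- data.frame(gene = "g", codon_index = 20L, source = "empirical")
  class(ed) <- c("editing_table", "data.frame")
  st_without <- annotate_genome(genome, c("ref|g" = ref),
                                circular = FALSE)$status
  st_with <- annotate_genome(genome, c("ref|g" = ref), editing = ed,
                             circular = FALSE)$status
  expect_equal(st_without$status, "pseudogene")
  expect_equal(st_with$status, "intact")
})

test_that("classification is deterministic and order-independent in HSP input", {
  set.seed(91)
  gene <- rand_dna(600)
  g2 <- mutate_seq(gene, 0.85, 2)
  genome2 <- paste0(rand_dna(300), substr(g2, 1, 300), rand_dna(300),
                    substr(g2, 301, 600), rand_dna(300))
  h <- seeded_local_search(gene, genome2, sensitive_scheme(), query_id = "q")
  m1 <- chain_hsps(h, "g", nchar(genome2))[[1]]
  m2 <- chain_hsps(h[sample.int(nrow(h)), ], "g", nchar(genome2))[[1]]
  c1 <- classify_gene_status(m1, gene)
  c2 <- classify_gene_status(m2, gene)
  expect_identical(c1$status, c2$status)
  expect_identical(c1$reasons, c2$reasons)
})

test_that("ORF persistence probability matches enumeration and Monte Carlo", {
  expect_equal(orf_persistence_probability(100, 0), 1)
  # single ATG codon: none of the 9 substitutions creates a stop
  expect_equal(orf_persistence_probability(n_subs = 1, sequence = "ATG"), 1)
  # TAT: TAA and TAG are single third-position changes -> 7/9
  expect_equal(orf_persistence_probability(n_subs = 1, sequence = "TAT"),
               7 / 9)
  expect_error(orf_persistence_probability(10, 5,
                                           base_composition = c(1, 1, 0, 0)),
               "sum to 1")
  # analytic vs Monte Carlo at L = 50, n = 30
  pa <- orf_persistence_probability(50, 30)
  pm <- orf_persistence_probability(50, 30, method = "mc", n_rep = 4000,
                                    seed = 2)
  se <- sqrt(pm * (1 - pm) / 4000)
  expect_lt(abs(pa - pm), 4 * se + 0.01)
})
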
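test_that("simulation is deterministic and respects degenerate limits", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,c:0.2);")
  cfg <- sim_config(tr, omega = 0.3, gene_lengths = c(g = 60L), seed = 5)
  s1 <- simulate_gene_family(cfg, "g")
  s2 <- simulate_gene_family(cfg, "g")
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$truth, s2$truth)

  tr0 <- tr; tr0$edge.length[] <- 0
  cfg0 <- sim_config(tr0, omega = 0.3, gene_lengths = c(g = 60L), seed = 5)
  s0 <- simulate_gene_family(cfg0, "g")
  expect_equal(length(unique(s0$cds)), 1L)   # all leaves equal the root
  expect_equal(sum(s0$truth$syn_count + s0$truth$nonsyn_count), 0L)
})

test_that("generated coding sequences never contain internal stops", {
  tr <- ape::read.tree(text = "(a:0.5,b:0.8);")
  for (r in 1:40) {
    cfg <- sim_config(tr, omega = runif(1, 0.1, 1.5),
                      gene_lengths = c(g = 40L), seed = r)
    s <- simulate_gene_family(cfg, "g")
    for (cds in s$cds)
      expect_false(grepl("\\*", translate_cds(cds)))
  }
})

test_that("replaying the event log reproduces every leaf sequence", {
  tr <- ape::read.tree(text = "((a:0.3,b:0.2):0.1,(c:0.15,d:0.4):0.05);")
  for (r in 1:5) {
    cfg <- sim_config(tr, omega = 0.4, gene_lengths = c(g = 80L), seed = r)
    s <- simulate_gene_family(cfg, "g")
    expect_identical(replay_sim(s), s$cds)
  }
})

test_that("realized dS converges to branch length times the synonymous fraction", {
  # realized synonymous events per synonymous site, averaged over
  # replicates, must match t * rhoS / S from the flux decomposition
  tr <- ape::read.tree(text = "(a:0.25,b:0.25);")
  fl <- gy94_flux(2, 0.3)
  expected_dS <- 0.5 * fl$rhoS / fl$S
  L <- 300L
  ds <- numeric(0)
  for (r in 1:40) {
    cfg <- sim_config(tr, kappa = 2, omega = 0.3,
                      gene_lengths = c(g = L), seed = 100 + r)
    s <- simulate_gene_family(cfg, "g")
    ds <- c(ds, sum(s$truth$syn_count) / (fl$S * L))
  }
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - expected_dS), 3 * se + 1e-9)
})

test_that("pseudogenization events are verifiably present", {
  cds <- strrep("ATGGCTAAAGCT", 25)   # 100 codons, no stops
  expect_equal(inject_pseudogenization(cds, list())$seq, cds)
  # nonsense at codon 10 truncates the ORF to 9 codons
  inj <- inject_pseudogenization(cds, list(list(type = "nonsense", pos = 10L)))
  expect_equal(nchar(translate_cds(inj$seq, to_stop = TRUE)), 9L)
  # single-base deletion shifts the downstream frame
  inj2 <- inject_pseudogenization(cds, list(list(type = "frameshift",
                                                 pos = 30L)))
  expect_equal(nchar(inj2$seq), nchar(cds) - 1L)
  expect_error(inject_pseudogenization(cds, list(list(type = "frameshift",
                                                      pos = 1000L))),
               "beyond")
})

test_that("rRNA evolution respects n_subs and the compensatory fraction", {
  struct <- random_secondary_structure(200, 5, seed = 3)
  expect_equal(simulate_rrna(struct, 0, 1, seed = 1)$seq, struct$seq)
  ev <- simulate_rrna(struct, 40, 1, seed = 2)
  # closed loop: classify_paired_changes must count exactly the
  # compensatory changes the generator planted
  aln <- setNames(c(struct$seq, ev$seq), c("ref", "query"))
  pm <- map_structure(struct$seq, struct, aln)
  rep0 <- classify_paired_changes(pm, struct$seq, ev$seq)
  expect_equal(rep0$n_fully_compensatory,
               sum(ev$truth$type == "compensatory"))
  expect_equal(rep0$n_disruptive, sum(ev$truth$type == "disruptive"))
  # f_cbc = 0: no compensatory changes at all
  ev0 <- simulate_rrna(struct, 40, 0, seed = 4)
  expect_equal(sum(ev0$truth$type == "compensatory"), 0L)
  pm0 <- map_structure(struct$seq, struct,
                       setNames(c(struct$seq, ev0$seq), c("ref", "query")))
  expect_equal(classify_paired_changes(pm0, struct$seq,
                                       ev0$seq)$n_fully_compensatory, 0L)
  expect_error(simulate_rrna(struct, 1000, 0.5), "exceeds")
})

test_that("assembled genomes carry exact truth coordinates", {
  set.seed(7)
  genes <- setNames(lapply(1:5, function(i) rand_dna(300)),
                    paste0("g", 1:5))
  genes <- vapply(genes, identity, "")
  asm <- assemble_mitogenome(genes, seed = 9)
  expect_equal(length(unique(asm$features$gene)), 5L)
  for (g in names(genes))
    expect_equal(extract_feature(asm$genome, asm$features,
                                 paste0(g, "_t")), unname(genes[g]))
  # two-exon split: concatenated exon extraction equals the original CDS
  asm2 <- assemble_mitogenome(genes, split = list(g2 = 2L), seed = 9)
  fx <- asm2$features[asm2$features$gene == "g2", ]
  expect_equal(nrow(fx), 2L)
  expect_equal(extract_feature(asm2$genome, asm2$features, "g2_t"),
               unname(genes["g2"]))
})

test_that("the HGT gene descends from the donor lineage, not the resident one", {
  study <- simulate_study(viscum_scenario(4))
  g <- study$scenario$hgt_gene
  fam <- study$families[[g]]
  focal <- fam$cds[["focal"]]
  id_donor <- percent_identity(focal, fam$cds[["donor"]])
  id_ref <- percent_identity(focal, fam$cds[["reference"]])
  # a vertical gene of the same length, for contrast
  vert <- study$families[["ccmC"]]
  id_vert_ref <- percent_identity(vert$cds[["focal"]],
                                  vert$cds[["reference"]])
  expect_gt(id_donor, 95)
  expect_gt(id_ref, id_vert_ref + 15)   # anomalously low divergence
})

test_that("the relaxation-regime simulator honours k on the test branches", {
  tr <- ape::read.tree(text = "((f1:0.2,f2:0.2):0.1,c:0.2,d:0.3);")
  te <- 1:3
  a1 <- simulate_relax_alignment(tr, 100, k = 1, test_edges = te, seed = 1)
  a2 <- simulate_relax_alignment(tr, 100, k = 1, test_edges = te, seed = 1)
  expect_identical(a1, a2)
  expect_equal(unique(nchar(a1)), 300L)
})
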
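test_that("back-translation mirrors the protein alignment", {
  ca <- backtranslate_alignment(c(a = "M", b = "M"),
                                c(a = "ATG", b = "ATG"))
  expect_equal(unname(ca$codons[, 1]), c("ATG", "ATG"))
  ca2 <- backtranslate_alignment(c(a = "MA", b = "M-"),
                                 c(a = "ATGGCT", b = "ATG"))
  expect_equal(unname(ca2$codons["b", 2]), "---")
  # translation disagreement is reported with taxon and position
  expect_error(backtranslate_alignment(c(a = "MAKDE", b = "MAKDE"),
                                       c(a = "ATGGCTAAAGATGAA",
                                         b = "ATGGCTAAAGGTGAA")),
               "taxon b at position 4")
})

test_that("editing masks remove codon columns from every estimator", {
  seqs <- c(a = strrep("ATGGCTAAAGCTGATCCTGGTACCTTAGCA", 1),
            b = strrep("ATGGCTAAAGCTGATCCTGGTACCTTAGCA", 1))
  ca <- codon_alignment(seqs)
  expect_equal(length(mask_edited_codons(ca)$mask), 0L)
  ca2 <- mask_edited_codons(ca, extra = c(3L, 7L))
  expect_equal(ca2$mask, c(3L, 7L))
  expect_equal(ng86_dnds(ca2)$n_codons, 8L)
  # a stop-looking codon is accepted once masked
  s3 <- c(a = "ATGTAAGCT", b = "ATGTAAGCT")
  expect_error(codon_alignment(s3), "stop")
  ca3 <- codon_alignment(s3, mask = 2L)
  expect_equal(ng86_dnds(ca3)$n_codons, 2L)
  # duplicating a masked column changes nothing
  s4 <- c(a = "ATGTAATAAGCT", b = "ATGTAATAAGCT")
  ca4 <- codon_alignment(s4, mask = c(2L, 3L))
  expect_identical(ng86_dnds(ca3)[, c("dN", "dS", "S", "N")],
                   ng86_dnds(ca4)[, c("dN", "dS", "S", "N")])
})

test_that("NG86 counting matches hand enumeration", {
  same <- strrep("GGT", 50)
  ca <- codon_alignment(c(a = same, b = same))
  est <- ng86_dnds(ca)
  expect_equal(est$dN, 0)
  expect_equal(est$dS, 0)
  # GGT (glycine): third-position changes are all synonymous, first and
  # second position changes all nonsynonymous -> exactly 1 synonymous
  # site per codon; one third-position difference in 50 codons gives
  # pS = 1/50 and the Jukes-Cantor correction of that
  b <- paste0(strrep("GGT", 49), "GGC")
  est2 <- ng86_dnds(codon_alignment(c(a = same, b = b)))
  expect_equal(est2$S, 50)
  expect_equal(est2$dN, 0)
  expect_equal(est2$dS, -0.75 * log(1 - 4 * (1 / 50) / 3))
  # saturation on one side is flagged, not fatal
  sat <- ng86_dnds(codon_alignment(c(a = "GGTGGT", b = "GGCGGA")))
  expect_true(sat$saturated_dS)
  expect_false(sat$saturated_dN)
})

test_that("pairwise GY94 handles identical sequences and recovers parameters", {
  same <- strrep("ATGGCTAAAGCTGATCCTGGT", 10)
  f0 <- fit_pairwise_gy94(codon_alignment(c(a = same, b = same)),
                          n_restarts = 0L)
  expect_lt(f0$t, 1e-6)
  expect_equal(f0$dN, 0, tolerance = 1e-6)
  expect_equal(f0$dS, 0, tolerance = 1e-6)
  # single-replicate recovery sanity (the full 100-replicate check is in
  # the acceptance suite)
  tr <- ape::read.tree(text = "(a:0.2,b:0.2);")
  cfg <- sim_config(tr, kappa = 2, omega = 0.3, gene_lengths = c(g = 400L),
                    seed = 77)
  sim <- simulate_gene_family(cfg, "g")
  f <- fit_pairwise_gy94(codon_alignment(sim$cds), n_restarts = 0L,
                         se = TRUE)
  expect_lt(abs(f$omega_mle - 0.3), 0.15)
  expect_true(is.finite(f$se_omega) && f$se_omega > 0)
})

test_that("likelihood is invariant to taxon and column permutations", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.25);")
  cfg <- sim_config(tr, omega = 0.4, gene_lengths = c(g = 120L), seed = 3)
  sim <- simulate_gene_family(cfg, "g")
  ca <- codon_alignment(sim$cds)
  f1 <- fit_pairwise_gy94(ca, n_restarts = 0L)
  # permute codon columns
  perm <- sample(ncol(ca$codons))
  seqs_p <- apply(ca$codons[, perm], 1L, paste, collapse = "")
  f2 <- fit_pairwise_gy94(codon_alignment(seqs_p), n_restarts = 0L)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-8)
  expect_equal(f1$omega_mle, f2$omega_mle, tolerance = 1e-5)
})

test_that("omega = 0 data drive the estimate to the boundary", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  cfg <- sim_config(tr, omega = 0, gene_lengths = c(g = 300L), seed = 9)
  sim <- simulate_gene_family(cfg, "g")
  f <- fit_pairwise_gy94(codon_alignment(sim$cds), n_restarts = 0L)
  expect_lt(f$omega_mle, 0.01)
  expect_lt(f$dN, 0.002)
})

test_that("branch-class GY94 nests correctly and matches the pairwise fit", {
  tr <- ape::read.tree(text = "(a:0.15,b:0.15);")
  cfg <- sim_config(tr, omega = 0.35, gene_lengths = c(g = 300L), seed = 13)
  sim <- simulate_gene_family(cfg, "g")
  ca <- codon_alignment(sim$cds)
  pw <- fit_pairwise_gy94(ca, pi = "f3x4", n_restarts = 0L)
  bc <- fit_branch_class_gy94(ca, tr, classes = c(1L, 1L))
  expect_equal(bc$lnL, pw$lnL, tolerance = 1e-4)
  expect_equal(unname(bc$omega), pw$omega_mle, tolerance = 0.02)
  expect_equal(sum(bc$per_branch$t), pw$t, tolerance = 0.01)
  # a 2-class model on 4 taxa cannot fit worse than the 1-class model
  tr4 <- tree4()
  cfg4 <- sim_config(tr4, omega = 0.3, gene_lengths = c(g = 200L), seed = 17)
  sim4 <- simulate_gene_family(cfg4, "g")
  ca4 <- codon_alignment(sim4$cds)
  cls1 <- rep(1L, nrow(tr4$edge))
  cls2 <- cls1; cls2[1] <- 2L
  f1 <- fit_branch_class_gy94(ca4, tr4, cls1)
  f2 <- fit_branch_class_gy94(ca4, tr4, cls2)
  expect_gte(f2$lnL, f1$lnL - 1e-4)
  expect_error(fit_branch_class_gy94(ca4, tr4, c(1L, 1L, 1L, 1L, 3L)),
               "class")
})

test_that("branch-class recovery separates focal and background omega", {
  tr <- ape::read.tree(text = "((f:0.25,b:0.2):0.1,c:0.2,d:0.3);")
  focal_edge <- which(tr$edge[, 2] == which(tr$tip.label == "f"))
  cls <- rep(1L, nrow(tr$edge)); cls[focal_edge] <- 2L
  om_f <- om_b <- numeric(0)
  for (r in 1:8) {
    eo <- rep(0.2, nrow(tr$edge)); eo[focal_edge] <- 0.6
    cfg <- sim_config(tr, omega = eo, gene_lengths = c(g = 300L),
                      seed = 200 + r)
    sim <- simulate_gene_family(cfg, "g")
    fit <- fit_branch_class_gy94(codon_alignment(sim$cds), tr, cls)
    om_b <- c(om_b, fit$omega[1]); om_f <- c(om_f, fit$omega[2])
  }
  expect_lt(abs(mean(om_b) - 0.2), 3 * sd(om_b) / sqrt(8) + 0.03)
  expect_lt(abs(mean(om_f) - 0.6), 3 * sd(om_f) / sqrt(8) + 0.08)
})

test_that("relaxation test is directional and reciprocal under swap", {
  # mirror-symmetric tree: two clades of equal shape, relaxation (k =
  # 0.4) applied to one of them; swapping test and reference must flip
  # the estimated intensity across 1
  tr <- ape::read.tree(text = "((f1:0.2,f2:0.2):0.1,(c:0.2,d:0.2):0.1);")
  te <- which(tr$edge[, 2] %in% c(which(tr$tip.label %in% c("f1", "f2")),
                                  ape::getMRCA(tr, c("f1", "f2"))))
  ref_e <- setdiff(seq_len(nrow(tr$edge)), te)
  seqs <- simulate_relax_alignment(tr, 500, k = 0.4, test_edges = te,
                                   seed = 31)
  ca <- codon_alignment(seqs)
  r1 <- relaxation_test(ca, tr, te)
  expect_lt(r1$k, 1)
  expect_gte(r1$lnL_alt, r1$lnL_null)
  r2 <- relaxation_test(ca, tr, ref_e)
  # swapping test and reference inverts the direction of the intensity
  expect_gt(r2$k, 1)
  expect_lt(abs(log(r1$k) + log(r2$k)), 2)
  expect_error(relaxation_test(ca, tr, seq_len(nrow(tr$edge))), "subset")
})
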
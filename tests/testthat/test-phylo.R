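test_that("pruning equals brute-force enumeration on 4-taxon toys", {
  tr <- tree4()
  set.seed(101)
  aln <- simulate_gtr_alignment(tr, 10, list(pi = c(0.3, 0.2, 0.3, 0.2)),
                                seed = 1)
  params <- list(rates = c(1.2, 2.5, 0.8, 1.1, 3.0, 1),
                 pi = c(0.3, 0.2, 0.3, 0.2), alpha = Inf)
  res <- gtr_gamma_lnL(aln, tr, params)
  Q <- gtr_rate_matrix(params$rates, params$pi)
  expect_equal(res$lnL, brute_force_lnl(tr, aln, Q, params$pi),
               tolerance = 1e-10)
  # per-site values sum to the total
  expect_equal(sum(res$site_lnl), res$lnL, tolerance = 1e-6)
})

test_that("two identical zero-distance taxa give lnL = log pi per site", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- c(a = "A", b = "A")
  res <- gtr_gamma_lnL(aln, tr, list(pi = c(0.4, 0.2, 0.2, 0.2)))
  expect_equal(res$lnL, log(0.4), tolerance = 1e-9)
})

test_that("likelihood is invariant to re-rooting (reversibility)", {
  tr <- tree4()
  aln <- simulate_gtr_alignment(tr, 300, list(alpha = 0.7), seed = 2)
  params <- list(rates = c(1, 2, 1, 1, 2, 1), alpha = 0.7)
  l1 <- gtr_gamma_lnL(aln, tr, params)$lnL
  rt <- ape::unroot(ape::root(tr, outgroup = "c", resolve.root = TRUE))
  l2 <- gtr_gamma_lnL(aln, rt, params)$lnL
  expect_equal(l1, l2, tolerance = 1e-6)
})

test_that("GTR+Gamma likelihood matches phangorn on a shared model", {
  tr <- tree4()
  aln <- simulate_gtr_alignment(tr, 200, list(alpha = 1), seed = 3)
  pi <- rep(0.25, 4)
  params <- list(rates = rep(1, 6), pi = pi, alpha = 1, ncat = 4L)
  l1 <- gtr_gamma_lnL(aln, tr, params)$lnL
  dat <- phangorn::phyDat(t(sapply(aln, function(s)
    strsplit(s, "")[[1]])), type = "DNA")
  fit <- phangorn::pml(tr, dat, bf = pi, Q = rep(1, 6), k = 4, shape = 1)
  expect_equal(l1, as.numeric(fit$logLik), tolerance = 1e-4)
})

test_that("constrained JC fit reproduces the closed-form distance", {
  # 1000 sites with exactly 100 mismatches: p-hat = 0.1, JC distance
  # -(3/4) log(1 - 4 p / 3) = 0.10732
  a <- strrep("A", 1000)
  b <- paste0(strrep("C", 100), strrep("A", 900))
  tr <- ape::read.tree(text = "(x:0.05,y:0.05);")
  fit <- optimize_branch_lengths(c(x = a, y = b), tr,
                                 params = list(rates = rep(1, 6),
                                               pi = rep(0.25, 4),
                                               alpha = Inf))
  expect_equal(sum(fit$tree$edge.length), 0.10732, tolerance = 1e-3)
})

test_that("branch-length optimization is monotone and recovers truth", {
  tr <- ape::read.tree(
    text = "((a:0.12,b:0.08):0.09,(c:0.15,d:0.1):0.07,e:0.2);")
  aln <- simulate_gtr_alignment(tr, 4000, list(alpha = Inf), seed = 4)
  fit <- optimize_branch_lengths(aln, tr, list(alpha = Inf),
                                 method = "sweeps", max_sweeps = 8)
  expect_true(all(diff(fit$trace) >= -1e-8))   # lnL never decreases
  big <- tr$edge.length >= 0.05
  expect_true(all(abs(fit$tree$edge.length[big] - tr$edge.length[big]) /
                    tr$edge.length[big] < 0.2))
  # identical sequences: all branch lengths at the lower bound
  same <- setNames(rep(strrep("ACGT", 50), 5), tr$tip.label)
  fit0 <- optimize_branch_lengths(same, tr, list(alpha = Inf))
  expect_true(all(fit0$tree$edge.length < 1e-4))
})

test_that("4-taxon search is exhaustive and honours constraints", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.15,c:0.1,d:0.1);")
  aln <- simulate_gtr_alignment(tr, 2000, list(alpha = Inf), seed = 5)
  best <- search_ml_tree(aln, list(alpha = Inf))
  # equals the argmax over all 3 unrooted topologies
  cand <- phangorn::allTrees(4, rooted = FALSE, tip.label = names(aln))
  lnls <- vapply(as.list(cand), function(t0)
    optimize_branch_lengths(aln, t0, list(alpha = Inf))$lnL, 0)
  expect_equal(best$lnL, max(lnls), tolerance = 1e-4)
  expect_true(mitorescue:::.satisfies_constraint(best$tree,
                                                 list(c("a", "b"))))
  # constraint already satisfied by the optimum: same topology back
  con <- search_ml_tree(aln, list(alpha = Inf),
                        constraint = list(c("a", "b")))
  expect_equal(con$lnL, best$lnL, tolerance = 1e-4)
  # forcing the wrong clade must cost likelihood
  wrong <- search_ml_tree(aln, list(alpha = Inf),
                          constraint = list(c("a", "c")))
  expect_lt(wrong$lnL, best$lnL)
})

test_that("RELL tests behave on symmetric and decisive data", {
  set.seed(6)
  l <- matrix(rnorm(1000, -3, 0.5), 500, 2,
              dimnames = list(NULL, c("t1", "t2")))
  l[, 2] <- l[, 1]
  tt <- rell_topology_tests(l, B = 2000, seed = 3)
  expect_true(all(abs(tt$p_AU - 0.5) < 0.1))
  expect_true(all(tt$p_KH == 0.5))
  # the ML topology's AU/SH p-values top every other topology's
  l2 <- cbind(t1 = rnorm(500, -3, 0.5), t2 = rnorm(500, -3.2, 0.5))
  tt2 <- rell_topology_tests(l2, B = 2000, seed = 4)
  best <- which.max(tt2$lnL)
  expect_gte(tt2$p_AU[best], max(tt2$p_AU[-best]))
  expect_gte(tt2$p_SH[best], max(tt2$p_SH[-best]))
  expect_error(rell_topology_tests(l[, 1, drop = FALSE]), "2 topologies")
  expect_error(rell_topology_tests(l, scales = 1), "2 scale")
  expect_warning(rell_topology_tests(l, B = 500, seed = 1), "noisy")
})

test_that("KH normal approximation agrees with the empirical RELL tail", {
  tr <- tree4()
  aln <- simulate_gtr_alignment(tr, 500, list(alpha = Inf), seed = 7)
  f1 <- optimize_branch_lengths(aln, tr, list(alpha = Inf))
  tr2 <- ape::read.tree(text = "((a:0.1,c:0.2):0.15,b:0.12,d:0.3);")
  f2 <- optimize_branch_lengths(aln, tr2, list(alpha = Inf))
  L <- cbind(t1 = f1$site_lnl, t2 = f2$site_lnl)
  tt <- rell_topology_tests(L, B = 5000, seed = 8)
  # independent full nonparametric RELL bootstrap of the centred delta
  set.seed(9)
  d <- L[, 1] - L[, 2]
  dobs <- sum(d)
  boot <- replicate(5000, sum(sample(d, replace = TRUE)))
  p_emp <- mean((boot - mean(boot)) >= abs(dobs))
  worse <- which.min(tt$lnL)
  expect_lt(abs(tt$p_KH[worse] - p_emp), 0.05)
})

test_that("bootstrap support for the true bipartition grows with alignment length", {
  tr <- ape::read.tree(
    text = "(((a:0.08,b:0.08):0.03,c:0.1):0.02,(d:0.1,e:0.1):0.03,f:0.12);")
  tr2 <- ape::read.tree(
    text = "(((c:0.08,b:0.08):0.03,a:0.1):0.02,(d:0.1,e:0.1):0.03,f:0.12);")
  bp <- sapply(c(500, 5000), function(n) {
    aln <- simulate_gtr_alignment(tr, n, list(alpha = Inf), seed = 10)
    f1 <- optimize_branch_lengths(aln, tr, list(alpha = Inf))
    f2 <- optimize_branch_lengths(aln, tr2, list(alpha = Inf))
    tt <- rell_topology_tests(cbind(true = f1$site_lnl,
                                    wrong = f2$site_lnl),
                              B = 1000, seed = 11)
    tt$p_AU[1]
  })
  expect_gte(bp[2], bp[1])
})

test_that("HGT flagging requires both anomaly and topology rejection", {
  # divergence anomaly alone (no alignments that reject vertical) must
  # stay inconclusive or vertical, never hgt_candidate
  sp <- ape::read.tree(
    text = "(((focal:1,sister:1):1,rel:1):1,(ref:1,don:1):1,out:1);")
  cfg <- sim_config(sp, omega = 0.2, gene_lengths = setNames(
    rep(120L, 8L), paste0("g", 1:8)), seed = 21)
  alns <- list()
  for (g in names(cfg$gene_lengths)) {
    sim <- simulate_gene_family(
      sim_config(sp, omega = 0.2,
                 gene_lengths = cfg$gene_lengths, seed = 21), g)
    alns[[g]] <- sim$cds
  }
  div <- setNames(c(70, 71, 69, 72, 70, 68, 71, 95), names(alns))
  rep0 <- flag_hgt_candidates(alns, sp, "focal", "ref", divergence = div,
                              B = 1000, seed = 1)
  expect_equal(sum(rep0$anomalous), 1L)
  # the anomalous gene was simulated VERTICALLY, so the vertical topology
  # is not rejected: verdict inconclusive, not hgt_candidate
  expect_true(rep0$verdict[8] %in% c("inconclusive", "vertical"))
  expect_true(all(rep0$verdict[1:7] == "vertical"))
  expect_error(flag_hgt_candidates(alns[1:3], sp, "focal", "ref"),
               ">= 5 genes")
})
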
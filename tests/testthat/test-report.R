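test_that("inventory summary arithmetic is exact", {
  rows <- data.frame(gene = c("a", "b", "c"),
                     omega = c(0.2, 0.4, 0.9),
                     dS = c(0.1, 0.2, 0),
                     pct_id_vs_relative = c(99, 97, 95),
                     length_nt = c(300, 600, 900))
  s <- summarize_inventory(rows, length_cols = c(total = "length_nt"),
                           identity_thresholds = 98)
  expect_equal(s$mean_omega_raw, mean(c(0.2, 0.4)))  # dS = 0 excluded
  expect_equal(s$n_omega_used, 2L)
  expect_equal(unname(s$identity_counts["gt98"]), 1L)
  expect_equal(unname(s$concat_lengths["total"]), 1800)
  # single row: the mean is that row's omega
  s1 <- summarize_inventory(rows[1, ], identity_thresholds = 98)
  expect_equal(s1$mean_omega_raw, 0.2)
  expect_error(summarize_inventory(rows[3, ]), "excluded")
})

test_that("published per-gene values reproduce the study aggregates", {
  tab <- viscum_gene_table()
  expect_equal(nrow(tab), 19L)
  s <- summarize_inventory(tab, omega_col = "omega", ds_col = "dS",
                           identity_col = "pct_id_va_vs",
                           length_cols = c(lir = "length_lir_nt"))
  expect_equal(s$n_omega_used, 17L)
  expect_equal(s$mean_omega, 0.52)
  expect_equal(unname(s$identity_counts["gt98"]), 12L)
  expect_equal(unname(s$concat_lengths["lir"]), 16275)
  sz <- viscum_genome_sizes()
  expect_equal(round(max(sz$genome_size_kb) / min(sz$genome_size_kb), 1),
               8.6)
})

test_that("a gene-free genome yields only absent calls and an empty inventory", {
  set.seed(33)
  study <- simulate_study(viscum_scenario(3))
  cfg <- pipeline_config(genome = setNames(rand_dna(20000), "rand"),
                         panel = study$panel,
                         relative_genes = study$relative_genes,
                         stages = c("annotate", "dnds"), seed = 1)
  res <- run_pipeline(cfg)
  expect_true(all(res$annotation$status$status == "absent"))
  expect_true(is.null(res$inventory) || nrow(res$inventory) == 0L)
})

test_that("pipeline reruns with the same seed are byte-identical", {
  study <- simulate_study(viscum_scenario(6))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  res1 <- run_pipeline(study, stages = c("annotate", "rrna"),
                       out_dir = d1, seed = 4)
  res2 <- run_pipeline(study, stages = c("annotate", "rrna"),
                       out_dir = d2, seed = 4)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = paste("file", f))
})

test_that("the full pipeline recovers the synthetic scenario end to end", {
  study <- simulate_study(viscum_scenario(5))
  res <- run_pipeline(study, seed = 5)
  s <- res$summary
  expect_equal(s$n_intact + s$n_truncated_intact, 19L)
  expect_equal(s$n_pseudogene, 9L)
  expect_equal(s$n_absent, 2L)
  expect_equal(s$hgt_candidates, study$scenario$hgt_gene)
  expect_equal(s$n_functional_excluding_hgt, 18L)
  # inventory ratio column equals dN/dS recomputed from the row (2 dp)
  inv <- res$inventory
  ok <- !is.na(inv$omega) & inv$dS > 0
  expect_equal(inv$omega[ok], round(inv$dN[ok] / inv$dS[ok], 2))
  # concatenate length equals the per-gene sum
  expect_equal(unname(s$concat_lengths["focal_concat_nt"]),
               sum(inv$length_nt))
  # rRNA compensatory counts equal generator truth
  for (nm in names(study$rrna))
    expect_equal(res$rrna_report$n_compensatory[res$rrna_report$rrna == nm],
                 sum(study$rrna[[nm]]$truth$type == "compensatory"))
})
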
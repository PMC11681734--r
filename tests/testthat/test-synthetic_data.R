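small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_human_orthologs = 200, doses = c(0, 10), times = c(2, 6),
         individuals_per_species = 3, seed = 11),
    list(...))
  do.call(sim_config, args)
}

test_that("the same seed reproduces byte-identical simulated files", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_transcriptome(simulate_transcriptome(cfg), d1)
  write_transcriptome(simulate_transcriptome(cfg), d2)
  write_proteome(simulate_proteome(cfg), d1)
  write_proteome(simulate_proteome(cfg), d2)
  files <- list.files(d1)
  expect_identical(sort(files), sort(list.files(d2)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_transcriptome(simulate_transcriptome(small_cfg(seed = 12)), d3)
  expect_false(identical(
    readLines(file.path(d1, "expr_mouse.tsv")),
    readLines(file.path(d3, "expr_mouse.tsv"))))
})

test_that("planted fractions are counted exactly and validated", {
  cfg <- sim_config(n_human_orthologs = 1000, frac_baseline_de = 0.1,
                    doses = 0, times = 2, seed = 3)
  sim <- simulate_transcriptome(cfg)
  expect_identical(nrow(sim$truth$baseline), 100L)
  expect_identical(nrow(sim$truth$response), 100L)
  expect_identical(nrow(sim$truth$group_diff), 50L)
  # planted sets are disjoint
  ids <- c(sim$truth$baseline$gene_id, sim$truth$response$gene_id,
           sim$truth$group_diff$gene_id)
  expect_identical(anyDuplicated(ids), 0L)
  # every planted id exists in the emitted human universe
  expect_true(all(ids %in% sim$human_universe))

  expect_error(sim_config(frac_baseline_de = 0.6, frac_response_de = 0.5),
               "sum to more than 1")
  expect_error(sim_config(frac_baseline_de = -0.1), "\\[0,1\\]")
  expect_error(sim_config(doses = c(10, 100)), "include the 0 control")
})

test_that("a null configuration yields empty ground truth and near-zero group difference", {
  cfg <- small_cfg(frac_baseline_de = 0, frac_response_de = 0,
                   frac_group_response_diff = 0,
                   individuals_per_species = 5)
  sim <- simulate_transcriptome(cfg)
  expect_identical(nrow(sim$truth$baseline), 0L)
  expect_identical(nrow(sim$truth$response), 0L)
  expect_identical(nrow(sim$truth$group_diff), 0L)

  ht <- translate_study(sim$species_expr, sim$maps, sim$human_universe,
                        sim$sheet)
  b <- baseline_subset(log2_transform(ht), sim$sheet)
  sens <- b$sheet$group == "sensitive"
  # the individual-level intercepts are shared across genes, so gene-level
  # group differences carry a common offset of sd ~ 0.087 at this design
  gm_diff <- rowMeans(b$expr$values[, sens], na.rm = TRUE) -
    rowMeans(b$expr$values[, !sens], na.rm = TRUE)
  expect_lt(abs(mean(gm_diff, na.rm = TRUE)), 0.3)
})

test_that("the sample sheet design is paired and complete", {
  cfg <- small_cfg()
  sim <- simulate_transcriptome(cfg)
  sheet <- sim$sheet
  expect_s3_class(sheet, "xlps_sample_sheet")  # constructor validates pairing
  expect_identical(nrow(sheet), 10L * 3L * 4L)  # 10 species, 3 inds, 2x2 combos
  expect_identical(sort(unique(sheet$species)),
                   sort(c("mouse", "rat", "rhesus", "baboon", "rabbit", "pig",
                          "cow", "sheep", "chimpanzee", "human")))
  grp <- species_groups(sheet)
  expect_identical(unname(grp[c("mouse", "human")]),
                   c("resilient", "sensitive"))
})

test_that("per-species expression and maps are consistent with the human universe", {
  cfg <- small_cfg()
  sim <- simulate_transcriptome(cfg)
  for (spc in c("mouse", "human")) {
    expr <- sim$species_expr[[spc]]
    map <- sim$maps[[spc]]
    expect_true(all(map$relations$species_gene_id %in% rownames(expr)))
    expect_true(all(map$relations$human_gene_id %in% sim$human_universe))
    expect_true(all(expr >= 0))
  }
  # dropout: some human genes lack orthologs in at least one species
  ht <- translate_study(sim$species_expr, sim$maps, sim$human_universe,
                        sim$sheet)
  expect_gt(sum(ht$missing), 0)
})

test_that("planted response effects saturate in dose", {
  cfg <- small_cfg(frac_response_de = 0.2, response_effect_log2 = 3,
                   doses = c(0, 10, 1000), noise_sd_log2 = 0.2)
  sim <- simulate_transcriptome(cfg)
  ht <- translate_study(sim$species_expr, sim$maps, sim$human_universe,
                        sim$sheet)
  resp <- sim$truth$response
  up <- resp$gene_id[resp$sign > 0]
  fc_at <- function(dose) {
    rec <- paired_fold_changes(ht, sim$sheet, response_config(dose = dose), 6)
    mean(rec$log2fc[rec$gene_id %in% up])
  }
  fc10 <- fc_at(10); fc1000 <- fc_at(1000)
  expect_gt(fc10, 1.5)           # ~ 3 * 0.8 at peak time
  expect_gt(fc1000, fc10)        # monotone, but a minimal escalation
  expect_lt(fc1000 - fc10, 1)
})

test_that("simulated proteomes plant the three tiers as constructed", {
  cfg <- small_cfg()
  psim <- simulate_proteome(cfg)
  tab <- psim$table
  truth <- psim$truth
  expect_identical(nrow(truth),
                   as.integer(cfg$n_tier_anova + cfg$n_tier_foldchange +
                                cfg$n_tier_presence))
  expect_true(all(truth$protein_id %in% rownames(tab$lfq)))
  # presence-tier proteins are detected in exactly one group
  for (p in truth$protein_id[truth$tier == "presence"]) {
    det <- tab$detected[p, ]
    by_grp <- tapply(det, tab$groups, sum)
    expect_identical(sum(by_grp > 0), 1L)
    expect_gte(max(by_grp), 3)
  }
  # foldchange-tier proteins are ineligible for the ANOVA tier but have >= 4
  # occurrences spanning both groups
  for (p in truth$protein_id[truth$tier == "foldchange"]) {
    det <- tab$detected[p, ]
    by_grp <- tapply(det, tab$groups, sum)
    expect_identical(min(by_grp), 1L)
    expect_gte(sum(det), 4)
  }
  # determinism
  psim2 <- simulate_proteome(cfg)
  expect_identical(psim$table$lfq, psim2$table$lfq)
})

test_that("downstream recall of planted baseline effects is monotone in effect size", {
  recalls <- vapply(c(1, 1.5, 2), function(eff) {
    hits <- 0; total <- 0
    for (seed in 1:3) {
      cfg <- sim_config(n_human_orthologs = 300, doses = 0, times = 2,
                        baseline_effect_log2 = eff, seed = 900 + seed)
      sim <- simulate_transcriptome(cfg)
      ht <- translate_study(sim$species_expr, sim$maps, sim$human_universe,
                            sim$sheet)
      b <- baseline_subset(log2_transform(ht), sim$sheet)
      de <- fit_blocked_moderated_test(quantile_normalize(b$expr), b$sheet,
                                       de_config())
      sig <- de$gene_id[de$significant]
      hits <- hits + sum(sim$truth$baseline$gene_id %in% sig)
      total <- total + nrow(sim$truth$baseline)
    }
    hits / total
  }, numeric(1))
  expect_true(all(diff(recalls) >= -1e-12))
})
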
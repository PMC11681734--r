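mk_table <- function(lfq_rows, proteins = NULL) {
  species <- c("mouse", "rat", "rhesus", "baboon",
               "rabbit", "pig", "cow", "sheep", "chimpanzee", "human")
  groups <- stats::setNames(c(rep("resilient", 4), rep("sensitive", 6)),
                            species)
  m <- do.call(rbind, lfq_rows)
  rownames(m) <- if (is.null(proteins)) sprintf("P%02d", seq_along(lfq_rows))
  else proteins
  colnames(m) <- species
  protein_table(m, groups = groups)
}
RES <- 1:4   # resilient columns
SEN <- 5:10  # sensitive columns

test_that("tier 1 captures by raw ANOVA p, with the zero-variance rule", {
  # zero within-group variance, unequal means -> maximally significant
  r1 <- rep(NA_real_, 10); r1[RES] <- 13; r1[SEN] <- 10
  # zero variance, equal means -> uninformative
  r2 <- rep(11, 10)
  # insufficient replicates in one group -> remainder
  r3 <- rep(NA_real_, 10); r3[1] <- 15; r3[SEN] <- c(10, 11, 12, 10, 11, 12)
  tab <- mk_table(list(r1, r2, r3))
  t1 <- tier1_anova(tab, tier_config())
  a <- t1$assigned
  expect_identical(a$tier[a$protein_id == "P01"], "anova")
  expect_equal(a$statistic[a$protein_id == "P01"], 0)
  expect_identical(a$tier[a$protein_id == "P02"], "none")
  expect_identical(t1$remainder, "P03")
})

test_that("tier 1 p-values match the closed-form two-group F distribution", {
  set.seed(701)
  for (i in 1:10) {
    xr <- stats::rnorm(4, 20, 1)
    xs <- stats::rnorm(6, 20, 1)
    row <- rep(NA_real_, 10); row[RES] <- xr; row[SEN] <- xs
    tab <- mk_table(list(row))
    p_got <- tier1_anova(tab, tier_config())$assigned$statistic
    p_ref <- stats::oneway.test(c(xr, xs) ~ rep(c("r", "s"), c(4, 6)),
                                var.equal = TRUE)$p.value
    expect_equal(p_got, p_ref, tolerance = 1e-12)
  }
})

test_that("tier 2 applies the fold-change and occurrence rules", {
  cfg <- tier_config()
  # detected in 2 sensitive (18, 19) and 2 resilient (14, 15): fc = 4 -> capture
  r1 <- rep(NA_real_, 10); r1[1:2] <- c(14, 15); r1[5:6] <- c(18, 19)
  # same but resilient (16, 17): fc = 2 -> none
  r2 <- rep(NA_real_, 10); r2[1:2] <- c(16, 17); r2[5:6] <- c(18, 19)
  # 3 occurrences total with both groups represented -> none
  r3 <- rep(NA_real_, 10); r3[1] <- 10; r3[5:6] <- c(20, 21)
  # detected in one group only -> remainder
  r4 <- rep(NA_real_, 10); r4[5:8] <- 20
  tab <- mk_table(list(r1, r2, r3, r4))
  t2 <- tier2_foldchange(tab, cfg, rownames(tab$lfq))
  a <- t2$assigned
  expect_identical(a$tier[a$protein_id == "P01"], "foldchange")
  expect_equal(a$statistic[a$protein_id == "P01"], 4)
  expect_identical(a$tier[a$protein_id == "P02"], "none")
  expect_equal(a$statistic[a$protein_id == "P02"], 2)
  expect_identical(a$tier[a$protein_id == "P03"], "none")
  expect_identical(t2$remainder, "P04")
})

test_that("tier 3 captures presence/absence at the species minimum", {
  r1 <- rep(NA_real_, 10); r1[5:7] <- 20          # 3 sensitive, 0 resilient
  r2 <- rep(NA_real_, 10); r2[5:6] <- 20          # 2 sensitive -> none
  r3 <- rep(NA_real_, 10); r3[1:4] <- 20          # 4 resilient -> capture
  r4 <- rep(NA_real_, 10)                         # never detected -> none
  tab <- mk_table(list(r1, r2, r3, r4))
  a <- tier3_presence(tab, tier_config(), rownames(tab$lfq))
  expect_identical(a$tier, c("presence", "none", "presence", "none"))
  expect_identical(a$present_group[1], "sensitive")
  expect_identical(a$present_group[3], "resilient")
})

test_that("the cascade is an exhaustive, mutually exclusive partition with strict precedence", {
  set.seed(702)
  for (i in 1:30) {
    tab <- random_protein_table(n_proteins = 40,
                                missing_prob = stats::runif(1, 0.1, 0.6))
    cas <- run_cascade(tab, tier_config())
    a <- cas$assignments
    # every protein gets exactly one assignment
    expect_identical(a$protein_id, rownames(tab$lfq))
    expect_true(all(a$tier %in% c("anova", "foldchange", "presence", "none")))
    expect_identical(unname(cas$counts["total_discriminating"]),
                     sum(a$tier != "none"))
    # independent rule re-evaluation oracle
    want <- oracle_cascade(tab, tier_config())
    expect_identical(a$tier, unname(want[a$protein_id]))
    # precedence: every protein with enough values per group got a p-value
    det_r <- rowSums(tab$detected[, tab$groups == "resilient"])
    det_s <- rowSums(tab$detected[, tab$groups == "sensitive"])
    eligible1 <- det_r >= 2 & det_s >= 2
    expect_true(all(!is.na(a$statistic[eligible1])))
    expect_true(all(a$tier[eligible1] %in% c("anova", "none")))
  }
})

test_that("group-label swap flips present_group and negates tier-2 statistics", {
  set.seed(703)
  tab <- random_protein_table(n_proteins = 60, missing_prob = 0.5)
  swapped <- protein_table(
    tab$lfq,
    groups = stats::setNames(
      ifelse(tab$groups == "sensitive", "resilient", "sensitive"),
      names(tab$groups)),
    detected = tab$detected)
  a <- run_cascade(tab, tier_config())$assignments
  b <- run_cascade(swapped, tier_config())$assignments
  expect_identical(a$tier, b$tier)
  fc <- a$tier == "foldchange"
  expect_equal(b$statistic[fc], -a$statistic[fc], tolerance = 1e-12)
  pr <- a$tier == "presence"
  expect_identical(b$present_group[pr],
                   ifelse(a$present_group[pr] == "sensitive",
                          "resilient", "sensitive"))
})

test_that("an empty table yields an empty cascade", {
  tab <- protein_table(
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("mouse", "human"))),
    groups = c(mouse = "resilient", human = "sensitive"))
  cas <- run_cascade(tab, tier_config())
  expect_identical(nrow(cas$assignments), 0L)
  expect_identical(unname(cas$counts["total_discriminating"]), 0L)
})
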
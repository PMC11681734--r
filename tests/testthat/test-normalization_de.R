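log2_expr <- function(V) expression_matrix(V, scale = "log2")

test_that("quantile normalization maps every column onto the mean sorted distribution", {
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  out <- quantile_normalize(log2_expr(V))
  expect_equal(unname(out$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(out$values[, 2]), c(2.5, 3.5, 4.5))

  # identical distributions are left unchanged
  W <- matrix(stats::rnorm(30), 10, 3)
  W <- apply(W, 2, sort)
  dimnames(W) <- list(paste0("g", 1:10), paste0("s", 1:3))
  W[, 2] <- W[, 1]; W[, 3] <- W[, 1]
  expect_equal(quantile_normalize(log2_expr(W))$values, W, tolerance = 1e-12)

  # defining property on a random complete matrix
  set.seed(301)
  R <- matrix(stats::rnorm(2000), 200, 10,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
  qn <- quantile_normalize(log2_expr(R))
  sorted <- apply(qn$values, 2, sort)
  for (j in 2:10) expect_equal(sorted[, j], sorted[, 1], tolerance = 1e-9)
  ref <- rowMeans(apply(R, 2, sort))
  expect_equal(unname(sorted[, 1]), ref, tolerance = 1e-9)

  # idempotence
  qn2 <- quantile_normalize(qn)
  expect_equal(qn2$values, qn$values, tolerance = 1e-9)
})

test_that("quantile normalization agrees with an established implementation on complete data", {
  set.seed(302)
  R <- matrix(stats::rnorm(600, 5, 2), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  ours <- quantile_normalize(log2_expr(R))$values
  ref <- limma::normalizeQuantiles(R, ties = TRUE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-9)
})

test_that("quantile normalization handles missing values and rejects starved columns", {
  V <- matrix(stats::rnorm(40), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  miss <- matrix(FALSE, 10, 4)
  miss[1:3, 2] <- TRUE
  V[miss] <- NA
  out <- quantile_normalize(expression_matrix(V, missing = miss,
                                              scale = "log2"))
  expect_identical(out$missing, structure(miss, dimnames = dimnames(V)))
  expect_true(all(is.finite(out$values[!out$missing])))
  # rank order within each column is preserved
  for (j in 1:4) {
    obs <- !miss[, j]
    expect_identical(order(out$values[obs, j]), order(V[obs, j]))
  }

  starved <- V
  starved[2:10, 1] <- NA
  expect_error(quantile_normalize(log2_expr(starved)), "fewer than 2")
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance
  set.seed(303)
  p <- stats::runif(50)
  perm <- sample(50)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("the blocked test is exact on zero-effect genes and antisymmetric under label swap", {
  set.seed(304)
  sheet <- baseline_design(k = 3, m = 4)
  expr <- random_log2_expr(sheet, n_genes = 40, group_effect = 1.5,
                           genes_with_effect = 1:5)
  expr$values[40, ] <- 3.25  # constant gene
  de <- fit_blocked_moderated_test(expr, sheet, de_config())
  expect_equal(de$log2fc[40], 0)
  expect_false(de$significant[40])

  swapped <- sheet
  swapped$group <- ifelse(sheet$group == "sensitive", "resilient", "sensitive")
  class(swapped) <- class(sheet)
  de_sw <- fit_blocked_moderated_test(expr, swapped, de_config())
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-9)
  expect_equal(de_sw$moderated_t, -de$moderated_t, tolerance = 1e-9)
  expect_equal(de_sw$p_value, de$p_value, tolerance = 1e-9)
})

test_that("with prior_df = 0 the moderated t reduces to the ordinary GLS t", {
  set.seed(305)
  sheet <- baseline_design(k = 3, m = 3)
  expr <- random_log2_expr(sheet, n_genes = 30)
  rho <- 0.35
  de <- fit_blocked_moderated_test(expr, sheet, de_config(), prior_df = 0,
                                   rho = rho)
  # independent dense GLS per gene
  V <- diag(nrow(sheet)) * (1 - rho) +
    rho * outer(sheet$species, sheet$species, "==")
  Vi <- solve(V)
  X <- cbind(1, as.numeric(sheet$group == "sensitive"))
  XtVX_i <- solve(t(X) %*% Vi %*% X)
  for (g in c(1, 7, 30)) {
    y <- expr$values[g, ]
    beta <- XtVX_i %*% t(X) %*% Vi %*% y
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (nrow(sheet) - 2)
    t_gls <- beta[2] / sqrt(s2 * XtVX_i[2, 2])
    expect_equal(de$moderated_t[g], t_gls, tolerance = 1e-9)
    expect_equal(de$log2fc[g], beta[2], tolerance = 1e-9)
  }
  # with rho = 0 and no blocking structure it equals the OLS t
  de0 <- fit_blocked_moderated_test(expr, sheet, de_config(), prior_df = 0,
                                    rho = 0)
  for (g in c(2, 15)) {
    fit <- stats::lm(expr$values[g, ] ~ I(sheet$group == "sensitive"))
    expect_equal(de0$moderated_t[g],
                 unname(summary(fit)$coefficients[2, "t value"]),
                 tolerance = 1e-9)
  }
})

test_that("moderation matches limma's empirical-Bayes t when no blocking is active", {
  set.seed(306)
  sheet <- baseline_design(k = 3, m = 4)
  expr <- random_log2_expr(sheet, n_genes = 200, group_effect = 2,
                           genes_with_effect = 1:20)
  de <- fit_blocked_moderated_test(expr, sheet, de_config(), rho = 0)
  design <- cbind(1, as.numeric(sheet$group == "sensitive"))
  fit <- limma::eBayes(limma::lmFit(expr$values, design))
  expect_equal(de$moderated_t, fit$t[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(de$p_value, fit$p.value[, 2], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("genes missing a whole group are excluded with a reason; one-species groups refuse", {
  sheet <- baseline_design(k = 2, m = 3)
  expr <- random_log2_expr(sheet, n_genes = 10)
  miss <- matrix(FALSE, 10, nrow(sheet), dimnames = dimnames(expr$values))
  miss[3, sheet$group == "sensitive"] <- TRUE   # gene 3: whole group missing
  miss[4, sheet$species == "sen1"] <- TRUE      # gene 4: one species left
  V <- expr$values; V[miss] <- NA
  expr2 <- expression_matrix(V, missing = miss, scale = "log2")
  de <- fit_blocked_moderated_test(expr2, sheet, de_config())
  expect_identical(de$exclusion_reason[3], "fewer_than_2_species_in_a_group")
  expect_identical(de$exclusion_reason[4], "fewer_than_2_species_in_a_group")
  expect_true(is.na(de$p_value[3]))
  expect_true(all(is.na(de$exclusion_reason[-c(3, 4)])))

  one_sp <- sheet[sheet$species != "res2", ]
  class(one_sp) <- class(sheet)
  expr3 <- random_log2_expr(one_sp, n_genes = 5)
  expect_error(fit_blocked_moderated_test(expr3, one_sp, de_config()),
               "fewer than 2 species")
})

test_that("PCA overview is deterministic, sign-fixed and variance-ordered", {
  set.seed(307)
  sheet <- baseline_design(k = 2, m = 3)
  V <- matrix(stats::rnorm(20 * nrow(sheet)), 20, nrow(sheet),
              dimnames = list(sprintf("g%02d", 1:20), sheet$sample_id))
  V[, 2] <- V[, 1]  # two identical samples
  pc <- pca_overview(expression_matrix(V, scale = "log2"), sheet)
  expect_equal(unlist(pc$coordinates[1, -(1:2)]),
               unlist(pc$coordinates[2, -(1:2)]), tolerance = 1e-9)
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_lte(sum(pc$variance_fraction), 1 + 1e-9)

  # rank-1 matrix loads everything on PC1
  u <- stats::rnorm(20); w <- stats::rnorm(nrow(sheet))
  R1 <- outer(u, w)
  dimnames(R1) <- dimnames(V)
  pc1 <- pca_overview(expression_matrix(R1, scale = "log2"), sheet)
  expect_equal(pc1$variance_fraction[1], 1, tolerance = 1e-9)
})
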
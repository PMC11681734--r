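# Quantile normalization, the baseline sensitive-vs-resilient test with
# per-species blocking and empirical-Bayes variance moderation, BH FDR, and
# the PCA overview.
#
# The group test treats the sensitive/resilient contrast as a fixed effect
# and the blocking unit (species by default) as a random effect: a consensus
# intra-block correlation rho is estimated by averaging per-gene intraclass
# correlations on the Fisher-z scale, each gene is then fit by generalized
# least squares under a compound-symmetry covariance with that rho, and the
# residual variances are shrunk toward a pooled prior estimated by matching
# moments of the scaled-F model for sample variances. The moderated t gains
# the prior degrees of freedom.

#' Differential-expression configuration
#'
#' @param fold_cutoff minimum fold difference (linear scale) for a gene to be
#'   called significant. Default 2.
#' @param fdr_cutoff maximum BH-adjusted FDR. Default 0.05.
#' @param pseudocount TPM pseudocount for the log2 transform. Default 1.
#' @param block_on blocking unit for the random effect: `"species"` (default;
#'   the group contrast is between species sets) or `"individual"`.
#' @return An `xlps_de_config` list.
#' @export
de_config <- function(fold_cutoff = 2, fdr_cutoff = 0.05, pseudocount = 1,
                      block_on = c("species", "individual")) {
  block_on <- match.arg(block_on)
  stopifnot(fold_cutoff > 1, fdr_cutoff > 0, fdr_cutoff < 1, pseudocount >= 0)
  structure(list(fold_cutoff = fold_cutoff, fdr_cutoff = fdr_cutoff,
                 pseudocount = pseudocount, block_on = block_on),
            class = "xlps_de_config")
}

#' log2-transform a TPM expression matrix
#'
#' Applies value = log2(TPM + pseudocount) cell-wise; the missing mask is
#' preserved.
#'
#' @param expr an `xlps_expr` on the TPM scale.
#' @param pseudocount pseudocount, default 1 TPM.
#' @return An `xlps_expr` on the log2 scale.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  stopifnot(inherits(expr, "xlps_expr"))
  if (expr$scale != "tpm") stop("expected a TPM-scale matrix", call. = FALSE)
  vals <- log2(expr$values + pseudocount)
  expression_matrix(vals, missing = expr$missing, scale = "log2")
}

#' Subset an expression matrix to the baseline samples
#'
#' Baseline is defined as the unstimulated (dose 0) samples at the earliest
#' time point, the closest available estimate of the resting transcriptomic
#' state.
#'
#' @param expr an `xlps_expr`.
#' @param sheet matching sample sheet.
#' @param time baseline time point in hours; default the sheet's earliest.
#' @return List with `expr` (subset `xlps_expr`) and `sheet` (subset sheet).
#' @export
baseline_subset <- function(expr, sheet, time = min(sheet$time)) {
  keep <- sheet$dose == 0 & sheet$time == time
  if (!any(keep)) stop("no dose-0 samples at time ", time, call. = FALSE)
  sub <- sheet[keep, , drop = FALSE]
  ids <- intersect(sub$sample_id, colnames(expr$values))
  sub <- sub[match(ids, sub$sample_id), , drop = FALSE]
  list(
    expr = expression_matrix(expr$values[, ids, drop = FALSE],
                             missing = expr$missing[, ids, drop = FALSE],
                             scale = expr$scale),
    sheet = sheet[match(ids, sheet$sample_id), , drop = FALSE]
  )
}

#' Quantile normalization with missing-value support
#'
#' Forces every column (sample) of a log2 expression matrix onto a common
#' reference distribution: the mean of the per-column empirical quantile
#' functions, computed over non-missing entries with per-rank interpolation
#' when columns differ in how many values they carry. Tied values receive
#' the reference value at their mean quantile. When all columns are complete,
#' the sorted values of every column afterwards equal the mean of the sorted
#' input columns, and a second application changes nothing.
#'
#' @param expr an `xlps_expr` on the log2 scale.
#' @return Quantile-normalized `xlps_expr`.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "xlps_expr"))
  if (expr$scale != "log2") stop("quantile normalization expects log2 scale",
                                 call. = FALSE)
  V <- expr$values
  miss <- expr$missing
  n <- nrow(V)
  ncols <- ncol(V)
  n_obs <- colSums(!miss)
  if (any(n_obs < 2)) {
    stop("column(s) with fewer than 2 non-missing values: ",
         paste(colnames(V)[n_obs < 2], collapse = ", "), call. = FALSE)
  }
  grid <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0.5
  qmat <- matrix(NA_real_, n, ncols)
  for (j in seq_len(ncols)) {
    xj <- sort(V[!miss[, j], j])
    nj <- length(xj)
    pj <- if (nj > 1) (seq_len(nj) - 1) / (nj - 1) else 0.5
    qmat[, j] <- stats::approx(pj, xj, xout = grid, rule = 2, ties = "ordered")$y
  }
  ref <- rowMeans(qmat)
  out <- V
  for (j in seq_len(ncols)) {
    obs <- !miss[, j]
    xj <- V[obs, j]
    nj <- length(xj)
    r <- rank(xj, ties.method = "average")
    p <- if (nj > 1) (r - 1) / (nj - 1) else 0.5
    out[obs, j] <- stats::approx(grid, ref, xout = p, rule = 2,
                                 ties = "ordered")$y
  }
  expression_matrix(out, missing = miss, scale = "log2")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, order-preserving
#' with the input.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

# --- internal GLS machinery ------------------------------------------------

# Compound-symmetry correlation matrix over the given block labels.
.cs_matrix <- function(block, rho) {
  same <- outer(block, block, "==")
  V <- ifelse(same, rho, 0)
  diag(V) <- 1
  V
}

# Consensus intra-block correlation: per-gene intraclass correlation of the
# residuals after removing group means, averaged across genes on the
# Fisher-z scale with trimming, then bias-corrected. Under zero true
# correlation the per-gene ICC is a fixed function of an F(b-g, N-b) pivot,
# so the trimmed average has a known (negative) null expectation that would
# otherwise understate block-mean variances and inflate every t statistic;
# that expectation is computed by quadrature and subtracted. Uses genes
# observed in every sample.
.null_z_bias <- function(df1, df2, n0, trim) {
  h <- function(p) {
    f <- stats::qf(p, df1, df2)
    icc <- (f - 1) / (f + n0 - 1)
    atanh(pmin(pmax(icc, -0.98), 0.98))
  }
  stats::integrate(h, trim, 1 - trim, rel.tol = 1e-8)$value / (1 - 2 * trim)
}

.consensus_correlation <- function(Y, miss, group, block, trim = 0.15) {
  complete <- rowSums(miss) == 0
  if (sum(complete) < 2) {
    warning("too few complete genes to estimate the block correlation; using 0",
            call. = FALSE)
    return(0)
  }
  Yc <- Y[complete, , drop = FALSE]
  gfac <- factor(group)
  bfac <- factor(block)
  N <- ncol(Yc)
  b <- nlevels(bfac)
  g <- nlevels(gfac)
  if (b <= g || N <= b) return(0)
  gm <- t(rowsum(t(Yc), gfac) / as.vector(table(gfac)))
  R <- Yc - gm[, as.integer(gfac), drop = FALSE]
  nb <- as.numeric(table(bfac))
  Bmean <- sweep(t(rowsum(t(R), bfac)), 2, nb, "/")
  SSB <- rowSums(sweep(Bmean^2, 2, nb, "*"))
  SSW <- pmax(rowSums(R^2) - SSB, 0)
  MSB <- SSB / (b - g)
  MSW <- SSW / (N - b)
  n0 <- (N - sum(nb^2) / N) / (b - g)
  icc <- (MSB - MSW) / (MSB + (n0 - 1) * MSW)
  icc[!is.finite(icc)] <- 0
  icc <- pmin(pmax(icc, -0.98), 0.98)
  zbar <- mean(atanh(icc), trim = trim)
  rho <- tanh(zbar - .null_z_bias(b - g, N - b, n0, trim))
  # keep the compound-symmetry covariance positive definite
  lower <- -1 / (max(nb) - 1) + 0.01
  min(max(rho, lower), 0.99)
}

# GLS group fit per gene under compound symmetry, grouped by missingness
# pattern so the whitening is computed once per pattern.
# Returns per-gene coef (sensitive - resilient), s2, df, c22 (unscaled
# variance of the coefficient), n_used, reason (NA when fit).
.gls_group_fit <- function(Y, miss, group, block, species, rho,
                           min_species_per_group = 2) {
  ng <- nrow(Y)
  coef <- s2 <- c22 <- rep(NA_real_, ng)
  df <- n_used <- rep(NA_real_, ng)
  reason <- rep(NA_character_, ng)
  sens <- group == "sensitive"

  pat <- apply(miss, 1, function(m) paste(as.integer(m), collapse = ""))
  for (p in unique(pat)) {
    rows <- which(pat == p)
    use <- !miss[rows[1], ]
    nu <- sum(use)
    ok_groups <- all(vapply(unique(group), function(gl) {
      length(unique(species[use & group == gl])) >= min_species_per_group
    }, logical(1)))
    if (!ok_groups) {
      reason[rows] <- "fewer_than_2_species_in_a_group"
      next
    }
    if (nu < 4 || nu - 2 < 1) {
      reason[rows] <- "too_few_samples"
      next
    }
    V <- .cs_matrix(block[use], rho)
    Li <- backsolve(chol(V), diag(nu), transpose = TRUE)  # L^{-1}, V = L L'
    X <- cbind(intercept = 1, sensitive = as.numeric(sens[use]))
    Xw <- Li %*% X
    XtXi <- solve(crossprod(Xw))
    Yw <- Y[rows, use, drop = FALSE] %*% t(Li)
    beta <- Yw %*% Xw %*% XtXi
    resid <- Yw - beta %*% t(Xw)
    coef[rows] <- beta[, 2]
    df[rows] <- nu - 2
    s2[rows] <- rowSums(resid^2) / (nu - 2)
    c22[rows] <- XtXi[2, 2]
    n_used[rows] <- nu
  }
  list(coef = coef, s2 = s2, df = df, c22 = c22, n_used = n_used,
       reason = reason)
}

#' Blocked moderated group test (sensitive vs resilient)
#'
#' Fits, per gene, the fixed group effect (sensitive minus resilient) by
#' generalized least squares under a compound-symmetry covariance whose
#' intra-block correlation is a consensus estimate shared across genes, then
#' moderates the residual variances by empirical-Bayes shrinkage toward a
#' pooled prior (prior df and scale estimated by moment-matching of the
#' log-variance distribution under the scaled-F model). The moderated t has
#' the residual plus prior degrees of freedom; p-values are BH-adjusted
#' across all genes with a fit.
#'
#' Genes missing in so many samples that a group retains fewer than two
#' species are excluded with a recorded reason. Each group must contribute
#' at least two species overall.
#'
#' @param expr an `xlps_expr` on the log2 scale (baseline samples).
#' @param sheet matching sample sheet rows.
#' @param cfg a [de_config()].
#' @param prior_df override for the prior degrees of freedom: `NULL`
#'   (default) estimates it from the data; `0` disables moderation, giving
#'   the ordinary GLS t.
#' @param rho override for the consensus intra-block correlation; `NULL`
#'   estimates it.
#' @return data.frame with columns `gene_id`, `log2fc`, `moderated_t`,
#'   `p_value`, `fdr`, `significant`, `direction`, `n_samples_used`,
#'   `exclusion_reason`.
#' @export
fit_blocked_moderated_test <- function(expr, sheet, cfg = de_config(),
                                       prior_df = NULL, rho = NULL) {
  stopifnot(inherits(expr, "xlps_expr"))
  if (expr$scale != "log2") stop("expected log2-scale matrix", call. = FALSE)
  sheet <- sheet[match(colnames(expr$values), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("samples absent from sheet", call. = FALSE)
  group <- sheet$group
  species <- sheet$species
  block <- sheet[[cfg$block_on]]
  for (gl in c("sensitive", "resilient")) {
    if (length(unique(species[group == gl])) < 2) {
      stop("group '", gl, "' has fewer than 2 species; the random effect is ",
           "inestimable", call. = FALSE)
    }
  }
  Y <- expr$values
  Y[expr$missing] <- 0  # masked by pattern-wise subsetting below
  if (is.null(rho)) {
    rho <- .consensus_correlation(expr$values, expr$missing, group, block)
  }
  fit <- .gls_group_fit(Y, expr$missing, group, block, species, rho)
  tested <- is.na(fit$reason)

  mod_t <- p <- rep(NA_real_, nrow(Y))
  if (any(tested)) {
    if (is.null(prior_df)) {
      sq <- .squeeze_var(fit$s2[tested], fit$df[tested])
      var_post <- sq$var_post
      df_total <- fit$df[tested] + sq$df_prior
    } else if (prior_df == 0) {
      var_post <- fit$s2[tested]
      df_total <- fit$df[tested]
    } else {
      sq <- .squeeze_var(fit$s2[tested], fit$df[tested])
      s0 <- if (is.na(sq$var_prior)) mean(fit$s2[tested]) else sq$var_prior
      var_post <- (prior_df * s0 + fit$df[tested] * fit$s2[tested]) /
        (prior_df + fit$df[tested])
      df_total <- fit$df[tested] + prior_df
    }
    se <- sqrt(var_post * fit$c22[tested])
    tt <- fit$coef[tested] / se
    tt[se == 0] <- 0
    mod_t[tested] <- tt
    # an infinite prior df still cannot exceed the pooled residual df
    df_total <- pmin(df_total, sum(fit$df[tested]))
    p[tested] <- 2 * stats::pt(-abs(tt), df = df_total)
  }
  fdr <- rep(NA_real_, nrow(Y))
  fdr[tested] <- bh_fdr(p[tested])
  lfc <- fit$coef
  significant <- !is.na(lfc) & abs(lfc) >= log2(cfg$fold_cutoff) &
    !is.na(fdr) & fdr <= cfg$fdr_cutoff
  direction <- ifelse(is.na(lfc), NA_character_,
                      ifelse(lfc >= 0, "higher_in_sensitive",
                             "higher_in_resilient"))
  data.frame(
    gene_id = rownames(Y),
    log2fc = lfc,
    moderated_t = mod_t,
    p_value = p,
    fdr = fdr,
    significant = significant,
    direction = direction,
    n_samples_used = fit$n_used,
    exclusion_reason = fit$reason,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' PCA overview of samples
#'
#' Centered principal component analysis of the samples (genes as features),
#' for a global view of how individuals and species distribute. Missing
#' cells are mean-imputed per gene for this overview only. The sign of each
#' component is fixed so that its largest-magnitude gene loading is
#' positive.
#'
#' @param expr an `xlps_expr` on the log2 scale.
#' @param sheet matching sample sheet.
#' @param n_components number of components to report (default 3; reduced
#'   when fewer samples are available).
#' @return List with `coordinates` (data.frame sample_id, group, PC1..PCk)
#'   and `variance_fraction` (numeric vector).
#' @export
pca_overview <- function(expr, sheet, n_components = 3) {
  stopifnot(inherits(expr, "xlps_expr"))
  V <- expr$values
  if (any(expr$missing)) {
    rm <- rowMeans(V, na.rm = TRUE)
    rm[is.nan(rm)] <- 0
    idx <- which(expr$missing, arr.ind = TRUE)
    V[idx] <- rm[idx[, 1]]
  }
  k <- min(n_components, ncol(V) - 1, nrow(V))
  if (k < 1) stop("need at least 2 samples for a PCA overview", call. = FALSE)
  pc <- stats::prcomp(t(V), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  for (j in seq_len(k)) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)
  sheet <- sheet[match(colnames(expr$values), sheet$sample_id), , drop = FALSE]
  coords <- data.frame(sample_id = colnames(expr$values),
                       group = sheet$group, stringsAsFactors = FALSE)
  for (j in seq_len(k)) coords[[paste0("PC", j)]] <- pc$x[, j]
  list(coordinates = coords, variance_fraction = varfrac[seq_len(k)])
}
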
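# Internal helpers shared across modules. Not exported.

# Deterministic plain-text rendering of numerics: full double precision,
# "0" stays "0" (no exponent form for exact zero), NA -> "NA".
.fmt_num <- function(x) {
  out <- rep("NA", length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(x[ok], function(v) {
    if (v == 0) return("0")
    formatC(v, digits = 15, format = "g", width = 1)
  }, character(1))
  out
}

.fmt_cell <- function(x) {
  if (is.numeric(x)) .fmt_num(x) else {
    out <- as.character(x)
    out[is.na(out)] <- "NA"
    out
  }
}

# Write a data.frame as TSV, optionally with "# " comment header lines.
.write_tsv <- function(df, path, comments = character(0)) {
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e), call. = FALSE)
  })
  on.exit(close(con))
  lines <- character(0)
  if (length(comments)) lines <- paste0("# ", comments)
  cells <- lapply(df, .fmt_cell)
  body <- if (nrow(df)) do.call(paste, c(cells, sep = "\t")) else character(0)
  lines <- c(lines, paste(names(df), collapse = "\t"), body)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", ...)
}

# Write a numeric matrix with row-name id column as TSV (deterministic bytes).
.write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  df <- data.frame(id = rownames(mat), stringsAsFactors = FALSE)
  names(df) <- id_col
  for (j in seq_len(ncol(mat))) df[[colnames(mat)[j]]] <- mat[, j]
  .write_tsv(df, path)
}

# Inverse of trigamma by Newton iteration on 1/trigamma (monotone convex),
# the standard approach for fitting the scaled-F prior to sample variances.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Empirical-Bayes squeeze of per-gene sample variances s2 (df degrees of
# freedom each) toward a common prior: the distribution of s2 is modelled as
# scaled F and (d0, s0^2) are estimated by matching moments of log s2.
# Returns prior df (possibly Inf), prior variance, and posterior variances
#   var_post = (d0 * s0^2 + df * s2) / (d0 + df).
.squeeze_var <- function(s2, df) {
  stopifnot(length(s2) == length(df))
  n <- length(s2)
  ok <- is.finite(s2) & s2 > 0 & is.finite(df) & df > 0
  if (sum(ok) < 2) {
    # too few informative genes to pool: no moderation
    return(list(df_prior = 0, var_prior = NA_real_, var_post = s2))
  }
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(df[ok] / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread in log s2 beyond sampling noise: common variance
    d0 <- Inf
    s0 <- mean(s2[ok])
  }
  var_post <- if (is.finite(d0)) {
    (d0 * s0 + df * s2) / (d0 + df)
  } else {
    rep(s0, n)
  }
  # genes with df = 0 carry no variance information: posterior = prior
  var_post[df == 0] <- if (is.finite(d0)) s0 else s0
  list(df_prior = d0, var_prior = s0, var_post = var_post)
}

.results_header <- function(thresholds = NULL) {
  hdr <- paste0("xlps v", as.character(utils::packageVersion("xlps")))
  if (!is.null(thresholds) && length(thresholds)) {
    hdr <- c(hdr, paste0("thresholds: ",
                         paste(names(thresholds), unlist(thresholds),
                               sep = "=", collapse = "; ")))
  }
  hdr
}
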
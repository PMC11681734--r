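# Complete-separation screens: genes whose baseline expression (or LPS
# response) in every individual of one group strictly exceeds that in every
# individual of the other group, with a single missing annotation tolerated
# in the more strongly expressed or induced class (to accommodate
# incompleteness of genome annotations). A missing value in the lower class
# is never tolerated, because it cannot certify non-overlap.

#' Complete-separation screen
#'
#' For each gene: the candidate higher class is the group with the larger
#' mean over non-missing values; the gene is separated when every
#' non-missing value of the higher class strictly exceeds every non-missing
#' value of the lower class, the higher class has at most `tolerance`
#' missing individuals, and the lower class has none. Ties across classes
#' break separation. Genes with no non-missing value in either class are not
#' separated and carry `higher_class = "none"`.
#'
#' @param values numeric matrix, genes x individuals, on the analysis scale
#'   (log2 baseline expression, or per-individual log2 fold change).
#' @param labels character vector (length `ncol(values)`) giving each
#'   individual's group, `"sensitive"` or `"resilient"`.
#' @param missing optional logical mask, defaults to `is.na(values)`.
#' @param tolerance missing individuals tolerated in the higher class;
#'   default 1.
#' @return data.frame with columns `gene_id`, `separated`, `higher_class`,
#'   `gap` (min higher minus max lower), `n_missing_higher`,
#'   `n_missing_lower`, `rank_score` (sensitive minus resilient group mean).
#' @export
complete_separation_screen <- function(values, labels, missing = NULL,
                                       tolerance = 1) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (length(labels) != ncol(values)) {
    stop("one group label per column is required", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% GROUPS)) {
    stop("unlabeled individual or unknown group label", call. = FALSE)
  }
  if (is.null(missing)) missing <- is.na(values)
  stopifnot(all(dim(missing) == dim(values)))
  V <- values
  V[missing] <- NA_real_

  stat_group <- function(g) {
    idx <- which(labels == g)
    sub <- V[, idx, drop = FALSE]
    cols <- lapply(seq_len(ncol(sub)), function(j) sub[, j])
    list(
      min = do.call(pmin, c(cols, na.rm = TRUE)),
      max = do.call(pmax, c(cols, na.rm = TRUE)),
      mean = rowMeans(sub, na.rm = TRUE),
      n_missing = rowSums(missing[, idx, drop = FALSE])
    )
  }
  s <- stat_group("sensitive")
  r <- stat_group("resilient")
  mean_s <- s$mean; mean_s[is.nan(mean_s)] <- NA_real_
  mean_r <- r$mean; mean_r[is.nan(mean_r)] <- NA_real_

  both <- !is.na(mean_s) & !is.na(mean_r) & mean_s != mean_r
  higher <- rep("none", nrow(V))
  higher[both & mean_s > mean_r] <- "sensitive"
  higher[both & mean_s < mean_r] <- "resilient"

  gap <- rep(NA_real_, nrow(V))
  nm_h <- nm_l <- rep(NA_integer_, nrow(V))
  sep <- rep(FALSE, nrow(V))
  hs <- higher == "sensitive"
  hr <- higher == "resilient"
  gap[hs] <- s$min[hs] - r$max[hs]
  gap[hr] <- r$min[hr] - s$max[hr]
  nm_h[hs] <- s$n_missing[hs]; nm_l[hs] <- r$n_missing[hs]
  nm_h[hr] <- r$n_missing[hr]; nm_l[hr] <- s$n_missing[hr]
  ok <- hs | hr
  sep[ok] <- gap[ok] > 0 & nm_h[ok] <= tolerance & nm_l[ok] == 0

  data.frame(
    gene_id = rownames(V),
    separated = sep,
    higher_class = higher,
    gap = gap,
    n_missing_higher = as.integer(nm_h),
    n_missing_lower = as.integer(nm_l),
    rank_score = mean_s - mean_r,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Top-k separated genes by group difference
#'
#' Filters the separation records to separated genes (optionally also
#' requiring BH FDR <= `fdr_cutoff` in a matching differential-expression
#' result, as for the response screens), orders by |rank_score| descending
#' with a deterministic lexicographic tie-break on gene id, and returns the
#' first k gene ids (fewer when fewer qualify; no padding).
#'
#' @param records output of [complete_separation_screen()].
#' @param de optional data.frame with `gene_id` and `fdr` columns.
#' @param k number of genes requested (>= 1).
#' @param require_significant when `TRUE`, keep only genes with
#'   `fdr <= fdr_cutoff` in `de`.
#' @param fdr_cutoff FDR threshold used with `require_significant`.
#' @return Character vector of gene ids, at most length k.
#' @export
top_k_by_difference <- function(records, de = NULL, k,
                                require_significant = FALSE,
                                fdr_cutoff = 0.05) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  sel <- records[records$separated, , drop = FALSE]
  if (require_significant) {
    if (is.null(de)) stop("require_significant needs a DE result", call. = FALSE)
    fdr <- de$fdr[match(sel$gene_id, de$gene_id)]
    sel <- sel[!is.na(fdr) & fdr <= fdr_cutoff, , drop = FALSE]
  }
  if (!nrow(sel)) return(character(0))
  ord <- order(-abs(sel$rank_score), sel$gene_id, method = "radix")
  utils::head(sel$gene_id[ord], k)
}

#' Direction census of a separated gene list
#'
#' Counts how many genes in the list are higher in the sensitive versus the
#' resilient class.
#'
#' @param records output of [complete_separation_screen()].
#' @param genes optional character vector restricting (and ordering) the
#'   census; defaults to all separated genes.
#' @return Named integer vector `c(sensitive = , resilient = )`.
#' @export
direction_census <- function(records, genes = NULL) {
  if (is.null(genes)) genes <- records$gene_id[records$separated]
  sub <- records[match(genes, records$gene_id), , drop = FALSE]
  c(sensitive = sum(sub$higher_class == "sensitive", na.rm = TRUE),
    resilient = sum(sub$higher_class == "resilient", na.rm = TRUE))
}
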
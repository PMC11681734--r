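# Readers, writers and validated containers for all tabular formats the
# pipeline touches. The sole dialect is tab-separated UTF-8 text with "NA"
# as the missing-value token, matching common omics supplementary-table
# practice.

GROUPS <- c("sensitive", "resilient")

#' Construct and validate a sample sheet
#'
#' A sample sheet describes the paired, blocked ex vivo stimulation design:
#' one row per whole-blood sample, identified by species, group (sensitive or
#' resilient to LPS), individual animal, LPS dose (ng/mL) and incubation time
#' (hours). Every stimulated sample (dose > 0) must have an unstimulated
#' (dose 0) sample from the same individual at the same time point, which
#' serves as its paired control.
#'
#' @param df data.frame with columns `sample_id`, `species`, `group`,
#'   `individual`, `dose`, `time`.
#' @param pairing `"error"` to fail on a stimulated sample lacking its dose-0
#'   control, `"warn"` to tolerate partial designs with a warning.
#' @return A validated `xlps_sample_sheet` (a data.frame).
#' @export
sample_sheet <- function(df, pairing = c("error", "warn")) {
  pairing <- match.arg(pairing)
  required <- c("sample_id", "species", "group", "individual", "dose", "time")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("sample sheet is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, required]
  df$sample_id <- as.character(df$sample_id)
  df$species <- as.character(df$species)
  df$group <- as.character(df$group)
  df$individual <- as.character(df$individual)
  df$dose <- as.numeric(df$dose)
  df$time <- as.numeric(df$time)

  if (anyNA(df)) stop("sample sheet contains missing values", call. = FALSE)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(df$group), GROUPS)
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         " (expected sensitive/resilient)", call. = FALSE)
  }
  key <- paste(df$species, df$individual, df$dose, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (species, individual, dose, time) combination",
         call. = FALSE)
  }
  sp_groups <- unique(df[, c("species", "group")])
  if (anyDuplicated(sp_groups$species)) {
    bad <- sp_groups$species[duplicated(sp_groups$species)]
    stop("species mapped to more than one group: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  stim <- df[df$dose > 0, , drop = FALSE]
  if (nrow(stim)) {
    ctrl_key <- with(df[df$dose == 0, , drop = FALSE],
                     paste(species, individual, time, sep = "\r"))
    stim_key <- with(stim, paste(species, individual, time, sep = "\r"))
    unpaired <- !(stim_key %in% ctrl_key)
    if (any(unpaired)) {
      msg <- paste0("stimulated sample(s) without a dose-0 control at the same ",
                    "time: ", paste(stim$sample_id[unpaired], collapse = ", "))
      if (pairing == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  class(df) <- c("xlps_sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @param path path to a TSV file with header columns `sample_id`, `species`,
#'   `group`, `individual`, `dose`, `time`.
#' @inheritParams sample_sheet
#' @return A validated `xlps_sample_sheet`.
#' @export
read_sample_sheet <- function(path, pairing = c("error", "warn")) {
  sample_sheet(.read_tsv(path), pairing = pairing)
}

#' Species-to-group lookup from a sample sheet
#' @param sheet an `xlps_sample_sheet`.
#' @return Named character vector mapping species to group.
#' @export
species_groups <- function(sheet) {
  u <- unique(sheet[, c("species", "group")])
  stats::setNames(u$group, u$species)
}

#' Construct an expression matrix container
#'
#' Holds a gene-by-sample abundance matrix on either the TPM or log2 scale,
#' together with an explicit missingness mask. A cell is missing when the
#' gene has no measurement for that sample, e.g. because the gene has no
#' annotated ortholog in that sample's species.
#'
#' @param values numeric matrix, genes x samples, with rownames (gene ids)
#'   and colnames (sample ids).
#' @param missing logical matrix of the same shape; `TRUE` marks no
#'   measurement. Defaults to `is.na(values)`.
#' @param scale `"tpm"` (non-negative abundances) or `"log2"`.
#' @return An `xlps_expr` object (list with `values`, `missing`, `scale`).
#' @export
expression_matrix <- function(values, missing = NULL, scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix requires gene rownames and sample colnames",
         call. = FALSE)
  }
  if (is.null(missing)) missing <- is.na(values)
  stopifnot(is.logical(missing), all(dim(missing) == dim(values)))
  obs <- values[!missing]
  if (any(!is.finite(obs))) {
    stop("non-finite value in a non-missing cell", call. = FALSE)
  }
  if (scale == "tpm" && any(obs < 0)) {
    stop("negative TPM value", call. = FALSE)
  }
  values[missing] <- NA_real_
  dimnames(missing) <- dimnames(values)
  structure(list(values = values, missing = missing, scale = scale),
            class = "xlps_expr")
}

#' @export
print.xlps_expr <- function(x, ...) {
  cat(sprintf("<xlps_expr> %d genes x %d samples, scale=%s, %.1f%% missing\n",
              nrow(x$values), ncol(x$values), x$scale,
              100 * mean(x$missing)))
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene identifiers; remaining columns must be sample ids
#' present in `sheet`. "NA" cells mark missing measurements. Columns are
#' reordered to match the sheet's sample order (restricted to the samples
#' present in the file).
#'
#' @param path path to TSV.
#' @param sheet an `xlps_sample_sheet` the columns are validated against.
#' @param scale abundance scale of the file, `"tpm"` or `"log2"`.
#' @return An `xlps_expr`.
#' @export
read_expression_matrix <- function(path, sheet, scale = c("tpm", "log2")) {
  scale <- match.arg(scale)
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("expression TSV needs a gene column plus samples",
                         call. = FALSE)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids", call. = FALSE)
  samp <- names(df)[-1]
  unknown <- setdiff(samp, sheet$sample_id)
  if (length(unknown)) {
    stop("sample column(s) not in sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values", call. = FALSE)
  rownames(vals) <- gene_ids
  keep <- sheet$sample_id[sheet$sample_id %in% samp]
  vals <- vals[, keep, drop = FALSE]
  expression_matrix(vals, scale = scale)
}

#' Construct a protein LFQ table
#'
#' Protein-by-species table of log2 label-free quantification intensities,
#' with a detection mask (`FALSE` = protein not detected in that species'
#' plasma). Each species carries a sensitive/resilient group label.
#'
#' @param lfq numeric matrix, proteins x species, log2 LFQ; `NA` where not
#'   detected.
#' @param groups named character vector mapping every species (column) to
#'   `"sensitive"` or `"resilient"`.
#' @param detected optional logical matrix; defaults to `!is.na(lfq)`.
#' @return An `xlps_protein_table`.
#' @export
protein_table <- function(lfq, groups, detected = NULL) {
  stopifnot(is.matrix(lfq), is.numeric(lfq))
  if ((nrow(lfq) > 0 && is.null(rownames(lfq))) || is.null(colnames(lfq))) {
    stop("protein table requires protein rownames and species colnames",
         call. = FALSE)
  }
  if (nrow(lfq) == 0 && is.null(rownames(lfq))) rownames(lfq) <- character(0)
  if (is.null(detected)) detected <- !is.na(lfq)
  stopifnot(is.logical(detected), all(dim(detected) == dim(lfq)))
  if (any(!is.finite(lfq[detected]))) {
    stop("non-finite LFQ value in a detected cell", call. = FALSE)
  }
  missing_sp <- setdiff(colnames(lfq), names(groups))
  if (length(missing_sp)) {
    stop("no group label for species: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  groups <- groups[colnames(lfq)]
  bad <- setdiff(unique(groups), GROUPS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  lfq[!detected] <- NA_real_
  dimnames(detected) <- dimnames(lfq)
  structure(list(lfq = lfq, detected = detected, groups = groups),
            class = "xlps_protein_table")
}

#' Read a protein LFQ table from TSV
#'
#' First column holds protein identifiers; remaining columns are species.
#' Blank or "NA" cells mean the protein was not detected in that species.
#'
#' @param path path to TSV.
#' @param groups named character vector mapping species to group.
#' @return An `xlps_protein_table`.
#' @export
read_protein_table <- function(path, groups) {
  df <- .read_tsv(path, colClasses = "character")
  if (ncol(df) < 2) stop("protein TSV needs a protein column plus species",
                         call. = FALSE)
  ids <- df[[1]]
  if (anyDuplicated(ids)) stop("duplicate protein ids", call. = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == ""] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- !is.na(vals) & is.na(num)
  if (any(bad)) {
    stop("non-numeric LFQ cell(s): ",
         paste(utils::head(vals[bad], 3), collapse = ", "), call. = FALSE)
  }
  rownames(num) <- ids
  protein_table(num, groups = groups)
}

#' Write a results table to TSV
#'
#' Writes any results data.frame (differential-expression results, separation
#' records, tier assignments) with a stable column order, full double
#' precision (round-trips to better than 1e-12 relative), and a comment
#' header recording the package version and the thresholds in force.
#'
#' @param results a data.frame.
#' @param path output path.
#' @param thresholds optional named list recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, thresholds = NULL) {
  stopifnot(is.data.frame(results))
  .write_tsv(as.data.frame(results), path, comments = .results_header(thresholds))
}

#' Read back a results table written by [write_results_table()]
#' @param path path to TSV.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  .read_tsv(path)
}
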
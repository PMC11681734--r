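# Per-species paired LPS-response analysis and the between-group
# difference-in-fold-changes test.
#
# The response of a gene in an individual is the paired log2 fold change of
# TPM between that individual's stimulated and unstimulated samples at the
# same time point. Per-species significance uses a moderated one-sample t
# across individuals; the between-group test feeds the per-individual fold
# changes into the same blocked moderated machinery as the baseline test,
# with species as blocks.

#' Response-analysis configuration
#'
#' @param dose LPS dose (ng/mL) analysed against the dose-0 control. Default
#'   10, the dose carried through the downstream analyses (dose escalation
#'   has a consistent but minimal effect).
#' @param per_species_fold_cutoff minimum fold change for per-species
#'   significance. Default 2.
#' @param group_diff_fold_cutoff minimum between-group difference in fold
#'   changes, interpreted multiplicatively. Default 1.5.
#' @param fdr_cutoff maximum BH FDR. Default 0.05.
#' @param pseudocount TPM pseudocount inside the fold-change ratio. Default 1.
#' @return An `xlps_response_config` list.
#' @export
response_config <- function(dose = 10, per_species_fold_cutoff = 2,
                            group_diff_fold_cutoff = 1.5, fdr_cutoff = 0.05,
                            pseudocount = 1) {
  stopifnot(dose > 0, per_species_fold_cutoff > 1, group_diff_fold_cutoff > 1,
            fdr_cutoff > 0, fdr_cutoff < 1, pseudocount >= 0)
  structure(list(dose = dose,
                 per_species_fold_cutoff = per_species_fold_cutoff,
                 group_diff_fold_cutoff = group_diff_fold_cutoff,
                 fdr_cutoff = fdr_cutoff, pseudocount = pseudocount),
            class = "xlps_response_config")
}

#' Paired per-individual log2 fold changes
#'
#' For every individual with both a stimulated (configured dose) and a
#' control (dose 0) sample at the requested time, computes per gene
#' log2((TPM_dose + pc) / (TPM_0 + pc)). A record exists only where both
#' paired measurements are non-missing. Individuals lacking either member of
#' the pair contribute no records.
#'
#' @param expr an `xlps_expr` on the TPM scale (human-ortholog space).
#' @param sheet matching sample sheet.
#' @param cfg a [response_config()].
#' @param time time point in hours.
#' @return data.frame with columns `gene_id`, `species`, `group`,
#'   `individual`, `time`, `log2fc` (long format).
#' @export
paired_fold_changes <- function(expr, sheet, cfg = response_config(), time) {
  stopifnot(inherits(expr, "xlps_expr"))
  if (expr$scale != "tpm") stop("fold changes are defined on TPM", call. = FALSE)
  sheet <- sheet[sheet$sample_id %in% colnames(expr$values), , drop = FALSE]
  stim <- sheet[sheet$dose == cfg$dose & sheet$time == time, , drop = FALSE]
  ctrl <- sheet[sheet$dose == 0 & sheet$time == time, , drop = FALSE]
  key_s <- paste(stim$species, stim$individual, sep = "\r")
  key_c <- paste(ctrl$species, ctrl$individual, sep = "\r")
  paired <- intersect(key_s, key_c)
  if (!length(paired)) {
    stop("no stimulated/control pairs at dose ", cfg$dose, ", time ", time,
         call. = FALSE)
  }
  out <- vector("list", length(paired))
  pc <- cfg$pseudocount
  for (i in seq_along(paired)) {
    srow <- stim[match(paired[i], key_s), ]
    crow <- ctrl[match(paired[i], key_c), ]
    vs <- expr$values[, srow$sample_id]
    vc <- expr$values[, crow$sample_id]
    ok <- !expr$missing[, srow$sample_id] & !expr$missing[, crow$sample_id]
    if (!any(ok)) next
    out[[i]] <- data.frame(
      gene_id = rownames(expr$values)[ok],
      species = srow$species, group = srow$group,
      individual = srow$individual, time = time,
      log2fc = log2(vs[ok] + pc) - log2(vc[ok] + pc),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reshape fold-change records into a genes-by-individuals matrix
#'
#' Pivots the long output of [paired_fold_changes()] to a gene x individual
#' matrix (NA where an individual has no record for a gene) plus the
#' individual-level species/group labels, the shape consumed by the response
#' divergence screen.
#'
#' @param records output of [paired_fold_changes()].
#' @return List with `matrix` (genes x individuals) and `labels` (data.frame
#'   individual, species, group).
#' @export
fold_change_matrix <- function(records) {
  genes <- sort(unique(records$gene_id))
  inds <- unique(records[, c("individual", "species", "group")])
  M <- matrix(NA_real_, length(genes), nrow(inds),
              dimnames = list(genes, inds$individual))
  M[cbind(match(records$gene_id, genes),
          match(records$individual, inds$individual))] <- records$log2fc
  list(matrix = M, labels = inds)
}

#' Per-species LPS response test
#'
#' For each species, tests per gene whether the mean paired log2 fold change
#' across individuals differs from zero, using an empirical-Bayes moderated
#' one-sample t (variances pooled across genes within the species).
#' Significant genes satisfy |mean log2fc| >= log2(`per_species_fold_cutoff`)
#' and BH FDR <= `fdr_cutoff`. Genes with fewer than 3 paired individuals in
#' a species are excluded with a recorded reason.
#'
#' @param records output of [paired_fold_changes()] (any number of species).
#' @param cfg a [response_config()].
#' @return data.frame with columns `species`, `gene_id`, `log2fc`
#'   (mean), `moderated_t`, `p_value`, `fdr`, `significant`, `direction`
#'   (up/down), `n_individuals`, `exclusion_reason`.
#' @export
per_species_de <- function(records, cfg = response_config()) {
  pieces <- lapply(split(records, records$species), function(rec) {
    fm <- fold_change_matrix(rec)
    M <- fm$matrix
    n <- rowSums(!is.na(M))
    m <- rowMeans(M, na.rm = TRUE)
    s2 <- apply(M, 1, stats::var, na.rm = TRUE)
    tested <- n >= 3
    mod_t <- p <- fdr <- rep(NA_real_, nrow(M))
    if (any(tested)) {
      sq <- .squeeze_var(s2[tested], n[tested] - 1)
      se <- sqrt(sq$var_post / n[tested])
      tt <- m[tested] / se
      tt[se == 0] <- 0
      mod_t[tested] <- tt
      df_total <- pmin((n[tested] - 1) + sq$df_prior, sum(n[tested] - 1))
      p[tested] <- 2 * stats::pt(-abs(tt), df = df_total)
      fdr[tested] <- bh_fdr(p[tested])
    }
    data.frame(
      species = rec$species[1],
      gene_id = rownames(M),
      log2fc = ifelse(tested, m, NA_real_),
      moderated_t = mod_t, p_value = p, fdr = fdr,
      significant = tested & !is.na(fdr) &
        abs(m) >= log2(cfg$per_species_fold_cutoff) & fdr <= cfg$fdr_cutoff,
      direction = ifelse(tested, ifelse(m >= 0, "up", "down"), NA_character_),
      n_individuals = n,
      exclusion_reason = ifelse(tested, NA_character_, "fewer_than_3_pairs"),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Between-group difference in LPS responses
#'
#' Tests, per gene, whether the mean paired log2 fold change differs between
#' sensitive and resilient species, by running the blocked moderated GLS
#' test on the per-individual fold changes with species as the blocking
#' unit. Significance requires |difference of mean log2 fold changes| >=
#' log2(`group_diff_fold_cutoff`) and BH FDR <= `fdr_cutoff`.
#'
#' @param records output of [paired_fold_changes()] covering both groups.
#' @param cfg a [response_config()].
#' @param prior_df,rho passed to [fit_blocked_moderated_test()].
#' @return data.frame as from [fit_blocked_moderated_test()]; `log2fc` holds
#'   the sensitive-minus-resilient difference in mean fold change.
#' @export
group_response_difference <- function(records, cfg = response_config(),
                                      prior_df = NULL, rho = NULL) {
  fm <- fold_change_matrix(records)
  labels <- fm$labels
  pseudo_sheet <- data.frame(
    sample_id = labels$individual,
    species = labels$species,
    group = labels$group,
    individual = labels$individual,
    dose = 0, time = unique(records$time)[1],
    stringsAsFactors = FALSE)
  class(pseudo_sheet) <- c("xlps_sample_sheet", "data.frame")
  expr <- expression_matrix(fm$matrix, scale = "log2")
  dcfg <- de_config(fold_cutoff = cfg$group_diff_fold_cutoff,
                    fdr_cutoff = cfg$fdr_cutoff, block_on = "species")
  fit_blocked_moderated_test(expr, pseudo_sheet, dcfg,
                             prior_df = prior_df, rho = rho)
}
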
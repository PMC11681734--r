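# Three mutually exclusive capture tiers for discriminating plasma (or HDL)
# proteins between sensitive and resilient species, applied as a cascade:
#
#   tier 1 (anova):      proteins with enough detected values in both groups
#                        receive a two-group ANOVA p-value; p < cutoff
#                        captures them. A protein that received a p-value
#                        exits the cascade whether captured or not.
#   tier 2 (foldchange): proteins without a p-value but detected in both
#                        groups and in enough species total are compared by
#                        the difference of group means of detected log2 LFQ;
#                        |difference| >= cutoff captures them.
#   tier 3 (presence):   proteins detected in only one group are captured
#                        when detected in enough species of that group.

#' Tier configuration for the proteomics cascade
#'
#' @param anova_p_cutoff raw ANOVA p-value threshold for tier 1 (no multiple
#'   testing correction; this initial capture uses the raw p). Default 0.05.
#' @param log2fc_cutoff absolute log2 group fold-change threshold for tier
#'   2. Default 3.
#' @param min_occurrences minimum number of species with a detected value
#'   for tier-2 eligibility. Default 4.
#' @param min_presence_species minimum detected species for tier-3 capture.
#'   Default 3.
#' @param min_values_per_group_for_anova minimum detected values per group
#'   for a tier-1 p-value. Default 2.
#' @return An `xlps_tier_config` list.
#' @export
tier_config <- function(anova_p_cutoff = 0.05, log2fc_cutoff = 3,
                        min_occurrences = 4, min_presence_species = 3,
                        min_values_per_group_for_anova = 2) {
  stopifnot(anova_p_cutoff > 0, log2fc_cutoff > 0, min_occurrences >= 1,
            min_presence_species >= 1, min_values_per_group_for_anova >= 1)
  structure(list(anova_p_cutoff = anova_p_cutoff,
                 log2fc_cutoff = log2fc_cutoff,
                 min_occurrences = min_occurrences,
                 min_presence_species = min_presence_species,
                 min_values_per_group_for_anova = min_values_per_group_for_anova),
            class = "xlps_tier_config")
}

.protein_group_split <- function(table, p) {
  det <- table$detected[p, ]
  x <- table$lfq[p, ]
  sens <- table$groups == "sensitive"
  list(x_s = x[det & sens], x_r = x[det & !sens],
       n_s = sum(det & sens), n_r = sum(det & !sens))
}

# Two-group one-way ANOVA p-value on species-level log2 LFQ. Degenerate
# zero-variance cases: unequal means are treated as maximally significant
# (p = 0), equal means as uninformative (p = 1).
.anova_p <- function(x_s, x_r) {
  x <- c(x_s, x_r)
  g <- factor(c(rep("s", length(x_s)), rep("r", length(x_r))))
  n <- length(x)
  gm <- tapply(x, g, mean)
  ssb <- sum(tapply(x, g, length) * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  if (ssw <= .Machine$double.eps * sum(x^2)) {
    return(if (abs(diff(gm)) > 0) 0 else 1)
  }
  f <- (ssb / 1) / (ssw / (n - 2))
  stats::pf(f, 1, n - 2, lower.tail = FALSE)
}

#' Tier 1: ANOVA capture
#'
#' @param table an `xlps_protein_table`.
#' @param cfg a [tier_config()].
#' @param proteins protein ids to consider (default all).
#' @return List with `assigned` (data.frame protein_id, tier, statistic,
#'   present_group for proteins that received a p-value) and `remainder`
#'   (protein ids passed on).
#' @export
tier1_anova <- function(table, cfg = tier_config(),
                        proteins = rownames(table$lfq)) {
  rows <- lapply(proteins, function(p) {
    gs <- .protein_group_split(table, p)
    if (gs$n_s >= cfg$min_values_per_group_for_anova &&
        gs$n_r >= cfg$min_values_per_group_for_anova) {
      pval <- .anova_p(gs$x_s, gs$x_r)
      data.frame(protein_id = p,
                 tier = if (pval < cfg$anova_p_cutoff) "anova" else "none",
                 statistic = pval, present_group = NA_character_,
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  assigned <- do.call(rbind, rows)
  if (is.null(assigned)) assigned <- .empty_tiers()
  list(assigned = assigned,
       remainder = setdiff(proteins, assigned$protein_id))
}

#' Tier 2: fold-change capture
#'
#' @inheritParams tier1_anova
#' @param proteins protein ids that did not receive a tier-1 p-value.
#' @return List with `assigned` and `remainder` as in [tier1_anova()];
#'   `statistic` is the sensitive-minus-resilient difference of group means
#'   of detected log2 LFQ.
#' @export
tier2_foldchange <- function(table, cfg = tier_config(), proteins) {
  rows <- lapply(proteins, function(p) {
    gs <- .protein_group_split(table, p)
    if (gs$n_s >= 1 && gs$n_r >= 1) {
      total <- gs$n_s + gs$n_r
      fc <- mean(gs$x_s) - mean(gs$x_r)
      tier <- if (total >= cfg$min_occurrences &&
                  abs(fc) >= cfg$log2fc_cutoff) "foldchange" else "none"
      data.frame(protein_id = p, tier = tier, statistic = fc,
                 present_group = NA_character_, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  })
  assigned <- do.call(rbind, rows)
  if (is.null(assigned)) assigned <- .empty_tiers()
  list(assigned = assigned,
       remainder = setdiff(proteins, assigned$protein_id))
}

#' Tier 3: presence/absence capture
#'
#' @inheritParams tier1_anova
#' @param proteins protein ids detected in at most one group.
#' @return data.frame of assignments (every remaining protein gets
#'   `presence` or `none`; `present_group` records the detected group).
#' @export
tier3_presence <- function(table, cfg = tier_config(), proteins) {
  rows <- lapply(proteins, function(p) {
    gs <- .protein_group_split(table, p)
    n_det <- gs$n_s + gs$n_r
    one_group <- (gs$n_s == 0) != (gs$n_r == 0)
    if (one_group && n_det >= cfg$min_presence_species) {
      data.frame(protein_id = p, tier = "presence", statistic = NA_real_,
                 present_group = if (gs$n_s > 0) "sensitive" else "resilient",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = p, tier = "none", statistic = NA_real_,
                 present_group = NA_character_, stringsAsFactors = FALSE)
    }
  })
  assigned <- do.call(rbind, rows)
  if (is.null(assigned)) assigned <- .empty_tiers()
  assigned
}

.empty_tiers <- function() {
  data.frame(protein_id = character(0), tier = character(0),
             statistic = numeric(0), present_group = character(0),
             stringsAsFactors = FALSE)
}

#' Run the full three-tier cascade
#'
#' Applies the tiers in order with strict precedence: a protein that could
#' be evaluated by an earlier tier is never passed to a later one, so every
#' protein receives exactly one assignment from {anova, foldchange,
#' presence, none}.
#'
#' @param table an `xlps_protein_table`.
#' @param cfg a [tier_config()].
#' @return List with `assignments` (data.frame in the table's protein order:
#'   protein_id, tier, statistic, present_group) and `counts` (named integer
#'   vector of captured proteins per tier plus `none` and
#'   `total_discriminating`).
#' @export
run_cascade <- function(table, cfg = tier_config()) {
  stopifnot(inherits(table, "xlps_protein_table"))
  proteins <- rownames(table$lfq)
  if (!length(proteins)) {
    return(list(assignments = .empty_tiers(),
                counts = c(anova = 0L, foldchange = 0L, presence = 0L,
                           none = 0L, total_discriminating = 0L)))
  }
  t1 <- tier1_anova(table, cfg, proteins)
  t2 <- tier2_foldchange(table, cfg, t1$remainder)
  t3 <- tier3_presence(table, cfg, t2$remainder)
  assignments <- rbind(t1$assigned, t2$assigned, t3)
  assignments <- assignments[match(proteins, assignments$protein_id), ,
                             drop = FALSE]
  rownames(assignments) <- NULL
  counts <- c(
    anova = sum(assignments$tier == "anova"),
    foldchange = sum(assignments$tier == "foldchange"),
    presence = sum(assignments$tier == "presence"),
    none = sum(assignments$tier == "none")
  )
  counts <- c(counts,
              total_discriminating = sum(counts[c("anova", "foldchange",
                                                  "presence")]))
  list(assignments = assignments, counts = counts)
}
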
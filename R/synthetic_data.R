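# Synthetic multi-species study generator.
#
# Emulates the ex vivo whole-blood LPS stimulation design: 4 resilient
# species (mouse, rat, rhesus, baboon) and 6 sensitive species (rabbit, pig,
# cow, sheep, chimpanzee, human), 4-5 individuals per species, paired
# stimulated/control samples at doses {0, 10, 100, 1000} ng/mL and times
# {2, 6, 24} h, per-species gene spaces linked to a shared human-ortholog
# universe by sampled m:n orthology topologies (with dropouts), log-normal
# TPM noise, and planted baseline, response and group-response-difference
# effects with known ground truth.

RESILIENT_SPECIES <- c("mouse", "rat", "rhesus", "baboon")
SENSITIVE_SPECIES <- c("rabbit", "pig", "cow", "sheep", "chimpanzee", "human")

#' Simulation configuration
#'
#' Defaults mirror the study design: 4 resilient + 6 sensitive species, 5
#' individuals each, the full dose-by-time grid, log-normal abundance noise
#' of 0.5 on the log2 scale, and an individual-level random intercept of sd
#' 0.3 shared across all of an individual's samples (making the paired
#' design strictly more informative than an unpaired one). Planted baseline
#' effects favour the sensitive group (`baseline_up_prob`) and planted
#' group-response differences favour stronger induction in the resilient
#' group (`group_diff_up_prob`), mirroring the directionality the screens
#' are asked to report. The dose effect saturates (factors 0.8/0.9/1.0 at
#' 10/100/1000 ng/mL) so escalation has a consistent but minimal effect, and
#' the response peaks at 6 h.
#'
#' @param n_resilient_species,n_sensitive_species numbers of species per
#'   group. With the default 4/6 the real species names are used.
#' @param individuals_per_species individuals (paired sample donors) per
#'   species.
#' @param n_human_orthologs size of the shared human-ortholog universe.
#' @param doses,times LPS doses (ng/mL; must include 0) and sampling times (h).
#' @param frac_baseline_de fraction of orthologs with a planted baseline
#'   group effect of `baseline_effect_log2` (log2 units).
#' @param baseline_effect_log2 planted baseline effect size.
#' @param baseline_up_prob probability a planted baseline effect is higher in
#'   the sensitive group.
#' @param frac_response_de fraction of orthologs with a planted LPS response
#'   (both groups) of `response_effect_log2` at full dose and peak time.
#' @param response_effect_log2 planted response size.
#' @param response_up_prob probability a planted response is an induction.
#' @param frac_group_response_diff fraction of orthologs whose response
#'   differs between groups by `group_response_diff_log2`.
#' @param group_response_diff_log2 planted between-group response difference.
#' @param group_diff_up_prob probability the resilient group is the stronger
#'   responder for a planted group-difference gene.
#' @param noise_sd_log2 per-sample log2 abundance noise sd.
#' @param individual_sd_log2 sd of the individual-level random intercept.
#' @param ortholog_topology_weights sampling weights over the orthology
#'   topologies `1:1`, `2:1`, `1:2`, `2:3` and `missing` (gene absent from
#'   the species' annotation).
#' @param pseudocount pseudocount used when mapping log2 signal to TPM
#'   (TPM = 2^value - pseudocount, clipped at 0).
#' @param n_proteins,protein_sd_log2 plasma proteome size and log2 LFQ noise.
#' @param n_tier_anova,n_tier_foldchange,n_tier_presence planted numbers of
#'   discriminating proteins per capture tier.
#' @param tier_anova_effect_log2 planted group shift for ANOVA-tier proteins.
#' @param tier_foldchange_effect_log2 planted group difference for
#'   fold-change-tier proteins (kept well above the 3.0 capture threshold).
#' @param protein_detect_prob background detection probability per cell.
#' @param seed integer seed; the seed fully determines all outputs.
#' @return A `xlps_sim_config` list.
#' @export
sim_config <- function(n_resilient_species = 4,
                       n_sensitive_species = 6,
                       individuals_per_species = 5,
                       n_human_orthologs = 1000,
                       doses = c(0, 10, 100, 1000),
                       times = c(2, 6, 24),
                       frac_baseline_de = 0.1,
                       baseline_effect_log2 = 1.5,
                       baseline_up_prob = 0.95,
                       frac_response_de = 0.1,
                       response_effect_log2 = 2,
                       response_up_prob = 0.9,
                       frac_group_response_diff = 0.05,
                       group_response_diff_log2 = 1.5,
                       group_diff_up_prob = 0.9,
                       noise_sd_log2 = 0.5,
                       individual_sd_log2 = 0.3,
                       ortholog_topology_weights = c("1:1" = 0.80, "2:1" = 0.06,
                                                     "1:2" = 0.06, "2:3" = 0.03,
                                                     "missing" = 0.05),
                       pseudocount = 1,
                       n_proteins = 300,
                       protein_sd_log2 = 1,
                       n_tier_anova = 20,
                       n_tier_foldchange = 20,
                       n_tier_presence = 20,
                       tier_anova_effect_log2 = 3,
                       tier_foldchange_effect_log2 = 6,
                       protein_detect_prob = 0.9,
                       seed = 1L) {
  fracs <- c(frac_baseline_de, frac_response_de, frac_group_response_diff)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must be in [0,1]", call. = FALSE)
  if (sum(fracs) > 1) {
    stop("planted fractions sum to more than 1; the planted sets are disjoint",
         call. = FALSE)
  }
  if (!0 %in% doses) stop("doses must include the 0 control", call. = FALSE)
  topo <- c("1:1", "2:1", "1:2", "2:3", "missing")
  if (!all(topo %in% names(ortholog_topology_weights))) {
    stop("ortholog_topology_weights must name ", paste(topo, collapse = ", "),
         call. = FALSE)
  }
  n_tiers <- n_tier_anova + n_tier_foldchange + n_tier_presence
  if (n_tiers > n_proteins) stop("more planted proteins than proteins", call. = FALSE)
  cfg <- list(
    n_resilient_species = n_resilient_species,
    n_sensitive_species = n_sensitive_species,
    individuals_per_species = individuals_per_species,
    n_human_orthologs = n_human_orthologs,
    doses = sort(doses), times = sort(times),
    frac_baseline_de = frac_baseline_de,
    baseline_effect_log2 = baseline_effect_log2,
    baseline_up_prob = baseline_up_prob,
    frac_response_de = frac_response_de,
    response_effect_log2 = response_effect_log2,
    response_up_prob = response_up_prob,
    frac_group_response_diff = frac_group_response_diff,
    group_response_diff_log2 = group_response_diff_log2,
    group_diff_up_prob = group_diff_up_prob,
    noise_sd_log2 = noise_sd_log2,
    individual_sd_log2 = individual_sd_log2,
    ortholog_topology_weights = ortholog_topology_weights[topo],
    pseudocount = pseudocount,
    n_proteins = n_proteins,
    protein_sd_log2 = protein_sd_log2,
    n_tier_anova = n_tier_anova,
    n_tier_foldchange = n_tier_foldchange,
    n_tier_presence = n_tier_presence,
    tier_anova_effect_log2 = tier_anova_effect_log2,
    tier_foldchange_effect_log2 = tier_foldchange_effect_log2,
    protein_detect_prob = protein_detect_prob,
    seed = as.integer(seed)
  )
  class(cfg) <- "xlps_sim_config"
  cfg
}

.sim_species_names <- function(cfg) {
  res <- if (cfg$n_resilient_species == length(RESILIENT_SPECIES)) {
    RESILIENT_SPECIES
  } else {
    sprintf("resilient%02d", seq_len(cfg$n_resilient_species))
  }
  sen <- if (cfg$n_sensitive_species == length(SENSITIVE_SPECIES)) {
    SENSITIVE_SPECIES
  } else {
    sprintf("sensitive%02d", seq_len(cfg$n_sensitive_species))
  }
  list(resilient = res, sensitive = sen)
}

# Saturating dose effect and peak-at-6h time effect on the planted response.
.dose_factor <- function(dose) {
  f <- c("10" = 0.8, "100" = 0.9, "1000" = 1.0)
  out <- f[as.character(dose)]
  out[is.na(out)] <- ifelse(dose[is.na(out)] > 0, 1.0, 0)
  unname(out)
}

.time_factor <- function(time) {
  f <- c("2" = 0.7, "6" = 1.0, "24" = 0.5)
  out <- f[as.character(time)]
  out[is.na(out)] <- 1.0
  unname(out)
}

# Partition the human universe into orthology components (gene families).
# The m:n family structure is shared across species, as gene families are;
# only annotation dropout is species-specific. Weights over the m:n types
# exclude "missing", which is applied per species downstream.
.sample_topology <- function(n_genes, weights) {
  types <- setdiff(names(weights), "missing")
  probs <- weights[types] / sum(weights[types])
  comps <- list()
  i <- 1L
  while (i <= n_genes) {
    type <- sample(types, 1L, prob = probs)
    need <- switch(type, "1:2" = 2L, "2:3" = 3L, 1L)
    if (i + need - 1L > n_genes) type <- "1:1"
    comp <- switch(type,
      "1:1" = list(h = i, m = 1L),
      "2:1" = list(h = i, m = 2L),
      "1:2" = list(h = c(i, i + 1L), m = 1L),
      "2:3" = list(h = c(i, i + 1L, i + 2L), m = 2L)
    )
    comps[[length(comps) + 1L]] <- comp
    i <- i + length(comp$h)
  }
  comps
}

#' Simulate a multi-species transcriptome study
#'
#' Generates, from one seed: a sample sheet over all species, individuals,
#' doses and times; per-species gene-by-sample TPM matrices in each species'
#' own gene space; per-species many-to-many ortholog maps to the shared
#' human universe; and the ground truth of planted effects. Baseline log2
#' abundance for gene g is Normal(mu_g, `noise_sd_log2`) around a gene-level
#' mean mu_g ~ Uniform(2, 10), plus an individual-level intercept shared
#' across that individual's samples. Planted baseline effects add the group
#' shift to every sample of the favoured group; planted responses add a
#' dose-saturating, time-modulated shift to stimulated samples. Species-gene
#' abundances are obtained by splitting each orthology component's human TPM
#' total across its m species genes with fixed random weights, so the
#' component-sum translation rule recovers the component totals exactly.
#'
#' @param cfg a [sim_config()].
#' @return List with `sheet` (sample sheet), `species_expr` (named list of
#'   species-gene x sample TPM matrices), `maps` (named list of
#'   `xlps_ortholog_map`), `human_universe`, and `truth` (list with
#'   `baseline` data.frame gene_id/sign, `response` gene_id/sign,
#'   `group_diff` gene_id/higher_group, plus `baseline_linked`,
#'   `response_linked` and `group_diff_linked`: genes that inherit a planted
#'   effect through membership in the same orthology family, hence genuinely
#'   carry signal in human space without being planted themselves).
#' @export
simulate_transcriptome <- function(cfg) {
  stopifnot(inherits(cfg, "xlps_sim_config"))
  set.seed(cfg$seed)
  sp <- .sim_species_names(cfg)
  species <- c(sp$resilient, sp$sensitive)
  group_of <- stats::setNames(
    c(rep("resilient", length(sp$resilient)),
      rep("sensitive", length(sp$sensitive))), species)
  n <- cfg$n_human_orthologs
  universe <- sprintf("HG%05d", seq_len(n))

  # disjoint planted sets
  n_b <- round(cfg$frac_baseline_de * n)
  n_r <- round(cfg$frac_response_de * n)
  n_d <- round(cfg$frac_group_response_diff * n)
  shuffled <- sample.int(n)
  idx_b <- shuffled[seq_len(n_b)]
  idx_r <- shuffled[n_b + seq_len(n_r)]
  idx_d <- shuffled[n_b + n_r + seq_len(n_d)]

  mu <- stats::runif(n, 2, 10)
  eff_base <- numeric(n)
  if (n_b) {
    sign_b <- ifelse(stats::runif(n_b) < cfg$baseline_up_prob, 1, -1)
    eff_base[idx_b] <- sign_b * cfg$baseline_effect_log2
  }
  eff_resp <- numeric(n)
  if (n_r) {
    sign_r <- ifelse(stats::runif(n_r) < cfg$response_up_prob, 1, -1)
    eff_resp[idx_r] <- sign_r * cfg$response_effect_log2
  }
  diff_group <- character(0)
  eff_diff <- numeric(n)
  if (n_d) {
    diff_group <- ifelse(stats::runif(n_d) < cfg$group_diff_up_prob,
                         "resilient", "sensitive")
    eff_diff[idx_d] <- cfg$group_response_diff_log2
  }

  combos <- expand.grid(dose = cfg$doses, time = cfg$times,
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$time, combos$dose), , drop = FALSE]

  # gene-family (m:n) structure shared across species; per-species dropout
  comps <- .sample_topology(n, cfg$ortholog_topology_weights)
  w_missing <- cfg$ortholog_topology_weights[["missing"]] /
    sum(cfg$ortholog_topology_weights)

  sheet_rows <- list()
  species_expr <- list()
  maps <- list()

  for (spc in species) {
    grp <- group_of[[spc]]
    inds <- sprintf("%s_i%d", spc, seq_len(cfg$individuals_per_species))
    a_ind <- stats::setNames(
      stats::rnorm(length(inds), 0, cfg$individual_sd_log2), inds)

    sample_meta <- do.call(rbind, lapply(inds, function(ind) {
      data.frame(sample_id = sprintf("%s_d%g_t%g", ind, combos$dose, combos$time),
                 species = spc, group = grp, individual = ind,
                 dose = combos$dose, time = combos$time,
                 stringsAsFactors = FALSE)
    }))
    sheet_rows[[spc]] <- sample_meta
    ns <- nrow(sample_meta)

    # human-space log2 signal for this species' samples
    base_shift <- if (grp == "sensitive") eff_base else numeric(n)
    stim_scale <- .dose_factor(sample_meta$dose) * .time_factor(sample_meta$time)
    x <- matrix(mu + base_shift, nrow = n, ncol = ns)
    x <- x + matrix(a_ind[sample_meta$individual], nrow = n, ncol = ns,
                    byrow = TRUE)
    resp_col <- eff_resp
    diff_col <- numeric(n)
    if (n_d) {
      mine <- diff_group == grp
      diff_col[idx_d[mine]] <- eff_diff[idx_d[mine]]
    }
    x <- x + outer(resp_col + diff_col, stim_scale)
    x <- x + matrix(stats::rnorm(n * ns, 0, cfg$noise_sd_log2), n, ns)
    tpm_h <- pmax(2^x - cfg$pseudocount, 0)
    dimnames(tpm_h) <- list(universe, sample_meta$sample_id)

    # species-gene space: shared families, species-specific annotation dropout
    keep_comp <- stats::runif(length(comps)) >= w_missing
    rel_sp <- character(0); rel_hu <- character(0)
    sg_rows <- list()
    counter <- 0L
    for (ci in which(keep_comp)) {
      comp <- comps[[ci]]
      counter_ids <- sprintf("%s_g%05d", spc, counter + seq_len(comp$m))
      counter <- counter + comp$m
      # complete bipartite relation within the component
      rel_sp <- c(rel_sp, rep(counter_ids, each = length(comp$h)))
      rel_hu <- c(rel_hu, rep(universe[comp$h], times = comp$m))
      total <- colSums(tpm_h[comp$h, , drop = FALSE])
      w <- if (comp$m > 1L) {
        raw <- stats::runif(comp$m, 0.2, 1)
        raw / sum(raw)
      } else 1
      sg_rows[[length(sg_rows) + 1L]] <- outer(w, total)
      names(sg_rows)[length(sg_rows)] <- paste(counter_ids, collapse = "\r")
    }
    expr <- do.call(rbind, sg_rows)
    rownames(expr) <- unlist(strsplit(names(sg_rows), "\r", fixed = TRUE))
    colnames(expr) <- sample_meta$sample_id
    species_expr[[spc]] <- expr
    maps[[spc]] <- ortholog_map(
      data.frame(species_gene_id = rel_sp, human_gene_id = rel_hu,
                 stringsAsFactors = FALSE), species = spc)
  }

  sheet <- sample_sheet(do.call(rbind, sheet_rows))
  # genes that receive a planted effect indirectly, through membership in the
  # same orthology family (the component-sum translation spreads a member's
  # abundance shift over all n human genes of its component)
  comp_of <- integer(n)
  for (ci in seq_along(comps)) comp_of[comps[[ci]]$h] <- ci
  linked <- function(idx) {
    if (!length(idx)) return(character(0))
    fam <- unlist(lapply(comps[unique(comp_of[idx])], function(cp) cp$h))
    universe[setdiff(fam, idx)]
  }
  truth <- list(
    baseline = data.frame(
      gene_id = universe[idx_b],
      sign = if (n_b) ifelse(eff_base[idx_b] > 0, 1, -1) else integer(0),
      stringsAsFactors = FALSE),
    response = data.frame(
      gene_id = universe[idx_r],
      sign = if (n_r) ifelse(eff_resp[idx_r] > 0, 1, -1) else integer(0),
      stringsAsFactors = FALSE),
    group_diff = data.frame(
      gene_id = universe[idx_d],
      higher_group = diff_group,
      stringsAsFactors = FALSE),
    baseline_linked = linked(idx_b),
    response_linked = linked(idx_r),
    group_diff_linked = linked(idx_d)
  )
  list(sheet = sheet, species_expr = species_expr, maps = maps,
       human_universe = universe, truth = truth, config = cfg)
}

#' Simulate a plasma proteome table with planted discriminating proteins
#'
#' Per-species log2 LFQ values are Normal(protein mean, `protein_sd_log2`)
#' around protein means ~ Uniform(18, 30). Planted ANOVA-tier proteins carry
#' a group shift detectable by a two-group ANOVA at p < 0.05; planted
#' fold-change-tier proteins carry a large group difference but are detected
#' in only one species of one group, so the ANOVA tier cannot evaluate them;
#' planted presence-tier proteins are detected in every species of exactly
#' one group and none of the other.
#'
#' @param cfg a [sim_config()].
#' @return List with `table` (an `xlps_protein_table`) and `truth`
#'   (data.frame protein_id/tier).
#' @export
simulate_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "xlps_sim_config"))
  set.seed(cfg$seed + 1L)
  sp <- .sim_species_names(cfg)
  species <- c(sp$resilient, sp$sensitive)
  groups <- stats::setNames(
    c(rep("resilient", length(sp$resilient)),
      rep("sensitive", length(sp$sensitive))), species)
  np <- cfg$n_proteins
  ids <- sprintf("PROT%04d", seq_len(np))
  shuffled <- sample.int(np)
  idx_a <- shuffled[seq_len(cfg$n_tier_anova)]
  idx_f <- shuffled[cfg$n_tier_anova + seq_len(cfg$n_tier_foldchange)]
  idx_p <- shuffled[cfg$n_tier_anova + cfg$n_tier_foldchange +
                      seq_len(cfg$n_tier_presence)]

  mu <- stats::runif(np, 18, 30)
  lfq <- matrix(stats::rnorm(np * length(species), mu, cfg$protein_sd_log2),
                nrow = np, ncol = length(species),
                dimnames = list(ids, species))
  detected <- matrix(stats::runif(np * length(species)) < cfg$protein_detect_prob,
                     nrow = np, ncol = length(species),
                     dimnames = list(ids, species))
  is_sens <- groups[species] == "sensitive"

  # ANOVA tier: group shift, fully detected so the tier-1 test is eligible
  if (length(idx_a)) {
    sgn <- ifelse(stats::runif(length(idx_a)) < 0.5, 1, -1)
    lfq[idx_a, is_sens] <- lfq[idx_a, is_sens] +
      sgn * cfg$tier_anova_effect_log2
    detected[idx_a, ] <- TRUE
  }
  # fold-change tier: one detected value in one group, >= 3 in the other, so
  # the ANOVA tier is ineligible but >= 4 occurrences support a fold change
  if (length(idx_f)) {
    sgn <- ifelse(stats::runif(length(idx_f)) < 0.5, 1, -1)
    for (k in seq_along(idx_f)) {
      p <- idx_f[k]
      lfq[p, is_sens] <- mu[p] + sgn[k] * cfg$tier_foldchange_effect_log2 / 2 +
        stats::rnorm(sum(is_sens), 0, cfg$protein_sd_log2)
      lfq[p, !is_sens] <- mu[p] - sgn[k] * cfg$tier_foldchange_effect_log2 / 2 +
        stats::rnorm(sum(!is_sens), 0, cfg$protein_sd_log2)
      lone_group <- if (k %% 2 == 0) is_sens else !is_sens
      det <- rep(FALSE, length(species))
      det[sample(which(lone_group), 1L)] <- TRUE
      det[which(!lone_group)] <- TRUE
      detected[p, ] <- det
    }
  }
  # presence tier: detected in all species of exactly one group
  if (length(idx_p)) {
    for (k in seq_along(idx_p)) {
      p <- idx_p[k]
      present_sens <- k %% 2 == 1
      detected[p, ] <- if (present_sens) is_sens else !is_sens
    }
  }
  lfq[!detected] <- NA_real_
  truth <- data.frame(
    protein_id = ids[c(idx_a, idx_f, idx_p)],
    tier = c(rep("anova", length(idx_a)),
             rep("foldchange", length(idx_f)),
             rep("presence", length(idx_p))),
    stringsAsFactors = FALSE)
  list(table = protein_table(lfq, groups = groups), truth = truth,
       config = cfg)
}

#' Write a simulated transcriptome study to a directory
#'
#' Emits `sample_sheet.tsv`, `human_universe.txt`, per-species
#' `expr_<species>.tsv` (species genes x samples, TPM) and
#' `orthologs_<species>.tsv`, plus `ground_truth.tsv`. Output bytes are a
#' deterministic function of the configuration seed.
#'
#' @param sim result of [simulate_transcriptome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_transcriptome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(as.data.frame(sim$sheet), file.path(dir, "sample_sheet.tsv"))
  writeLines(sim$human_universe, file.path(dir, "human_universe.txt"))
  for (spc in names(sim$species_expr)) {
    .write_matrix_tsv(sim$species_expr[[spc]],
                      file.path(dir, sprintf("expr_%s.tsv", spc)),
                      id_col = "gene_id")
    .write_tsv(sim$maps[[spc]]$relations,
               file.path(dir, sprintf("orthologs_%s.tsv", spc)))
  }
  truth <- rbind(
    if (nrow(sim$truth$baseline)) data.frame(
      gene_id = sim$truth$baseline$gene_id, kind = "baseline",
      detail = as.character(sim$truth$baseline$sign), stringsAsFactors = FALSE),
    if (nrow(sim$truth$response)) data.frame(
      gene_id = sim$truth$response$gene_id, kind = "response",
      detail = as.character(sim$truth$response$sign), stringsAsFactors = FALSE),
    if (nrow(sim$truth$group_diff)) data.frame(
      gene_id = sim$truth$group_diff$gene_id, kind = "group_diff",
      detail = sim$truth$group_diff$higher_group, stringsAsFactors = FALSE)
  )
  if (is.null(truth)) {
    truth <- data.frame(gene_id = character(0), kind = character(0),
                        detail = character(0), stringsAsFactors = FALSE)
  }
  .write_tsv(truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Write a simulated proteome to a directory
#'
#' Emits `proteome_lfq.tsv` (proteins x species, log2 LFQ, NA = not
#' detected), `species_groups.tsv` and `proteome_truth.tsv`.
#'
#' @param sim result of [simulate_proteome()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_proteome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  .write_matrix_tsv(sim$table$lfq, file.path(dir, "proteome_lfq.tsv"),
                    id_col = "protein_id")
  .write_tsv(data.frame(species = names(sim$table$groups),
                        group = unname(sim$table$groups),
                        stringsAsFactors = FALSE),
             file.path(dir, "species_groups.tsv"))
  .write_tsv(sim$truth, file.path(dir, "proteome_truth.tsv"))
  invisible(dir)
}
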
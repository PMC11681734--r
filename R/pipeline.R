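# End-to-end pipeline: simulate (or load) a multi-species study, translate
# every species into human-ortholog space, run the baseline group test and
# divergence screen, the per-species and between-group response analyses,
# and the proteomics cascade, writing every result as TSV. All outputs are
# a deterministic function of the inputs.

#' Translate and merge all species of a study into human-ortholog space
#'
#' @param species_expr named list of species-gene x sample TPM matrices.
#' @param maps named list of `xlps_ortholog_map`, same names.
#' @param human_universe ordered human gene ids.
#' @param sheet sample sheet covering all samples.
#' @return An `xlps_expr` (TPM scale) over all samples.
#' @export
translate_study <- function(species_expr, maps, human_universe, sheet) {
  stopifnot(identical(sort(names(species_expr)), sort(names(maps))))
  mats <- lapply(names(species_expr), function(spc) {
    translate_expression(species_expr[[spc]], maps[[spc]], human_universe)
  })
  merge_species(mats, sheet)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulates transcriptome and proteome data from `cfg`, then runs every
#' analysis stage and writes the inputs and results under `out_dir`:
#' simulated inputs, the merged human-space TPM matrix, the baseline
#' differential-expression table, the baseline complete-separation screen
#' and its top-k list, the per-species and between-group response tables at
#' the configured dose, the response separation screen, and the proteomics
#' tier assignments. Output bytes depend only on the configuration (seed
#' included).
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param de_cfg a [de_config()].
#' @param resp_cfg a [response_config()].
#' @param tiers a [tier_config()].
#' @param response_time time point (h) for the response analyses; default 6,
#'   where the response peaks.
#' @param top_k size of the reported top gene lists. Default 50.
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir,
                         de_cfg = de_config(), resp_cfg = response_config(),
                         tiers = tier_config(), response_time = 6,
                         top_k = 50) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_transcriptome(cfg)
  write_transcriptome(sim, file.path(out_dir, "inputs"))
  psim <- simulate_proteome(cfg)
  write_proteome(psim, file.path(out_dir, "inputs"))

  human_tpm <- translate_study(sim$species_expr, sim$maps,
                               sim$human_universe, sim$sheet)
  .write_matrix_tsv(round(human_tpm$values, 6),
                    file.path(out_dir, "human_tpm.tsv"))

  # baseline group test on quantile-normalized log2 TPM
  human_log2 <- log2_transform(human_tpm, pseudocount = de_cfg$pseudocount)
  base <- baseline_subset(human_log2, sim$sheet)
  base_norm <- quantile_normalize(base$expr)
  baseline_de <- fit_blocked_moderated_test(base_norm, base$sheet, de_cfg)
  write_results_table(baseline_de, file.path(out_dir, "baseline_de.tsv"),
                      thresholds = list(fold = de_cfg$fold_cutoff,
                                        fdr = de_cfg$fdr_cutoff))

  # baseline divergence screen on per-individual log2 expression
  labels <- base$sheet$group[match(colnames(base_norm$values),
                                   base$sheet$sample_id)]
  base_screen <- complete_separation_screen(base_norm$values, labels,
                                            missing = base_norm$missing)
  write_results_table(base_screen, file.path(out_dir, "baseline_screen.tsv"),
                      thresholds = list(tolerance = 1))
  base_top <- top_k_by_difference(base_screen, k = top_k)
  writeLines(base_top, file.path(out_dir, "baseline_top_genes.txt"))

  # response analyses
  records <- paired_fold_changes(human_tpm, sim$sheet, resp_cfg,
                                 time = response_time)
  species_de <- per_species_de(records, resp_cfg)
  write_results_table(species_de, file.path(out_dir, "response_per_species.tsv"),
                      thresholds = list(dose = resp_cfg$dose,
                                        time = response_time,
                                        fold = resp_cfg$per_species_fold_cutoff,
                                        fdr = resp_cfg$fdr_cutoff))
  group_de <- group_response_difference(records, resp_cfg)
  write_results_table(group_de, file.path(out_dir, "response_group_diff.tsv"),
                      thresholds = list(dose = resp_cfg$dose,
                                        time = response_time,
                                        fold = resp_cfg$group_diff_fold_cutoff,
                                        fdr = resp_cfg$fdr_cutoff))
  fm <- fold_change_matrix(records)
  resp_screen <- complete_separation_screen(
    fm$matrix, fm$labels$group[match(colnames(fm$matrix),
                                     fm$labels$individual)])
  write_results_table(resp_screen, file.path(out_dir, "response_screen.tsv"),
                      thresholds = list(tolerance = 1))
  resp_top <- top_k_by_difference(resp_screen, de = group_de, k = 10,
                                  require_significant = TRUE,
                                  fdr_cutoff = resp_cfg$fdr_cutoff)
  writeLines(resp_top, file.path(out_dir, "response_top_genes.txt"))

  # proteomics cascade
  cascade <- run_cascade(psim$table, tiers)
  write_results_table(cascade$assignments,
                      file.path(out_dir, "protein_tiers.tsv"),
                      thresholds = list(anova_p = tiers$anova_p_cutoff,
                                        log2fc = tiers$log2fc_cutoff,
                                        min_occurrences = tiers$min_occurrences,
                                        min_presence = tiers$min_presence_species))

  invisible(list(sim = sim, proteome = psim, human_tpm = human_tpm,
                 baseline_de = baseline_de, baseline_screen = base_screen,
                 baseline_top = base_top, records = records,
                 species_de = species_de, group_de = group_de,
                 response_screen = resp_screen, response_top = resp_top,
                 cascade = cascade))
}
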
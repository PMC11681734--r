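# Translation of per-species gene abundances into human-ortholog space.
#
# Orthology between a species and human is a many-to-many relation. Within a
# connected component of that relation holding m species genes and n human
# genes (m >= 0, n >= 1), the abundance of each human ortholog is taken to be
# the sum of the m species-gene abundances divided by n. Components are the
# only partition under which "the m genes" and "the n orthologs" are
# simultaneously well defined; a per-human-gene reading would double-count
# species genes shared between human orthologs.

#' Construct an ortholog map for one species
#'
#' @param relations data.frame with columns `species_gene_id` and
#'   `human_gene_id`; one row per orthology relation pair.
#' @param species species name the map belongs to.
#' @return An `xlps_ortholog_map`.
#' @export
ortholog_map <- function(relations, species) {
  required <- c("species_gene_id", "human_gene_id")
  if (!all(required %in% names(relations))) {
    stop("ortholog map needs columns species_gene_id, human_gene_id",
         call. = FALSE)
  }
  relations <- data.frame(
    species_gene_id = as.character(relations$species_gene_id),
    human_gene_id = as.character(relations$human_gene_id),
    stringsAsFactors = FALSE
  )
  if (anyNA(relations)) stop("NA in ortholog map", call. = FALSE)
  if (anyDuplicated(paste(relations$species_gene_id,
                          relations$human_gene_id, sep = "\r"))) {
    stop("duplicate relation pair in ortholog map", call. = FALSE)
  }
  structure(list(relations = relations, species = as.character(species)),
            class = "xlps_ortholog_map")
}

#' Read a one-species ortholog map from TSV
#' @param path TSV with columns `species_gene_id`, `human_gene_id`.
#' @param species species name.
#' @return An `xlps_ortholog_map`.
#' @export
read_ortholog_map <- function(path, species) {
  ortholog_map(.read_tsv(path, colClasses = "character"), species = species)
}

#' Connected components of the orthology relation
#'
#' Partitions the bipartite species-gene/human-gene relation graph into its
#' connected components via union-find. Every relation pair lands in exactly
#' one component.
#'
#' @param map an `xlps_ortholog_map`.
#' @return List of components, each a list with `species_genes` and
#'   `human_genes` (character vectors).
#' @export
build_components <- function(map) {
  stopifnot(inherits(map, "xlps_ortholog_map"))
  rel <- map$relations
  if (!nrow(rel)) return(list())
  # distinct node namespaces: species genes prefixed s:, human genes h:
  sp <- paste0("s:", rel$species_gene_id)
  hu <- paste0("h:", rel$human_gene_id)
  nodes <- unique(c(sp, hu))
  parent <- seq_along(nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)

  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) {
      nxt <- parent[i]
      parent[i] <<- root
      i <- nxt
    }
    root
  }
  for (k in seq_len(nrow(rel))) {
    a <- find(idx[[sp[k]]])
    b <- find(idx[[hu[k]]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp_ids <- unique(roots)
  lapply(comp_ids, function(r) {
    members <- nodes[roots == r]
    list(
      species_genes = sort(substring(members[startsWith(members, "s:")], 3)),
      human_genes = sort(substring(members[startsWith(members, "h:")], 3))
    )
  })
}

#' Translate one species' expression into human-ortholog space
#'
#' For each connected component of the orthology relation, the component's
#' total TPM over its species genes is redistributed equally over its n human
#' genes (sum divided by n), per sample. Human genes in `human_universe` that
#' belong to no component for this species are marked missing. Species genes
#' present in the map but absent from the quantification are treated as
#' abundance 0 (with a warning), since annotation and quantification gene
#' sets rarely coincide exactly.
#'
#' @param expr_species numeric matrix, species genes x samples, TPM scale.
#' @param map an `xlps_ortholog_map` for the same species.
#' @param human_universe ordered character vector of human gene ids defining
#'   the output row space.
#' @return An `xlps_expr` in human space (TPM scale) for this species'
#'   samples.
#' @export
translate_expression <- function(expr_species, map, human_universe) {
  stopifnot(is.matrix(expr_species), is.numeric(expr_species))
  if (any(expr_species < 0, na.rm = TRUE)) {
    stop("negative TPM in species expression", call. = FALSE)
  }
  comps <- build_components(map)
  n_samples <- ncol(expr_species)
  out <- matrix(NA_real_, nrow = length(human_universe), ncol = n_samples,
                dimnames = list(human_universe, colnames(expr_species)))
  miss <- matrix(TRUE, nrow = length(human_universe), ncol = n_samples,
                 dimnames = dimnames(out))
  seen_human <- character(0)
  unquantified <- character(0)
  for (comp in comps) {
    hg <- intersect(comp$human_genes, human_universe)
    dup <- intersect(comp$human_genes, seen_human)
    if (length(dup)) {
      stop("human gene in two components: ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    seen_human <- c(seen_human, comp$human_genes)
    if (!length(hg)) next
    sg <- comp$species_genes
    present <- sg[sg %in% rownames(expr_species)]
    unquantified <- c(unquantified, setdiff(sg, present))
    total <- if (length(present)) {
      colSums(expr_species[present, , drop = FALSE])
    } else {
      numeric(n_samples)
    }
    share <- total / length(comp$human_genes)
    out[hg, ] <- matrix(share, nrow = length(hg), ncol = n_samples,
                        byrow = TRUE)
    miss[hg, ] <- FALSE
  }
  if (length(unquantified)) {
    warning(length(unique(unquantified)),
            " mapped species gene(s) absent from quantification; treated as 0",
            call. = FALSE)
  }
  expression_matrix(out, missing = miss, scale = "tpm")
}

#' Merge per-species human-space matrices into one expression matrix
#'
#' Column-concatenates human-space matrices for several species, preserving
#' each species' missingness mask, and orders columns to follow the sample
#' sheet.
#'
#' @param mats list of `xlps_expr` objects sharing the same human gene order.
#' @param sheet an `xlps_sample_sheet` covering all samples.
#' @return One `xlps_expr` over all samples.
#' @export
merge_species <- function(mats, sheet) {
  stopifnot(length(mats) >= 1)
  universe <- rownames(mats[[1]]$values)
  for (m in mats) {
    stopifnot(inherits(m, "xlps_expr"))
    if (!identical(rownames(m$values), universe)) {
      stop("matrices do not share the same human gene universe order",
           call. = FALSE)
    }
    if (m$scale != mats[[1]]$scale) stop("mixed scales in merge", call. = FALSE)
  }
  all_samples <- unlist(lapply(mats, function(m) colnames(m$values)))
  if (anyDuplicated(all_samples)) {
    stop("duplicated sample id across species: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "),
         call. = FALSE)
  }
  values <- do.call(cbind, lapply(mats, function(m) m$values))
  missing <- do.call(cbind, lapply(mats, function(m) m$missing))
  keep <- sheet$sample_id[sheet$sample_id %in% colnames(values)]
  values <- values[, keep, drop = FALSE]
  missing <- missing[, keep, drop = FALSE]
  expression_matrix(values, missing = missing, scale = mats[[1]]$scale)
}
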
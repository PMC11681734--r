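# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# --- ortholog translation oracle ------------------------------------------

# Connected components by repeated merging of relation pairs until fixpoint.
oracle_components <- function(relations) {
  sets <- lapply(seq_len(nrow(relations)), function(i) {
    list(s = relations$species_gene_id[i], h = relations$human_gene_id[i])
  })
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(sets)) {
      j <- i + 1
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]]$s, sets[[j]]$s)) ||
            length(intersect(sets[[i]]$h, sets[[j]]$h))) {
          sets[[i]] <- list(s = union(sets[[i]]$s, sets[[j]]$s),
                            h = union(sets[[i]]$h, sets[[j]]$h))
          sets[[j]] <- NULL
          merged <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
    if (!merged) break
  }
  lapply(sets, function(x) list(species_genes = sort(x$s),
                                human_genes = sort(x$h)))
}

# Apply the sum/n redistribution rule directly from oracle components.
oracle_translate <- function(expr, relations, universe) {
  comps <- oracle_components(relations)
  out <- matrix(NA_real_, length(universe), ncol(expr),
                dimnames = list(universe, colnames(expr)))
  for (cp in comps) {
    present <- intersect(cp$species_genes, rownames(expr))
    total <- if (length(present)) colSums(expr[present, , drop = FALSE]) else
      numeric(ncol(expr))
    for (h in intersect(cp$human_genes, universe)) {
      out[h, ] <- total / length(cp$human_genes)
    }
  }
  out
}

random_ortholog_instance <- function(n_species_genes = 12, n_human_genes = 10,
                                     n_relations = 15, n_samples = 3) {
  sg <- sprintf("sg%02d", seq_len(n_species_genes))
  hg <- sprintf("hg%02d", seq_len(n_human_genes))
  rel <- unique(data.frame(
    species_gene_id = sample(sg, n_relations, replace = TRUE),
    human_gene_id = sample(hg, n_relations, replace = TRUE),
    stringsAsFactors = FALSE))
  expr <- matrix(round(stats::runif(n_species_genes * n_samples, 0, 100), 3),
                 n_species_genes, n_samples,
                 dimnames = list(sg, sprintf("s%d", seq_len(n_samples))))
  list(relations = rel, expr = expr, universe = hg)
}

# --- complete-separation oracle -------------------------------------------

# Checks every cross-group pair of values explicitly; tolerance rule applied
# to whichever class has the larger mean.
oracle_separation <- function(values, labels, missing = is.na(values),
                              tolerance = 1) {
  v <- values
  v[missing] <- NA
  t(vapply(seq_len(nrow(v)), function(g) {
    xs <- v[g, labels == "sensitive"]
    xr <- v[g, labels == "resilient"]
    ms <- sum(is.na(xs)); mr <- sum(is.na(xr))
    xs <- xs[!is.na(xs)]; xr <- xr[!is.na(xr)]
    if (!length(xs) || !length(xr) || mean(xs) == mean(xr)) {
      return(c(sep = FALSE, higher_s = NA))
    }
    if (mean(xs) > mean(xr)) {
      hi <- xs; lo <- xr; mh <- ms; ml <- mr; higher_s <- TRUE
    } else {
      hi <- xr; lo <- xs; mh <- mr; ml <- ms; higher_s <- FALSE
    }
    all_pairs <- all(outer(hi, lo, ">"))
    c(sep = all_pairs && mh <= tolerance && ml == 0, higher_s = higher_s)
  }, c(sep = FALSE, higher_s = NA)))
}

# --- proteomics cascade oracle --------------------------------------------

# Evaluates the three rules independently, then applies precedence.
oracle_cascade <- function(table, cfg) {
  sens <- table$groups == "sensitive"
  vapply(rownames(table$lfq), function(p) {
    det <- table$detected[p, ]
    x <- table$lfq[p, ]
    xs <- x[det & sens]; xr <- x[det & !sens]
    # rule 1 applicability
    if (length(xs) >= cfg$min_values_per_group_for_anova &&
        length(xr) >= cfg$min_values_per_group_for_anova) {
      pv <- tryCatch(stats::t.test(xs, xr, var.equal = TRUE)$p.value,
                     error = function(e) NA_real_)
      if (is.na(pv)) {  # zero variance
        pv <- if (mean(xs) != mean(xr)) 0 else 1
      }
      return(if (pv < cfg$anova_p_cutoff) "anova" else "none")
    }
    # rule 2
    if (length(xs) >= 1 && length(xr) >= 1) {
      if (length(xs) + length(xr) >= cfg$min_occurrences &&
          abs(mean(xs) - mean(xr)) >= cfg$log2fc_cutoff) {
        return("foldchange")
      }
      return("none")
    }
    # rule 3
    n_det <- length(xs) + length(xr)
    if (n_det >= cfg$min_presence_species) "presence" else "none"
  }, character(1))
}

random_protein_table <- function(n_proteins = 40, missing_prob = 0.35) {
  species <- c("mouse", "rat", "rhesus", "baboon",
               "rabbit", "pig", "cow", "sheep", "chimpanzee", "human")
  groups <- stats::setNames(c(rep("resilient", 4), rep("sensitive", 6)),
                            species)
  lfq <- matrix(stats::rnorm(n_proteins * 10, 22, 3), n_proteins, 10,
                dimnames = list(sprintf("P%03d", seq_len(n_proteins)), species))
  lfq[stats::runif(length(lfq)) < missing_prob] <- NA
  protein_table(lfq, groups = groups)
}

# --- small design fixtures ------------------------------------------------

tiny_sheet <- function() {
  sample_sheet(data.frame(
    sample_id = c("m1_0", "m1_10", "h1_0", "h1_10"),
    species = c("mouse", "mouse", "human", "human"),
    group = c("resilient", "resilient", "sensitive", "sensitive"),
    individual = c("m1", "m1", "h1", "h1"),
    dose = c(0, 10, 0, 10),
    time = 2, stringsAsFactors = FALSE))
}

# balanced two-group baseline design: k species per group, m individuals each
baseline_design <- function(k = 3, m = 4) {
  species <- c(sprintf("res%d", seq_len(k)), sprintf("sen%d", seq_len(k)))
  group <- rep(c("resilient", "sensitive"), each = k)
  rows <- do.call(rbind, lapply(seq_along(species), function(i) {
    data.frame(
      sample_id = sprintf("%s_i%d_b", species[i], seq_len(m)),
      species = species[i], group = group[i],
      individual = sprintf("%s_i%d", species[i], seq_len(m)),
      dose = 0, time = 2, stringsAsFactors = FALSE)
  }))
  sample_sheet(rows)
}

random_log2_expr <- function(sheet, n_genes = 50, group_effect = 0,
                             genes_with_effect = integer(0)) {
  V <- matrix(stats::rnorm(n_genes * nrow(sheet), 6, 1), n_genes, nrow(sheet),
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sheet$sample_id))
  if (length(genes_with_effect)) {
    sens <- sheet$group == "sensitive"
    V[genes_with_effect, sens] <- V[genes_with_effect, sens] + group_effect
  }
  expression_matrix(V, scale = "log2")
}
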
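#' Configuration for the synthetic-data generator
#'
#' The generator emits data with exactly the statistical structure the
#' downstream stages assume: replicate log2 signals are Normal around
#' per-condition means, gene-specific residual precisions 1/sigma^2 are
#' Gamma(shape `rvm_a`, scale `rvm_b`) (the randomized-variance-model prior),
#' differential genes follow integer model-profile trajectories scaled by
#' `effect_scale` log2 units per profile step, and signals are emitted on the
#' linear scale as 2^x. Defaults describe a desk-scale version of a
#' three-condition CO2-series chip experiment with triplicate biology.
#'
#' @param n_genes number of probes.
#' @param conditions ordered condition labels; first is the reference.
#' @param reps_per_condition biological replicates per condition (>= 2).
#' @param rvm_a,rvm_b gamma shape/scale of the precision prior (mean precision
#'   `rvm_a * rvm_b`).
#' @param de_fraction fraction of genes given a planted profile.
#' @param profile_mix named numeric vector of weights over planted profile
#'   ids (names matching [default_profiles()] ids); default: the five series
#'   shapes most represented in a CO2-series experiment, weighted by their
#'   observed prevalence.
#' @param effect_scale log2 units per unit profile step.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 expression.
#' @param seed integer master seed; sub-generators use fixed offsets from it.
#' @param n_categories,category_size annotation-collection dimensions.
#' @param n_planted_categories categories built with enrichment for DE genes.
#' @param planted_enrichment_odds sampling odds of a DE gene vs a background
#'   gene inside planted categories (1 = null).
#' @param interaction_density probability that an ordered DE-gene pair gets a
#'   random catalog relation.
#' @param plant_bridge insert a two-cluster interaction motif whose clusters
#'   communicate only through one bridge gene (a known high-betweenness node).
#' @param ct_noise_sd technical Ct noise (cycles) in the qPCR generator.
#' @param qpcr_bio_reps,qpcr_tech_reps qPCR replication structure.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_genes = 5000,
                         conditions = c("T0", "T1", "T2"),
                         reps_per_condition = 3,
                         rvm_a = 3, rvm_b = 2,
                         de_fraction = 0.1,
                         profile_mix = NULL,
                         effect_scale = 2,
                         baseline_log2_mean = 8,
                         baseline_log2_sd = 2,
                         seed = 1,
                         n_categories = 50,
                         category_size = 50,
                         n_planted_categories = 5,
                         planted_enrichment_odds = 20,
                         interaction_density = 0.005,
                         plant_bridge = TRUE,
                         ct_noise_sd = 0.1,
                         qpcr_bio_reps = 3,
                         qpcr_tech_reps = 3) {
  if (is.null(profile_mix)) {
    # series shapes with prevalence weights typical of a three-point CO2 series
    profile_mix <- c("12" = 864, "16" = 531, "10" = 499, "6" = 498, "5" = 440)
    profile_mix <- profile_mix / sum(profile_mix)
  }
  cfg <- list(
    n_genes = as.integer(n_genes), conditions = as.character(conditions),
    reps_per_condition = as.integer(reps_per_condition),
    rvm_a = rvm_a, rvm_b = rvm_b, de_fraction = de_fraction,
    profile_mix = profile_mix, effect_scale = effect_scale,
    baseline_log2_mean = baseline_log2_mean, baseline_log2_sd = baseline_log2_sd,
    seed = as.integer(seed), n_categories = as.integer(n_categories),
    category_size = as.integer(category_size),
    n_planted_categories = as.integer(n_planted_categories),
    planted_enrichment_odds = planted_enrichment_odds,
    interaction_density = interaction_density, plant_bridge = isTRUE(plant_bridge),
    ct_noise_sd = ct_noise_sd, qpcr_bio_reps = as.integer(qpcr_bio_reps),
    qpcr_tech_reps = as.integer(qpcr_tech_reps))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 1) abort("n_genes must be positive.")
  if (length(cfg$conditions) < 2) abort("need >= 2 conditions.")
  if (cfg$reps_per_condition < 2) abort("reps_per_condition must be >= 2 (residual variance must be estimable).")
  if (cfg$rvm_a <= 0 || cfg$rvm_b <= 0) abort("rvm_a and rvm_b must be > 0.")
  if (cfg$de_fraction < 0 || cfg$de_fraction > 1) abort("de_fraction must be in [0, 1].")
  if (abs(sum(cfg$profile_mix) - 1) > 1e-8) abort("profile_mix weights must sum to 1.")
  if (cfg$effect_scale <= 0) abort("effect_scale must be > 0.")
  if (cfg$interaction_density < 0 || cfg$interaction_density > 1) {
    abort("interaction_density must be in [0, 1].")
  }
  invisible(cfg)
}

# fixed per-generator offsets from the master seed keep the three generators
# reproducible yet decoupled
synth_seed <- function(cfg, stream) {
  offset <- c(expression = 0L, annotations = 1000003L, qpcr = 2000003L)[[stream]]
  (cfg$seed + offset) %% .Machine$integer.max
}

#' Generate a synthetic expression matrix with ground truth
#'
#' Per-gene residual precision is drawn from Gamma(`rvm_a`, scale `rvm_b`);
#' replicate log2 signals are Normal(condition mean, sigma^2); differential
#' genes get condition means equal to baseline + `effect_scale` x profile
#' shape; signals are exponentiated to the positive linear scale.
#'
#' @param config a [synth_config()].
#' @param profiles model-profile catalog indexed by `profile_mix` names;
#'   defaults to [default_profiles()].
#' @return List with `matrix` (an [expr_matrix()]) and `truth` (list holding a
#'   per-gene tibble `genes` with is_de/profile/sigma2, the latent
#'   `log2_means` matrix, and the config).
#' @export
generate_expression <- function(config = synth_config(), profiles = default_profiles()) {
  validate_synth_config(config)
  set.seed(synth_seed(config, "expression"))
  n <- config$n_genes
  k <- length(config$conditions)
  reps <- config$reps_per_condition
  gene_ids <- sprintf("g%05d", seq_len(n))

  n_de <- round(n * config$de_fraction)
  is_de <- rep(FALSE, n)
  if (n_de > 0) is_de[sample.int(n, n_de)] <- TRUE

  shape_of <- function(pid) {
    row <- profiles[profiles$profile == as.integer(pid), ]
    if (nrow(row) != 1) abort(paste0("profile_mix references unknown profile id ", pid))
    row$shape[[1]]
  }
  mix_ids <- names(config$profile_mix)
  shapes <- vapply(mix_ids, shape_of, numeric(k))  # k x n_profiles

  profile_id <- rep(NA_integer_, n)
  if (n_de > 0) {
    profile_id[is_de] <- as.integer(mix_ids[
      sample.int(length(mix_ids), n_de, replace = TRUE, prob = config$profile_mix)])
  }

  precision <- rgamma(n, shape = config$rvm_a, scale = config$rvm_b)
  sigma2 <- 1 / precision
  baseline <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)

  log2_means <- matrix(baseline, n, k)
  if (n_de > 0) {
    idx <- match(as.character(profile_id[is_de]), mix_ids)
    log2_means[is_de, ] <- log2_means[is_de, , drop = FALSE] +
      config$effect_scale * t(shapes[, idx, drop = FALSE])
  }
  colnames(log2_means) <- config$conditions
  rownames(log2_means) <- gene_ids

  sample_sheet <- tidyr::expand_grid(condition = config$conditions,
                                     replicate = seq_len(reps)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$condition, .data$replicate)) |>
    dplyr::select("sample_id", "condition", "replicate")

  mean_per_sample <- log2_means[, sample_sheet$condition, drop = FALSE]
  noise <- matrix(rnorm(n * k * reps, 0, 1), n, k * reps) * sqrt(sigma2)
  log2_signals <- mean_per_sample + noise
  signals <- 2^log2_signals
  dimnames(signals) <- list(gene_ids, sample_sheet$sample_id)

  truth <- list(
    genes = tibble::tibble(gene = gene_ids, is_de = is_de,
                           profile = profile_id, sigma2 = sigma2),
    log2_means = log2_means,
    config = config)
  list(matrix = expr_matrix(signals, sample_sheet), truth = truth)
}

#' Generate annotations and an interaction catalog matching a synthetic truth
#'
#' Planted categories sample DE genes at `planted_enrichment_odds` times the
#' background rate; with odds 1 the collection is null. The interaction
#' catalog covers random ordered DE-gene pairs at `interaction_density` and,
#' when `plant_bridge` is on, inserts a two-cluster motif drawn from one
#' planted profile whose halves communicate only through a single bridge gene.
#'
#' @param truth truth list from [generate_expression()].
#' @param config the same [synth_config()].
#' @return List with `annotations` (an `annotation_set`), `catalog`
#'   (source/relation/target tibble), `category_truth` (tibble of category,
#'   planted flag) and `bridge_gene` (id or NA).
#' @export
generate_annotations <- function(truth, config = truth$config) {
  validate_synth_config(config)
  set.seed(synth_seed(config, "annotations"))
  genes <- truth$genes$gene
  de_genes <- genes[truth$genes$is_de]
  n_cat <- config$n_categories
  planted <- seq_len(min(config$n_planted_categories, n_cat))
  cat_ids <- sprintf("CAT%03d", seq_len(n_cat))

  weights_planted <- ifelse(truth$genes$is_de, config$planted_enrichment_odds, 1)
  categories <- purrr::map(seq_len(n_cat), function(i) {
    w <- if (i %in% planted) weights_planted else rep(1, length(genes))
    sample(genes, min(config$category_size, length(genes)), prob = w)
  })
  ann <- annotation_set(
    tibble::tibble(category = cat_ids,
                   description = ifelse(seq_len(n_cat) %in% planted,
                                        "planted enriched category",
                                        "background category"),
                   genes = categories),
    namespace = "synthetic")

  relation_types <- c("activation", "inhibition", "phosphorylation", "expression")
  random_within <- function(pool) {
    if (length(pool) < 2 || config$interaction_density <= 0) return(NULL)
    pairs <- t(utils::combn(pool, 2))
    keep <- runif(nrow(pairs)) < config$interaction_density
    if (!any(keep)) return(NULL)
    pairs <- pairs[keep, , drop = FALSE]
    flip <- runif(nrow(pairs)) < 0.5
    tibble::tibble(
      source = ifelse(flip, pairs[, 2], pairs[, 1]),
      relation = sample(relation_types, nrow(pairs), replace = TRUE),
      target = ifelse(flip, pairs[, 1], pairs[, 2]))
  }

  bridge_gene <- NA_character_
  if (config$plant_bridge && length(de_genes) >= 9) {
    # The bridge is planted as the cut vertex between two communities, each
    # built from one of the two best-populated planted profiles so that every
    # motif edge joins strongly (anti-)co-expressed genes and survives the
    # downstream |r| filter. Each community is an anchor clique plus members
    # wired to two anchors; the communities talk only through the bridge,
    # which therefore carries every cross-community shortest path. Motif
    # roles go to the quietest genes first so the planted structure is
    # essentially always detected.
    prof_counts <- sort(table(truth$genes$profile[truth$genes$is_de]),
                        decreasing = TRUE)
    prof_pool <- function(pid) {
      in_prof <- !is.na(truth$genes$profile) & truth$genes$profile == pid
      truth$genes$gene[in_prof][order(truth$genes$sigma2[in_prof])]
    }
    pool_a <- prof_pool(as.integer(names(prof_counts)[1]))
    pool_b <- prof_pool(as.integer(names(prof_counts)[2]))
    n_anchor <- min((length(pool_a) - 1) %/% 2, length(pool_b) %/% 2, 10L)
    bridge_gene <- pool_a[1]
    anchor_a <- pool_a[1 + seq_len(n_anchor)]
    anchor_b <- pool_b[seq_len(n_anchor)]
    memb_a <- pool_a[-seq_len(1 + n_anchor)]
    memb_b <- pool_b[-seq_len(n_anchor)]
    pool <- c(pool_a, pool_b)
    clique <- function(members) {
      if (length(members) < 2) return(NULL)
      pairs <- t(utils::combn(members, 2))
      tibble::tibble(source = pairs[, 1], relation = "activation", target = pairs[, 2])
    }
    attach_members <- function(members, anchors) {
      if (length(members) == 0) return(NULL)
      purrr::map(members, function(g) {
        tibble::tibble(source = sample(anchors, min(2, length(anchors))),
                       relation = "expression", target = g)
      }) |> dplyr::bind_rows()
    }
    catalog <- dplyr::bind_rows(
      clique(anchor_a), clique(anchor_b),
      tibble::tibble(source = anchor_a, relation = "activation", target = bridge_gene),
      tibble::tibble(source = bridge_gene, relation = "activation", target = anchor_b),
      attach_members(memb_a, anchor_a), attach_members(memb_b, anchor_b),
      random_within(setdiff(de_genes, pool)))
  } else {
    catalog <- random_within(de_genes)
  }
  if (is.null(catalog) || nrow(catalog) == 0) {
    catalog <- tibble::tibble(source = character(), relation = character(),
                              target = character())
  }
  catalog <- dplyr::distinct(catalog)

  list(annotations = ann, catalog = catalog,
       category_truth = tibble::tibble(category = cat_ids,
                                       planted = seq_len(n_cat) %in% planted),
       bridge_gene = bridge_gene)
}

#' Generate a qPCR plate consistent with a synthetic truth
#'
#' Inverse model of 2^-ddCt quantification: for each biological replicate
#' block, Ct(gene, condition) = Ct0(gene) - log2 fold(condition vs reference
#' condition) + block shift + technical noise. The block shift is shared by
#' all genes in a block (it cancels in dCt) and the reference gene's fold is
#' identically 1, so with zero noise 2^-ddCt recovers the planted fold exactly.
#'
#' @param truth truth list from [generate_expression()].
#' @param genes gene ids to assay (must exist in the truth).
#' @param config the same [synth_config()].
#' @param reference_gene id used for the housekeeping gene rows.
#' @return A `qpcr_plate`.
#' @export
generate_qpcr <- function(truth, genes, config = truth$config,
                          reference_gene = "actin") {
  validate_synth_config(config)
  unknown <- setdiff(genes, truth$genes$gene)
  if (length(unknown) > 0) {
    abort(paste0("unknown gene id(s): ", paste(unknown, collapse = ", ")))
  }
  set.seed(synth_seed(config, "qpcr"))
  conds <- config$conditions
  log2fc <- truth$log2_means[genes, , drop = FALSE] -
    truth$log2_means[genes, 1]
  rownames(log2fc) <- genes

  grid <- tidyr::expand_grid(condition = conds,
                             bio_rep = seq_len(config$qpcr_bio_reps))
  block_shift <- rnorm(nrow(grid), 0, 0.3)
  ct0 <- stats::setNames(rnorm(length(genes) + 1, 25, 2), c(genes, reference_gene))

  rows <- purrr::pmap(cbind(grid, shift = block_shift), function(condition, bio_rep, shift) {
    purrr::map(c(genes, reference_gene), function(g) {
      fold <- if (g == reference_gene) 0 else log2fc[g, condition]
      tibble::tibble(
        gene = g, condition = condition, bio_rep = bio_rep,
        tech_rep = seq_len(config$qpcr_tech_reps),
        ct = ct0[[g]] - fold + shift +
          rnorm(config$qpcr_tech_reps, 0, config$ct_noise_sd))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  rows$ct <- pmin(pmax(rows$ct, 0), 45)
  qpcr_plate(rows, reference_gene)
}

#' Write a complete synthetic demo dataset to disk
#'
#' Emits the exact file formats the readers accept: expression TSV + sample
#' sheet CSV, GMT annotations, SIF catalog, qPCR CSV, and a truth TSV.
#'
#' @param out_dir destination directory.
#' @param config a [synth_config()].
#' @return Invisibly, a named character vector of written paths.
#' @export
write_synthetic_dataset <- function(out_dir, config = synth_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- generate_expression(config)
  ann <- generate_annotations(sim$truth, config)
  qpcr_genes <- head(sim$truth$genes$gene[sim$truth$genes$is_de], 8)
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    sample_sheet = file.path(out_dir, "expression_samples.csv"),
    gmt = file.path(out_dir, "annotations.gmt"),
    sif = file.path(out_dir, "interactions.sif"),
    qpcr = file.path(out_dir, "qpcr.csv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_expression_matrix(sim$matrix, paths[["expression"]], paths[["sample_sheet"]])
  write_gmt(ann$annotations, paths[["gmt"]])
  write_sif(ann$catalog, paths[["sif"]])
  if (length(qpcr_genes) > 0) {
    write_qpcr(generate_qpcr(sim$truth, qpcr_genes, config), paths[["qpcr"]])
  }
  readr::write_tsv(sim$truth$genes, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
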
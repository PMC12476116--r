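# Stage wrapper: each stage declares its output files; a stage re-runs
# only when an output is missing or the configuration hash changed.
# Skipped stages rebuild their in-memory result from the written outputs
# via `loader`, so downstream stages can still consume them. The manifest
# records the config hash and md5 of every output for provenance.
#' @noRd
.run_stage <- function(state, name, outputs, fun, loader = NULL) {
  entry <- state$manifest$stages[[name]]
  paths <- file.path(state$out_dir, outputs)
  fresh <- !is.null(entry) && identical(entry$config_hash, state$config_hash) &&
    all(file.exists(paths)) &&
    identical(unname(tools::md5sum(paths)), unname(unlist(entry$md5)))
  if (fresh && !is.null(loader)) {
    message("stage '", name, "': up to date, skipped")
    state$results[[name]] <- loader(paths)
    state$skipped <- c(state$skipped, name)
    return(state)
  }
  message("stage '", name, "': running")
  state$results[[name]] <- fun()
  .assert(all(file.exists(paths)), paste0("stage '", name, "' did not write its outputs"))
  state$manifest$stages[[name]] <- list(
    config_hash = state$config_hash, outputs = outputs,
    md5 = as.list(unname(tools::md5sum(paths))),
    timestamp = format(Sys.time(), tz = "UTC"))
  state
}

#' Run the full synthetic analysis pipeline
#'
#' Executes, in order: cohort simulation; fALFF computation; voxel-wise
#' CRP regression with cluster-extent FWE; skeleton TFCE-FWE inference;
#' parcellation and spatial association with neurotransmitter and
#' behavioral map families (separate FDR families); transcriptomic
#' association (gene scores, ensemble GCEA, PLS with permutation p and
#' top-25% loading sets); and bootstrap mediation of the CRP effect on
#' the sustained-attention score through cluster fALFF. Writes stage
#' outputs (TSV/NIfTI) plus a JSON manifest with the master seed and
#' file hashes to `out_dir`; on re-run with an unchanged configuration,
#' completed stages are skipped and reloaded from disk.
#'
#' All CRP terms enter the models as log(CRP), reflecting the skewed
#' marker distribution.
#'
#' @param config a [pipeline_config()] (or a file path accepted by
#'   [read_pipeline_config()]).
#' @param out_dir output directory (created if needed).
#' @return list with per-stage `results`, the names of `skipped`
#'   stages, the `manifest` and `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("inflamap_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  cfg <- config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man_path <- file.path(out_dir, "manifest.json")
  state <- new.env(parent = emptyenv())
  state$out_dir <- out_dir
  state$manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path) else list(stages = list())
  state$config_hash <- digest_config(unclass(cfg))
  state$results <- list()
  state$skipped <- character(0)

  spec <- cohort_spec(n_patients = cfg$n_patients, n_controls = cfg$n_controls,
                      seed = cfg$seed)
  grid <- grid_spec(shape = cfg$grid_shape, voxel_size = cfg$voxel_size,
                    tr = cfg$tr, n_timepoints = cfg$n_timepoints)
  maskv <- which(grid$mask)
  coords <- arrayInd(maskv, grid$shape)
  planted_lin <- grid$cluster_seed_voxels[, 1] +
    (grid$cluster_seed_voxels[, 2] - 1) * grid$shape[1] +
    (grid$cluster_seed_voxels[, 3] - 1) * grid$shape[1] * grid$shape[2]
  planted_pos <- match(planted_lin, maskv)

  read_panel <- function(p) as.matrix(read.delim(p, header = FALSE))

  state <- .run_stage(state, "simulate",
    c("subjects.tsv", "falff_panel.tsv", "skeleton_panel.tsv", "atlas.tsv"),
    fun = function() {
      subjects <- generate_subject_table(spec)
      write_subject_table(subjects, file.path(out_dir, "subjects.tsv"))
      falff <- generate_falff_panel(spec, grid, subjects, band = cfg$band,
                                    spectrum = cfg$spectrum)
      write.table(falff$data, file.path(out_dir, "falff_panel.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      skel <- generate_skeleton_panel(spec, subjects,
                                      n_voxels = cfg$skeleton_voxels,
                                      planted = cfg$skeleton_planted)
      write.table(skel$data, file.path(out_dir, "skeleton_panel.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
      atlas <- generate_region_atlas(grid, n_regions = cfg$n_regions,
                                     seed = cfg$seed)
      write.table(data.frame(region_id = seq_len(atlas$n_regions),
                             atlas$centroids,
                             gm_probability = atlas$gm_probability),
                  file.path(out_dir, "atlas.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(subjects = subjects, falff = falff, skeleton = skel, atlas = atlas)
    },
    loader = function(paths) {
      falff <- voxel_panel(read_panel(paths[2]), coords, grid$shape)
      attr(falff, "planted_pos") <- planted_pos
      list(subjects = read_subject_table(paths[1]),
           falff = falff,
           skeleton = skeleton_panel(read_panel(paths[3]),
                                     cbind(seq_len(cfg$skeleton_voxels - 1),
                                           2:cfg$skeleton_voxels)),
           atlas = generate_region_atlas(grid, n_regions = cfg$n_regions,
                                         seed = cfg$seed))
    })

  sim <- state$results$simulate
  mdd_rows <- which(sim$subjects$group == "MDD")
  subjects_mdd <- sim$subjects[mdd_rows, , drop = FALSE]
  subjects_mdd$crp <- log(subjects_mdd$crp)
  covs <- cfg$covariates_falff
  if (cfg$sensitivity_bmi) covs <- union(covs, "bmi")

  state <- .run_stage(state, "glm_cluster",
    c("clusters.tsv", "cluster_labels.tsv", "tmap.nii"),
    fun = function() {
      pan <- voxel_panel(sim$falff$data[mdd_rows, , drop = FALSE],
                         sim$falff$coords, sim$falff$dims)
      des <- glm_design(subjects_mdd, "crp", covs)
      res <- cluster_fwe(pan, des, cluster_p = cfg$cluster_p,
                         n_perm = cfg$n_perm, seed = .substream_seed(cfg$seed, 11))
      write.table(res$clusters, file.path(out_dir, "clusters.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(voxel = seq_along(res$labels), label = res$labels),
                  file.path(out_dir, "cluster_labels.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      tvol <- array(0, dim = grid$shape)
      tvol[grid$mask] <- res$stat$t
      write_volume(tvol, file.path(out_dir, "tmap.nii"), cfg$voxel_size)
      res
    },
    loader = function(paths) {
      tvol <- read_volume(paths[3])
      list(clusters = read.delim(paths[1]),
           labels = read.delim(paths[2])$label,
           stat = structure(list(t = tvol[grid$mask]), class = "stat_map"))
    })

  state <- .run_stage(state, "tbss_infer", "tfce_p.tsv",
    fun = function() {
      desd <- glm_design(subjects_mdd, "crp", cfg$covariates_dti)
      skel_mdd <- skeleton_panel(sim$skeleton$data[mdd_rows, , drop = FALSE],
                                 sim$skeleton$edges, sim$skeleton$metric)
      res <- tfce_fwe(skel_mdd, desd, n_perm = cfg$n_perm,
                      seed = .substream_seed(cfg$seed, 12))
      write.table(data.frame(voxel = seq_along(res$p_pos), t = res$stat$t,
                             p_fwe_pos = res$p_pos, p_fwe_neg = res$p_neg),
                  file.path(out_dir, "tfce_p.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      res
    },
    loader = function(paths) {
      tb <- read.delim(paths[1])
      list(stat = structure(list(t = tb$t), class = "stat_map"),
           p_pos = tb$p_fwe_pos, p_neg = tb$p_fwe_neg)
    })

  glmres <- state$results$glm_cluster
  atlas <- sim$atlas
  tmap_region <- parcellate(glmres$stat$t, atlas$region_id, atlas$n_regions)
  pattern <- .region_effect_pattern(atlas, grid)
  surr <- surrogate_maps(tmap_region, atlas$centroids, cfg$n_surr,
                         seed = .substream_seed(cfg$seed, 13))

  state <- .run_stage(state, "spatial_assoc",
    c("assoc_neurotransmitter.tsv", "assoc_behavioral.tsv"),
    fun = function() {
      neuro <- generate_annotation_maps(atlas, cfg$k_neuro_maps, pattern,
                                        planted = 1:3,
                                        seed = .substream_seed(cfg$seed, 14),
                                        prefix = "nt")
      behav <- generate_annotation_maps(atlas, cfg$k_behav_maps, pattern,
                                        planted = 1:5,
                                        seed = .substream_seed(cfg$seed, 15),
                                        prefix = "term")
      res <- list(
        neurotransmitter = assoc_test(tmap_region, neuro,
                                      z = atlas$gm_probability, surrogates = surr),
        behavioral = assoc_test(tmap_region, behav,
                                z = atlas$gm_probability, surrogates = surr))
      write.table(res$neurotransmitter,
                  file.path(out_dir, "assoc_neurotransmitter.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(res$behavioral, file.path(out_dir, "assoc_behavioral.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      res
    },
    loader = function(paths)
      list(neurotransmitter = read.delim(paths[1]),
           behavioral = read.delim(paths[2])))

  state <- .run_stage(state, "transcriptome",
    c("gene_scores.tsv", "gcea.tsv", "pls.tsv"),
    fun = function() {
      es <- generate_expression(atlas, n_genes = cfg$n_genes, phenotype = pattern,
                                n_categories = cfg$n_categories,
                                seed = .substream_seed(cfg$seed, 16))
      gs <- gene_score(es$expr, tmap_region)
      write.table(data.frame(gene_id = names(gs), score = gs),
                  file.path(out_dir, "gene_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      gcea <- gcea_ensemble(es$expr, tmap_region, es$categories, surr)
      write.table(gcea, file.path(out_dir, "gcea.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      pls <- pls_first_component(es$expr, tmap_region)
      plsp <- pls_permutation_p(es$expr, tmap_region, surr)
      sets <- select_top_loadings(pls$loadings)
      write.table(data.frame(gene_id = names(pls$loadings),
                             loading = pls$loadings,
                             pls_plus = names(pls$loadings) %in% sets$pls_plus,
                             pls_minus = names(pls$loadings) %in% sets$pls_minus,
                             r = pls$r, p_perm = plsp$p_perm),
                  file.path(out_dir, "pls.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      list(gene_scores = gs, gcea = gcea, pls = pls, pls_p = plsp, sets = sets,
           planted_category = es$planted_category,
           planted_genes = es$planted_genes)
    },
    loader = function(paths) {
      pls <- read.delim(paths[3])
      list(gene_scores = setNames(read.delim(paths[1])$score,
                                  read.delim(paths[1])$gene_id),
           gcea = read.delim(paths[2]),
           pls = list(r = pls$r[1],
                      loadings = setNames(pls$loading, pls$gene_id)),
           pls_p = list(r = pls$r[1], p_perm = pls$p_perm[1]),
           sets = list(pls_plus = pls$gene_id[pls$pls_plus],
                       pls_minus = pls$gene_id[pls$pls_minus]),
           planted_category = "planted",
           planted_genes = sprintf("g%04d", 1:15))
    })

  state <- .run_stage(state, "mediate", "mediation.tsv",
    fun = function() {
      cl <- glmres$clusters
      roi_idx <- if (nrow(cl) == 0) attr(sim$falff, "planted_pos") else
        which(abs(glmres$labels) == cl$cluster[1])
      m <- rowMeans(sim$falff$data[mdd_rows, roi_idx, drop = FALSE])
      med <- mediate(x = drop(scale(subjects_mdd$crp)),   # already log
                     m = drop(scale(m)), y = subjects_mdd$cpt,
                     covariates = subjects_mdd[, cfg$covariates_falff],
                     n_boot = cfg$n_boot,
                     seed = .substream_seed(cfg$seed, 17))
      write.table(data.frame(a = med$a, b = med$b, c = med$c,
                             c_prime = med$c_prime, indirect = med$indirect,
                             ci_lo = med$ci[1], ci_hi = med$ci[2], n = med$n),
                  file.path(out_dir, "mediation.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      med
    },
    loader = function(paths) as.list(read.delim(paths[1])))

  state$manifest$config <- unclass(cfg)
  state$manifest$seed <- cfg$seed
  jsonlite::write_json(state$manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = state$results, skipped = state$skipped,
                 manifest = state$manifest, out_dir = out_dir))
}

#' Hash a configuration list for the provenance manifest
#'
#' Deterministic digest of a configuration (serialized canonically as
#' JSON, then md5), used to decide whether a completed stage can be
#' skipped on re-run.
#'
#' @param cfg a list.
#' @return character md5 hash.
#' @export
digest_config <- function(cfg) {
  j <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(j, tf)
  unname(tools::md5sum(tf))
}
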
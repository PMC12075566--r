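#' Default pipeline configuration
#'
#' All tunable parameters of the screening pipeline with their default
#' values: the 1.0 Angstrom RMSD gate, 50% hypothesis coverage, best-10
#' hypothesis cap, top-5000 / two-model first-pass filter, 40 decoys per
#' active, mean-plus-2-SD docking threshold (implied by the method),
#' normalized cluster cut 0.75, minimum cluster size 3, 5 Angstrom contact
#' radius with the 0.5 high-contact rule, and 0.5 Angstrom pore profiling
#' step. Synthetic-stage block sizes control the seeded generators.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @return Nested named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(planted = TRUE, hypotheses = TRUE, validation = TRUE,
                  screening = TRUE, clustering = TRUE, contacts = TRUE,
                  pore = TRUE),
    planted = list(signature = "APRR", sigma = 0.2, n_actives = 6L,
                   n_decoys_per_active = 40L, n_distractors = 2L),
    hypotheses = list(min_features = 3L, max_features = 5L,
                      min_coverage = 0.5, tolerance = 1.0,
                      max_hypotheses = 10L),
    screening = list(rmsd_max = 1.0, top_n = 5000L, min_hypotheses = 2L),
    clustering = list(normalized_threshold = 0.75, min_cluster_size = 3L,
                      reps_per_cluster = 1L),
    contacts = list(cutoff = 5.0, high_threshold = 0.5, n_residues = 20L,
                    n_poses = 12L),
    pore = list(step = 0.5, n_restarts = 8L, max_radius = 15,
                ring_z = c(-10, 10), ring_R = 5.0, constriction_R = 3.0,
                constriction_z = 0.0, atom_vdw = 1.5, atoms_per_ring = 24L))
}

# Recursively check that cfg introduces no keys unknown to the defaults.
check_config_keys <- function(cfg, ref, path = "") {
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    abort_config(sprintf("unknown config key%s: %s",
                         if (length(extra) > 1) "s" else "",
                         paste0(path, extra, collapse = ", ")))
  for (k in names(cfg))
    if (is.list(ref[[k]]) && is.list(cfg[[k]]))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

merge_config <- function(cfg, ref) {
  for (k in names(cfg)) {
    ref[[k]] <- if (is.list(ref[[k]]) && is.list(cfg[[k]]))
      merge_config(cfg[[k]], ref[[k]]) else cfg[[k]]
  }
  ref
}

#' Run the end-to-end screening pipeline on synthetic data
#'
#' Executes the stages in dependency order on seeded synthetic fixtures:
#' planted ligand-set generation, hypothesis generation, decoy validation,
#' two-pass screening with TPS_S aggregation and docking-threshold
#' selection, fingerprint diversity clustering with representative-hit
#' selection, toy pose contact analysis, and toy pore profiling with zone
#' derivation. Each stage writes a CSV (or JSON) table into `out_dir`; a
#' manifest records the configuration, its hash, the seed and per-stage row
#' counts. Re-running with an identical configuration reproduces identical
#' tables.
#'
#' @param config Configuration list (see [default_config()]), or a path to
#'   a YAML file holding one. Unknown keys are a config error; omitted keys
#'   take defaults.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("metscreen_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  check_config_keys(config, ref)
  cfg <- merge_config(config, ref)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(package = "metscreen",
                   version = as.character(utils::packageVersion("metscreen")),
                   seed = cfg$seed, stages = list())
  results <- list(config = cfg)

  tick <- function(stage, rows, file = NULL) {
    manifest$stages[[stage]] <<- list(status = "ok", rows = rows,
                                      file = if (is.null(file)) NA else basename(file))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e))))
  }

  planted <- NULL
  hypos <- NULL

  if (isTRUE(cfg$stages$planted)) {
    planted <- run_stage("planted", {
      spec <- planted_spec(signature = cfg$planted$signature,
                           sigma = cfg$planted$sigma,
                           n_actives = cfg$planted$n_actives,
                           n_decoys_per_active = cfg$planted$n_decoys_per_active,
                           n_distractors = cfg$planted$n_distractors,
                           seed = child_seed(cfg$seed, "planted"))
      gen_planted_set(spec, tolerance = cfg$hypotheses$tolerance)
    })
    f <- file.path(out_dir, "feature_sets.json")
    write_feature_sets(c(planted$actives, planted$decoys), f)
    tick("planted", length(planted$actives) + length(planted$decoys), f)
    results$planted <- planted
  }

  if (isTRUE(cfg$stages$hypotheses)) {
    hypos <- run_stage("hypotheses", generate_hypotheses(
      planted$actives,
      min_features = cfg$hypotheses$min_features,
      max_features = cfg$hypotheses$max_features,
      min_coverage = cfg$hypotheses$min_coverage,
      tolerance = cfg$hypotheses$tolerance,
      max_hypotheses = cfg$hypotheses$max_hypotheses))
    f <- file.path(out_dir, "hypotheses.json")
    write_hypotheses(hypos, f)
    utils::write.csv(hypothesis_report(hypos, n_training = cfg$planted$n_actives),
                     file.path(out_dir, "hypothesis_report.csv"), row.names = FALSE)
    tick("hypotheses", length(hypos), f)
    results$hypotheses <- hypos
  }

  if (isTRUE(cfg$stages$validation)) {
    val <- run_stage("validation", validate_hypotheses(
      planted$actives, planted$decoys, hypos,
      rmsd_max = cfg$screening$rmsd_max))
    f <- file.path(out_dir, "validation.csv")
    utils::write.csv(val, f, row.names = FALSE)
    tick("validation", nrow(val), f)
    results$validation <- val
  }

  if (isTRUE(cfg$stages$screening)) {
    scr <- run_stage("screening", {
      library_fsets <- c(planted$actives, planted$decoys)
      sl <- screen_library(library_fsets, hypos, rmsd_max = cfg$screening$rmsd_max)
      passed <- first_pass_filter(
        sl$matches[, c("molecule_id", "hypothesis_id", "rmsd")],
        top_n = cfg$screening$top_n,
        min_hypotheses = cfg$screening$min_hypotheses)
      c(sl, list(first_pass = passed))
    })
    sm <- scr$screen_matrix
    tab <- data.frame(molecule_id = rownames(sm$score_matrix),
                      sm$score_matrix,
                      tpss = sm$tpss,
                      selected = rownames(sm$score_matrix) %in% sm$selected,
                      check.names = FALSE)
    f <- file.path(out_dir, "screen.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    writeLines(sprintf("mean_tpss=%.6f sd_tpss=%.6f d_threshold=%.6f",
                       sm$mean_tpss, sm$sd_tpss, sm$d_threshold),
               file.path(out_dir, "screen_threshold.log"))
    tick("screening", nrow(tab), f)
    results$screening <- scr
  }

  if (isTRUE(cfg$stages$clustering)) {
    clu <- run_stage("clustering", {
      smiles <- demo_molecule_set()
      fps <- morgan_fingerprints(smiles)
      sim <- tanimoto_matrix(fps)
      ca <- cluster_cut(1 - sim, cfg$clustering$normalized_threshold)
      energies <- gen_energy_table(fps$ids, seed = child_seed(cfg$seed, "energy"))
      hits <- select_representatives(ca, energies,
                                     min_cluster_size = cfg$clustering$min_cluster_size,
                                     reps_per_cluster = cfg$clustering$reps_per_cluster)
      list(fingerprints = fps, similarity = sim, assignment = ca,
           energies = energies, hits = hits,
           consistency = consistency_check(hits, energies))
    })
    f <- file.path(out_dir, "clusters.csv")
    utils::write.csv(data.frame(id = names(clu$assignment$labels),
                                cluster = clu$assignment$labels,
                                clu$energies[match(names(clu$assignment$labels),
                                                   clu$energies$id),
                                             c("dg_without", "dg_with")],
                                selected = names(clu$assignment$labels) %in% clu$hits$id,
                                row.names = NULL),
                     f, row.names = FALSE)
    utils::write.csv(clu$hits, file.path(out_dir, "hits.csv"), row.names = FALSE)
    tick("clustering", clu$assignment$n_clusters, f)
    results$clustering <- clu
  }

  if (isTRUE(cfg$stages$contacts)) {
    con <- run_stage("contacts", {
      toy <- gen_toy_poseset(cfg$contacts$n_residues, cfg$contacts$n_poses,
                             seed = child_seed(cfg$seed, "poses"))
      prof <- contact_frequency(toy$pose_set, cutoff = cfg$contacts$cutoff,
                                high_threshold = cfg$contacts$high_threshold)
      list(toy = toy, profile = prof)
    })
    f <- file.path(out_dir, "contacts.csv")
    utils::write.csv(con$profile, f, row.names = FALSE)
    tick("contacts", nrow(con$profile), f)
    results$contacts <- con
  }

  if (isTRUE(cfg$stages$pore)) {
    por <- run_stage("pore", {
      zr <- seq(cfg$pore$ring_z[1], cfg$pore$ring_z[2], by = 1)
      R <- ifelse(abs(zr - cfg$pore$constriction_z) < 0.5,
                  cfg$pore$constriction_R, cfg$pore$ring_R)
      toy <- gen_toy_pore(data.frame(z = zr, R = R),
                          atom_vdw = cfg$pore$atom_vdw,
                          atoms_per_ring = cfg$pore$atoms_per_ring,
                          seed = child_seed(cfg$seed, "pore"))
      prof <- profile_pore(toy$structure, step = cfg$pore$step,
                           seed = child_seed(cfg$seed, "poreopt"),
                           n_restarts = cfg$pore$n_restarts,
                           max_radius = cfg$pore$max_radius,
                           anchor = c(0, 0, 0),
                           z_range = cfg$pore$ring_z)
      zones <- zone_boundaries_from_profile(prof)
      list(toy = toy, profile = prof, zones = zones)
    })
    f <- file.path(out_dir, "pore.csv")
    write_pore_profile(por$profile, f)
    tick("pore", nrow(por$profile$profile), f)
    results$pore <- por
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
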
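# Orchestration: one-config end-to-end runs with caching and a manifest,
# and the ablation grid over embedding / architecture / ordering axes.

#' Pipeline configuration
#'
#' @param synthetic A [synthetic_config()].
#' @param aspect Subontology to model.
#' @param embedding,architecture,ordering Model axes (see
#'   [run_experiment()]).
#' @param config A [transformer_config()].
#' @param tc A [train_config()].
#' @param d_z,ae_epochs,ae_lr Autoencoder settings.
#' @param n_held_out Zero-shot holdout size (0 = standard run).
#' @param seed Master seed (propagated to all stages).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            aspect = "MF", embedding = "combined",
                            architecture = "decoder",
                            ordering = "hierarchical",
                            config = transformer_config(),
                            tc = train_config(), d_z = 64L,
                            ae_epochs = 150L, ae_lr = 5e-3,
                            n_held_out = 0L, seed = 1L) {
  synthetic$seed <- as.integer(seed)
  tc$seed <- as.integer(seed)
  structure(list(synthetic = synthetic, aspect = aspect,
                 embedding = embedding, architecture = architecture,
                 ordering = ordering, config = config, tc = tc,
                 d_z = as.integer(d_z), ae_epochs = as.integer(ae_epochs),
                 ae_lr = ae_lr, n_held_out = as.integer(n_held_out),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline with caching
#'
#' Stages: `simulate` (synthetic dataset), `autoencode` (GO latents),
#' `train` + `evaluate` (via [run_experiment()]), `rollout`. Each stage's
#' output is cached under `out_dir` keyed by the configuration checksum; a
#' rerun with an unchanged configuration loads the caches instead of
#' recomputing. A `manifest.json` with seeds, checksums, per-stage timings
#' and output paths is written at the end.
#'
#' @param pc A [pipeline_config()].
#' @param out_dir Output directory.
#' @param stages Subset of `c("simulate", "autoencode", "train",
#'   "evaluate", "rollout")`; earlier stages are implied by later ones.
#' @return The run manifest (list), invisibly; outputs on disk.
#' @export
run_pipeline <- function(pc, out_dir,
                         stages = c("simulate", "autoencode", "train",
                                    "evaluate", "rollout")) {
  known <- c("simulate", "autoencode", "train", "evaluate", "rollout")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop_hiergo("unknown stage(s): ", paste(bad, collapse = ", "),
                class = "hiergo_config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_sum <- object_checksum(pc)
  timings <- list()
  paths <- list()

  cached <- function(name, compute) {
    f <- file.path(out_dir, paste0(name, ".rds"))
    t0 <- proc.time()[["elapsed"]]
    out <- if (file.exists(f) && identical(readRDS(f)$config_checksum,
                                           cfg_sum)) {
      readRDS(f)$value
    } else {
      v <- compute()
      saveRDS(list(config_checksum = cfg_sum, value = v), f)
      v
    }
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    paths[[name]] <<- f
    out
  }

  dataset <- cached("simulate", function() simulate_dataset(pc$synthetic))

  ae <- if (pc$embedding == "combined") {
    cached("autoencode", function() {
      fit_autoencoder(dataset$term_embeddings, dataset$graph, d_z = pc$d_z,
                      epochs = pc$ae_epochs, lr = pc$ae_lr, seed = pc$seed)
    })
  }

  exp <- cached("train", function() {
    scenario <- if (pc$n_held_out > 0) {
      make_zero_shot_scenario(dataset, n_held_out = pc$n_held_out,
                              seed = pc$seed)
    }
    run_experiment(dataset, scenario, aspect = pc$aspect,
                   embedding = pc$embedding,
                   architecture = pc$architecture,
                   ordering = pc$ordering, config = pc$config, tc = pc$tc,
                   ae = ae, d_z = pc$d_z, ae_epochs = pc$ae_epochs,
                   ae_lr = pc$ae_lr)
  })

  if ("evaluate" %in% stages) {
    rep <- exp$report
    jsonlite::write_json(
      list(fmax = rep$fmax, threshold = rep$threshold,
           macro_aupr = rep$macro_aupr, micro_aupr = rep$micro_aupr,
           auc = rep$auc,
           held_out_auc = if (!is.null(exp$held_out_auc)) {
             stats::setNames(as.list(exp$held_out_auc$auc),
                             exp$held_out_auc$term_id)
           }),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    paths$evaluate <- file.path(out_dir, "metrics.json")
  }

  if ("rollout" %in% stages && pc$architecture != "mlp") {
    ro <- cached("rollout", function() rollout_report(exp, dataset))
    utils::write.table(ro, file.path(out_dir, "rollout.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hiergo")),
    seed = pc$seed, config_checksum = cfg_sum,
    dataset_checksum = dataset$manifest$config_checksum,
    stages = stages, timings = timings,
    paths = lapply(paths, normalizePath)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Ablation grid over embedding, architecture and ordering
#'
#' Runs [run_experiment()] for every combination of the requested axis
#' values on one shared dataset and seed, and consolidates the evaluation
#' metrics into a table. Orderings other than `"hierarchical"` are skipped
#' (with a log line) for the MLP architecture, which has no term sequence.
#'
#' @param dataset A `synthetic_dataset`.
#' @param axes Named list with any of `embeddings`, `architectures`,
#'   `orderings`.
#' @param aspect Subontology.
#' @param config,tc Model/training configuration shared by all runs.
#' @param d_z,ae_epochs,ae_lr Autoencoder settings (fitted once, shared).
#' @return Data frame: one row per run with the axis values and metrics,
#'   plus attribute `dataset_checksum`.
#' @export
run_ablation_grid <- function(dataset,
                              axes = list(embeddings = "combined",
                                          architectures = "decoder",
                                          orderings = c("hierarchical",
                                                        "go_id")),
                              aspect = "MF",
                              config = transformer_config(),
                              tc = train_config(), d_z = 64L,
                              ae_epochs = 150L, ae_lr = 5e-3) {
  embeddings <- axes$embeddings %||% "combined"
  architectures <- axes$architectures %||% "decoder"
  orderings <- axes$orderings %||% "hierarchical"
  ae <- if ("combined" %in% embeddings) {
    fit_autoencoder(dataset$term_embeddings, dataset$graph, d_z = d_z,
                    epochs = ae_epochs, lr = ae_lr, seed = tc$seed)
  }
  scenario <- make_protein_split(dataset, seed = tc$seed)
  rows <- list()
  for (emb in embeddings) {
    for (arch in architectures) {
      for (ord in orderings) {
        if (arch == "mlp" && ord != orderings[1]) {
          message("skipping ordering=", ord, " for mlp (no term sequence)")
          next
        }
        exp <- run_experiment(dataset, scenario, aspect = aspect,
                              embedding = emb, architecture = arch,
                              ordering = ord, config = config, tc = tc,
                              ae = ae)
        rows[[length(rows) + 1L]] <- data.frame(
          embedding = emb, architecture = arch, ordering = ord,
          fmax = exp$report$fmax, macro_aupr = exp$report$macro_aupr,
          micro_aupr = exp$report$micro_aupr, auc = exp$report$auc,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "dataset_checksum") <- dataset$manifest$config_checksum
  out
}
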
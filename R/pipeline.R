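# End-to-end orchestration: synth -> fc -> effects -> classify.

#' Default pipeline configuration
#'
#' Desk-scale settings: 16 subjects, 30 regions, the 15-clip catalogue at
#' quarter duration. Every field can be overridden via the `config` argument
#' of [run_pipeline()] or a YAML file with the same keys.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    seed = 1,
    cohort = list(n_subjects = 16, sex_ratio = 0.5),
    truth = list(n_regions = 30, clip_edges = 150, clip_strength = 0.25,
                 fingerprint_edges = 40, fingerprint_sd = 0.15,
                 sex_edges = 20, sex_delta = 0.1,
                 age_edges = 20, age_slope = 0.05),
    dataset = list(duration_scale = 0.25, extra_tr = 10),
    fc = list(sparsity = 0.25, rank_by = "signed"),
    effects = list(alpha = 0.05),
    classify = list(cv = "loocv", n_folds = 10,
                    k_grid = default_k_grid(), include_full = TRUE,
                    sparsity_grid = 0.25),
    log_level = "info"
  )
}

# Recursive schema check: unknown keys are rejected, known keys must have
# the same type class as the default.
validate_config <- function(config, template = default_config(), path = "") {
  if (!is.list(config)) stop_invalid("config", path, " must be a list")
  unknown <- setdiff(names(config), names(template))
  if (length(unknown) > 0L) {
    stop_invalid("unknown config key", if (length(unknown) > 1) "s", ": ",
                 paste0(path, unknown, collapse = ", "))
  }
  merged <- template
  for (nm in names(config)) {
    if (is.list(template[[nm]])) {
      merged[[nm]] <- validate_config(config[[nm]], template[[nm]],
                                      paste0(path, nm, "."))
    } else {
      merged[[nm]] <- config[[nm]]
    }
  }
  merged
}

check_config_values <- function(cfg) {
  sp <- c(cfg$fc$sparsity, cfg$classify$sparsity_grid)
  if (any(sp <= 0 | sp >= 1)) stop_invalid("sparsity values must lie in (0, 1)")
  if (cfg$effects$alpha <= 0 || cfg$effects$alpha >= 1) {
    stop_invalid("alpha must lie in (0, 1)")
  }
  if (cfg$cohort$n_subjects < 3) stop_invalid("pipeline needs at least 3 subjects")
  if (!cfg$classify$cv %in% c("loocv", "kfold")) {
    stop_invalid("classify.cv must be 'loocv' or 'kfold'")
  }
  invisible(cfg)
}

pipe_log <- function(level, stage, msg, t0 = NULL) {
  if (identical(level, "quiet")) return(invisible())
  elapsed <- if (is.null(t0)) "" else sprintf(" [%.1fs]", as.numeric(Sys.time()) - t0)
  message(sprintf("[moviefc] %-9s %s%s", stage, msg, elapsed))
}

stage_done <- function(manifest, stage, hash, files) {
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$config_hash, hash) &&
    all(file.exists(files))
}

#' Run the full analysis pipeline into a directory
#'
#' Stages run in dependency order (synthesise data, build FC edge vectors,
#' fit per-edge effects, classify clips); a JSON manifest records the config
#' hash, seed and MD5 checksum of every output, and a completed stage whose
#' config and outputs are unchanged is skipped on re-run.
#'
#' @param config a (possibly partial) configuration list, or the path to a
#'   YAML file; merged over [default_config()] and validated — unknown keys
#'   are rejected before any stage runs.
#' @param out_dir output directory for all stage outputs and the manifest.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- check_config_values(validate_config(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- digest_config(cfg)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else {
    list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  }
  if (!identical(manifest$config_hash, cfg_hash)) {
    manifest <- list(config_hash = cfg_hash, seed = cfg$seed, stages = list())
  }
  lvl <- cfg$log_level

  # --- synth ---------------------------------------------------------------
  data_dir <- file.path(out_dir, "data")
  synth_files <- file.path(data_dir, c("participants.tsv", "clips.tsv",
                                       "networks.tsv", "ground_truth.json"))
  cohort <- make_cohort(cfg$cohort$n_subjects, cfg$cohort$sex_ratio, cfg$seed)
  catalogue <- clip_catalogue()
  truth <- do.call(make_ground_truth,
                   c(list(partition = network_partition(cfg$truth$n_regions),
                          seed = cfg$seed),
                     cfg$truth))
  dataset <- make_dataset(cohort, catalogue, truth,
                          duration_scale = cfg$dataset$duration_scale,
                          extra_tr = cfg$dataset$extra_tr)
  if (!stage_done(manifest, "synth", cfg_hash, synth_files)) {
    t0 <- as.numeric(Sys.time())
    written <- write_dataset(dataset, data_dir)
    manifest$stages$synth <- list(config_hash = cfg_hash,
                                  files = checksum_files(written))
    pipe_log(lvl, "synth", sprintf("wrote %d files (seed %s)", length(written), cfg$seed), t0)
  } else {
    pipe_log(lvl, "synth", "up to date, skipped")
  }

  # --- fc ------------------------------------------------------------------
  fc_file <- file.path(out_dir, "fc_edges.tsv")
  idx_file <- file.path(out_dir, "edge_index.tsv")
  stack <- fc_stack(dataset, sparsity = cfg$fc$sparsity, rank_by = cfg$fc$rank_by)
  if (!stage_done(manifest, "fc", cfg_hash, c(fc_file, idx_file))) {
    t0 <- as.numeric(Sys.time())
    write_stack_tsv(stack, fc_file)
    utils::write.table(edge_index(truth$n_regions), idx_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest$stages$fc <- list(config_hash = cfg_hash,
                               files = checksum_files(c(fc_file, idx_file)))
    pipe_log(lvl, "fc", sprintf("stacked %d x %d x %d edge vectors",
                                dim(stack$values)[1], dim(stack$values)[2],
                                dim(stack$values)[3]), t0)
  } else {
    pipe_log(lvl, "fc", "up to date, skipped")
  }

  # --- effects -------------------------------------------------------------
  eff_file <- file.path(out_dir, "effects.tsv")
  net_files <- file.path(out_dir, sprintf("network_counts_%s.tsv",
                                          gsub(":", "_", effect_terms)))
  if (!stage_done(manifest, "effects", cfg_hash, c(eff_file, net_files))) {
    t0 <- as.numeric(Sys.time())
    eff <- fit_edge_models(stack, cohort, alpha = cfg$effects$alpha)
    utils::write.table(eff, eff_file, sep = "\t", quote = FALSE, row.names = FALSE)
    for (ti in seq_along(effect_terms)) {
      agg <- aggregate_by_network(eff, truth$partition, effect_terms[ti],
                                  index = edge_index(truth$n_regions))
      utils::write.table(agg$net, net_files[ti], sep = "\t", quote = FALSE,
                         col.names = NA)
    }
    manifest$stages$effects <- list(config_hash = cfg_hash,
                                    files = checksum_files(c(eff_file, net_files)))
    pipe_log(lvl, "effects", sprintf("tested %d edges x %d terms",
                                     dim(stack$values)[3], length(effect_terms)), t0)
  } else {
    pipe_log(lvl, "effects", "up to date, skipped")
  }

  # --- classify ------------------------------------------------------------
  res_file <- file.path(out_dir, "classification.tsv")
  if (!stage_done(manifest, "classify", cfg_hash, res_file)) {
    t0 <- as.numeric(Sys.time())
    sweep <- k_sweep(dataset,
                     k_grid = unlist(cfg$classify$k_grid),
                     sparsity_grid = unlist(cfg$classify$sparsity_grid),
                     cv = cfg$classify$cv, n_folds = cfg$classify$n_folds,
                     seed = cfg$seed,
                     include_full = isTRUE(cfg$classify$include_full))
    utils::write.table(sweep, res_file, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$classify <- list(config_hash = cfg_hash,
                                     files = checksum_files(res_file))
    pipe_log(lvl, "classify", sprintf("%d result cells", nrow(sweep)), t0)
  } else {
    pipe_log(lvl, "classify", "up to date, skipped")
  }

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

digest_config <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

checksum_files <- function(files) {
  sums <- tools::md5sum(files)
  stats::setNames(as.list(unname(sums)), basename(files))
}

# Long-format export: one row per subject x clip, edge columns.
write_stack_tsv <- function(stack, path) {
  v <- stack$values
  n <- dim(v)[1L]; s <- dim(v)[2L]; e_t <- dim(v)[3L]
  flat <- matrix(v, n * s, e_t)
  df <- data.frame(subject_id = rep(stack$subjects, s),
                   clip_label = rep(stack$clip_labels, each = n))
  edge_df <- as.data.frame(flat)
  names(edge_df) <- paste0("edge_", seq_len(e_t) - 1L)
  utils::write.table(cbind(df, edge_df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a long-format FC edge TSV back into a session stack
#'
#' @param path TSV written by the fc stage (columns `subject_id`,
#'   `clip_label`, `edge_0` ...).
#' @param sparsity sparsity annotation for the resulting stack.
#' @return a [session_stack()].
#' @export
read_stack_tsv <- function(path, sparsity = NA_real_) {
  df <- utils::read.delim(path, check.names = FALSE)
  subjects <- unique(df$subject_id)
  clips <- sort(unique(df$clip_label))
  e_cols <- grep("^edge_", names(df), value = TRUE)
  vals <- array(NA_real_, dim = c(length(subjects), length(clips), length(e_cols)))
  si <- match(df$subject_id, subjects)
  ci <- match(df$clip_label, clips)
  for (r in seq_len(nrow(df))) {
    vals[si[r], ci[r], ] <- as.numeric(df[r, e_cols])
  }
  session_stack(vals, subjects, clips, sparsity = sparsity)
}
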
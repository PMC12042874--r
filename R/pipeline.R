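# Pipeline driver: wires the stages (simulate -> label -> train -> select
# -> interpret -> enrich -> evaluate) behind a single schema-validated
# configuration, writing artifacts plus a manifest recording the config
# hash, seeds and produced files.

canya_default_config <- function() {
  list(
    out_dir = "canya_run",
    stages = c("simulate", "label", "train", "select", "interpret",
               "enrich", "evaluate"),
    simulate = list(n_peptides = 5000, seed = 1, library_id = "NNK1"),
    label = list(min_reads = 100, alpha = 0.05),
    train = list(n_replicates = 2, base_seed = 100, epochs = 8,
                 n_filters = 16, dense_units = 16, batch_size = 128),
    select_stage = list(),
    interpret = list(n_backgrounds = 500, gia_seed = 7, top_filters = 8),
    enrich = list(n_fixtures = 40, seed = 11),
    evaluate = list(n_boot = 200, seed = 3)
  )
}

validate_config <- function(config) {
  def <- canya_default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (nm in intersect(names(config), names(def))) {
    if (is.list(def[[nm]])) {
      bad <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(bad) > 0) {
        abort(sprintf("unknown key(s) in section '%s': %s", nm,
                      paste(bad, collapse = ", ")))
      }
    }
  }
  modifyList(def, config)
}

#' Read a pipeline configuration file
#'
#' YAML document matching the default schema; unknown keys are rejected by
#' name.
#'
#' @param path YAML file path.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

config_hash <- function(config) {
  config$out_dir <- NULL  # hash the run's parameters, not its location
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline
#'
#' Executes any contiguous span of stages on the synthetic library, writing
#' each stage's artifacts under `out_dir` and a `manifest.json` recording
#' the configuration hash, seeds and produced files. Later stages read the
#' artifacts of earlier ones, so a missing upstream artifact raises an
#' error naming the stage that must run first.
#'
#' @param config Configuration list (see [read_run_config()]); missing
#'   fields take defaults.
#' @param stages Stages to run (default: those in the config).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), stages = NULL) {
  cfg <- validate_config(config)
  stages <- stages %||% cfg$stages
  all_stages <- c("simulate", "label", "train", "select", "interpret",
                  "enrich", "evaluate")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(cfg$out_dir, name)
  need <- function(path, stage) {
    if (!file.exists(path)) {
      abort(sprintf("missing artifact %s: run stage '%s' first",
                    basename(path), stage))
    }
    path
  }
  produced <- character(0)
  emit <- function(path) {
    produced <<- c(produced, path)
    path
  }

  if ("simulate" %in% stages) {
    lib <- simulate_library(cfg$simulate$n_peptides,
                            seed = cfg$simulate$seed,
                            library_id = cfg$simulate$library_id)
    write_scored_table(lib, emit(art("scored_library.tsv")))
    fx <- make_structure_fixtures(cfg$enrich$n_fixtures,
                                  seed = cfg$enrich$seed)
    write_structure_table(fx, emit(art("structure_fixtures.tsv")))
  }
  if ("label" %in% stages) {
    lib <- read_scored_table(need(art("scored_library.tsv"), "simulate"))
    labeled <- label_library(lib, min_reads = cfg$label$min_reads,
                             alpha = cfg$label$alpha)
    write_scored_table(labeled, emit(art("labeled_library.tsv")))
    rep <- attr(labeled, "report")
    jsonlite::write_json(rep, emit(art("labeling_report.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if ("train" %in% stages) {
    labeled <- read_scored_table(need(art("labeled_library.tsv"), "label"))
    labeled <- filter(labeled, nchar(.data$aa_seq) >= 3)
    tcfg <- canya_config(n_filters = cfg$train$n_filters,
                         dense_units = cfg$train$dense_units,
                         batch_size = cfg$train$batch_size)
    reps <- train_replicates(labeled, cfg$train$n_replicates,
                             base_seed = cfg$train$base_seed,
                             config = tcfg, epochs = cfg$train$epochs)
    for (i in seq_along(reps$models)) {
      canya_save(reps$models[[i]], emit(art(sprintf("model%03d.rds", i))))
    }
    readr::write_tsv(as_tibble(reps$summaries),
                     emit(art("replicate_summaries.tsv")))
  }
  if ("select" %in% stages) {
    summaries <- readr::read_tsv(need(art("replicate_summaries.tsv"),
                                      "train"),
                                 show_col_types = FALSE, progress = FALSE)
    chosen <- select_model(summaries)
    writeLines(chosen, emit(art("selected_model.txt")))
  }
  if ("interpret" %in% stages) {
    chosen <- readLines(need(art("selected_model.txt"), "select"))[1]
    model <- canya_load(need(art(paste0(chosen, ".rds")), "train"))
    labeled <- read_scored_table(need(art("labeled_library.tsv"), "label"))
    n_top <- min(cfg$interpret$top_filters, model$config$n_filters)
    pwms <- lapply(seq_len(n_top), function(f) extract_pwm(model, f))
    write_meme(pwms, emit(art("motifs.meme")))
    bg <- select_backgrounds(model, labeled,
                             n = cfg$interpret$n_backgrounds,
                             seed = cfg$interpret$gia_seed)
    imp <- vapply(pwms, function(p)
      gia_importance(model, p, bg, seed = cfg$interpret$gia_seed)$importance,
      numeric(1))
    clusters <- blosum_cluster(pwms, imp, seed = cfg$interpret$gia_seed)
    readr::write_tsv(as_tibble(clusters), emit(art("motif_clusters.tsv")))
    gia_rows <- list()
    for (cid in unique(clusters$cluster_id)) {
      members <- which(clusters$cluster_id == cid & !clusters$pruned)
      if (length(members) == 0) next
      feat <- cluster_feature(pwms[members], imp[members], cid)
      gia_rows[[length(gia_rows) + 1]] <-
        gia_importance(model, feat, bg, seed = cfg$interpret$gia_seed + cid)
    }
    readr::write_tsv(bind_rows(gia_rows), emit(art("cluster_gia.tsv")))
  }
  if ("enrich" %in% stages) {
    chosen <- readLines(need(art("selected_model.txt"), "select"))[1]
    model <- canya_load(need(art(paste0(chosen, ".rds")), "train"))
    clusters <- readr::read_tsv(need(art("motif_clusters.tsv"), "interpret"),
                                show_col_types = FALSE, progress = FALSE)
    fx <- read_structure_table(need(art("structure_fixtures.tsv"),
                                    "simulate"))
    rows <- list()
    for (cid in unique(clusters$cluster_id)) {
      members <- clusters$filter_id[clusters$cluster_id == cid &
                                      !clusters$pruned]
      if (length(members) == 0) next
      for (lab in c("strand", "coil", "disorder")) {
        r <- enrichment_auroc(model, members, fx, lab,
                              n_boot = cfg$evaluate$n_boot,
                              seed = cfg$evaluate$seed)
        r$cluster_id <- cid
        rows[[length(rows) + 1]] <- r
      }
    }
    readr::write_tsv(bind_rows(rows), emit(art("structure_enrichment.tsv")))
  }
  if ("evaluate" %in% stages) {
    chosen <- readLines(need(art("selected_model.txt"), "select"))[1]
    model <- canya_load(need(art(paste0(chosen, ".rds")), "train"))
    labeled <- read_scored_table(need(art("labeled_library.tsv"), "label"))
    test <- labeled[nchar(labeled$aa_seq) >= 3, , drop = FALSE]
    sc_model <- pre_activation(model, test$aa_seq)
    sc_hydro <- hydrophobicity_baseline(test$aa_seq)
    sc_comp <- composition_baseline(test, test)
    rows <- bind_rows(
      mutate(auroc_auprc(sc_model, test$label, n_boot = cfg$evaluate$n_boot,
                         seed = cfg$evaluate$seed), method = "canya"),
      mutate(auroc_auprc(sc_hydro, test$label, n_boot = cfg$evaluate$n_boot,
                         seed = cfg$evaluate$seed), method = "hydrophobicity"),
      mutate(auroc_auprc(sc_comp, test$label, n_boot = cfg$evaluate$n_boot,
                         seed = cfg$evaluate$seed), method = "composition"))
    readr::write_tsv(rows, emit(art("evaluation.tsv")))
  }

  manifest <- list(
    config_hash = config_hash(cfg),
    seeds = list(simulate = cfg$simulate$seed,
                 train_base = cfg$train$base_seed,
                 gia = cfg$interpret$gia_seed,
                 enrich = cfg$enrich$seed,
                 evaluate = cfg$evaluate$seed),
    stages_run = stages,
    artifacts = basename(produced)
  )
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
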
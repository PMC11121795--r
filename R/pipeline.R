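#' @title Pipeline orchestration
#' @description Runs the protocol end to end from a structured config:
#' baseline characterization (sampling + density filtering + profile),
#' patient trio construction and consensus models, task analysis,
#' optional cross-validation, sensitivity cube + PLS-DA, and
#' stratification. Every stage derives its RNG stream from the single
#' master seed, and a JSON manifest records digests, seed and outputs.
#' @name pipeline-module
NULL

pipeline_defaults <- function() {
  list(model = "toy", tasks = "toy", cohort = "synthetic",
       cohort_effects = "strong", biomass_floor = 0.5,
       n_baseline_samples = 2000L, n_trio_samples = 400L,
       trio_adaptive = FALSE, method = "continuous",
       sweep_steps = 20L, sweep_min_points = 5L,
       cv_alpha = 0.01, cv_subsample = 100L, cv_points = 300L,
       n_clusters = NULL,
       stages = c("baseline", "integrate", "tasks", "stratify"))
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config) &&
                  requireNamespace("yaml", quietly = TRUE))
      yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(pipeline_defaults(), as.list(config))
  known <- names(pipeline_defaults())
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  cfg
}

#' Run the full pipeline
#'
#' @param config list or path to a JSON/YAML config; unknown fields are
#'   rejected before any computation. Fields and defaults: see
#'   `exogem:::pipeline_defaults()`.
#' @param out_dir output directory (created).
#' @param seed master seed; all stage seeds derive from it.
#' @return a `run_manifest` (invisibly written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)

  model <- if (identical(cfg$model, "toy")) make_toy_model()
           else load_model(cfg$model)
  tasks <- if (identical(cfg$tasks, "toy")) toy_tasks()
           else load_tasks(cfg$tasks)
  cohort <- if (identical(cfg$cohort, "synthetic"))
    simulate_cohort(cohort_spec(effects = cfg$cohort_effects, seed = seed))
  else if (inherits(cfg$cohort, "patient_cohort")) cfg$cohort
  else read_cohort(cfg$cohort$patients, cfg$cohort$controls,
                   cfg$cohort$map, cfg$cohort$groups)
  stats_tab <- control_stats(cohort)

  state <- list(model = model, cohort = cohort)

  if ("baseline" %in% cfg$stages) {
    base <- set_biomass_floor(model, cfg$biomass_floor)
    bs <- sample_fluxes(base, cfg$n_baseline_samples, seed = seed)
    br <- resos(bs, method = cfg$method)
    profile <- baseline_profile(base, bs, br)
    utils::write.table(profile$bounds, file.path(out_dir, "baseline_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "baseline_profile.tsv"))
    write_resos_json(br, file.path(out_dir, "baseline_resos.json"))
    emit(file.path(out_dir, "baseline_resos.json"))
    state$base <- base; state$profile <- profile; state$base_resos <- br
  }

  if ("integrate" %in% cfg$stages) {
    if (is.null(state$profile)) stop("integrate stage requires baseline stage")
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    pts <- rownames(cohort$patient_table)
    state$patient_models <- stats::setNames(vector("list", length(pts)), pts)
    for (pi in seq_along(pts)) {
      p <- pts[pi]
      trio <- build_patient_trio(state$base, state$profile, cohort,
                                 stats_tab, p)
      feas <- vapply(trio, function(x) isTRUE(attr(x, "feasible")), TRUE)
      if (!any(feas))
        stop("patient '", p, "': no feasible trio member")
      if (!all(feas))
        warning("patient '", p, "': skipping infeasible trio member(s): ",
                paste(names(trio)[!feas], collapse = ", "))
      trio <- trio[feas]
      tsam <- lapply(seq_along(trio), function(i) {
        if (cfg$trio_adaptive)
          sample_adaptive(trio[[i]], state$base_resos$params,
                          batch = max(100L, cfg$n_trio_samples %/% 4L),
                          max_points = cfg$n_trio_samples,
                          seed = seed + 1000L * pi + i)
        else sample_fluxes(trio[[i]], cfg$n_trio_samples,
                           seed = seed + 1000L * pi + i)
      })
      cons <- build_consensus_model(state$base, tsam, method = cfg$method,
                                    percentile = state$base_resos$percentile)
      state$patient_models[[p]] <- cons$model
      fp <- file.path(out_dir, "models", paste0(p, ".json"))
      write_model_json(cons$model, fp)
      emit(fp)
    }
  }

  if ("tasks" %in% cfg$stages) {
    if (is.null(state$patient_models)) stop("tasks stage requires integrate stage")
    tm <- evaluate_task_matrix(state$patient_models, tasks,
                               group_labels = cohort$group_labels)
    write_task_matrix_tsv(tm, file.path(out_dir, "task_activity.tsv"))
    emit(file.path(out_dir, "task_activity.tsv"))
    state$task_matrix <- tm
  }

  if ("validate" %in% cfg$stages) {
    if (is.null(state$patient_models)) stop("validate stage requires integrate stage")
    mex <- unname(cohort$metabolite_map)
    rows <- list()
    for (pi in seq_along(state$patient_models)) {
      p <- names(state$patient_models)[pi]
      sc <- sample_fluxes(state$patient_models[[p]], cfg$cv_points,
                          seed = seed + 5000L + pi)
      rep_p <- crossvalidate_exchanges(state$patient_models[[p]],
                                       state$profile, sc, mex,
                                       alpha = cfg$cv_alpha,
                                       subsample_n = cfg$cv_subsample,
                                       seed = seed + 6000L + pi,
                                       n_points = cfg$cv_points)
      rows[[p]] <- cbind(patient = p, rep_p$table)
    }
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(out_dir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "validation.tsv"))
    state$validation <- tab
  }

  if ("sensitivity" %in% cfg$stages) {
    if (is.null(state$patient_models)) stop("sensitivity stage requires integrate stage")
    cube <- build_cube(state$patient_models, cohort$metabolite_map, tasks,
                       n_steps = cfg$sweep_steps,
                       min_points = cfg$sweep_min_points)
    write_cube(cube, file.path(out_dir, "cube"))
    emit(file.path(out_dir, "cube", "axes.json"))
    flat <- flatten_cube(cube)
    utils::write.table(data.frame(patient = rownames(flat), flat,
                                  check.names = FALSE),
                       file.path(out_dir, "cube_flat.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "cube_flat.tsv"))
    gl <- cohort$group_labels[rownames(flat)]
    fit <- plsda(flat, gl, n_components = min(5L, nrow(flat) - 1L))
    utils::write.table(data.frame(patient = rownames(flat), fit$scores),
                       file.path(out_dir, "plsda_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit(file.path(out_dir, "plsda_scores.tsv"))
    state$cube <- cube; state$plsda <- fit
  }

  if ("stratify" %in% cfg$stages) {
    if (is.null(state$task_matrix)) stop("stratify stage requires tasks stage")
    Z <- row_standardize(state$task_matrix$values)
    k <- cfg$n_clusters %||% length(unique(cohort$group_labels))
    cl <- hierarchical_cluster(Z, axis = "columns", k = k)
    contrib <- cluster_group_contributions(cl, cohort$group_labels)
    export_heatmap_tsv(Z, col_assignment = cl,
                       path = file.path(out_dir, "heatmap.tsv"))
    emit(file.path(out_dir, "heatmap.tsv"))
    jsonlite::write_json(list(
      assignment = as.list(cl$assignment),
      contributions = as.data.frame(contrib),
      ari = adjusted_rand_index(cl$assignment,
                                cohort$group_labels[names(cl$assignment)])),
      file.path(out_dir, "stratify.json"), auto_unbox = TRUE, digits = NA)
    emit(file.path(out_dir, "stratify.json"))
    state$clusters <- cl
  }

  manifest <- list(command = "run_pipeline",
                   config_digest = digest::digest(cfg),
                   model_digest = model_digest(model),
                   seed = seed,
                   version = as.character(utils::packageVersion("exogem")),
                   started = format(t0), finished = format(Sys.time()),
                   outputs = outputs)
  missing <- outputs[!file.exists(outputs)]
  if (length(missing))
    stop("manifest invariant violated; missing outputs: ",
         paste(missing, collapse = ", "))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  attr(manifest, "state") <- state
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `synth` (write a synthetic cohort + toy model),
#' `sample`, `resos`, `baseline`, `tasks`, `knockout`, and `run` /
#' `integrate` / `validate` / `sensitivity` / `stratify` (stage
#' selections of the full pipeline). Global flags: `--config`,
#' `--seed`, `--out-dir`, plus subcommand-specific `--model`,
#' `--samples`, `--n`, `--method`.
#'
#' @param args character vector (default: command line).
#' @return exit status 0 invisibly.
#' @export
exogem_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: exogem <synth|sample|resos|baseline|tasks|knockout|run|",
        "integrate|validate|sensitivity|stratify> [--config F] [--seed N]",
        "[--out-dir D] [--model F] [--samples F] [--n N] [--method M]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- list(seed = 1L, `out-dir` = "exogem_out", n = 1000L,
              method = "continuous", config = NULL, model = NULL,
              samples = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opt$seed)
  out <- opt$`out-dir`
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  getmodel <- function() if (is.null(opt$model) || opt$model == "toy")
    make_toy_model() else load_model(opt$model)
  stage_sets <- list(
    run = NULL,
    integrate = c("baseline", "integrate"),
    validate = c("baseline", "integrate", "validate"),
    sensitivity = c("baseline", "integrate", "sensitivity"),
    stratify = c("baseline", "integrate", "tasks", "stratify"))

  if (cmd == "synth") {
    cohort <- simulate_cohort(cohort_spec(seed = seed))
    write_cohort(cohort, out)
    write_model_json(make_toy_model(), file.path(out, "model.json"))
  } else if (cmd == "sample") {
    ss <- sample_fluxes(getmodel(), as.integer(opt$n), seed = seed)
    write_samples_tsv(ss, file.path(out, "samples.tsv"))
  } else if (cmd == "resos") {
    if (is.null(opt$samples)) stop("resos needs --samples")
    ss <- read_samples_tsv(opt$samples)
    write_resos_json(resos(ss, method = opt$method),
                     file.path(out, "resos.json"))
  } else if (cmd == "baseline") {
    m <- set_biomass_floor(getmodel(), 0.5)
    ss <- sample_fluxes(m, as.integer(opt$n), seed = seed)
    rr <- resos(ss, method = opt$method)
    pf <- baseline_profile(m, ss, rr)
    utils::write.table(pf$bounds, file.path(out, "baseline_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_resos_json(rr, file.path(out, "baseline_resos.json"))
  } else if (cmd == "tasks") {
    tm <- evaluate_task_matrix(list(model = getmodel()), toy_tasks())
    write_task_matrix_tsv(tm, file.path(out, "task_activity.tsv"))
  } else if (cmd == "knockout") {
    m <- getmodel()
    sl <- synthetic_lethal_scan(m)
    singles <- attr(sl, "singles")
    utils::write.table(singles, file.path(out, "essentiality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sl, file.path(out, "synthetic_lethals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (cmd %in% names(stage_sets)) {
    cfg <- if (!is.null(opt$config)) opt$config else list()
    if (!is.null(stage_sets[[cmd]])) {
      cfg <- load_pipeline_config(cfg)
      cfg$stages <- stage_sets[[cmd]]
    }
    run_pipeline(cfg, out, seed = seed)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
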
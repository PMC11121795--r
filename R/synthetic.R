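#' @title Synthetic fixtures: toy GEM and simulated cohorts
#' @description A deterministic, hand-authored 22-reaction toy network
#' (8 exchange reactions, a glucose-to-biomass backbone, a redundant
#' respiration/fermentation pair for synthetic-lethality tests, a
#' dead-end branch for pruning tests and one blocked exchange for the
#' zero-baseline boundary rule) plus a lognormal plasma-cohort
#' generator with planted multiplicative group effects, so the whole
#' pipeline is testable without external downloads.
#' @name synthetic-module
NULL

#' The shipped 22-reaction toy model
#' @return a [metabolic_model] (8 exchanges, positive biomass optimum).
#' @export
make_toy_model <- function() {
  load_model(system.file("extdata", "toy_model.json", package = "exogem",
                         mustWork = TRUE), format = "json")
}

#' The shipped example task battery for the toy model
#' @return list of [task_definition]s.
#' @export
toy_tasks <- function() {
  load_tasks(system.file("extdata", "toy_tasks.json", package = "exogem",
                         mustWork = TRUE))
}

#' Metabolite-to-exchange map for the toy model
#' @return named character vector (measured metabolite -> exchange id).
#' @export
toy_metabolite_map <- function() {
  c(glucose = "EX_glc", oxygen = "EX_o2", ammonium = "EX_nh4",
    phosphate = "EX_pi", aminoacid = "EX_aa", lactate = "EX_lac",
    co2 = "EX_co2", xmet = "EX_x")
}

#' Specification of a synthetic patient cohort
#'
#' Control concentrations are lognormal per metabolite; patients are
#' drawn from the same baseline and multiplied by their group's fold
#' change on the affected metabolite subset. The default effect
#' configuration plants strong (4-fold up or down) derangements in
#' three of four groups; `effects = "null"` plants none.
#'
#' @param n_groups number of patient groups (labels A, B, C, ...).
#' @param patients_per_group patients per group.
#' @param n_controls healthy controls.
#' @param metabolites measured metabolite names.
#' @param control_log_mean,control_log_sd lognormal baseline parameters
#'   (recycled per metabolite). The default `control_log_sd = NULL`
#'   assigns 0.05 to homeostatically regulated metabolites (glucose,
#'   phosphate; their exchange envelopes tolerate only mild rescaling
#'   under the biomass floor) and 0.15 to the rest.
#' @param effects `"strong"`, `"null"`, or a named list group ->
#'   named fold-change vector over metabolite subsets.
#' @param seed RNG seed.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_groups = 4L, patients_per_group = 6L,
                        n_controls = 20L,
                        metabolites = names(toy_metabolite_map()),
                        control_log_mean = 0, control_log_sd = NULL,
                        effects = "strong", seed = 42L) {
  stopifnot(n_groups >= 1, patients_per_group >= 1, n_controls >= 1)
  groups <- LETTERS[seq_len(n_groups)]
  if (is.null(control_log_sd))
    control_log_sd <- ifelse(
      metabolites %in% c("glucose", "phosphate", "ammonium"), 0.05, 0.15)
  if (identical(effects, "strong")) {
    ## Strong (3- to 4-fold) derangements planted on metabolites whose
    ## exchange envelopes tolerate rescaling under the biomass floor;
    ## backbone nutrients (glucose, phosphate) are left at control
    ## levels so every trio member stays solvable.
    ## oxygen and co2 move together (respiration couples them 1:1;
    ## shifting one without the other contradicts the forced-secretion
    ## envelope and renders patients infeasible)
    ## every planted effect must RESTRICT or FORCE flux through its
    ## exchange: widening a bound beyond the network's internal caps
    ## leaves the sampled dense region (and hence the consensus
    ## envelope) unchanged and is invisible downstream
    ## the network exposes two strong restrictable axes (respiration;
    ## amino acid supply with compensatory lactate overflow); the four
    ## groups sit at the four corners of that plane
    effects <- list(
      B = c(oxygen = 0.1, co2 = 0.1),
      C = c(oxygen = 0.1, co2 = 0.1, aminoacid = 0.2, lactate = 3),
      D = c(aminoacid = 0.2, lactate = 3))
    effects <- effects[names(effects) %in% groups]
  } else if (identical(effects, "null")) {
    effects <- list()
  }
  for (g in names(effects)) {
    if (any(effects[[g]] <= 0)) stop("fold changes must be > 0")
    if (!all(names(effects[[g]]) %in% metabolites))
      stop("group '", g, "': effect on unknown metabolite")
  }
  structure(list(n_groups = n_groups, groups = groups,
                 patients_per_group = patients_per_group,
                 n_controls = n_controls, metabolites = metabolites,
                 control_log_mean = rep(control_log_mean,
                                        length.out = length(metabolites)),
                 control_log_sd = rep(control_log_sd,
                                      length.out = length(metabolites)),
                 effects = effects, seed = seed), class = "cohort_spec")
}

#' Simulate a patient cohort from a specification
#'
#' Deterministic for a fixed spec (same seed gives bit-identical
#' tables).
#' @param spec a [cohort_spec].
#' @return a [patient_cohort] with group labels and the toy metabolite
#'   map attached.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  M <- length(spec$metabolites)
  draw <- function(n) {
    m <- matrix(stats::rlnorm(n * M,
                              meanlog = rep(spec$control_log_mean, each = n),
                              sdlog = rep(spec$control_log_sd, each = n)),
                n, M)
    colnames(m) <- spec$metabolites
    m
  }
  controls <- draw(spec$n_controls)
  rownames(controls) <- sprintf("C%02d", seq_len(spec$n_controls))
  np <- spec$n_groups * spec$patients_per_group
  patients <- draw(np)
  pid <- sprintf("P%02d", seq_len(np))
  rownames(patients) <- pid
  gl <- rep(spec$groups, each = spec$patients_per_group)
  names(gl) <- pid
  for (g in names(spec$effects)) {
    rows <- which(gl == g)
    fc <- spec$effects[[g]]
    patients[rows, names(fc)] <-
      sweep(patients[rows, names(fc), drop = FALSE], 2, fc, `*`)
  }
  map <- toy_metabolite_map()
  patient_cohort(patients, controls,
                 metabolite_map = map[names(map) %in% spec$metabolites],
                 group_labels = gl)
}
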
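#' @title Integrating relative plasma metabolome data into a GEM
#' @description The patient's measured metabolite concentrations are
#' expressed relative to a control group (ratio patient/control, with
#' the control summarized by its minimum, mean and maximum to absorb
#' control heterogeneity) and used to rescale the exchange-reaction
#' bounds of a baseline-characterized model. Exchange bounds whose
#' baseline envelope is identically zero receive the conventional
#' (-10, +10) window before rescaling.
#' @name exointegration-module
NULL

#' Assemble a patient cohort container
#'
#' @param patient_table patients x metabolites concentration matrix
#'   (non-negative, arbitrary consistent units; rownames = patient ids).
#' @param control_table controls x metabolites matrix over the same
#'   metabolite columns.
#' @param metabolite_map named character vector: metabolite name ->
#'   model exchange reaction id.
#' @param group_labels named character vector: patient id -> group.
#' @return a `patient_cohort` object.
#' @export
patient_cohort <- function(patient_table, control_table, metabolite_map,
                           group_labels = NULL) {
  patient_table <- as.matrix(patient_table)
  control_table <- as.matrix(control_table)
  shared <- intersect(colnames(patient_table), colnames(control_table))
  if (length(shared) == 0) stop("no shared metabolite columns")
  if (any(patient_table < 0, na.rm = TRUE) ||
      any(control_table < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed")
  structure(list(patient_table = patient_table[, shared, drop = FALSE],
                 control_table = control_table[, shared, drop = FALSE],
                 metabolite_map = metabolite_map,
                 group_labels = group_labels,
                 metabolites = shared), class = "patient_cohort")
}

#' Per-metabolite control-group summary statistics
#' @param cohort a [patient_cohort] (or a controls x metabolites matrix).
#' @return data.frame with `metabolite`, `min`, `mean`, `max`.
#' @export
control_stats <- function(cohort) {
  tab <- if (inherits(cohort, "patient_cohort")) cohort$control_table
         else as.matrix(cohort)
  data.frame(metabolite = colnames(tab),
             min = apply(tab, 2, min),
             mean = colMeans(tab),
             max = apply(tab, 2, max),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Baseline flux profile from density-retained samples
#'
#' Per-reaction minimum/maximum flux over the retained dense-region
#' samples of the baseline model, together with the saved sampling
#' parameters. This envelope is the "boundary(Met, Control)" that
#' patient ratios rescale.
#'
#' @param model the baseline [metabolic_model].
#' @param samples a [flux_sample_set] drawn from `model`.
#' @param resos_result the `resos_result` computed on `samples`.
#' @return a `baseline_profile`: data.frame `bounds` (id, lower, upper)
#'   plus `resos_params`.
#' @export
baseline_profile <- function(model, samples, resos_result) {
  if (!is.na(samples$model_digest) &&
      samples$model_digest != model_digest(model))
    stop("sample set was not drawn from this model (digest mismatch)")
  kept <- filter_solutions(samples, resos_result)
  if (nrow(kept$matrix) == 0) stop("empty retained set")
  structure(list(
    bounds = data.frame(id = samples$reaction_ids,
                        lower = apply(kept$matrix, 2, min),
                        upper = apply(kept$matrix, 2, max),
                        row.names = NULL, stringsAsFactors = FALSE),
    resos_params = resos_result$params), class = "baseline_profile")
}

#' Constrain a model to a baseline profile envelope
#' @param model a [metabolic_model].
#' @param profile a `baseline_profile`.
#' @param reactions reaction ids to constrain (default: all profiled).
#' @return model copy with bounds set to the profile envelope.
#' @export
apply_profile <- function(model, profile, reactions = profile$bounds$id) {
  sel <- match(reactions, profile$bounds$id)
  if (anyNA(sel)) stop("profile missing reactions: ",
                       paste(reactions[is.na(sel)], collapse = ", "))
  idx <- reaction_index(model, reactions)
  model$reactions$lower_bound[idx] <- profile$bounds$lower[sel]
  model$reactions$upper_bound[idx] <- profile$bounds$upper[sel]
  validate_model(model)
  model
}

#' Patient-to-control concentration ratios (min / mean / max)
#'
#' `ratio_stat[m] = patient[m] / control_stat[m]` for each control
#' summary statistic. Zero control statistics are replaced by `eps`
#' with a warning (the ratio is undefined otherwise).
#'
#' @param cohort a [patient_cohort].
#' @param stats result of [control_stats()].
#' @param patient patient id (rowname of the patient table).
#' @param eps replacement for zero control statistics.
#' @return list of three named ratio vectors: `min`, `mean`, `max`.
#' @export
compute_ratios <- function(cohort, stats, patient, eps = 1e-6) {
  if (!patient %in% rownames(cohort$patient_table))
    stop("unknown patient '", patient, "'")
  conc <- cohort$patient_table[patient, ]
  if (any(conc < 0)) stop("negative concentration for patient ", patient)
  si <- match(cohort$metabolites, stats$metabolite)
  if (anyNA(si)) stop("control stats missing for some metabolites")
  out <- lapply(c(min = "min", mean = "mean", max = "max"), function(s) {
    denom <- stats[[s]][si]
    if (any(denom == 0)) {
      warning("zero control ", s, " replaced by eps for: ",
              paste(cohort$metabolites[denom == 0], collapse = ", "))
      denom[denom == 0] <- eps
    }
    stats::setNames(as.numeric(conc) / denom, cohort$metabolites)
  })
  out
}

#' Rescale one baseline boundary by a concentration ratio
#'
#' The boundary-update expression algebraically reduces to
#' `baseline_bound * ratio` for nonzero bounds; `audit = TRUE`
#' additionally evaluates the literal printed form
#' `b + (b/b) * b * (ratio - 1)` and checks agreement to 1e-12.
#'
#' @param baseline_bound finite flux bound.
#' @param ratio non-negative dimensionless ratio.
#' @param audit verify the unreduced expression agrees.
#' @return rescaled bound.
#' @export
rescale_boundary <- function(baseline_bound, ratio, audit = FALSE) {
  if (any(ratio < 0)) stop("ratio must be >= 0")
  out <- baseline_bound * ratio
  if (audit) {
    nz <- baseline_bound != 0
    lit <- baseline_bound[nz] +
      (baseline_bound[nz] / baseline_bound[nz]) * baseline_bound[nz] *
      (rep(ratio, length.out = length(baseline_bound))[nz] - 1)
    if (any(abs(lit - out[nz]) > 1e-12 * pmax(1, abs(out[nz]))))
      stop("audit failure: literal and reduced boundary forms disagree")
  }
  out
}

## One exchange's (lower, upper) pair: zero-flux baseline envelopes get
## the conventional (-10, +10) window before rescaling; inverted pairs
## (possible when an envelope straddles zero) are swapped and flagged.
rescale_bound_pair <- function(lower, upper, ratio, zero_window = 10) {
  flagged <- FALSE
  if (lower == 0 && upper == 0) {
    lower <- -zero_window; upper <- zero_window
  }
  lo <- rescale_boundary(lower, ratio)
  hi <- rescale_boundary(upper, ratio)
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp; flagged <- TRUE }
  list(lower = lo, upper = hi, swapped = flagged)
}

#' Build the minimum / mean / maximum patient model trio
#'
#' Three copies of the baseline-constrained model whose mapped exchange
#' bounds are rescaled by the patient's min-, mean- and max-control
#' ratios. The baseline characterization fixes the exchange-reaction
#' boundaries: all exchanges are first set to their baseline-profile
#' envelope (internal reactions keep the model bounds; the all-reaction
#' envelope is imposed later, at the consensus step), then mapped
#' exchanges are rescaled. Unmapped exchanges keep the baseline-profile
#' bounds; measured metabolites without a mapping raise a warning and
#' are left untouched.
#'
#' @param model baseline [metabolic_model].
#' @param profile `baseline_profile` of the baseline model.
#' @param cohort a [patient_cohort].
#' @param stats result of [control_stats()].
#' @param patient patient id.
#' @return named list of three models (`min`, `mean`, `max`); each
#'   carries attributes `feasible` (logical) and `swapped_bounds`
#'   (reaction ids whose rescaled pair was inverted).
#' @export
build_patient_trio <- function(model, profile, cohort, stats, patient) {
  ratios <- compute_ratios(cohort, stats, patient)
  base <- apply_profile(model, profile, find_exchange_reactions(model))
  mapped <- cohort$metabolite_map
  unmapped <- setdiff(cohort$metabolites, names(mapped))
  if (length(unmapped))
    warning("measured but unmapped metabolites left untouched: ",
            paste(unmapped, collapse = ", "))
  mapped <- mapped[names(mapped) %in% cohort$metabolites]
  bad <- setdiff(unname(mapped), model$reactions$id)
  if (length(bad))
    stop("mapped exchange id(s) not in model: ", paste(bad, collapse = ", "))
  lapply(ratios, function(rv) {
    m <- base
    swapped <- character()
    for (met in names(mapped)) {
      ex <- mapped[[met]]
      k <- reaction_index(m, ex)
      pr <- rescale_bound_pair(m$reactions$lower_bound[k],
                               m$reactions$upper_bound[k], rv[[met]])
      m$reactions$lower_bound[k] <- pr$lower
      m$reactions$upper_bound[k] <- pr$upper
      if (pr$swapped) swapped <- c(swapped, ex)
    }
    feasible <- !inherits(try(fba(m), silent = TRUE), "try-error")
    attr(m, "feasible") <- feasible
    attr(m, "swapped_bounds") <- swapped
    m
  })
}

#' Consensus patient model from the fused trio samples
#'
#' Concatenates the three trio sample sets, runs the density filtering
#' on the fusion, and sets each reaction's bounds to the min/max over
#' the retained fused solutions.
#'
#' @param model the (baseline-constrained) [metabolic_model] providing
#'   structure and reaction order.
#' @param trio_samples list of three [flux_sample_set]s over identical
#'   reaction ordering.
#' @param method density scoring method.
#' @param percentile optional saved percentile from the baseline run,
#'   reused instead of re-deriving the dynamic threshold (the saved
#'   sampling parameters exist for exactly this reuse; re-deriving per
#'   patient injects a random retained-fraction scale into every
#'   downstream task score).
#' @return list with `model` (consensus-constrained copy) and `resos`
#'   (the fusion `resos_result`).
#' @export
build_consensus_model <- function(model, trio_samples,
                                  method = "continuous",
                                  percentile = NULL) {
  ids <- trio_samples[[1]]$reaction_ids
  for (s in trio_samples)
    if (!identical(s$reaction_ids, ids))
      stop("trio sample sets have mismatched reaction ordering")
  if (!identical(ids, model$reactions$id))
    stop("sample reaction order does not match model")
  fused <- new_flux_sample_set(do.call(rbind, lapply(trio_samples,
                                                     function(s) s$matrix)),
                               ids, trio_samples[[1]]$seed, NA_character_)
  res <- resos(fused, method = method, percentile = percentile)
  kept <- filter_solutions(fused, res)
  m <- model
  m$reactions$lower_bound <- apply(kept$matrix, 2, min)
  m$reactions$upper_bound <- apply(kept$matrix, 2, max)
  validate_model(m)
  list(model = m, resos = res)
}

#' Read cohort tables from TSV/CSV
#'
#' @param patient_path,control_path delimited files, first column =
#'   patient/control id, remaining columns metabolites.
#' @param map_path optional two-column TSV (metabolite, exchange id).
#' @param groups_path optional two-column TSV (patient, group).
#' @param sep field separator (default tab).
#' @return a [patient_cohort].
#' @export
read_cohort <- function(patient_path, control_path, map_path = NULL,
                        groups_path = NULL, sep = "\t") {
  rd <- function(p) {
    d <- utils::read.table(p, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    m
  }
  map <- NULL
  if (!is.null(map_path)) {
    md <- utils::read.table(map_path, header = FALSE, sep = sep,
                            stringsAsFactors = FALSE)
    map <- stats::setNames(md[[2]], md[[1]])
  }
  gl <- NULL
  if (!is.null(groups_path)) {
    gd <- utils::read.table(groups_path, header = FALSE, sep = sep,
                            stringsAsFactors = FALSE)
    gl <- stats::setNames(gd[[2]], gd[[1]])
  }
  patient_cohort(rd(patient_path), rd(control_path), map, gl)
}

#' Write cohort tables as TSV
#' @param cohort a [patient_cohort].
#' @param dir output directory (created if needed).
#' @return paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wp <- function(m, f) {
    d <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wp(cohort$patient_table, "patients.tsv")
  wp(cohort$control_table, "controls.tsv")
  if (!is.null(cohort$metabolite_map))
    utils::write.table(data.frame(names(cohort$metabolite_map),
                                  cohort$metabolite_map),
                       file.path(dir, "metabolite_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(cohort$group_labels))
    utils::write.table(data.frame(names(cohort$group_labels),
                                  cohort$group_labels),
                       file.path(dir, "groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
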
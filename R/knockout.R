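#' @title Essentiality and synthetic-lethality screening
#' @description Single and paired reaction deletions are scored by a
#' choice of post-knockout flux predictor (plain FBA re-solve, a
#' ROOM-style minimal-change LP, or density-based resampling with saved
#' sampling parameters). A deletion is lethal when the predicted
#' biomass falls below a viability fraction (default 5%) of the
#' wild-type optimum. Candidate sets are pruned FastSL-style from a
#' parsimonious flux distribution.
#' @name knockout-module
NULL

#' Knockout scan configuration
#'
#' @param viability_fraction lethal threshold as a fraction of the
#'   wild-type optimum (strictly between 0 and 1; default 0.05).
#' @param exclude reaction classes excluded from scans: any of
#'   `"exchanges"`, `"objective"`.
#' @param predictor `"fba"`, `"room"` or `"resos"`.
#' @param resos_params saved [sampling_parameters] (resos predictor).
#' @param resos_batch,resos_max_points,seed resampling controls.
#' @param room_delta,room_epsilon ROOM flux band parameters.
#' @return a `knockout_config`.
#' @export
knockout_config <- function(viability_fraction = 0.05,
                            exclude = c("exchanges", "objective"),
                            predictor = c("fba", "room", "resos"),
                            resos_params = NULL, resos_batch = 200L,
                            resos_max_points = 2000L, seed = 1L,
                            room_delta = 0.03, room_epsilon = 0.001) {
  stopifnot(viability_fraction > 0, viability_fraction < 1)
  structure(list(viability_fraction = viability_fraction,
                 exclude = exclude, predictor = match.arg(predictor),
                 resos_params = resos_params, resos_batch = resos_batch,
                 resos_max_points = resos_max_points, seed = seed,
                 room_delta = room_delta, room_epsilon = room_epsilon),
            class = "knockout_config")
}

#' FastSL-style candidate pruning
#'
#' Reactions carrying non-negligible flux (|v| > 1e-9) in a
#' minimal-L1-norm optimal flux distribution ([pfba()]), minus the
#' excluded classes. A reaction with zero flux in that solution cannot
#' be singly essential.
#'
#' @param model a [metabolic_model].
#' @param config a [knockout_config].
#' @return character vector of candidate reaction ids.
#' @export
prune_candidates <- function(model, config = knockout_config()) {
  v <- pfba(model)$values
  ids <- names(v)[abs(v) > 1e-9]
  drop_excluded(ids, model, config)
}

drop_excluded <- function(ids, model, config) {
  if ("exchanges" %in% config$exclude)
    ids <- setdiff(ids, find_exchange_reactions(model))
  if ("objective" %in% config$exclude)
    ids <- setdiff(ids, model$objective_id)
  ids
}

## Predicted biomass after deleting `ids`, per the configured predictor.
predict_knockout_biomass <- function(model, ids, config, wild = NULL) {
  del <- delete_reactions(model, ids)
  if (config$predictor == "fba") {
    tryCatch(fba(del)$objective_value,
             error = function(e) 0)
  } else if (config$predictor == "room") {
    if (is.null(wild)) wild <- fba(model)
    room_reference_flux(model, ids, wild,
                        delta = config$room_delta,
                        epsilon = config$room_epsilon)$biomass
  } else {
    params <- config$resos_params
    if (is.null(params)) stop("resos predictor requires saved resos_params")
    ok <- tryCatch({ fba(del); TRUE }, error = function(e) FALSE)
    if (!ok) return(0)
    ss <- tryCatch(
      sample_adaptive(del, params, batch = config$resos_batch,
                      max_points = config$resos_max_points,
                      seed = config$seed),
      error = function(e) NULL)
    if (is.null(ss) || is.null(ss$resos)) {
      ## degenerate post-deletion space (all samples coincide): the
      ## unique point's biomass is the FBA optimum
      return(fba(del)$objective_value)
    }
    central <- ss$resos$central_index
    obj <- match(model$objective_id, ss$reaction_ids)
    ss$matrix[central, obj]
  }
}

#' Single-reaction essentiality scan
#'
#' A reaction is essential when the predicted post-deletion biomass is
#' below `viability_fraction` x wild-type optimum.
#'
#' @param model a [metabolic_model] with positive biomass optimum.
#' @param config a [knockout_config].
#' @param candidates reaction ids to scan (default:
#'   [prune_candidates()]).
#' @return data.frame `id`, `biomass`, `essential`; scan errors are
#'   recorded in attribute `errors` and the run continues.
#' @export
essentiality_scan <- function(model, config = knockout_config(),
                              candidates = NULL) {
  wt <- fba(model)
  if (wt$objective_value <= 0) stop("wild-type biomass optimum is not positive")
  thr <- config$viability_fraction * wt$objective_value
  if (is.null(candidates)) candidates <- prune_candidates(model, config)
  errs <- character()
  bm <- vapply(candidates, function(id) {
    r <- tryCatch(predict_knockout_biomass(model, id, config, wt),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errs <<- c(errs, paste0(id, ": ", conditionMessage(r)))
      return(NA_real_)
    }
    r
  }, 0)
  out <- data.frame(id = candidates, biomass = bm,
                    essential = !is.na(bm) & bm < thr,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "errors") <- errs
  attr(out, "wild_type_biomass") <- wt$objective_value
  out
}

#' Synthetic-lethal pair scan
#'
#' FastSL-style: for each non-essential candidate `i`, the deleted
#' model's parsimonious flux identifies newly active partner reactions
#' `j`; the unordered pair is synthetic lethal when the joint deletion
#' drops predicted biomass below threshold while neither single
#' deletion does. `full_enumeration = TRUE` tests all candidate pairs
#' instead.
#'
#' @param model a [metabolic_model].
#' @param config a [knockout_config].
#' @param full_enumeration enumerate all pairs of the candidate set.
#' @return data.frame with columns `rxn1`, `rxn2` (rxn1 < rxn2,
#'   sorted); the single-deletion scan is attached as attribute
#'   `singles`.
#' @export
synthetic_lethal_scan <- function(model, config = knockout_config(),
                                  full_enumeration = FALSE) {
  singles <- if (full_enumeration)
    essentiality_scan(model, config,
                      candidates = drop_excluded(model$reactions$id,
                                                 model, config))
  else essentiality_scan(model, config)
  ess <- singles$id[singles$essential]
  noness <- setdiff(singles$id, ess)
  wt <- fba(model)
  thr <- config$viability_fraction * wt$objective_value
  pairs <- list()
  seen <- character()
  consider <- function(i, j) {
    key <- paste(sort(c(i, j)), collapse = "|")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    bm <- tryCatch(predict_knockout_biomass(model, c(i, j), config, wt),
                   error = function(e) NA_real_)
    if (!is.na(bm) && bm < thr)
      pairs[[length(pairs) + 1L]] <<- sort(c(i, j))
  }
  if (full_enumeration) {
    if (length(noness) >= 2) {
      cmb <- utils::combn(sort(noness), 2)
      for (k in seq_len(ncol(cmb))) consider(cmb[1, k], cmb[2, k])
    }
  } else {
    for (i in noness) {
      del <- delete_reactions(model, i)
      v2 <- tryCatch(pfba(del)$values, error = function(e) NULL)
      if (is.null(v2)) next
      partners <- setdiff(
        drop_excluded(names(v2)[abs(v2) > 1e-9], model, config),
        c(ess, i))
      for (j in partners) consider(i, j)
    }
  }
  out <- if (length(pairs))
    unique(data.frame(rxn1 = vapply(pairs, `[`, "", 1),
                      rxn2 = vapply(pairs, `[`, "", 2),
                      stringsAsFactors = FALSE))
  else data.frame(rxn1 = character(), rxn2 = character(),
                  stringsAsFactors = FALSE)
  out <- out[order(out$rxn1, out$rxn2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "singles") <- singles
  out
}

#' ROOM-style minimal-change flux after deletion
#'
#' Linear relaxation of regulatory on/off minimization: find a feasible
#' flux of the deleted model minimizing the (relaxed) number of
#' reactions whose flux leaves the wild-type band
#' `w +/- (delta |w| + epsilon)`. Indicator variables are relaxed to
#' `[0, 1]`; `exact = TRUE` solves the true mixed-integer program by
#' branch-and-bound on the relaxation (practical for toy-scale models).
#'
#' @param model a [metabolic_model].
#' @param deleted_ids reaction ids to knock out (may be empty).
#' @param wild_type_flux a `flux_vector` for the intact model.
#' @param delta relative band half-width (default 0.03).
#' @param epsilon absolute band half-width (default 0.001).
#' @param exact solve the integer program exactly.
#' @return list: `flux` (named vector or `NULL`), `biomass`,
#'   `n_changed` (reactions outside their band), `objective` (relaxed
#'   or integer indicator sum), `status`.
#' @export
room_reference_flux <- function(model, deleted_ids, wild_type_flux,
                                delta = 0.03, epsilon = 0.001,
                                exact = FALSE) {
  rx <- if (length(deleted_ids)) delete_reactions(model, deleted_ids)$reactions
        else model$reactions
  w <- wild_type_flux$values
  n <- nrow(rx); m <- nrow(model$S)
  wu <- w + delta * abs(w) + epsilon
  wl <- w - delta * abs(w) - epsilon
  lb <- rx$lower_bound; ub <- rx$upper_bound
  ## v_i - y_i (ub_i - wu_i) <= wu_i ; v_i - y_i (lb_i - wl_i) >= wl_i
  A <- rbind(cbind(model$S, matrix(0, m, n)),
             cbind(diag(n), -diag(ub - wu)),
             cbind(diag(n), -diag(lb - wl)))
  rhs <- c(rep(0, m), wu, wl)
  dir <- c(rep("=", m), rep("<=", n), rep(">=", n))
  obj <- c(rep(0, n), rep(1, n))
  lbv <- c(lb, rep(0, n)); ubv <- c(ub, rep(1, n))
  solve_relax <- function(ylo, yhi) {
    lp_solve(obj, A, rhs, dir, c(lb, ylo), c(ub, yhi), maximize = FALSE)
  }
  base <- solve_relax(rep(0, n), rep(1, n))
  if (base$status != "optimal")
    return(list(flux = NULL, biomass = 0, n_changed = NA_integer_,
                objective = NA_real_, status = base$status))
  sol <- base
  if (exact) {
    best <- list(obj = Inf, sol = NULL)
    bnb <- function(ylo, yhi) {
      r <- solve_relax(ylo, yhi)
      if (r$status != "optimal" || r$objval >= best$obj - 1e-9) return()
      y <- r$x[n + seq_len(n)]
      frac <- which(y > 1e-6 & y < 1 - 1e-6)
      if (!length(frac)) {
        best <<- list(obj = r$objval, sol = r)
        return()
      }
      k <- frac[which.max(pmin(y[frac], 1 - y[frac]))]
      yl <- ylo; yh <- yhi
      yh[k] <- 0; bnb(yl, yh)           # y_k = 0 branch
      yl <- ylo; yh <- yhi
      yl[k] <- 1; bnb(yl, yh)           # y_k = 1 branch
    }
    bnb(rep(0, n), rep(1, n))
    if (!is.null(best$sol)) sol <- best$sol
  }
  v <- sol$x[seq_len(n)]
  names(v) <- rx$id
  band_tol <- 1e-6
  n_changed <- sum(v > wu + band_tol | v < wl - band_tol)
  obj_rxn <- match(model$objective_id, rx$id)
  list(flux = v, biomass = v[[obj_rxn]], n_changed = n_changed,
       objective = sol$objval, status = "optimal")
}

#' Map gene essentiality onto reactions through GPR rules
#'
#' Rules: a single-gene reaction is essential when its gene is; an OR
#' association (isozymes) is essential only when all alternatives are
#' essential; an AND association (complex) is essential when any
#' member is. Nested expressions are evaluated recursively with these
#' semantics.
#'
#' @param gpr_rules named character vector: reaction id -> rule string.
#' @param essential_genes character vector of essential gene ids.
#' @return character vector of essential reaction ids.
#' @export
map_gene_to_reaction_essentiality <- function(gpr_rules, essential_genes) {
  ess_node <- function(node) {
    if (!is.null(node$gene)) return(node$gene %in% essential_genes)
    vals <- vapply(node$args, ess_node, TRUE)
    if (node$op == "or") all(vals) else any(vals)
  }
  res <- vapply(names(gpr_rules), function(rid) {
    ast <- tryCatch(gpr_parse(gpr_rules[[rid]]),
                    error = function(e)
                      stop("reaction '", rid, "': ", conditionMessage(e)))
    if (is.null(ast)) FALSE else ess_node(ast)
  }, TRUE)
  names(gpr_rules)[res]
}

#' Contingency table and prediction ratio
#'
#' @param TP,TN,FP,FN non-negative counts.
#' @return a `contingency_table`.
#' @export
contingency_table <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0)) stop("contingency counts must be non-negative")
  structure(as.list(v), class = "contingency_table")
}

#' @describeIn contingency_table accuracy `(TP+TN)/(TP+TN+FP+FN)`.
#' @param table a `contingency_table`.
#' @export
prediction_ratio <- function(table) {
  tot <- table$TP + table$TN + table$FP + table$FN
  if (tot <= 0) stop("empty contingency table")
  (table$TP + table$TN) / tot
}

#' Contingency of predicted vs gold-standard sets
#'
#' @param predicted,gold character vectors of positives.
#' @param universe all evaluated items.
#' @return a `contingency_table`.
#' @export
compare_predictions <- function(predicted, gold, universe) {
  predicted <- intersect(predicted, universe)
  gold <- intersect(gold, universe)
  contingency_table(
    TP = length(intersect(predicted, gold)),
    TN = length(setdiff(setdiff(universe, predicted), gold)),
    FP = length(setdiff(predicted, gold)),
    FN = length(setdiff(gold, predicted)))
}

#' Read gold-standard gene or pair lists
#'
#' One gene per line, or one comma-separated gene pair per line;
#' `#` comments and blank lines ignored.
#' @param path text file.
#' @return character vector (pairs normalized to `"a,b"`, sorted).
#' @export
read_gold_standard <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  vapply(strsplit(ln, ","), function(p)
    paste(sort(trimws(p)), collapse = ","), "")
}
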
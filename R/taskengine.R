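#' @title Metabolic task analysis
#' @description A metabolic task asks whether (and how strongly) a model
#' can produce a set of product metabolites from a set of substrate
#' metabolites. Evaluation adds temporary uptake reactions for the
#' substrates and sink reactions for the products, then maximizes total
#' product sink flux by FBA. Patient-specific exchange bounds stay
#' active by default, so a task probes the patient's constrained
#' capability.
#' @name taskengine-module
NULL

#' Define a metabolic task
#'
#' @param id task identifier.
#' @param substrates named numeric vector: metabolite id -> maximum
#'   uptake flux (default 10 when `NA`).
#' @param products named numeric vector: metabolite id -> minimum
#'   production flux (>= 0).
#' @param description free text.
#' @return a `task_definition`.
#' @export
task_definition <- function(id, substrates = numeric(), products,
                            description = "") {
  if (length(products) == 0) stop("task '", id, "': products must be non-empty")
  substrates[is.na(substrates)] <- 10
  if (any(products < 0)) stop("task '", id, "': negative minimum production")
  structure(list(id = id, substrates = substrates, products = products,
                 description = description), class = "task_definition")
}

#' Load task definitions from JSON or TSV
#'
#' JSON: a list of objects with `id`, `substrates` (map metabolite ->
#' max uptake), `products` (map metabolite -> min production),
#' `description`. TSV: columns `task`, `role` (`substrate`/`product`),
#' `metabolite`, `flux`.
#'
#' @param path file path.
#' @return list of `task_definition`s.
#' @export
load_tasks <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    lapply(doc, function(t)
      task_definition(t$id,
                      substrates = unlist(t$substrates) %||% numeric(),
                      products = unlist(t$products),
                      description = t$description %||% ""))
  } else {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    lapply(split(d, d$task), function(g)
      task_definition(g$task[1],
        substrates = stats::setNames(g$flux[g$role == "substrate"],
                                     g$metabolite[g$role == "substrate"]),
        products = stats::setNames(g$flux[g$role == "product"],
                                   g$metabolite[g$role == "product"])))
  }
}

#' Evaluate one metabolic task on a model
#'
#' Temporary uptake columns (bounded by the stated maximum) supply the
#' substrates and sink columns drain the products; the objective is the
#' summed product sink flux. The input model is never mutated.
#'
#' @param model a [metabolic_model].
#' @param task a [task_definition].
#' @param closed_exchanges close all exchange reactions first
#'   (alternative convention; default keeps patient bounds active).
#' @return task score (flux, >= 0) with attribute `infeasible`.
#' @export
evaluate_task <- function(model, task, closed_exchanges = FALSE) {
  rx <- model$reactions
  if (closed_exchanges) {
    ex <- reaction_index(model, find_exchange_reactions(model))
    rx$lower_bound[ex] <- 0
    rx$upper_bound[ex] <- 0
  }
  mets <- c(names(task$substrates), names(task$products))
  mi <- match(mets, model$metabolites$id)
  if (anyNA(mi))
    stop("task '", task$id, "': unknown metabolite '", mets[is.na(mi)][1], "'")
  n <- nrow(rx); m <- nrow(model$S)
  ns <- length(task$substrates); np <- length(task$products)
  Aug <- matrix(0, m, ns + np)
  lb2 <- ub2 <- numeric(ns + np)
  for (i in seq_len(ns)) {
    Aug[match(names(task$substrates)[i], model$metabolites$id), i] <- 1
    lb2[i] <- 0; ub2[i] <- task$substrates[[i]]
  }
  for (i in seq_len(np)) {
    Aug[match(names(task$products)[i], model$metabolites$id), ns + i] <- -1
    lb2[ns + i] <- task$products[[i]]
    ub2[ns + i] <- 1e4
  }
  obj <- c(rep(0, n), rep(0, ns), rep(1, np))
  sol <- lp_solve(obj, cbind(model$S, Aug), rep(0, m), rep("=", m),
                  c(rx$lower_bound, lb2), c(rx$upper_bound, ub2),
                  maximize = TRUE)
  if (sol$status != "optimal")
    return(structure(0, infeasible = TRUE))
  structure(max(0, sol$objval), infeasible = FALSE)
}

#' Evaluate a task battery over patient models
#'
#' @param models named list: patient id -> [metabolic_model].
#' @param tasks list of [task_definition]s.
#' @param group_labels optional named vector patient -> group.
#' @param closed_exchanges see [evaluate_task()].
#' @return a `task_activity_matrix`: `values` (tasks x patients),
#'   `infeasible` flag matrix, `task_ids`, `patient_ids`,
#'   `group_labels`, `errors` (character, per-cell messages).
#' @export
evaluate_task_matrix <- function(models, tasks, group_labels = NULL,
                                 closed_exchanges = FALSE) {
  stopifnot(length(models) >= 1, length(tasks) >= 1)
  tid <- vapply(tasks, function(t) t$id, "")
  pid <- names(models)
  vals <- matrix(0, length(tasks), length(models),
                 dimnames = list(tid, pid))
  infl <- matrix(FALSE, length(tasks), length(models),
                 dimnames = list(tid, pid))
  errs <- character()
  for (j in seq_along(models)) for (i in seq_along(tasks)) {
    r <- tryCatch(evaluate_task(models[[j]], tasks[[i]], closed_exchanges),
                  error = function(e) e)
    if (inherits(r, "error")) {
      errs <- c(errs, paste0(tid[i], "/", pid[j], ": ", conditionMessage(r)))
      vals[i, j] <- 0; infl[i, j] <- TRUE
    } else {
      vals[i, j] <- as.numeric(r)
      infl[i, j] <- isTRUE(attr(r, "infeasible"))
    }
  }
  structure(list(values = vals, infeasible = infl, task_ids = tid,
                 patient_ids = pid, group_labels = group_labels,
                 errors = errs), class = "task_activity_matrix")
}

#' Select tasks whose activity rank shifts consistently across groups
#'
#' Task rows are standardized across all patients (z-score per row;
#' zero-variance rows become 0). Within each group, tasks are ranked by
#' the group mean of the standardized activity (rank 1 = most active,
#' ties by task order). A task is selected when its rank trajectory
#' along `group_order` moves consistently in one direction — monotone
#' up to a slack of `mono_tol` positions, since intermediate groups
#' oscillate and near-tied tasks inevitably swap adjacent ranks between
#' groups — and the first-to-last rank shift is at least `min_shift`
#' positions (inclusive).
#'
#' @param matrix a `task_activity_matrix`.
#' @param group_order group labels from lowest to highest severity.
#' @param min_shift minimum first-vs-last rank difference (default 10).
#' @param mono_tol tolerated counter-direction movement per step, in
#'   rank positions (0 = strictly one-directional).
#' @return character vector of selected task ids; the per-group rank
#'   table is attached as attribute `ranks`.
#' @export
rank_change_filter <- function(matrix, group_order, min_shift = 10L,
                               mono_tol = 3L) {
  stopifnot(length(group_order) >= 2, min_shift >= 0)
  gl <- matrix$group_labels
  if (is.null(gl)) stop("task matrix carries no group labels")
  Z <- row_standardize(matrix$values)
  ranks <- sapply(group_order, function(g) {
    cols <- which(gl[matrix$patient_ids] == g)
    if (length(cols) == 0) stop("no patients in group '", g, "'")
    if (length(cols) < 2)
      warning("group '", g, "' has fewer than 2 patients")
    gm <- rowMeans(Z[, cols, drop = FALSE])
    rank(-gm, ties.method = "first")
  })
  shift <- abs(ranks[, 1] - ranks[, ncol(ranks)])
  mono <- apply(ranks, 1, function(r) {
    d <- diff(r)
    all(d >= -mono_tol) || all(d <= mono_tol)
  })
  sel <- matrix$task_ids[mono & shift >= min_shift]
  attr(sel, "ranks") <- ranks
  sel
}

#' Write a task activity matrix as TSV
#' @param matrix a `task_activity_matrix`.
#' @param path output path.
#' @export
write_task_matrix_tsv <- function(matrix, path) {
  d <- data.frame(task = matrix$task_ids, matrix$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
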
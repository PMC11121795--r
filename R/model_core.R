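#' @title Genome-scale metabolic model container
#' @description A `metabolic_model` is a list with a reaction table
#' (id, name, bounds, gene-reaction rule, objective coefficient), a
#' metabolite table (id, name, compartment), the dense stoichiometric
#' matrix `S` (metabolites x reactions) and the id of the objective
#' reaction. Bounds are fluxes in mmol/gDW/h by convention; negative
#' exchange flux is uptake, positive is secretion.
#' @name metabolic_model
NULL

new_metabolic_model <- function(id, reactions, metabolites, S) {
  obj <- reactions$id[reactions$objective_coefficient != 0]
  m <- structure(list(id = id, reactions = reactions,
                      metabolites = metabolites, S = S,
                      objective_id = if (length(obj)) obj[[1]] else NA_character_),
                 class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks that bounds are ordered, every stoichiometric entry references
#' an existing metabolite, the objective reaction exists and `S` is
#' consistent with the reaction/metabolite tables.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with an informative error naming
#'   the offending record otherwise.
#' @export
validate_model <- function(model) {
  rx <- model$reactions
  bad <- which(rx$lower_bound > rx$upper_bound)
  if (length(bad))
    stop("reaction '", rx$id[bad[1]], "': lower_bound > upper_bound")
  if (anyDuplicated(rx$id))
    stop("duplicated reaction id '", rx$id[anyDuplicated(rx$id)], "'")
  if (anyDuplicated(model$metabolites$id))
    stop("duplicated metabolite id")
  if (!identical(dim(model$S),
                 c(nrow(model$metabolites), nrow(rx))))
    stop("S dimensions do not match metabolite/reaction counts")
  if (!all(is.finite(model$S))) stop("non-finite stoichiometry in S")
  if (is.na(model$objective_id) || !model$objective_id %in% rx$id)
    stop("objective reaction missing or not in model")
  invisible(model)
}

reaction_index <- function(model, ids) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx))
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  idx
}

#' Load a metabolic model from COBRA JSON or SBML L3/FBC
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @return a validated [metabolic_model].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

read_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$reactions) || is.null(doc$metabolites))
    stop("not a COBRA-dialect JSON model: ", path)
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, ""),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, ""),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "", ""),
    stringsAsFactors = FALSE)
  nr <- length(doc$reactions)
  rx <- data.frame(
    id = vapply(doc$reactions, function(r) r$id, ""),
    name = vapply(doc$reactions, function(r) r$name %||% r$id, ""),
    lower_bound = vapply(doc$reactions, function(r) {
      if (is.null(r$lower_bound)) stop("reaction '", r$id, "': missing lower_bound")
      as.numeric(r$lower_bound)
    }, 0),
    upper_bound = vapply(doc$reactions, function(r) {
      if (is.null(r$upper_bound)) stop("reaction '", r$id, "': missing upper_bound")
      as.numeric(r$upper_bound)
    }, 0),
    gene_reaction_rule = vapply(doc$reactions,
                                function(r) r$gene_reaction_rule %||% "", ""),
    objective_coefficient = vapply(doc$reactions,
                                   function(r) as.numeric(r$objective_coefficient %||% 0), 0),
    stringsAsFactors = FALSE)
  S <- matrix(0, nrow(mets), nr, dimnames = list(mets$id, rx$id))
  for (k in seq_len(nr)) {
    st <- doc$reactions[[k]]$metabolites
    if (is.null(st) || length(st) == 0)
      stop("reaction '", rx$id[k], "': missing or empty stoichiometry")
    mi <- match(names(st), mets$id)
    if (anyNA(mi))
      stop("reaction '", rx$id[k], "': unknown metabolite '",
           names(st)[is.na(mi)][1], "'")
    S[mi, k] <- vapply(st, as.numeric, 0)
  }
  new_metabolic_model(doc$id %||% basename(path), rx, mets, S)
}

#' Write a model as COBRA-dialect JSON
#' @param model a [metabolic_model].
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  rxl <- lapply(seq_len(nrow(model$reactions)), function(k) {
    r <- model$reactions[k, ]
    st <- model$S[, k]
    st <- st[st != 0]
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(st),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gene_reaction_rule)
    if (r$objective_coefficient != 0)
      out$objective_coefficient <- r$objective_coefficient
    out
  })
  metl <- lapply(seq_len(nrow(model$metabolites)), function(k) {
    m <- model$metabolites[k, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  jsonlite::write_json(list(id = model$id, metabolites = metl, reactions = rxl),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Identify exchange (boundary) reactions
#'
#' An exchange reaction involves exactly one metabolite; by convention
#' negative flux is uptake into the system, positive flux secretion.
#'
#' @param model a [metabolic_model].
#' @return character vector of reaction ids in model order.
#' @export
find_exchange_reactions <- function(model) {
  n_met <- colSums(model$S != 0)
  model$reactions$id[n_met == 1]
}

#' Content digest of a model
#'
#' Hash over reaction ids, bounds, stoichiometry and objective; used to
#' tie sample sets to the exact model they were drawn from.
#' @param model a [metabolic_model].
#' @return character md5 digest.
#' @export
model_digest <- function(model) {
  digest::digest(list(model$reactions$id, model$reactions$lower_bound,
                      model$reactions$upper_bound, model$metabolites$id,
                      as.vector(model$S), model$objective_id), algo = "md5")
}

#' Flux balance analysis
#'
#' Solves the steady-state LP optimize `c'v` s.t. `S v = 0`,
#' `lb <= v <= ub` with the built-in simplex.
#'
#' @param model a [metabolic_model].
#' @param sense `"max"` or `"min"`.
#' @return a `flux_vector`: list with named `values`, `objective_value`
#'   and solver `status`.
#' @export
fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  rx <- model$reactions
  obj <- rx$objective_coefficient
  sol <- lp_solve(obj, model$S, rep(0, nrow(model$S)),
                  rep("=", nrow(model$S)), rx$lower_bound, rx$upper_bound,
                  maximize = sense == "max")
  if (sol$status != "optimal") {
    stop(structure(class = c(paste0("exogem_", sol$status), "error", "condition"),
                   list(message = paste0("FBA ", sol$status, " for model '",
                                         model$id, "'"), call = sys.call())))
  }
  v <- sol$x
  names(v) <- rx$id
  structure(list(values = v, objective_value = sol$objval, status = sol$status),
            class = "flux_vector")
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum attainable flux, optionally holding
#' the objective at a fraction of its optimum.
#'
#' @param model a [metabolic_model].
#' @param reactions reaction ids (default: all).
#' @param fraction_of_optimum keep `c'v >= fraction * optimum` (0 = off).
#' @return data.frame with `id`, `min`, `max`.
#' @export
fva <- function(model, reactions = model$reactions$id,
                fraction_of_optimum = 0) {
  rx <- model$reactions
  A <- model$S
  rhs <- rep(0, nrow(A))
  dir <- rep("=", nrow(A))
  if (fraction_of_optimum > 0) {
    opt <- fba(model)$objective_value
    A <- rbind(A, rx$objective_coefficient)
    rhs <- c(rhs, fraction_of_optimum * opt - 1e-9)
    dir <- c(dir, ">=")
  }
  idx <- reaction_index(model, reactions)
  res <- lapply(idx, function(k) {
    e <- numeric(nrow(rx)); e[k] <- 1
    lo <- lp_solve(e, A, rhs, dir, rx$lower_bound, rx$upper_bound, maximize = FALSE)
    hi <- lp_solve(e, A, rhs, dir, rx$lower_bound, rx$upper_bound, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("FVA failed for reaction '", rx$id[k], "'")
    c(lo$objval, hi$objval)
  })
  data.frame(id = rx$id[idx],
             min = vapply(res, `[`, 0, 1),
             max = vapply(res, `[`, 0, 2),
             stringsAsFactors = FALSE)
}

#' Parsimonious FBA flux
#'
#' Fixes the objective at its optimum and minimizes total absolute flux
#' (L1 norm); used for FastSL-style candidate pruning.
#'
#' @param model a [metabolic_model].
#' @return a `flux_vector` with the minimal-L1 optimal flux.
#' @export
pfba <- function(model) {
  opt <- fba(model)$objective_value
  rx <- model$reactions
  n <- nrow(rx); m <- nrow(model$S)
  ## variables [v, t]; t_i >= |v_i|
  A <- rbind(cbind(model$S, matrix(0, m, n)),
             cbind(diag(n), -diag(n)),        # v - t <= 0
             cbind(-diag(n), -diag(n)),       # -v - t <= 0
             c(rx$objective_coefficient, rep(0, n)))
  rhs <- c(rep(0, m), rep(0, 2 * n), opt - 1e-7 * max(1, abs(opt)))
  dir <- c(rep("=", m), rep("<=", 2 * n), ">=")
  big <- max(1e3, max(abs(rx$lower_bound)), max(abs(rx$upper_bound)))
  sol <- lp_solve(c(rep(0, n), rep(1, n)), A, rhs, dir,
                  lb = c(rx$lower_bound, rep(0, n)),
                  ub = c(rx$upper_bound, rep(big, n)),
                  maximize = FALSE)
  if (sol$status != "optimal") stop("pFBA failed: ", sol$status)
  v <- sol$x[seq_len(n)]
  names(v) <- rx$id
  structure(list(values = v,
                 objective_value = sum(rx$objective_coefficient * v),
                 status = "optimal"), class = "flux_vector")
}

#' Enforce a minimum biomass production
#'
#' Sets the objective reaction's lower bound to `fraction` times the FBA
#' optimum (the activation floor used when characterizing baseline
#' models).
#'
#' @param model a [metabolic_model].
#' @param fraction ratio in `[0, 1]`.
#' @return modified copy of the model.
#' @export
set_biomass_floor <- function(model, fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  opt <- fba(model)$objective_value
  k <- reaction_index(model, model$objective_id)
  model$reactions$lower_bound[k] <- max(model$reactions$lower_bound[k],
                                        fraction * opt)
  validate_model(model)
  model
}

#' Knock out reactions by closing their bounds
#'
#' Sets `lb = ub = 0` for each id; the matrix shape is preserved so
#' sampling machinery can be reused on the deleted model.
#'
#' @param model a [metabolic_model].
#' @param ids reaction ids to delete.
#' @return modified copy.
#' @export
delete_reactions <- function(model, ids) {
  if (length(ids) == 0) return(model)
  idx <- reaction_index(model, ids)
  model$reactions$lower_bound[idx] <- 0
  model$reactions$upper_bound[idx] <- 0
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model>", x$id, "\n",
      nrow(x$reactions), "reactions,", nrow(x$metabolites), "metabolites,",
      length(find_exchange_reactions(x)), "exchanges; objective:",
      x$objective_id, "\n")
  invisible(x)
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> objective =", format(x$objective_value), "over",
      length(x$values), "reactions\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
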
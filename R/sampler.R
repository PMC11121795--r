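#' @title Flux sample sets
#' @description A `flux_sample_set` holds `N` sampled steady-state flux
#' vectors over the `R` reactions of one model: fields `matrix`
#' (N x R, columns named by reaction id), `reaction_ids`, `seed` and
#' `model_digest` (hash of the sampled model, see [model_digest()]).
#' @name flux_sample_set
NULL

new_flux_sample_set <- function(M, reaction_ids, seed, digest) {
  colnames(M) <- reaction_ids
  structure(list(matrix = M, reaction_ids = reaction_ids, seed = seed,
                 model_digest = digest), class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set>", nrow(x$matrix), "samples x",
      ncol(x$matrix), "reactions (seed", x$seed, ")\n")
  invisible(x)
}

## Orthogonal projector onto the null space of S (flux space), used to
## keep long hit-and-run chains on the steady-state subspace.
nullspace_projector <- function(S) {
  sv <- svd(S, nu = 0)
  keep <- sv$d > max(dim(S)) * max(sv$d, 0) * 1e-12
  V1 <- sv$v[, keep, drop = FALSE]
  diag(ncol(S)) - V1 %*% t(V1)
}

#' Generate warmup flux vectors spanning the feasible polytope
#'
#' Per-reaction maximization/minimization LPs (the classic warmup for
#' hit-and-run walkers), topped up with randomized-objective LPs when
#' `count` exceeds twice the reaction count.
#'
#' @param model a [metabolic_model].
#' @param count number of warmup points.
#' @param seed RNG seed for the randomized objectives.
#' @return a [flux_sample_set] of `count` feasible vertices.
#' @export
generate_warmup <- function(model, count = 2L * nrow(model$reactions),
                            seed = 1L) {
  rx <- model$reactions
  n <- nrow(rx); m <- nrow(model$S)
  rhs <- rep(0, m); dir <- rep("=", m)
  solve_obj <- function(w, maximize) {
    s <- lp_solve(w, model$S, rhs, dir, rx$lower_bound, rx$upper_bound,
                  maximize = maximize)
    if (s$status != "optimal")
      stop(structure(class = c("exogem_infeasible", "error", "condition"),
                     list(message = paste("infeasible model:", model$id),
                          call = sys.call())))
    s$x
  }
  set.seed(seed)
  pts <- vector("list", count)
  k <- 0L
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- 1
    for (mx in c(TRUE, FALSE)) {
      if (k >= count) break
      k <- k + 1L
      pts[[k]] <- solve_obj(e, mx)
    }
  }
  while (k < count) {
    k <- k + 1L
    pts[[k]] <- solve_obj(stats::rnorm(n), TRUE)
  }
  M <- do.call(rbind, pts[seq_len(count)])
  new_flux_sample_set(M, rx$id, seed, model_digest(model))
}

## warmup vertices depend only on the model for count <= 2n (they are
## per-reaction min/max LP solutions); cache them by content digest so
## repeated sampling of the same model skips ~2n LPs. The chain RNG
## state is re-seeded after retrieval, so results are bit-identical
## with and without a cache hit.
.warmup_cache <- new.env(parent = emptyenv())

achr_state <- function(model, seed, warmup_count = NULL, thin = 100L) {
  n <- nrow(model$reactions)
  if (is.null(warmup_count)) warmup_count <- 2L * n
  if (warmup_count <= 2L * n) {
    key <- paste0(model_digest(model), ":", warmup_count)
    W <- .warmup_cache[[key]]
    if (is.null(W)) {
      W <- generate_warmup(model, warmup_count, seed = seed)$matrix
      assign(key, W, envir = .warmup_cache)
    }
    set.seed(seed)
  } else {
    W <- generate_warmup(model, warmup_count, seed = seed)$matrix
  }
  e <- new.env(parent = emptyenv())
  e$W <- W
  e$center <- colMeans(W)
  e$x <- e$center
  e$lb <- model$reactions$lower_bound
  e$ub <- model$reactions$upper_bound
  e$proj <- nullspace_projector(model$S)
  e$thin <- as.integer(thin)
  e$n_kept <- 0L
  e
}

achr_draw <- function(state, n_points) {
  W <- state$W; lb <- state$lb; ub <- state$ub
  nw <- nrow(W); x <- state$x
  out <- matrix(0, n_points, ncol(W))
  for (s in seq_len(n_points)) {
    for (it in seq_len(state$thin)) {
      d <- W[sample.int(nw, 1L), ] - state$center
      nd <- sqrt(sum(d * d))
      if (nd < 1e-12) next
      d <- d / nd
      act <- which(abs(d) > 1e-11)
      if (!length(act)) next
      r1 <- (lb[act] - x[act]) / d[act]
      r2 <- (ub[act] - x[act]) / d[act]
      tmin <- max(pmin(r1, r2))
      tmax <- min(pmax(r1, r2))
      if (!is.finite(tmin) || !is.finite(tmax) || tmax - tmin < 1e-12) next
      x <- x + stats::runif(1, tmin, tmax) * d
    }
    x <- as.vector(state$proj %*% x)          # re-anchor on S v = 0
    x <- pmin(pmax(x, lb - 1e-9), ub + 1e-9)  # shave float excursions
    out[s, ] <- x
    ## running center update (artificially centered walker)
    state$n_kept <- state$n_kept + 1L
    state$center <- state$center +
      (x - state$center) / (nrow(W) + state$n_kept)
  }
  state$x <- x
  out
}

#' Sample steady-state flux vectors by hit-and-run
#'
#' Artificially centered hit-and-run over the flux polytope
#' `{v : S v = 0, lb <= v <= ub}`. Deterministic for a fixed seed and
#' model. The walker is pluggable desk-scale machinery behind the
#' sampling contract: every emitted row is feasible.
#'
#' @param model a [metabolic_model].
#' @param n_points number of retained samples (>= 1).
#' @param seed RNG seed.
#' @param thin chain steps per retained sample.
#' @param warmup_count warmup LP count (default 2x reactions).
#' @return a [flux_sample_set].
#' @export
sample_fluxes <- function(model, n_points, seed = 1L, thin = 100L,
                          warmup_count = NULL) {
  if (n_points < 1) stop("n_points must be >= 1")
  st <- achr_state(model, seed, warmup_count, thin)
  M <- achr_draw(st, n_points)
  new_flux_sample_set(M, model$reactions$id, seed, model_digest(model))
}

#' Saved sampling parameters
#'
#' The two quantities the density analysis stores for reuse on the same
#' network: the Euclidean distance between the central and furthest
#' retained solutions (`span`), the number of retained solutions
#' (`retained_count`), and the percentile that produced them.
#'
#' @param span non-negative flux-space distance.
#' @param retained_count integer >= 1.
#' @param percentile integer in 1..100.
#' @return a `sampling_parameters` object.
#' @export
sampling_parameters <- function(span, retained_count, percentile = NA_integer_) {
  stopifnot(span >= 0, retained_count >= 1,
            is.na(percentile) || (percentile >= 1 && percentile <= 100))
  structure(list(span = span, retained_count = retained_count,
                 percentile = as.integer(percentile)),
            class = "sampling_parameters")
}

#' Adaptive sampling against saved parameters
#'
#' Samples in batches and, after each batch, applies the density
#' filtering to the accumulated set; stops once the retained count
#' reaches `params$retained_count` and the central-furthest span is
#' within `span_tol` (relative) of `params$span`, or once `max_points`
#' is reached (the returned set then carries `budget_exhausted = TRUE`).
#' A saved span of zero degenerates to the count condition alone.
#'
#' @param model a [metabolic_model].
#' @param params a [sampling_parameters] from a prior density run.
#' @param batch samples added per round.
#' @param max_points sampling budget.
#' @param seed RNG seed.
#' @param method density scoring method, `"continuous"` or `"discrete"`.
#' @param span_tol relative span tolerance (default 5%).
#' @return a [flux_sample_set] with fields `budget_exhausted` and
#'   `resos` (the final [resos_result]).
#' @export
sample_adaptive <- function(model, params, batch = 500L, max_points = 50000L,
                            seed = 1L, method = "continuous",
                            span_tol = 0.05) {
  if (max_points < batch) stop("max_points must be >= batch")
  st <- achr_state(model, seed, NULL, 100L)
  M <- NULL
  exhausted <- TRUE
  res <- NULL
  while (is.null(M) || nrow(M) < max_points) {
    nb <- min(batch, max_points - if (is.null(M)) 0L else nrow(M))
    M <- rbind(M, achr_draw(st, nb))
    if (nrow(M) < 10L) next
    ss <- new_flux_sample_set(M, model$reactions$id, seed, model_digest(model))
    res <- resos(ss, method = method)
    ok_count <- res$params$retained_count >= params$retained_count
    ok_span <- if (params$span <= 0) TRUE else
      abs(res$params$span - params$span) / max(params$span, 1e-12) <= span_tol
    if (ok_count && ok_span) { exhausted <- FALSE; break }
  }
  out <- new_flux_sample_set(M, model$reactions$id, seed, model_digest(model))
  out$budget_exhausted <- exhausted
  out$resos <- res
  out
}

#' Check sample feasibility against a model
#'
#' @param samples a [flux_sample_set].
#' @param model the sampled [metabolic_model].
#' @param tol_sv steady-state tolerance on `|S v|`.
#' @param tol_bound bound tolerance.
#' @return logical vector, one entry per sample row.
#' @export
samples_feasible <- function(samples, model, tol_sv = 1e-6, tol_bound = 1e-9) {
  M <- samples$matrix
  resid <- abs(model$S %*% t(M))
  ok_sv <- apply(resid, 2, max) <= tol_sv
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  ok_b <- apply(M, 1, function(v) all(v >= lb - tol_bound & v <= ub + tol_bound))
  ok_sv & ok_b
}

#' Write / read a sample set as TSV (header = reaction ids)
#' @param samples a [flux_sample_set].
#' @param path TSV path; a JSON sidecar `<path>.json` stores seed/digest.
#' @export
write_samples_tsv <- function(samples, path) {
  utils::write.table(samples$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = samples$seed,
                            model_digest = samples$model_digest),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_samples_tsv
#' @export
read_samples_tsv <- function(path) {
  M <- as.matrix(utils::read.delim(path, check.names = FALSE))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else
    list(seed = NA_integer_, model_digest = NA_character_)
  new_flux_sample_set(M, colnames(M), meta$seed, meta$model_digest)
}
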
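#' @title Exchange-perturbation sensitivity analysis
#' @description Each measured exchange is swept across its bounds (100
#' evenly spaced fixations by default) while every metabolic task is
#' re-evaluated, yielding a response table per (patient, metabolite).
#' Responses are min-max rescaled on both axes and summarized by an
#' ordinary least-squares slope, producing a tasks x metabolites x
#' patients sensitivity cube that is flattened for PLS-DA.
#' @name sensitivity-module
NULL

#' Sweep one exchange reaction across its bounds
#'
#' For each of `n_steps` evenly spaced values `v` in `[lb, ub]` of the
#' exchange, the exchange is fixed (`lb = ub = v`) and every task is
#' evaluated; infeasible points are recorded as missing. The input
#' model is left untouched.
#'
#' @param model a [metabolic_model].
#' @param exchange_id exchange reaction id.
#' @param tasks list of [task_definition]s.
#' @param n_steps grid size (>= 2; a degenerate `lb == ub` exchange
#'   yields a single-point sweep with a warning).
#' @return a `perturbation_sweep`: `grid` (flux values), `values`
#'   (steps x tasks matrix, NA = infeasible), `exchange_id`.
#' @export
perturbation_sweep <- function(model, exchange_id, tasks, n_steps = 100L) {
  k <- reaction_index(model, exchange_id)
  lb <- model$reactions$lower_bound[k]
  ub <- model$reactions$upper_bound[k]
  if (ub - lb < 1e-12) {
    warning("exchange '", exchange_id, "' is fixed; single-point sweep")
    grid <- lb
  } else {
    stopifnot(n_steps >= 2)
    grid <- seq(lb, ub, length.out = n_steps)
  }
  tid <- vapply(tasks, function(t) t$id, "")
  vals <- matrix(NA_real_, length(grid), length(tasks),
                 dimnames = list(NULL, tid))
  for (s in seq_along(grid)) {
    m <- model
    m$reactions$lower_bound[k] <- grid[s]
    m$reactions$upper_bound[k] <- grid[s]
    feas <- tryCatch({ fba(m); TRUE },
                     error = function(e) FALSE)
    if (!feas) next
    for (i in seq_along(tasks)) {
      r <- evaluate_task(m, tasks[[i]])
      vals[s, i] <- if (isTRUE(attr(r, "infeasible"))) NA_real_
                    else as.numeric(r)
    }
  }
  structure(list(grid = grid, values = vals, exchange_id = exchange_id),
            class = "perturbation_sweep")
}

#' Task response slopes from a sweep
#'
#' Both the perturbation axis and each task response are min-max
#' rescaled to `[0, 1]` over the feasible points, then an ordinary
#' least-squares slope is fitted. Constant responses and tasks with
#' fewer than `min_points` feasible points yield slope 0 (flagged).
#'
#' @param sweep a `perturbation_sweep`.
#' @param min_points minimum feasible points for a fit (default 10).
#' @return named slope vector (one per task) with attribute `flagged`
#'   (logical: degenerate or under-supported fits).
#' @export
response_slope <- function(sweep, min_points = 10L) {
  x0 <- sweep$grid
  out <- numeric(ncol(sweep$values))
  flag <- logical(ncol(sweep$values))
  for (i in seq_len(ncol(sweep$values))) {
    y <- sweep$values[, i]
    ok <- !is.na(y)
    if (sum(ok) < max(2L, min_points)) { flag[i] <- TRUE; next }
    x <- x0[ok]; yy <- y[ok]
    rx <- diff(range(x)); ry <- diff(range(yy))
    if (rx < 1e-12 || ry < 1e-12) { flag[i] <- TRUE; next }
    xs <- (x - min(x)) / rx
    ys <- (yy - min(yy)) / ry
    out[i] <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sum((xs - mean(xs))^2)
  }
  names(out) <- colnames(sweep$values)
  attr(out, "flagged") <- stats::setNames(flag, colnames(sweep$values))
  out
}

#' Build the tasks x metabolites x patients sensitivity cube
#'
#' @param models named list patient -> constrained [metabolic_model].
#' @param metabolite_map named vector metabolite -> exchange id.
#' @param tasks list of [task_definition]s.
#' @param n_steps sweep grid size.
#' @param min_points passed to [response_slope()].
#' @return a `sensitivity_cube`: 3-d `values` array with dimnames
#'   (task, metabolite, patient) and a parallel `n_feasible` array.
#' @export
build_cube <- function(models, metabolite_map, tasks, n_steps = 100L,
                       min_points = 10L) {
  tid <- vapply(tasks, function(t) t$id, "")
  mets <- names(metabolite_map)
  pid <- names(models)
  vals <- array(NA_real_, c(length(tid), length(mets), length(pid)),
                dimnames = list(tid, mets, pid))
  nfeas <- array(0L, dim(vals), dimnames = dimnames(vals))
  for (p in seq_along(models)) for (j in seq_along(mets)) {
    sw <- perturbation_sweep(models[[p]], metabolite_map[[j]], tasks,
                             n_steps)
    vals[, j, p] <- response_slope(sw, min_points)
    nfeas[, j, p] <- colSums(!is.na(sw$values))
  }
  structure(list(values = vals, n_feasible = nfeas,
                 task_ids = tid, metabolites = mets, patient_ids = pid),
            class = "sensitivity_cube")
}

#' Flatten a sensitivity cube to patients x (tasks * metabolites)
#'
#' Task-major, metabolite-minor column ordering: column
#' `(t-1) * n_metabolites + m` holds task `t` x metabolite `m`, named
#' `"task|metabolite"`.
#'
#' @param cube a `sensitivity_cube` (or plain 3-d array).
#' @return numeric matrix, one row per patient.
#' @export
flatten_cube <- function(cube) {
  a <- if (inherits(cube, "sensitivity_cube")) cube$values else cube
  dn <- dimnames(a)
  nt <- dim(a)[1]; nm <- dim(a)[2]; np <- dim(a)[3]
  out <- matrix(NA_real_, np, nt * nm,
                dimnames = list(dn[[3]], paste(
                  rep(dn[[1]], each = nm), rep(dn[[2]], nt), sep = "|")))
  for (t in seq_len(nt)) for (m in seq_len(nm))
    out[, (t - 1L) * nm + m] <- a[t, m, ]
  out
}

#' Restore a flattened matrix to a cube (inverse of [flatten_cube()])
#' @param mat flattened patients x features matrix.
#' @param task_ids,metabolites axis labels in flattening order.
#' @return 3-d array (task x metabolite x patient).
#' @export
unflatten_cube <- function(mat, task_ids, metabolites) {
  nt <- length(task_ids); nm <- length(metabolites)
  stopifnot(ncol(mat) == nt * nm)
  a <- array(NA_real_, c(nt, nm, nrow(mat)),
             dimnames = list(task_ids, metabolites, rownames(mat)))
  for (t in seq_len(nt)) for (m in seq_len(nm))
    a[t, m, ] <- mat[, (t - 1L) * nm + m]
  a
}

#' Partial least squares discriminant analysis (NIPALS PLS2)
#'
#' X is column-wise z-scored (zero-variance features dropped with a
#' warning), labels are one-hot encoded and centered, and latent
#' components are extracted iteratively with deflation. Feature
#' relevance is ranked by summed absolute X-loadings over the leading
#' components.
#'
#' @param X patients x features matrix.
#' @param labels group label per row (>= 2 groups).
#' @param n_components number of latent components.
#' @return a `plsda_result`: `scores`, `x_loadings`, `x_weights`,
#'   `y_loadings`, `explained_y_variance`, `group_labels`,
#'   `features`.
#' @export
plsda <- function(X, labels, n_components = 2L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("PLS-DA needs at least 2 groups")
  sds <- apply(X, 2, stats::sd)
  drop <- sds < 1e-12 | is.na(sds)
  if (any(drop)) {
    warning("dropping ", sum(drop), " zero-variance feature(s)")
    X <- X[, !drop, drop = FALSE]
  }
  Xs <- scale(X)
  Y <- stats::model.matrix(~ 0 + factor(labels))
  colnames(Y) <- levels(factor(labels))
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n_components <- min(n_components, nrow(Xs) - 1L, ncol(Xs))
  ss_y_tot <- sum(Y^2)
  Tm <- matrix(0, nrow(Xs), n_components)
  P <- matrix(0, ncol(Xs), n_components,
              dimnames = list(colnames(Xs), NULL))
  W <- P
  Q <- matrix(0, ncol(Y), n_components)
  expl <- numeric(n_components)
  Xc <- Xs; Yc <- Y
  for (a in seq_len(n_components)) {
    u <- Yc[, which.max(colSums(Yc^2))]
    t_old <- rep(Inf, nrow(Xc))
    for (it in seq_len(500L)) {
      w <- crossprod(Xc, u); w <- w / sqrt(sum(w^2))
      tt <- Xc %*% w
      q <- crossprod(Yc, tt) / sum(tt^2)
      u <- Yc %*% q / sum(q^2)
      if (sqrt(sum((tt - t_old)^2)) < 1e-10 * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    p <- crossprod(Xc, tt) / sum(tt^2)
    ss_before <- sum(Yc^2)
    Xc <- Xc - tt %*% t(p)
    Yc <- Yc - tt %*% t(q)
    expl[a] <- (ss_before - sum(Yc^2)) / ss_y_tot
    Tm[, a] <- tt; P[, a] <- p; W[, a] <- w; Q[, a] <- q
  }
  rownames(Tm) <- rownames(X)
  structure(list(scores = Tm, x_loadings = P, x_weights = W,
                 y_loadings = Q, explained_y_variance = expl,
                 group_labels = labels, features = colnames(Xs)),
            class = "plsda_result")
}

#' Rank features by summed absolute loadings
#' @param fit a `plsda_result`.
#' @param n_components leading components to sum over (default: all).
#' @return named numeric vector sorted decreasing.
#' @export
plsda_feature_ranking <- function(fit, n_components = ncol(fit$x_loadings)) {
  k <- min(n_components, ncol(fit$x_loadings))
  sc <- rowSums(abs(fit$x_loadings[, seq_len(k), drop = FALSE]))
  sort(sc, decreasing = TRUE)
}

#' Two-component PCA separation check
#'
#' Centered PCA of pooled samples with model-of-origin labels; returns
#' the first two component scores and the mean silhouette width of the
#' labels in that plane (how distinctly the pooled trio clouds
#' separate).
#'
#' @param M pooled samples matrix (rows = samples).
#' @param labels origin label per row (>= 2 distinct).
#' @return list `scores` (n x 2), `silhouette` (mean width).
#' @export
pca_check <- function(M, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 origin labels")
  if (nrow(M) < 3) stop("fewer samples than components")
  keep <- apply(M, 2, stats::sd) > 1e-12
  pc <- stats::prcomp(M[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  sc <- pc$x[, 1:2, drop = FALSE]
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(sc))
  list(scores = sc, silhouette = mean(sil[, "sil_width"]))
}

#' Write a sensitivity cube as per-patient TSVs plus a JSON manifest
#' @param cube a `sensitivity_cube`.
#' @param dir output directory.
#' @export
write_cube <- function(cube, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in cube$patient_ids) {
    d <- data.frame(task = cube$task_ids, cube$values[, , p],
                    check.names = FALSE)
    utils::write.table(d, file.path(dir, paste0(p, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(list(tasks = cube$task_ids,
                            metabolites = cube$metabolites,
                            patients = cube$patient_ids),
                       file.path(dir, "axes.json"), auto_unbox = TRUE)
  invisible(dir)
}
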
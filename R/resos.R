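#' @title Density exploration of the sampled flux solution space
#' @description Tools for locating the densest region of a set of
#' sampled flux solutions: per-solution density scores (continuous
#' pairwise-distance sums or discrete per-reaction histogram
#' frequencies), identification of the central and furthest solutions,
#' a dynamic percentile threshold placed at the inflection of the
#' span-versus-percentile curve, and filtering of the retained set.
#' @name resos-module
NULL

#' Euclidean distance between two flux vectors
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a-b)^2))`.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("flux vectors differ in length (", length(a), " vs ", length(b), ")")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite flux values")
  sqrt(sum((a - b)^2))
}

## Blockwise per-solution distance totals: totals[i] = sum_j d(i, j).
## O(N^2) work but bounded memory.
distance_totals <- function(M, block = NULL) {
  N <- nrow(M)
  if (is.null(block)) block <- max(1L, floor(2e7 / N))
  sq <- rowSums(M * M)
  totals <- numeric(N)
  i <- 1L
  while (i <= N) {
    j <- min(N, i + block - 1L)
    G <- M[i:j, , drop = FALSE] %*% t(M)
    D2 <- outer(sq[i:j], sq, "+") - 2 * G
    D2[D2 < 0] <- 0
    ## the Gram expansion cancels catastrophically for near-coincident
    ## points; recompute those few pairs from the direct difference
    close <- which(D2 < 1e-4, arr.ind = TRUE)
    if (nrow(close)) {
      D2[close] <- rowSums((M[i - 1L + close[, 1L], , drop = FALSE] -
                              M[close[, 2L], , drop = FALSE])^2)
    }
    totals[i:j] <- rowSums(sqrt(D2))
    i <- j + 1L
  }
  totals
}

#' Score sampled solutions by local density
#'
#' Continuous method: `totals[i]` is the sum of Euclidean distances from
#' solution `i` to every other solution (column sums of the symmetric
#' distance matrix); smaller totals mean denser surroundings. Discrete
#' method: each reaction's flux values are binned into `bins` histogram
#' bins normalized to unit area, and `totals[i]` is the summed bin
#' frequency (count/N) over reactions of the bins containing solution
#' `i`; larger totals mean denser surroundings.
#'
#' @param samples a [flux_sample_set] (N >= 2).
#' @param method `"continuous"` or `"discrete"`.
#' @param bins histogram bins per reaction (discrete method).
#' @return a `density_scores` object: `totals`, `normalized`
#'   (totals / grand sum), `method`, and for the discrete method a
#'   `histograms` list.
#' @export
score_solutions <- function(samples, method = c("continuous", "discrete"),
                            bins = 100L) {
  method <- match.arg(method)
  M <- samples$matrix
  N <- nrow(M)
  if (N < 2) stop("need at least 2 samples to score")
  if (method == "continuous") {
    totals <- distance_totals(M)
    gs <- sum(totals)
    if (gs <= 0)
      stop("degenerate normalization: all samples identical (grand sum 0)")
    scores <- list(totals = totals, normalized = totals / gs,
                   method = method, bins = NA_integer_)
  } else {
    R <- ncol(M)
    totals <- numeric(N)
    hists <- vector("list", R)
    for (r in seq_len(R)) {
      v <- M[, r]
      lo <- min(v); hi <- max(v)
      if (hi - lo < 1e-12) {
        freq <- 1
        idx <- rep(1L, N)
        br <- c(lo, lo)
        dens <- NA_real_
      } else {
        br <- seq(lo, hi, length.out = bins + 1L)
        idx <- findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
        cnt <- tabulate(idx, nbins = bins)
        freq <- cnt / N
        dens <- freq / diff(br)          # unit-area histogram
      }
      hists[[r]] <- list(breaks = br, freq = freq, density = dens)
      totals <- totals + freq[idx]
    }
    scores <- list(totals = totals, normalized = totals / sum(totals),
                   method = method, bins = as.integer(bins),
                   histograms = hists)
  }
  structure(scores, class = "density_scores")
}

#' Index of the central solution
#'
#' The solution in the densest surroundings: smallest distance total
#' (continuous) or largest summed bin frequency (discrete). Ties break
#' to the smallest index.
#' @param scores a `density_scores` object.
#' @return integer solution index.
#' @export
find_central <- function(scores) {
  if (scores$method == "continuous") which.min(scores$totals)
  else which.max(scores$totals)
}

#' Index of the furthest solution (sparsest surroundings)
#' @param scores a `density_scores` object.
#' @return integer solution index.
#' @export
find_furthest <- function(scores) {
  if (scores$method == "continuous") which.max(scores$totals)
  else which.min(scores$totals)
}

## Outlyingness: monotone score where larger = more outlying, so the
## same percentile machinery serves both methods.
outlyingness <- function(scores) {
  if (scores$method == "continuous") scores$totals else -scores$totals
}

## Centered moving average with symmetric edge shrinkage (a centered
## mean of a linear sequence is the sequence itself, so exactly linear
## curves stay linear).
moving_average <- function(x, window = 5L) {
  h <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    hi <- min(h, i - 1L, n - i)
    mean(x[(i - hi):(i + hi)])
  }, 0)
}

## Inflection of the span-vs-percentile curve. The window-5 moving
## average alone proved noise-dominated on sampled data (its raw second
## difference flips sign almost everywhere), so the smoothed curve is
## fit with a cubic smoothing spline and its analytic second derivative
## is analyzed:
##   1. If the curve has a DOMINANT concavity change -- a zero crossing
##      of d2 away from the curve ends whose flanking curvature peaks
##      reach at least 30% of the maximum curvature -- the crossing
##      midpoint is chosen (a clean sigmoidal curve lands here).
##   2. Otherwise the curve is treated as one-signed (convex growth
##      toward the outlier tail) and the knee is used: the percentile
##      of maximum deviation from the chord joining the curve's
##      endpoints (fallback, flagged).
##   3. An exactly linear or constant curve has no knee: percentile
##      100, flagged.
find_inflection <- function(spans, window = 5L) {
  s <- moving_average(spans, window)
  n <- length(s)
  if (stats::sd(s) < 1e-12) return(list(percentile = 100L, warning = TRUE))
  fit <- stats::smooth.spline(seq_len(n), s, df = min(8, n - 1))
  d2 <- stats::predict(fit, seq_len(n), deriv = 2)$y
  win <- max(3L, round(0.03 * n)):min(n - 3L, round(0.97 * n))
  mxw <- max(abs(d2[win]))
  scale_ok <- is.finite(mxw) && mxw >= 1e-10 * max(1, max(abs(s)))
  if (scale_ok) {
    sg <- sign(d2)
    sg[abs(d2) < 1e-3 * mxw] <- 0
    nz <- intersect(which(sg != 0), win)
    best <- list(p = NA_integer_, signif = -Inf)
    if (length(nz) > 1) for (k in 2:length(nz)) {
      i <- nz[k - 1L]; j <- nz[k]
      if (sg[i] == sg[j]) next
      signif <- min(max(abs(d2[win[1]:i])), max(abs(d2[j:win[length(win)]])))
      if (signif > best$signif)
        best <- list(p = as.integer((i + j) %/% 2L), signif = signif)
    }
    if (is.finite(best$signif) && best$signif >= 0.3 * mxw)
      return(list(percentile = best$p, warning = FALSE))
  }
  ## knee fallback: farthest point below/above the endpoint chord
  chord <- s[1] + (s[n] - s[1]) * (seq_len(n) - 1) / (n - 1)
  dev <- abs(s - chord)
  if (max(dev) < 1e-9 * max(1, max(abs(s))))
    return(list(percentile = 100L, warning = TRUE))
  list(percentile = as.integer(which.max(dev)), warning = TRUE)
}

#' Dynamic non-arbitrary percentile threshold
#'
#' For every percentile p in 1..100, solutions with outlyingness at or
#' below the p-th percentile are retained; the span (Euclidean distance
#' between the central solution and the furthest retained solution) and
#' the retained count are recorded. The span-versus-percentile curve is
#' smoothed (moving average, window 5) and the chosen percentile is the
#' first sign change of its second finite difference — the point past
#' which admitting further solutions mostly admits outliers. With no
#' sign change the percentile of maximum curvature is used, else 100,
#' with a warning flag.
#'
#' @param samples a [flux_sample_set] with N >= 10.
#' @param scores matching `density_scores` (computed if missing).
#' @param window smoothing window for the span curve.
#' @param percentile optional saved percentile from a prior run on the
#'   same network; when given, the inflection search is skipped and the
#'   saved threshold is applied (the protocol's parameter reuse for
#'   case-specific and knockout analyses).
#' @return a `resos_result`: `central_index`, `furthest_index`,
#'   `percentile`, `retained_indices`, `params`
#'   ([sampling_parameters]), `curve` (percentile/retained/span table),
#'   `method`, `fallback_warning`.
#' @export
dynamic_percentile <- function(samples, scores = NULL, window = 5L,
                               percentile = NULL) {
  M <- samples$matrix
  N <- nrow(M)
  if (N < 10) stop("dynamic percentile needs at least 10 samples")
  if (is.null(scores)) scores <- score_solutions(samples)
  out <- outlyingness(scores)
  central <- find_central(scores)
  thr <- stats::quantile(out, (1:100) / 100, type = 7, names = FALSE)
  retained <- integer(100)
  spans <- numeric(100)
  for (p in 1:100) {
    keep <- which(out <= thr[p])
    retained[p] <- length(keep)
    if (length(keep) == 0) { spans[p] <- 0; next }
    f <- keep[which.max(out[keep])]
    spans[p] <- pairwise_distance(M[central, ], M[f, ])
  }
  infl <- if (is.null(percentile)) find_inflection(spans, window)
          else list(percentile = as.integer(percentile), warning = FALSE)
  p <- infl$percentile
  keep <- which(out <= thr[p])
  structure(list(
    central_index = central,
    furthest_index = find_furthest(scores),
    percentile = p,
    retained_indices = keep,
    params = sampling_parameters(spans[p], retained[p], p),
    curve = data.frame(percentile = 1:100, retained = retained,
                       span = spans),
    method = scores$method,
    fallback_warning = infl$warning), class = "resos_result")
}

#' Keep only the retained dense-region solutions
#' @param samples the [flux_sample_set] the result was computed from.
#' @param result a `resos_result`.
#' @return a [flux_sample_set] of the retained rows.
#' @export
filter_solutions <- function(samples, result) {
  idx <- result$retained_indices
  if (any(idx < 1 | idx > nrow(samples$matrix)))
    stop("internal consistency error: retained index out of range")
  if (!result$central_index %in% idx)
    stop("internal consistency error: central solution not retained")
  if (length(idx) != result$curve$retained[result$percentile])
    stop("internal consistency error: retained count mismatch with curve")
  out <- new_flux_sample_set(samples$matrix[idx, , drop = FALSE],
                             samples$reaction_ids, samples$seed,
                             samples$model_digest)
  out
}

#' Full density-exploration pass over a sample set
#'
#' Convenience wrapper: scores the solutions, applies the dynamic
#' percentile and returns the `resos_result`.
#' @inheritParams score_solutions
#' @param window smoothing window for the span curve.
#' @param percentile optional saved percentile (see
#'   [dynamic_percentile()]).
#' @return a `resos_result`.
#' @export
resos <- function(samples, method = c("continuous", "discrete"),
                  bins = 100L, window = 5L, percentile = NULL) {
  method <- match.arg(method)
  dynamic_percentile(samples, score_solutions(samples, method, bins),
                     window, percentile)
}

#' @export
print.resos_result <- function(x, ...) {
  cat("<resos_result>", x$method, "method; percentile", x$percentile,
      if (x$fallback_warning) "(fallback)" else "", "\n  retained",
      length(x$retained_indices), "solutions; span",
      format(x$params$span), "\n")
  invisible(x)
}

#' Serialize / read a resos_result as JSON
#' @param result a `resos_result`.
#' @param path output JSON path; the curve table is also written as
#'   `<path>.curve.tsv` for plotting.
#' @export
write_resos_json <- function(result, path) {
  jsonlite::write_json(list(
    central_index = result$central_index,
    furthest_index = result$furthest_index,
    percentile = result$percentile,
    retained_indices = result$retained_indices,
    params = unclass(result$params),
    method = result$method,
    fallback_warning = result$fallback_warning,
    curve = result$curve), path, auto_unbox = TRUE, digits = NA)
  utils::write.table(result$curve, paste0(path, ".curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
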
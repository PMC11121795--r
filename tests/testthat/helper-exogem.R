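## Shared fixtures and independent oracles for the test suite.

toy <- make_toy_model()
TOY_OPTIMUM <- 125 / 17  # hand-derived LP optimum, confirmed by an
                         # independent solver on the shipped fixture

## Independent LP oracle: brute-force basic-solution enumeration for
## max c'v s.t. S v = 0, lb <= v <= ub (finite bounds). Exponential --
## usable only at toy scale. Deliberately shares no code with lp_solve.
brute_lp_max <- function(obj, S, lb, ub, tol = 1e-7) {
  n <- length(obj); m <- nrow(S)
  qrS <- qr(S)
  m_eff <- qrS$rank
  best <- -Inf
  ## a vertex has >= n - m_eff variables at a bound; enumerate bases
  combos <- utils::combn(n, m_eff)
  for (ci in seq_len(ncol(combos))) {
    basis <- combos[, ci]
    nb <- setdiff(seq_len(n), basis)
    B <- S[, basis, drop = FALSE]
    if (qr(B)$rank < m_eff) next
    Bq <- qr(B)
    grid <- if (length(nb) == 0) matrix(logical(), 1, 0)
            else as.matrix(expand.grid(rep(list(c(FALSE, TRUE)),
                                           length(nb))))
    for (gi in seq_len(nrow(grid))) {
      xN <- ifelse(grid[gi, ], ub[nb], lb[nb])
      rhs <- -as.vector(S[, nb, drop = FALSE] %*% xN)
      xB <- tryCatch(qr.coef(Bq, rhs), error = function(e) NULL)
      if (is.null(xB) || anyNA(xB)) next
      x <- numeric(n); x[basis] <- xB; x[nb] <- xN
      if (any(x < lb - tol) || any(x > ub + tol)) next
      if (max(abs(S %*% x)) > 1e-6) next
      val <- sum(obj * x)
      if (val > best) best <- val
    }
  }
  best
}

## Brute-force per-solution distance totals (O(N^2) double loop).
brute_totals <- function(M) {
  N <- nrow(M)
  tot <- numeric(N)
  for (i in seq_len(N)) for (j in seq_len(N))
    tot[i] <- tot[i] + sqrt(sum((M[i, ] - M[j, ])^2))
  tot
}

## Build a flux_sample_set directly from a matrix.
as_samples <- function(M, ids = paste0("r", seq_len(ncol(M)))) {
  exogem:::new_flux_sample_set(as.matrix(M), ids, 1L, NA_character_)
}

## Pure box model (k uncoupled reactions): S has one all-zero row, so
## the feasible set is exactly the bound box.
box_model <- function(lb, ub) {
  k <- length(lb)
  rx <- data.frame(id = paste0("r", seq_len(k)), name = paste0("r", seq_len(k)),
                   lower_bound = lb, upper_bound = ub,
                   gene_reaction_rule = "",
                   objective_coefficient = c(1, rep(0, k - 1)),
                   stringsAsFactors = FALSE)
  mets <- data.frame(id = "m1", name = "m1", compartment = "c",
                     stringsAsFactors = FALSE)
  S <- matrix(0, 1, k, dimnames = list("m1", rx$id))
  exogem:::new_metabolic_model("box", rx, mets, S)
}

## Two-reaction chain: R1 makes X, R2 consumes X; flux range [-5, 5].
chain_model <- function() {
  rx <- data.frame(id = c("R1", "R2"), name = c("R1", "R2"),
                   lower_bound = c(-5, -5), upper_bound = c(5, 5),
                   gene_reaction_rule = "",
                   objective_coefficient = c(0, 1),
                   stringsAsFactors = FALSE)
  mets <- data.frame(id = "X", name = "X", compartment = "c",
                     stringsAsFactors = FALSE)
  S <- matrix(c(1, -1), 1, 2, dimnames = list("X", rx$id))
  exogem:::new_metabolic_model("chain", rx, mets, S)
}

## Exhaustive knockout oracles (direct delete + re-solve; no pruning).
exhaustive_essentials <- function(model, frac = 0.05) {
  wt <- fba(model)$objective_value
  internal <- setdiff(model$reactions$id,
                      c(find_exchange_reactions(model), model$objective_id))
  ess <- character()
  for (id in internal) {
    bm <- tryCatch(fba(delete_reactions(model, id))$objective_value,
                   error = function(e) 0)
    if (bm < frac * wt) ess <- c(ess, id)
  }
  sort(ess)
}

exhaustive_sl <- function(model, frac = 0.05) {
  wt <- fba(model)$objective_value
  internal <- setdiff(model$reactions$id,
                      c(find_exchange_reactions(model), model$objective_id))
  ess <- exhaustive_essentials(model, frac)
  cand <- setdiff(internal, ess)
  out <- list()
  cmb <- utils::combn(sort(cand), 2)
  for (k in seq_len(ncol(cmb))) {
    bm <- tryCatch(fba(delete_reactions(model, cmb[, k]))$objective_value,
                   error = function(e) 0)
    if (bm < frac * wt) out[[length(out) + 1L]] <- cmb[, k]
  }
  do.call(rbind, out)
}
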
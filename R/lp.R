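#' Solve a linear program with bounded variables
#'
#' Dense two-phase primal simplex for problems of the form
#' optimize `c'x` subject to `A x (<=, =, >=) b` and `lb <= x <= ub`.
#' All lower bounds must be finite; upper bounds may be `Inf`.
#' This is the solver behind [fba()], parsimonious flux minimization,
#' ROOM-style knockout prediction and task evaluation. It is dimensioned
#' for desk-scale metabolic models (hundreds of variables), not for
#' large-scale production LPs.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n); may have zero rows.
#' @param rhs right-hand side (length m).
#' @param dir character vector of row senses: `"<="`, `">="` or `"="`.
#' @param lb,ub variable bounds; `lb` finite, `ub` may be `Inf`.
#' @param maximize logical; minimizes when `FALSE`.
#' @param tol pivot/feasibility tolerance.
#' @param max_iter simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `x` (length n) and `objval`.
#' @export
lp_solve <- function(obj, A, rhs, dir = rep("=", length(rhs)), lb, ub,
                     maximize = TRUE, tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  A <- as.matrix(A)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(rhs) == m, length(dir) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb))) stop("lp_solve requires finite lower bounds")
  if (any(lb > ub + 1e-12)) return(list(status = "infeasible", x = NULL,
                                        objval = NA_real_))

  ## slacks for inequality rows
  ns <- sum(dir != "=")
  if (ns > 0) {
    Sl <- matrix(0, m, ns)
    k <- 0L
    for (i in seq_len(m)) {
      if (dir[i] == "=") next
      k <- k + 1L
      Sl[i, k] <- if (dir[i] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    obj <- c(obj, rep(0, ns))
    lb <- c(lb, rep(0, ns))
    ub <- c(ub, rep(Inf, ns))
  }
  res <- simplex_bounded(if (maximize) obj else -obj, A, rhs, lb, ub,
                         tol = tol, max_iter = max_iter)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    list(status = "optimal", x = x,
         objval = sum(obj[seq_len(n)] * x) * 1)
  } else {
    list(status = res$status, x = NULL, objval = NA_real_)
  }
}

## Core bounded-variable simplex: max c'x, A x = b, l <= x <= u.
## Nonbasic variables sit at a bound; statuses: 1 = lower, 2 = upper.
simplex_bounded <- function(cc, A, b, l, u, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) { # pure box problem
    x <- ifelse(cc > 0, u, l)
    x[cc == 0] <- l[cc == 0]
    if (any(!is.finite(x))) return(list(status = "unbounded"))
    return(list(status = "optimal", x = x))
  }
  ## phase 1 artificials
  x0 <- l
  r <- b - as.vector(A %*% x0)
  sg <- ifelse(r >= 0, 1, -1)
  Aa <- cbind(A, diag(sg, m))
  la <- c(l, rep(0, m))
  ua <- c(u, rep(Inf, m))
  nt <- n + m
  basis <- n + seq_len(m)
  status <- rep(1L, nt)          # all real vars at lower bound
  fixed <- (ua - la) <= 1e-12    # cannot move; never let them enter

  run_phase <- function(cvec, basis, status, start_iter) {
    iter <- start_iter
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "iteration_limit"))
      nonbasic <- setdiff(seq_len(nt), basis)
      xN <- ifelse(status[nonbasic] == 1L, la[nonbasic], ua[nonbasic])
      B <- Aa[, basis, drop = FALSE]
      Binv_ok <- TRUE
      xB <- tryCatch(solve(B, b - as.vector(Aa[, nonbasic, drop = FALSE] %*% xN)),
                     error = function(e) { Binv_ok <<- FALSE; NULL })
      if (!Binv_ok) return(list(status = "singular"))
      y <- solve(t(B), cvec[basis])
      dN <- cvec[nonbasic] - as.vector(t(Aa[, nonbasic, drop = FALSE]) %*% y)
      improving <- (status[nonbasic] == 1L & dN > tol) |
                   (status[nonbasic] == 2L & dN < -tol)
      improving[fixed[nonbasic]] <- FALSE
      if (!any(improving)) {
        x <- numeric(nt); x[basis] <- xB; x[nonbasic] <- xN
        return(list(status = "optimal", x = x, basis = basis,
                    statusv = status, iter = iter))
      }
      cand <- which(improving)
      if (iter - start_iter > 3L * nt) {       # Bland anti-cycling
        j_rel <- cand[which.min(nonbasic[cand])]
      } else {
        j_rel <- cand[which.max(abs(dN[cand]))]
      }
      j <- nonbasic[j_rel]
      sigma <- if (status[j] == 1L) 1 else -1
      w <- solve(B, Aa[, j])
      delta <- -sigma * w                       # xB change per unit t
      tmax <- Inf; leave <- 0L; leave_to <- 1L
      for (i in seq_len(m)) {
        if (delta[i] < -tol) {
          ti <- (xB[i] - la[basis[i]]) / (-delta[i])
          if (ti < tmax - 1e-15) { tmax <- ti; leave <- i; leave_to <- 1L }
        } else if (delta[i] > tol) {
          if (is.finite(ua[basis[i]])) {
            ti <- (ua[basis[i]] - xB[i]) / delta[i]
            if (ti < tmax - 1e-15) { tmax <- ti; leave <- i; leave_to <- 2L }
          }
        }
      }
      t_bnd <- ua[j] - la[j]
      if (is.finite(t_bnd) && t_bnd <= tmax) {  # bound flip
        status[j] <- if (status[j] == 1L) 2L else 1L
        next
      }
      if (!is.finite(tmax)) return(list(status = "unbounded"))
      ## pivot: j enters, basis[leave] leaves to bound leave_to
      status[basis[leave]] <- leave_to
      basis[leave] <- j
      status[j] <- 0L
    }
  }

  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, status, 0L)
  if (!identical(p1$status, "optimal")) return(list(status = p1$status))
  art <- p1$x[n + seq_len(m)]
  if (sum(art) > 1e-7) return(list(status = "infeasible"))
  ## freeze artificials at zero for phase 2
  ua[n + seq_len(m)] <- 0
  la[n + seq_len(m)] <- 0
  fixed[n + seq_len(m)] <- TRUE
  c2 <- c(cc, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$statusv, 0L)
  if (!identical(p2$status, "optimal")) return(list(status = p2$status))
  list(status = "optimal", x = p2$x[seq_len(n)])
}
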
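# Linear programming for flux balance problems.
#
# The flux polytopes here are small (tens of reactions) but frequently
# degenerate: many bounds are active at the optimum and whole rows of the
# stoichiometric matrix are linearly dependent. The solver below is a dense
# two-phase primal simplex using Bland's rule throughout, which guarantees
# termination (no cycling) at the cost of speed that would matter only on
# problems orders of magnitude larger than a desk-scale network.

# Solve max c'x s.t. A x = b, x >= 0.
# Returns list(status = "optimal"|"infeasible"|"unbounded", x, value).
simplex_bland <- function(A, b, c, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  # tableau: m x (n + m artificials + 1 rhs)
  T <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)

  pivot <- function(T, pr, pc) {
    T[pr, ] <- T[pr, ] / T[pr, pc]
    for (i in seq_len(nrow(T))) {
      if (i != pr && abs(T[i, pc]) > 0) T[i, ] <- T[i, ] - T[i, pc] * T[pr, ]
    }
    T
  }

  run_phase <- function(T, basis, obj_cols, obj) {
    # obj: objective coefficients over columns of T (excluding rhs), maximised
    repeat {
      cb <- obj[basis]
      # reduced costs c_j - z_j over allowed columns
      red <- obj[obj_cols] - as.vector(cb %*% T[, obj_cols, drop = FALSE])
      ent_rel <- which(red > tol)
      if (length(ent_rel) == 0) return(list(T = T, basis = basis, status = "optimal"))
      ent <- obj_cols[min(ent_rel)]                       # Bland: smallest index
      col <- T[, ent]
      pos <- which(col > tol)
      if (length(pos) == 0) return(list(T = T, basis = basis, status = "unbounded"))
      ratios <- T[pos, ncol(T)] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      pr <- cand[which.min(basis[cand])]                  # Bland tie-break
      T <- pivot(T, pr, ent)
      basis[pr] <- ent
    }
  }

  # phase 1: minimise sum of artificials == maximise -sum
  obj1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(T, basis, seq_len(n + m), obj1)
  T <- ph1$T; basis <- ph1$basis
  art_val <- sum(T[basis > n, ncol(T)])
  if (art_val > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = rep(NA_real_, n), value = NA_real_))
  }
  # drive remaining (degenerate) artificials out of the basis
  for (i in which(basis > n)) {
    row <- T[i, seq_len(n)]
    pc <- which(abs(row) > tol)
    if (length(pc) > 0) {
      T <- pivot(T, i, pc[1])
      basis[i] <- pc[1]
    }
  }
  keep_rows <- basis <= n
  T <- T[keep_rows, , drop = FALSE]
  basis <- basis[keep_rows]

  # phase 2 on the original columns only
  obj2 <- c(c, rep(0, m))
  ph2 <- run_phase(T, basis, seq_len(n), obj2)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), value = NA_real_))
  }
  T <- ph2$T; basis <- ph2$basis
  x <- rep(0, n)
  x[basis] <- T[, ncol(T)]
  list(status = "optimal", x = x, value = sum(c * x))
}

#' Solve a bounded linear program
#'
#' Maximises (or minimises) `obj %*% v` subject to `S %*% v = 0` and
#' `lb <= v <= ub` — the steady-state flux balance problem, with `S` the
#' stoichiometric matrix (metabolites x reactions) and `v` the flux vector.
#'
#' Variables are shifted to `x = v - lb >= 0` and upper bounds become slack
#' rows, giving a standard-form program solved by a two-phase primal
#' simplex with Bland's anti-cycling rule. Infinite bounds are clamped to a
#' large finite box (`big`), safe because flux bounds in this package are
#' finite multiples of `b_max`.
#'
#' @param S numeric matrix, metabolites x reactions.
#' @param lb,ub numeric vectors of lower/upper bounds per reaction.
#' @param obj numeric objective coefficients per reaction.
#' @param maximize logical; maximise (default) or minimise.
#' @param big finite stand-in for infinite bounds.
#'
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` (numeric, `NA` unless optimal) and `flux` (numeric vector,
#'   named as the columns of `S`).
#' @keywords internal
lp_solve_bounded <- function(S, lb, ub, obj, maximize = TRUE, big = 1e6) {
  stopifnot(is.matrix(S), ncol(S) == length(lb), length(lb) == length(ub),
            length(obj) == length(lb))
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_,
                flux = stats::setNames(rep(NA_real_, ncol(S)), colnames(S))))
  }
  n <- length(lb)
  u <- ub - lb
  # standard form over z = [x, s]: S x = -S lb ; x + s = u ; z >= 0
  A <- rbind(cbind(S, matrix(0, nrow(S), n)),
             cbind(diag(n), diag(n)))
  b <- c(as.vector(-S %*% lb), u)
  cc <- c(if (maximize) obj else -obj, rep(0, n))
  res <- simplex_bland(A, b, cc)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_,
                flux = stats::setNames(rep(NA_real_, n), colnames(S))))
  }
  flux <- stats::setNames(res$x[seq_len(n)] + lb, colnames(S))
  list(status = "optimal",
       objective = sum(obj * flux),
       flux = flux)
}
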
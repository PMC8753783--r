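#' Solve a linear program with a two-phase simplex
#'
#' Minimises `obj %*% x` subject to `mat %*% x (dir) rhs` and `x >= 0`,
#' where `dir` is "<=", ">=" or "=" per row. A dense full-tableau two-phase
#' primal simplex: Dantzig pricing with a switch to Bland's rule after a
#' burn-in to guarantee termination on degenerate problems. Returns a basic
#' (vertex) optimal solution together with the dual value of every row —
#' both are load-bearing downstream: shadow-price sensitivity needs exact
#' duals, and the foods-equal-binding-constraints property only holds at a
#' vertex.
#'
#' Diet problems are small (tens of rows, at most a few hundred columns), so
#' a dense tableau is the right tool; no sparse machinery is used.
#'
#' @param obj Objective coefficients (length n).
#' @param mat Constraint matrix (m x n).
#' @param dir Character vector of row directions: "<=", ">=" or "=".
#' @param rhs Right-hand sides (length m).
#' @param tol Feasibility/pivot tolerance.
#' @param max_iter Iteration cap across both phases.
#' @return A list: `status` ("optimal", "infeasible" or "unbounded"), `x`
#'   (primal solution), `objective`, `duals` (length m, on the scale
#'   d objective / d rhs), and `basis` (column indices of the final basis).
#' @export
lp_solve <- function(obj, mat, dir, rhs, tol = 1e-9, max_iter = 20000L) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  stopifnot(length(obj) == n, length(rhs) == m, length(dir) == m)
  if (!all(dir %in% c("<=", ">=", "="))) stop("dir must be <=, >= or =")

  # normalise to b >= 0, remembering sign flips for the dual scale
  flip <- rhs < 0
  mat[flip, ] <- -mat[flip, , drop = FALSE]
  rhs[flip] <- -rhs[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]

  slack_sign <- ifelse(dir == "<=", 1, ifelse(dir == ">=", -1, 0))
  n_slack <- sum(slack_sign != 0)
  S <- matrix(0, m, n_slack)
  slack_of_row <- integer(m)
  j <- 0L
  for (i in seq_len(m)) {
    if (slack_sign[i] != 0) {
      j <- j + 1L
      S[i, j] <- slack_sign[i]
      slack_of_row[i] <- n + j
    }
  }
  # artificials for rows without a natural basic column (>= and = rows)
  art_rows <- which(slack_sign <= 0)
  n_art <- length(art_rows)
  Art <- matrix(0, m, n_art)
  for (k in seq_along(art_rows)) Art[art_rows[k], k] <- 1
  A <- cbind(mat, S, Art)
  N <- ncol(A)
  art_cols <- if (n_art) (n + n_slack + 1L):N else integer(0)

  basis <- integer(m)
  basis[slack_sign == 1] <- slack_of_row[slack_sign == 1]
  basis[art_rows] <- art_cols

  # phase 1: drive artificial infeasibility to zero
  c1 <- numeric(N); c1[art_cols] <- 1
  st <- simplex_iterate(A, rhs, c1, basis, allowed = seq_len(N),
                        tol = tol, max_iter = max_iter)
  if (st$status == "iteration_limit") stop("simplex iteration limit reached")
  if (st$objective > 1e-7) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                duals = NULL, basis = NULL))
  }
  # pivot zero-level artificials out of the basis where possible
  T2 <- st$tableau; basis <- st$basis
  for (i in seq_len(m)) {
    if (basis[i] %in% art_cols) {
      cand <- setdiff(which(abs(T2[i, seq_len(n + n_slack)]) > tol), basis)
      if (length(cand)) {
        T2 <- pivot_tableau(T2, i, cand[1])
        basis[i] <- cand[1]
      }
    }
  }

  # phase 2: original objective, artificial columns barred from entering
  c2 <- c(obj, numeric(n_slack), numeric(n_art))
  st2 <- simplex_iterate(A, rhs, c2, basis, allowed = seq_len(n + n_slack),
                         tol = tol, max_iter = max_iter,
                         tableau = T2)
  if (st2$status == "iteration_limit") stop("simplex iteration limit reached")
  if (st2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = -Inf,
                duals = NULL, basis = NULL))
  }
  basis <- st2$basis
  x_full <- numeric(N)
  x_full[basis] <- st2$tableau[, N + 1L]
  x <- x_full[seq_len(n)]
  # duals from the final basis: y' B = c_B'
  B <- A[, basis, drop = FALSE]
  y <- solve(t(B), c2[basis])
  y[flip] <- -y[flip]
  list(status = "optimal", x = x, objective = sum(obj * x),
       duals = as.numeric(y), basis = basis)
}

# One simplex run on an explicit tableau. `tableau`, if supplied, must be
# consistent with `basis` (rows already expressed in that basis).
simplex_iterate <- function(A, b, cost, basis, allowed, tol, max_iter,
                            tableau = NULL) {
  m <- nrow(A); N <- ncol(A)
  if (is.null(tableau)) {
    tableau <- cbind(A, b)
    for (i in seq_len(m)) tableau <- pivot_tableau(tableau, i, basis[i])
  }
  bland_after <- 2L * (m + N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) {
      return(list(status = "iteration_limit", tableau = tableau,
                  basis = basis, objective = NA_real_))
    }
    y <- solve(t(A[, basis, drop = FALSE]), cost[basis])
    red <- cost[allowed] - as.numeric(crossprod(A[, allowed, drop = FALSE], y))
    neg <- which(red < -tol)
    if (!length(neg)) {
      obj <- sum(cost[basis] * tableau[, N + 1L])
      return(list(status = "optimal", tableau = tableau, basis = basis,
                  objective = obj))
    }
    enter <- if (iter > bland_after) {
      allowed[neg[1L]]                      # Bland: smallest index
    } else {
      allowed[neg[which.min(red[neg])]]     # Dantzig: most negative
    }
    col <- tableau[, enter]
    pos <- which(col > tol)
    if (!length(pos)) {
      return(list(status = "unbounded", tableau = tableau, basis = basis,
                  objective = -Inf))
    }
    ratios <- tableau[pos, N + 1L] / col[pos]
    rmin <- min(ratios)
    tie <- pos[ratios <= rmin + tol * max(1, rmin)]
    leave <- tie[which.min(basis[tie])]     # Bland-compatible tie-break
    tableau <- pivot_tableau(tableau, leave, enter)
    basis[leave] <- enter
  }
}

pivot_tableau <- function(tableau, row, col) {
  piv <- tableau[row, col]
  if (abs(piv) < .Machine$double.eps * 100) stop("numerically singular pivot")
  tableau[row, ] <- tableau[row, ] / piv
  other <- setdiff(seq_len(nrow(tableau)), row)
  tableau[other, ] <- tableau[other, , drop = FALSE] -
    outer(tableau[other, col], tableau[row, ])
  tableau
}

#' Brute-force LP oracle by vertex enumeration
#'
#' Independent check for [lp_solve()] on small instances: enumerates every
#' candidate vertex (each choice of n active constraints among the m rows
#' plus the n non-negativity constraints), keeps the feasible ones, and
#' returns the minimum objective. Exponential in problem size; intended for
#' a handful of variables.
#'
#' @inheritParams lp_solve
#' @param feas_tol Feasibility slack allowed when screening vertices.
#' @return A list with `status` ("optimal" or "infeasible"), `objective`
#'   and `x` (an optimal vertex).
#' @export
lp_enumerate <- function(obj, mat, dir, rhs, feas_tol = 1e-7) {
  mat <- as.matrix(mat)
  m <- nrow(mat); n <- ncol(mat)
  Afull <- rbind(mat, diag(n))           # rows m+1..m+n are x_j = 0
  bfull <- c(rhs, numeric(n))
  best <- NULL
  combos <- utils::combn(m + n, n)
  scale <- pmax(1, abs(rhs))
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    Ak <- Afull[idx, , drop = FALSE]
    if (abs(det(Ak)) < 1e-12) next
    x <- tryCatch(solve(Ak, bfull[idx]), error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x))) next
    if (any(x < -feas_tol)) next
    lhs <- as.numeric(mat %*% x)
    ok <- all(
      ifelse(dir == "<=", lhs <= rhs + feas_tol * scale,
             ifelse(dir == ">=", lhs >= rhs - feas_tol * scale,
                    abs(lhs - rhs) <= feas_tol * scale))
    )
    if (!ok) next
    val <- sum(obj * x)
    if (is.null(best) || val < best$objective) {
      best <- list(status = "optimal", objective = val, x = pmax(x, 0))
    }
  }
  if (is.null(best)) list(status = "infeasible", objective = NA_real_, x = NULL)
  else best
}
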
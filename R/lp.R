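# Dense two-phase bounded-variable primal simplex.
#
# All flux-balance LPs in this package are small (toy fixtures and modest
# merged models), so a dense tableau-free revised simplex with an explicit
# solve() per iteration is adequate and keeps the package free of external
# solver dependencies. Bland's rule is used throughout, which guarantees
# termination and makes every result deterministic.

.LP_TOL <- 1e-9
.LP_BIG <- 1e9

#' Solve a bounded-variable linear program
#'
#' Minimizes or maximizes `obj %*% x` subject to equality and inequality
#' constraints and box bounds `lb <= x <= ub`. This is the numerical core
#' behind [fba()], [fva()] and [gimme_extract()].
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (dense or sparse), one row per constraint.
#' @param sense character vector of constraint senses, one of `"="`, `"<="`,
#'   `">="` per row.
#' @param rhs numeric right-hand side vector.
#' @param lb,ub numeric bound vectors; infinite entries are capped at
#'   `1e9` in absolute value (documented behaviour, adequate for flux
#'   models whose conventional bounds are +-1000).
#' @param direction `"max"` or `"min"`.
#' @return list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution vector, `NA` unless optimal) and
#'   `objval`.
#' @export
lp_solve <- function(obj, A, sense, rhs, lb, ub, direction = c("max", "min")) {
  direction <- match.arg(direction)
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(sense) == m,
            length(lb) == n, length(ub) == n)
  if (any(lb > ub + .LP_TOL)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  lb <- pmax(lb, -.LP_BIG)
  ub <- pmin(ub, .LP_BIG)

  # slacks for inequality rows
  ineq <- which(sense != "=")
  ns <- length(ineq)
  if (ns > 0) {
    Sl <- matrix(0, m, ns)
    for (k in seq_along(ineq)) {
      Sl[ineq[k], k] <- if (sense[ineq[k]] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    obj <- c(obj, rep(0, ns))
    lb <- c(lb, rep(0, ns))
    ub <- c(ub, rep(.LP_BIG, ns))
  }
  ntot <- n + ns

  cvec <- if (direction == "max") -obj else obj

  res <- .simplex_bounded(cvec, A, rhs, lb, ub)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    objval <- sum(obj[seq_len(n)] * x)
    list(status = "optimal", x = x, objval = objval)
  } else {
    list(status = res$status, x = rep(NA_real_, n), objval = NA_real_)
  }
}

# Core bounded simplex: minimize c'x s.t. A x = b, l <= x <= u (finite).
.simplex_bounded <- function(cvec, A, b, l, u) {
  m <- nrow(A); n <- ncol(A)
  # shift to y = x - l, 0 <= y <= w
  w <- u - l
  b0 <- b - as.vector(A %*% l)
  # flip rows so rhs >= 0
  neg <- b0 < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b0[neg] <- -b0[neg]
  }
  # artificial variables
  Afull <- cbind(A, diag(m))
  wfull <- c(w, rep(Inf, m))
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, n + m)   # status of nonbasic variables

  phase_cost <- c(rep(0, n), rep(1, m))
  r1 <- .simplex_iterate(phase_cost, Afull, b0, wfull, basis, at_upper)
  if (r1$status == "unbounded") stop("internal error: phase-1 unbounded")
  y <- r1$y
  if (sum(y[n + seq_len(m)]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  # phase 2: freeze artificials at zero
  wfull[n + seq_len(m)] <- 0
  cost2 <- c(cvec, rep(0, m))
  r2 <- .simplex_iterate(cost2, Afull, b0, wfull, r1$basis, r1$at_upper)
  if (r2$status == "unbounded") return(list(status = "unbounded"))
  ystr <- r2$y[seq_len(n)]
  list(status = "optimal", x = ystr + l)
}

# One simplex run (min c'y, A y = b, 0 <= y <= w) from a given basis.
.simplex_iterate <- function(cvec, A, b, w, basis, at_upper, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  tol <- .LP_TOL
  for (iter in seq_len(max_iter)) {
    Bmat <- A[, basis, drop = FALSE]
    # nonbasic values
    ynb <- numeric(n)
    upidx <- which(at_upper)
    upidx <- setdiff(upidx, basis)
    if (length(upidx)) ynb[upidx] <- w[upidx]
    rhs_adj <- b - as.vector(A[, upidx, drop = FALSE] %*% ynb[upidx])
    xB <- tryCatch(solve(Bmat, rhs_adj), error = function(e) NULL)
    if (is.null(xB)) stop("singular basis encountered in simplex")
    lambda <- tryCatch(solve(t(Bmat), cvec[basis]), error = function(e) NULL)
    if (is.null(lambda)) stop("singular basis encountered in simplex")
    nonbasic <- setdiff(seq_len(n), basis)
    d <- cvec[nonbasic] - as.vector(t(A[, nonbasic, drop = FALSE]) %*% lambda)
    low <- !at_upper[nonbasic]
    entering_mask <- (low & d < -tol) | (!low & d > tol)
    if (!any(entering_mask)) {
      # optimal: assemble solution
      y <- numeric(n)
      y[nonbasic] <- ifelse(at_upper[nonbasic], w[nonbasic], 0)
      y[basis] <- xB
      return(list(status = "optimal", y = y, basis = basis, at_upper = at_upper))
    }
    q <- min(nonbasic[entering_mask])          # Bland's rule
    sigma <- if (at_upper[q]) -1 else 1        # direction of change of y_q
    alpha <- as.vector(solve(Bmat, A[, q]))
    # basic variables move by -sigma * t * alpha
    delta <- -sigma * alpha
    t_best <- if (is.finite(w[q])) w[q] else Inf  # bound flip
    leave_pos <- 0L; leave_bound <- NA
    for (i in seq_len(m)) {
      di <- delta[i]
      if (di < -tol) {                          # basic var decreasing, floor 0
        ti <- xB[i] / (-di)
        if (ti < t_best - tol ||
            (ti < t_best + tol && (leave_pos == 0L || basis[i] < basis[leave_pos]))) {
          t_best <- min(ti, t_best); leave_pos <- i; leave_bound <- "lower"
        }
      } else if (di > tol && is.finite(w[basis[i]])) {  # increasing, cap w
        ti <- (w[basis[i]] - xB[i]) / di
        if (ti < t_best - tol ||
            (ti < t_best + tol && (leave_pos == 0L || basis[i] < basis[leave_pos]))) {
          t_best <- min(ti, t_best); leave_pos <- i; leave_bound <- "upper"
        }
      }
    }
    if (!is.finite(t_best)) return(list(status = "unbounded"))
    t_best <- max(t_best, 0)
    if (leave_pos == 0L) {
      # entering variable hits its opposite bound: flip, no basis change
      at_upper[q] <- !at_upper[q]
    } else {
      leave_var <- basis[leave_pos]
      basis[leave_pos] <- q
      at_upper[q] <- FALSE                     # becomes basic
      at_upper[leave_var] <- identical(leave_bound, "upper")
    }
  }
  stop("simplex iteration limit exceeded")
}
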
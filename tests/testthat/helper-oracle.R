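# Independent brute-force LP oracle: enumerates all vertices (basic
# feasible solutions) of {x : A x = b, lb <= x <= ub} and optimizes over
# them. Only valid for bounded polytopes (finite bounds) and small n; kept
# deliberately separate from the package's simplex code path.

oracle_vertices <- function(A, b, lb, ub, tol = 1e-8) {
  A <- as.matrix(A)
  n <- ncol(A)
  r <- qr(A)$rank
  verts <- list()
  basis_sets <- if (r == 0) list(integer(0)) else
    utils::combn(n, r, simplify = FALSE)
  for (B in basis_sets) {
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    N <- setdiff(seq_len(n), B)
    combos <- if (length(N) == 0) matrix(0, 1, 0) else
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(N))))
    for (ci in seq_len(nrow(combos))) {
      x <- numeric(n)
      x[N] <- ifelse(unlist(combos[ci, ]), ub[N], lb[N])
      rhs <- b - A[, N, drop = FALSE] %*% x[N]
      xB <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      x[B] <- xB
      if (max(abs(A %*% x - b)) > tol) next
      if (any(x < lb - tol) || any(x > ub + tol)) next
      verts[[length(verts) + 1L]] <- pmin(pmax(x, lb), ub)
    }
  }
  if (!length(verts)) return(NULL)
  V <- do.call(rbind, verts)
  V[!duplicated(round(V, 6)), , drop = FALSE]
}

# build the equality system of a model without going through the package's
# stoich_matrix() (plain double loop over the stored stoichiometries)
oracle_system <- function(model) {
  mids <- model$metabolites$id
  rids <- model$reactions$id
  A <- matrix(0, length(mids), length(rids),
              dimnames = list(mids, rids))
  for (r in rids) {
    st <- model$stoichiometry[[r]]
    for (m in names(st)) A[m, r] <- A[m, r] + st[[m]]
  }
  list(A = A, b = numeric(length(mids)),
       lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

oracle_fva <- function(model, reactions = NULL) {
  sys <- oracle_system(model)
  V <- oracle_vertices(sys$A, sys$b, sys$lb, sys$ub)
  if (is.null(V)) stop("oracle: no feasible vertex")
  if (is.null(reactions)) reactions <- model$reactions$id
  idx <- match(reactions, model$reactions$id)
  data.frame(reaction_id = reactions,
             min_flux = apply(V[, idx, drop = FALSE], 2, min),
             max_flux = apply(V[, idx, drop = FALSE], 2, max),
             stringsAsFactors = FALSE)
}

oracle_lp_max <- function(model, objective) {
  sys <- oracle_system(model)
  V <- oracle_vertices(sys$A, sys$b, sys$lb, sys$ub)
  if (is.null(V)) return(NA_real_)
  obj <- numeric(nrow(sys$A)); obj <- numeric(ncol(sys$A))
  obj[match(names(objective), model$reactions$id)] <- unname(objective)
  max(V %*% obj)
}
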
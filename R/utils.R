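#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois runif rgamma rexp rbinom cor cor.test lm
#'   pt pf pchisq p.adjust sd var median quantile anova coef vcov t.test
#'   wilcox.test model.matrix resid fitted predict setNames aggregate dist
#'   complete.cases qnorm pnorm optimize ave mad
#' @importFrom utils head tail
NULL

# Euclidean projection of each row of S onto the probability simplex
# (Held-Wolfe-Crowder / Michelot sort-based algorithm, vectorized over rows).
.project_simplex_rows <- function(S) {
  k <- ncol(S)
  if (k == 1L) return(matrix(1, nrow(S), 1L))
  n <- nrow(S)
  o <- order(row(S), -S)  # row-wise descending sort in one pass
  U <- matrix(S[o], n, k, byrow = TRUE)
  css <- U
  for (jj in 2:k) css[, jj] <- css[, jj - 1L] + U[, jj]
  j <- matrix(rep(seq_len(k), each = n), n)
  cond <- U + (1 - css) / j > 0
  rho <- max.col(ifelse(cond, j, 0L), ties.method = "last")
  theta <- (css[cbind(seq_len(n), rho)] - 1) / rho
  P <- pmax(S - theta, 0)
  # guard against all-zero rows from numerical underflow
  rs <- rowSums(P)
  bad <- rs <= 0
  if (any(bad)) P[bad, ] <- 1 / k
  P / rowSums(P)
}

# Exact simplex-constrained least squares: min_s ||t(A) %*% s - p||^2
# s.t. s >= 0, sum(s) = 1, by enumeration of active sets (k is small).
# Ties broken by minimal-norm s.
.simplex_lsq <- function(A, p) {
  k <- nrow(A)
  if (k == 1L) return(c(1))
  best <- NULL
  best_obj <- Inf
  best_norm <- Inf
  for (m in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    Aj <- A[idx, , drop = FALSE]
    nj <- length(idx)
    # KKT system for min ||Aj' s - p||^2 with sum(s)=1 on support idx
    G <- Aj %*% t(Aj)
    kkt <- rbind(cbind(G, 1), c(rep(1, nj), 0))
    rhs <- c(Aj %*% p, 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) {  # singular system (duplicate archetypes):
      sv <- svd(kkt)     # minimal-norm solution via pseudoinverse
      pos <- sv$d > max(sv$d) * 1e-12
      sol <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    }
    s <- sol[seq_len(nj)]
    if (any(s < -1e-9)) next
    s <- pmax(s, 0); s <- s / sum(s)
    r <- drop(t(Aj) %*% s - p)
    obj <- sum(r * r)
    nrm <- sum(s * s)
    if (obj < best_obj - 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 && nrm < best_norm)) {
      best_obj <- obj
      best_norm <- nrm
      best <- numeric(k); best[idx] <- s
    }
  }
  best
}

# Optimal one-to-one matching between rows of two coordinate matrices,
# minimizing total Euclidean distance. Exhaustive for k <= 8, greedy beyond.
.match_rows <- function(A, B) {
  k <- nrow(A)
  D <- as.matrix(dist(rbind(A, B)))[seq_len(k), k + seq_len(k), drop = FALSE]
  if (k <= 8L) {
    perms <- .permutations(k)
    costs <- apply(perms, 1L, function(p) sum(D[cbind(seq_len(k), p)]))
    perms[which.min(costs), ]
  } else {
    p <- integer(k)
    used <- logical(k)
    for (i in order(apply(D, 1L, min))) {
      j <- order(D[i, ])
      j <- j[!used[j]][1L]
      p[i] <- j; used[j] <- TRUE
    }
    p
  }
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (i in seq_len(k)) {
    out <- rbind(out, cbind(i, ifelse(sub >= i, sub + 1L, sub)))
  }
  unname(out)
}

# Deterministic local RNG: evaluate expr with a private seed, restoring
# the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
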
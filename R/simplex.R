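# Dense two-phase tableau simplex with Bland's anti-cycling rule.
#
# Solves  min c'x  s.t.  A_ge x >= b_ge,  A_le x <= b_le,  x >= 0.
# Written for the set-cover LPs of this package: tens to a few hundred
# variables, heavily degenerate optima (duplicated regulons), where
# pivoting with Bland's rule terminates finitely and deterministically.
# All right-hand sides are assumed nonnegative.

simplex_lp <- function(cc, A_ge = NULL, b_ge = NULL, A_le = NULL, b_le = NULL,
                       tol = 1e-9, max_iter = 100000L) {
  n <- length(cc)
  A <- rbind(A_ge, A_le)
  b <- c(b_ge, b_le)
  m_ge <- if (is.null(A_ge)) 0L else nrow(A_ge)
  m <- length(b)
  if (any(b < 0)) stop_solver("simplex_lp expects nonnegative right-hand sides")

  # columns: x (n) | surplus for >= rows (m_ge) | slack for <= rows (m - m_ge)
  # | artificials for >= rows (m_ge)
  n_slack <- m - m_ge
  n_art <- m_ge
  ncols <- n + m_ge + n_slack + n_art
  T <- matrix(0, m, ncols)
  T[, seq_len(n)] <- A
  if (m_ge > 0)
    T[cbind(seq_len(m_ge), n + seq_len(m_ge))] <- -1 # surplus
  if (n_slack > 0)
    T[cbind(m_ge + seq_len(n_slack), n + m_ge + seq_len(n_slack))] <- 1
  if (n_art > 0)
    T[cbind(seq_len(m_ge), n + m_ge + n_slack + seq_len(n_art))] <- 1
  rhs <- b
  basis <- integer(m)
  if (m_ge > 0) basis[seq_len(m_ge)] <- n + m_ge + n_slack + seq_len(n_art)
  if (n_slack > 0) basis[m_ge + seq_len(n_slack)] <- n + m_ge + seq_len(n_slack)

  run_phase <- function(obj, allowed, T, rhs, basis) {
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "iteration limit",
                                       T = T, rhs = rhs, basis = basis))
      # reduced costs z_j - c_j; for maximization a column with z_j - c_j < 0
      # improves the objective
      cb <- obj[basis]
      red <- as.numeric(crossprod(T, cb)) - obj
      red[basis] <- 0
      cand <- which(allowed & red < -tol)
      if (!length(cand)) return(list(status = "optimal", T = T, rhs = rhs,
                                     basis = basis))
      j <- cand[1] # Bland: smallest index enters
      col <- T[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded", T = T, rhs = rhs,
                                    basis = basis))
      ratio <- rhs[pos] / col[pos]
      rmin <- min(ratio)
      ties <- pos[ratio <= rmin + tol]
      i <- ties[which.min(basis[ties])] # Bland: smallest basis index leaves
      piv <- T[i, j]
      T[i, ] <- T[i, ] / piv
      rhs[i] <- rhs[i] / piv
      other <- setdiff(seq_len(m), i)
      f <- T[other, j]
      T[other, ] <- T[other, , drop = FALSE] - outer(f, T[i, ])
      rhs[other] <- rhs[other] - f * rhs[i]
      rhs[rhs < 0 & rhs > -tol] <- 0
      basis[i] <- j
    }
  }

  allowed <- rep(TRUE, ncols)
  if (n_art > 0) {
    obj1 <- c(rep(0, n + m_ge + n_slack), rep(-1, n_art)) # maximize -sum(art)
    ph1 <- run_phase(obj1, allowed, T, rhs, basis)
    if (ph1$status != "optimal") return(list(status = ph1$status))
    T <- ph1$T; rhs <- ph1$rhs; basis <- ph1$basis
    art_cols <- n + m_ge + n_slack + seq_len(n_art)
    if (sum(rhs[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible"))
    # pivot out any artificial still basic at zero level
    for (i in which(basis %in% art_cols)) {
      j <- which(abs(T[i, seq_len(n + m_ge + n_slack)]) > tol)[1]
      if (is.na(j)) next # redundant row
      piv <- T[i, j]
      T[i, ] <- T[i, ] / piv; rhs[i] <- rhs[i] / piv
      other <- setdiff(seq_len(m), i)
      f <- T[other, j]
      T[other, ] <- T[other, , drop = FALSE] - outer(f, T[i, ])
      rhs[other] <- rhs[other] - f * rhs[i]
      basis[i] <- j
    }
    allowed[art_cols] <- FALSE
  }
  obj2 <- c(-cc, rep(0, ncols - n)) # maximize -c'x == minimize c'x
  ph2 <- run_phase(obj2, allowed, T, rhs, basis)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  x <- numeric(n)
  in_x <- ph2$basis <= n
  x[ph2$basis[in_x]] <- ph2$rhs[in_x]
  list(status = "optimal", x = x, value = sum(cc * x))
}
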
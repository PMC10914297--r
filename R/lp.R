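# Dense two-phase primal simplex for the small envelopment programs solved by
# dea(). Problems here have at most a few dozen variables and ~10 rows, so a
# plain tableau with Bland's anti-cycling rule is both exact enough and fast.

#' @keywords internal
#' @noRd
lp_solve <- function(objective, const_mat, const_dir, const_rhs,
                     maximize = FALSE, tol = 1e-9, max_iter = 10000L) {
  n <- length(objective)
  stopifnot(is.matrix(const_mat), ncol(const_mat) == n,
            length(const_dir) == nrow(const_mat),
            length(const_rhs) == nrow(const_mat),
            all(const_dir %in% c("<=", ">=", "=")))
  m <- nrow(const_mat)
  cc <- if (maximize) -as.numeric(objective) else as.numeric(objective)

  A <- const_mat
  b <- as.numeric(const_rhs)
  dir <- const_dir

  # normalise to b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  # columns: n structural | slack/surplus | artificial
  n_slack <- sum(dir != "=")
  slack_col <- integer(m)   # column index of this row's slack/surplus (0 = none)
  art_col <- integer(m)     # column index of this row's artificial (0 = none)
  ncol_tab <- n + n_slack
  k <- n
  for (i in seq_len(m)) {
    if (dir[i] != "=") {
      k <- k + 1L
      slack_col[i] <- k
    }
  }
  need_art <- dir == ">=" | dir == "="
  n_art <- sum(need_art)
  for (i in seq_len(m)) {
    if (need_art[i]) {
      ncol_tab <- ncol_tab + 1L
      art_col[i] <- ncol_tab
    }
  }
  ncol_tab <- n + n_slack + n_art

  T <- matrix(0, m, ncol_tab)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  for (i in seq_len(m)) {
    if (slack_col[i] > 0L) {
      T[i, slack_col[i]] <- if (dir[i] == "<=") 1 else -1
    }
    if (art_col[i] > 0L) {
      T[i, art_col[i]] <- 1
      basis[i] <- art_col[i]
    } else {
      basis[i] <- slack_col[i]
    }
  }

  pivot <- function(T, b, basis, pr, pc) {
    piv <- T[pr, pc]
    T[pr, ] <- T[pr, ] / piv
    b[pr] <- b[pr] / piv
    for (i in seq_len(nrow(T))) {
      if (i != pr && abs(T[i, pc]) > 0) {
        f <- T[i, pc]
        T[i, ] <- T[i, ] - f * T[pr, ]
        b[i] <- b[i] - f * b[pr]
      }
    }
    basis[pr] <- pc
    list(T = T, b = b, basis = basis)
  }

  run_simplex <- function(T, b, basis, cost, active_cols) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex: iteration limit reached", call. = FALSE)
      # reduced costs z_j - c_j = c_B' T_j - c_j
      cb <- cost[basis]
      red <- drop(cb %*% T) - cost
      red[basis] <- 0
      cand <- active_cols[red[active_cols] > tol]
      if (length(cand) == 0L) break       # optimal
      pc <- min(cand)                     # Bland: smallest index enters
      col <- T[, pc]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(T = T, b = b, basis = basis, status = "unbounded"))
      }
      ratio <- b[pos] / col[pos]
      rmin <- min(ratio)
      tie <- pos[ratio <= rmin + tol]
      pr <- tie[which.min(basis[tie])]    # Bland: smallest basis index leaves
      up <- pivot(T, b, basis, pr, pc)
      T <- up$T; b <- up$b; basis <- up$basis
    }
    list(T = T, b = b, basis = basis, status = "optimal")
  }

  # run_simplex minimises cost'x: a column enters while z_j - c_j > 0
  all_cols <- seq_len(ncol_tab)
  if (n_art > 0L) {
    cost1 <- numeric(ncol_tab)
    cost1[art_col[art_col > 0L]] <- 1    # phase 1: minimise sum of artificials
    ph1 <- run_simplex(T, b, basis, cost1, all_cols)
    if (ph1$status != "optimal") {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    T <- ph1$T; b <- ph1$b; basis <- ph1$basis
    art_cols <- art_col[art_col > 0L]
    ph1_val <- sum(b[basis %in% art_cols])
    if (ph1_val > 1e-7) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # drive leftover zero-level artificials out of the basis
    keep <- setdiff(all_cols, art_cols)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        nz <- keep[abs(T[i, keep]) > tol]
        if (length(nz) > 0L) {
          up <- pivot(T, b, basis, i, nz[1L])
          T <- up$T; b <- up$b; basis <- up$basis
        }
        # else: redundant row; harmless to leave (stays at zero level)
      }
    }
    active <- keep
  } else {
    active <- all_cols
  }

  cost2 <- numeric(ncol_tab)
  cost2[seq_len(n)] <- cc
  ph2 <- run_simplex(T, b, basis, cost2, active)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  T <- ph2$T; b <- ph2$b; basis <- ph2$basis
  x <- numeric(ncol_tab)
  x[basis] <- b
  xs <- x[seq_len(n)]
  val <- sum(cc * xs)
  list(status = "optimal", x = xs, value = if (maximize) -val else val)
}
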
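# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the Gini oracle is the pairwise mean-absolute-
# difference definition (not the trapezoid rule), and the DEA oracle solves
# the envelopment program by exhaustive vertex enumeration (not the simplex).

# Base-share-weighted mean absolute difference Gini:
#   G = sum_ij w_i w_j |r_i - r_j| / (2 mu),  r = value/base, w = base share
gini_mad_oracle <- function(values, bases) {
  r <- values / bases
  w <- bases / sum(bases)
  mu <- sum(w * r)
  sum(outer(w, w) * abs(outer(r, r, "-"))) / (2 * mu)
}

# Input-oriented envelopment optimum by brute force: enumerate all basic
# solutions (vertices) of the feasible polyhedron in (theta, lambda) and take
# the minimal feasible theta. Only viable for tiny instances.
dea_bruteforce <- function(X, Y, j, frontier = c("crs", "vrs", "nirs")) {
  frontier <- match.arg(frontier)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  nv <- n + 1L
  # rows of  a'z ~ b  with z = (theta, lambda)
  A <- rbind(
    cbind(-X[j, ], t(X)),                      # <= 0   (inputs)
    cbind(0, t(Y)),                            # >= y0  (outputs)
    diag(nv)                                   # >= 0   (non-negativity)
  )
  b <- c(rep(0, m), Y[j, ], rep(0, nv))
  type <- c(rep("le", m), rep("ge", s), rep("ge", nv))
  if (frontier %in% c("vrs", "nirs")) {
    A <- rbind(A, c(0, rep(1, n)))
    b <- c(b, 1)
    type <- c(type, if (frontier == "vrs") "eq" else "le")
  }
  nr <- nrow(A)
  eq_rows <- which(type == "eq")
  free_rows <- setdiff(seq_len(nr), eq_rows)
  feas <- function(z) {
    lhs <- drop(A %*% z)
    all(ifelse(type == "le", lhs <= b + 1e-9,
               ifelse(type == "ge", lhs >= b - 1e-9, abs(lhs - b) <= 1e-9)))
  }
  best <- Inf
  k <- nv - length(eq_rows)
  combos <- utils::combn(free_rows, k)
  for (i in seq_len(ncol(combos))) {
    act <- c(eq_rows, combos[, i])
    M <- A[act, , drop = FALSE]
    if (abs(det(M)) < 1e-12) next
    z <- tryCatch(solve(M, b[act]), error = function(e) NULL)
    if (is.null(z) || !all(is.finite(z))) next
    if (feas(z) && z[1] < best) best <- z[1]
  }
  best
}

# small well-formed panel for io tests
make_tiny_panel <- function() {
  data.frame(
    region_id = rep(c("A", "B", "C"), each = 2),
    year = rep(c(2020L, 2021L), 3),
    population = rep(c(1e5, 2e5, 4e5), each = 2),
    area_km2 = rep(c(1000, 5000, 20000), each = 2),
    beds = c(150, 155, 260, 270, 410, 420),
    health_technicians = c(140, 144, 300, 310, 420, 430),
    licensed_physicians = c(60, 62, 110, 112, 150, 155),
    registered_nurses = c(50, 52, 100, 104, 140, 144),
    consultations = c(2e5, 2.1e5, 4e5, 4.2e5, 6e5, 6.1e5),
    admissions = c(4000, 4100, 7000, 7200, 10000, 10300))
}
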
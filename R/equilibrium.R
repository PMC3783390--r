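#' Spectral radius and Perron vector of a nonnegative matrix
#'
#' Computes the Perron-Frobenius pair of a nonnegative square matrix by power
#' iteration on the shifted matrix `C + I`. The unit diagonal shift makes any
#' irreducible matrix primitive (periodic structures such as pure cycles
#' would otherwise keep the iteration oscillating) and adds exactly 1 to the
#' dominant eigenvalue without changing its eigenvector, so the shift is
#' subtracted from the reported value. The returned vector is normalized to
#' sum 1 and is strictly positive whenever `C` is irreducible.
#'
#' @param C a [support_matrix()] or nonnegative square matrix.
#' @param tol convergence tolerance on the iterate (max-norm change).
#' @param max_iter iteration cap; reaching it raises an error.
#' @return A list of class `eigen_result` with `lambda_pf` (the spectral
#'   radius), `perron_vector` (sum-1 nonnegative eigenvector) and
#'   `iterations`.
#' @export
spectral_radius_and_perron <- function(C, tol = 1e-12, max_iter = 1e5) {
  M <- as_support_mat(C)
  if (nrow(M) < 1L) stop("matrix must be at least 1 x 1")
  if (any(M < 0)) stop("matrix must be nonnegative")
  storage.mode(M) <- "double"
  n <- nrow(M)
  diag(M) <- diag(M) + 1  # primitivity shift
  v <- rep(1 / n, n)
  lambda_shift <- NA_real_
  for (it in seq_len(max_iter)) {
    w <- as.vector(M %*% v)
    lambda_shift <- sum(w)
    v_new <- w / lambda_shift
    if (max(abs(v_new - v)) < tol) {
      return(structure(list(lambda_pf = lambda_shift - 1,
                            perron_vector = v_new, iterations = it),
                       class = "eigen_result"))
    }
    v <- v_new
  }
  stop("power iteration did not converge in ", max_iter, " iterations")
}

#' @export
print.eigen_result <- function(x, ...) {
  cat("<eigen_result> lambda_pf = ", format(x$lambda_pf), ", ",
      length(x$perron_vector), " occupations\n", sep = "")
  invisible(x)
}

#' Equilibrium productivity of an irreducible society
#'
#' At the attractor of the productivity dynamics every active occupation
#' satisfies `a (Cx)_i / x_i = bX`, so the equilibrium is the Perron vector
#' of `C` with total productivity `X* = (a/b) lambda_pf`:
#' `x* = (a/b) lambda_pf v` with `v` the sum-1 Perron vector. Only the ratio
#' `a/b` matters; rescaling both coefficients leaves `x*` unchanged.
#'
#' @param C irreducible [support_matrix()] or binary matrix of the active
#'   occupations. Reducible input is an error: its attractor must be found by
#'   dynamic integration ([develop()]) instead.
#' @param a supporting coefficient (> 0).
#' @param b environmental restriction coefficient (> 0).
#' @return Numeric vector of equilibrium productivities.
#' @export
equilibrium_productivity <- function(C, a, b = 1) {
  if (!is.numeric(a) || a <= 0 || !is.numeric(b) || b <= 0)
    stop("a and b must be positive")
  if (!is_irreducible(C))
    stop("support matrix is reducible; use develop() to find its attractor")
  e <- spectral_radius_and_perron(C)
  (a / b) * e$lambda_pf * e$perron_vector
}

#' Average reserve of a society
#'
#' Mean productivity of the active occupations minus the functioning
#' threshold limina. The reserve is the per-occupation buffer a society holds
#' against parasitism and disturbance; a value near zero marks a society at
#' risk.
#'
#' @param x a [society_state()] or a numeric productivity vector in which
#'   zero entries denote inactive occupations.
#' @param limina minimum functioning productivity.
#' @return The average reserve (may be negative).
#' @export
average_reserve <- function(x, limina) {
  if (inherits(x, "society_state")) {
    act <- x$active
    x <- x$x
  } else {
    act <- x > 0
  }
  if (!any(act)) stop("no active occupations: the society is extinct")
  mean(x[act]) - limina
}

#' Critical disturbance severity wiping out a uniform society
#'
#' For a society of `n0` occupations whose total productivity `X` is spread
#' uniformly, a pulse of severity `r_d` rescales every equilibrium
#' productivity by `1/r_d`; all occupations drop below limina together once
#' `X / (n0 r_d) < limina`. The critical severity is therefore
#' `r* = X / (n0 limina)`.
#'
#' @param X total productivity (> 0).
#' @param n0 occupation count (>= 1).
#' @param limina functioning threshold (> 0).
#' @return The smallest amplification factor of `b` that eliminates every
#'   occupation of a uniformly distributed society.
#' @export
wipeout_threshold <- function(X, n0, limina) {
  if (X <= 0 || n0 < 1 || limina <= 0)
    stop("X, n0 and limina must be positive")
  X / (n0 * limina)
}
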
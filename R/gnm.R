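#' Kirchhoff (connectivity) matrix of a C-alpha trace
#'
#' Builds the graph Laplacian of the C-alpha contact graph: off-diagonal
#' entries are -1 for residue pairs whose C-alpha distance is at most `rc`,
#' 0 otherwise, and each diagonal entry is the negated sum of its row's
#' off-diagonals (i.e. the contact degree). Every row sums to zero.
#'
#' @inheritParams domain_id
#' @param rc Distance cutoff in angstrom defining an interacting pair.
#'   The conventional C-alpha value of 10 is the default.
#' @return An n x n symmetric integer matrix with attribute `rc`.
#' @examples
#' dom <- synth_domain(n = 30, architecture = "straight_chain", seed = 1)
#' k <- kirchhoff(dom)
#' all(rowSums(k) == 0)
#' @export
kirchhoff <- function(domain, rc = 10) {
  validate_domain(domain)
  stopifnot(rc > 0)
  xyz <- domain_coords(domain)
  d <- as.matrix(stats::dist(xyz))
  g <- -(d <= rc)
  diag(g) <- 0
  diag(g) <- -colSums(g)
  storage.mode(g) <- "integer"
  attr(g, "rc") <- rc
  g
}

#' Gaussian network model mode spectrum
#'
#' Eigendecomposition of the Kirchhoff matrix. Eigenvalues are sorted
#' ascending; the number of (numerically) zero eigenvalues is counted against
#' `zero_tol`, and must be exactly one: a connected contact graph has a single
#' zero mode (the uniform vector), and dynamic elements are undefined across
#' disconnected components, so disconnection is a hard error naming the
#' components. Mode 1 is the slowest non-zero mode. The spring-constant
#' prefactor of the fluctuation covariance is set to 1: only signs and
#' relative magnitudes are consumed downstream.
#'
#' @inheritParams kirchhoff
#' @param zero_tol Absolute tolerance for a zero eigenvalue; default
#'   `1e-8 * max(lambda)` (scale-free).
#' @return An object of class `gnm_modes`: a list with `values` (ascending,
#'   length n), `vectors` (orthonormal columns, matching order), `n_zero`,
#'   `n`, `rc`, `domain_id`.
#' @examples
#' dom <- synth_domain(n = 40, seed = 1)
#' m <- gnm_modes(dom)
#' tidy(m)
#' @export
gnm_modes <- function(domain, rc = 10, zero_tol = NULL) {
  k <- kirchhoff(domain, rc = rc)
  gnm_modes_from_kirchhoff(k, zero_tol = zero_tol,
                           domain_id = domain_id(domain))
}

#' @rdname gnm_modes
#' @param K A Kirchhoff matrix from [kirchhoff()].
#' @param domain_id Label carried through to the result.
#' @export
gnm_modes_from_kirchhoff <- function(K, zero_tol = NULL, domain_id = "domain") {
  e <- eigen(K, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  if (is.null(zero_tol)) zero_tol <- 1e-8 * max(abs(values))
  n_zero <- sum(abs(values) < zero_tol)
  if (n_zero != 1L) {
    comp <- contact_components(K)
    abort(paste0(
      "disconnected contact graph: ", max(comp), " components of sizes ",
      paste(tabulate(comp), collapse = ", "),
      " (", n_zero, " zero eigenvalues)"
    ))
  }
  gaps <- diff(values[-1])
  if (any(gaps < 1e-6)) {
    inform(paste0("near-degenerate eigenvalues at mode(s) ",
                  paste(which(gaps < 1e-6), collapse = ", "),
                  "; sense vectors there are basis-dependent"))
  }
  structure(
    list(values = values, vectors = vectors, n_zero = n_zero,
         n = nrow(K), rc = attr(K, "rc") %||% NA_real_,
         domain_id = domain_id),
    class = "gnm_modes"
  )
}

contact_components <- function(K) {
  n <- nrow(K)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(K[v, ] < 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.gnm_modes <- function(x, ...) {
  cat("<gnm_modes> ", x$domain_id, ": n = ", x$n,
      ", rc = ", x$rc, " A, ", x$n - x$n_zero, " non-zero modes\n", sep = "")
  cat("slowest eigenvalues:",
      paste(signif(nonzero_values(x)[seq_len(min(7, x$n - x$n_zero))], 4),
            collapse = ", "), "\n")
  invisible(x)
}

nonzero_values <- function(modes) modes$values[-seq_len(modes$n_zero)]

#' Eigenvector of a non-zero mode
#' @param modes A `gnm_modes` object.
#' @param k Mode index, 1 = slowest non-zero mode.
#' @return Unit-norm numeric vector of length n.
#' @export
mode_vector <- function(modes, k) {
  n_modes <- modes$n - modes$n_zero
  if (k < 1 || k > n_modes) {
    abort(paste0("mode index ", k, " out of range 1..", n_modes))
  }
  modes$vectors[, modes$n_zero + k]
}

#' @export
tidy.gnm_modes <- function(x, ...) {
  n_modes <- x$n - x$n_zero
  tibble(mode = seq_len(n_modes), eigenvalue = nonzero_values(x))
}

#' @export
glance.gnm_modes <- function(x, ...) {
  tibble(domain_id = x$domain_id, n = x$n, rc = x$rc,
         n_modes = x$n - x$n_zero, n_zero = x$n_zero,
         lambda_1 = nonzero_values(x)[1])
}

#' Per-residue sense of one mode
#'
#' For an individual mode the normalized residue cross-correlations reduce to
#' the sign pattern of the eigenvector: residues with equal sign fluctuate in
#' the same sense, residues with opposite sign in opposite senses about
#' hinges. Components with magnitude below `zero_component_tol` (nodes of the
#' mode shape) inherit the preceding residue's sense; a leading run of such
#' components takes the first following non-zero sense. The overall sign of an
#' eigenvector is arbitrary; both labelings are equivalent downstream.
#'
#' @inheritParams mode_vector
#' @param zero_component_tol Magnitude below which a component is treated as
#'   a node (eigenvectors are unit-normalized; default 1e-8).
#' @return An integer vector of length n over {+1, -1}.
#' @export
mode_senses <- function(modes, k, zero_component_tol = 1e-8) {
  u <- mode_vector(modes, k)
  senses_from_vector(u, zero_component_tol)
}

senses_from_vector <- function(u, tol = 1e-8) {
  s <- sign(u)
  s[abs(u) < tol] <- 0L
  if (all(s == 0)) return(rep(1L, length(u)))
  # leading zeros take the next non-zero sense; others inherit the previous
  first_nz <- which(s != 0)[1L]
  if (first_nz > 1L) s[seq_len(first_nz - 1L)] <- s[first_nz]
  for (i in seq_along(s)[-1L]) if (s[i] == 0L) s[i] <- s[i - 1L]
  as.integer(s)
}

#' Sense tracks for a range of modes
#'
#' @inheritParams mode_vector
#' @param modes_idx Integer vector of mode indices (default the seven slowest).
#' @inheritParams mode_senses
#' @return A tibble with columns `mode`, `local_index`, `sense`.
#' @export
sense_profile <- function(modes, modes_idx = 1:7, zero_component_tol = 1e-8) {
  modes_idx <- modes_idx[modes_idx <= modes$n - modes$n_zero]
  purrr::map_dfr(modes_idx, function(k) {
    tibble(mode = k, local_index = seq_len(modes$n),
           sense = mode_senses(modes, k, zero_component_tol))
  })
}

#' Normalized residue cross-correlation matrix
#'
#' Sum over the requested non-zero modes of `lambda_k^-1 u_k u_k^T`,
#' normalized so the diagonal equals 1. Over all modes this is proportional
#' to the pseudo-inverse of the Kirchhoff matrix; for a single mode the sign
#' pattern is the outer product of the mode's senses.
#'
#' @inheritParams mode_vector
#' @param mode_set Integer vector of non-zero mode indices.
#' @return An n x n matrix with unit diagonal.
#' @export
cross_correlation <- function(modes, mode_set) {
  if (length(mode_set) == 0L) abort("mode_set must name at least one mode")
  n_modes <- modes$n - modes$n_zero
  if (any(mode_set < 1 | mode_set > n_modes)) abort("mode index out of range")
  lam <- nonzero_values(modes)[mode_set]
  u <- modes$vectors[, modes$n_zero + mode_set, drop = FALSE]
  cov <- u %*% (t(u) / lam)
  d <- sqrt(diag(cov))
  cov / tcrossprod(d)
}
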
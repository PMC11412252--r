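# run code under a locally-seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# equally-spaced points (chord length `step`) on a circular arc from a to b,
# bulging along unit vector w; returns the m-1 interior points
bridge_arc <- function(a, b, step = 3.8, w) {
  D <- sqrt(sum((b - a)^2))
  m <- max(2L, ceiling(D / step + 0.05))
  ratio <- D / step
  f <- function(alpha) sin(m * alpha / 2) / sin(alpha / 2) - ratio
  alpha <- stats::uniroot(f, c(1e-9, 2 * pi / m - 1e-9))$root
  R <- step / (2 * sin(alpha / 2))
  u <- (b - a) / D
  w <- w - sum(w * u) * u  # bulge direction must be orthogonal to the chord
  if (sum(w^2) < 1e-12) w <- c(-u[2], u[1], 0) + c(0, -u[3], u[2])
  w <- w / sqrt(sum(w^2))
  mid <- (a + b) / 2
  centre <- mid - w * R * cos(m * alpha / 2)
  # rotate a around centre in the (u, w) plane by k * alpha
  rel <- a - centre
  cu <- sum(rel * u); cw <- sum(rel * w)
  ks <- seq_len(m - 1L)
  t(vapply(ks, function(k) {
    th <- k * alpha
    centre + (cu * cos(th) + cw * sin(th)) * u +
      (-cu * sin(th) + cw * cos(th)) * w
  }, numeric(3)))
}

chain_helix_bundle <- function(n) {
  rise <- 1.5; twist <- 100 * pi / 180; radius <- 2.3
  axis_sep <- 9.5
  pts <- matrix(NA_real_, n, 3)
  i <- 0L; h <- 0L
  while (i < n) {
    helix_len <- sample(13:23, 1L)
    cx <- h * axis_sep
    up <- h %% 2L == 0L
    take <- min(helix_len, n - i)
    idx <- seq_len(take) - 1L
    z <- if (up) rise * idx else rise * (helix_len - 1L) - rise * idx
    ang <- twist * idx + stats::runif(1L, 0, 2 * pi)
    seg <- cbind(cx + radius * cos(ang), radius * sin(ang), z)
    if (i > 0L) {
      # short loop bridging the previous helix end to this helix start
      prev <- pts[i, ]
      w <- c(stats::runif(2L, -0.5, 0.5), if (up) -1 else 1)
      w <- w / sqrt(sum(w^2))
      loop <- bridge_arc(prev, seg[1L, ], step = 3.8, w = w)
      room <- min(nrow(loop), n - i)
      if (room > 0L) {
        pts[i + seq_len(room), ] <- loop[seq_len(room), , drop = FALSE]
        i <- i + room
      }
      take <- min(helix_len, n - i)
      if (take == 0L) break
      seg <- seg[seq_len(take), , drop = FALSE]
    }
    pts[i + seq_len(nrow(seg)), ] <- seg
    i <- i + nrow(seg)
    h <- h + 1L
  }
  pts[seq_len(n), , drop = FALSE]
}

chain_collapsed_walk <- function(n, step = 3.8, min_sep = 4.0,
                                 bias = 0.35, max_restart = 100L) {
  for (try in seq_len(max_restart)) {
    pts <- matrix(NA_real_, n, 3)
    pts[1, ] <- c(0, 0, 0)
    dir <- c(1, 0, 0)
    pts[2, ] <- pts[1, ] + step * dir
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      centroid <- colMeans(pts[seq_len(i - 1L), , drop = FALSE])
      for (att in seq_len(60L)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pull <- centroid - pts[i - 1L, ]
        np <- sqrt(sum(pull^2))
        if (np > 1e-6) u <- (1 - bias) * u + bias * pull / np
        u <- u / sqrt(sum(u^2))
        cand <- pts[i - 1L, ] + step * u
        d2 <- rowSums((pts[seq_len(i - 2L), , drop = FALSE] -
                         matrix(cand, i - 2L, 3, byrow = TRUE))^2)
        if (all(d2 >= min_sep^2)) {
          pts[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  abort("could not generate a self-avoiding collapsed walk")
}

#' Generate a synthetic C-alpha domain
#'
#' Builds connected, compact C-alpha chains with consecutive-residue spacing
#' of 3.8 (within 0.1) angstrom, for exercising the whole pipeline without
#' structure downloads. Three architectures: `helix_bundle` (ideal
#' alpha-helical segments — 1.5 angstrom rise, 100 degrees and 2.3 angstrom
#' radius per residue — joined by short arc loops), `collapsed_walk`
#' (self-avoiding 3.8-angstrom-step walk with centroid bias and a 4.0
#' angstrom minimum separation), and `straight_chain` (a degenerate control).
#' The contact graph at the usual 10 angstrom cutoff is verified connected
#' (it always is, since consecutive residues are in contact); generation is
#' retried up to 100 times otherwise.
#'
#' These chains emulate the sizes and packing of real domains, not their
#' detailed physics; see the methods vignette for what that does and does not
#' let the tests conclude.
#'
#' @param n Number of residues (default 250, a typical mid-size domain).
#' @param architecture One of `"helix_bundle"`, `"collapsed_walk"`,
#'   `"straight_chain"`.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `dyn_domain` tibble.
#' @examples
#' synth_domain(n = 60, seed = 1)
#' @export
synth_domain <- function(n = 250L,
                         architecture = c("helix_bundle", "collapsed_walk",
                                          "straight_chain"),
                         seed = NULL) {
  architecture <- match.arg(architecture)
  stopifnot(n >= 2L)
  pts <- with_seed(seed, switch(
    architecture,
    straight_chain = cbind(3.8 * (seq_len(n) - 1L), 0, 0),
    helix_bundle = chain_helix_bundle(n),
    collapsed_walk = chain_collapsed_walk(n)
  ))
  as_domain(pts, domain_id = paste0("synth_", architecture, "_n", n,
                                    if (!is.null(seed)) paste0("_s", seed)))
}

#' Plant themes on the DE boundaries of a target mode
#'
#' Positive-control generator: themes are laid over consecutive dynamic
#' element boundaries of one mode, so that at `jitter_sd = 0` the
#' full-coverage combination's partition is identical to the mode's DE
#' partition (AMI exactly 1). Internal boundaries are perturbed by rounded
#' Gaussian jitter, sequentially clamped inside 1..n so every theme keeps at
#' least `min_len` residues.
#'
#' @param elements Output of [dynamic_elements()].
#' @param target_mode Mode whose DE boundaries the themes should tile (must
#'   not be an N/A mode).
#' @param jitter_sd Standard deviation (residues) of the boundary jitter.
#' @param min_len Minimum planted theme length (default 15, the DE minimum).
#' @param seed Optional seed.
#' @return A theme tibble.
#' @export
plant_themes <- function(elements, target_mode, jitter_sd = 0, min_len = 15L,
                         seed = NULL) {
  el <- elements[elements$mode == target_mode, , drop = FALSE]
  if (nrow(el) == 0L) abort(paste0("mode ", target_mode,
                                   " has no DE decomposition (N/A)"))
  n <- max(el$end)
  k <- nrow(el)
  bounds <- el$end  # b_1 < ... < b_k = n
  with_seed(seed, {
    if (jitter_sd > 0 && k > 1L) {
      jit <- as.integer(round(stats::rnorm(k - 1L, 0, jitter_sd)))
      prev <- 0L
      for (i in seq_len(k - 1L)) {
        b <- bounds[i] + jit[i]
        b <- max(b, prev + min_len)
        b <- min(b, n - (k - i) * min_len)
        bounds[i] <- b
        prev <- b
      }
    }
    NULL
  })
  start <- c(1L, head(bounds, -1L) + 1L)
  tibble(theme_id = sprintf("planted%02d", seq_len(k)), variation = 0L,
         start = as.integer(start), end = as.integer(bounds),
         length = as.integer(bounds - start + 1L))
}

#' Random theme annotation (null control)
#'
#' The same sampler as [random_segment_set()], labeled as themes: the
#' negative control in which theme placement carries no information about
#' the dynamics.
#'
#' @inheritParams random_segment_set
#' @param seed Optional seed.
#' @return A theme tibble.
#' @export
random_themes <- function(n, n_themes = 30L, len_range = c(30L, 175L),
                          seed = NULL) {
  with_seed(seed, random_segment_set(n, size = n_themes,
                                     len_range = len_range))
}
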
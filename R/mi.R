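#' Contingency table between two residue partitions
#'
#' @param d_labels Integer labels 1..k (e.g. a DE partition).
#' @param t_labels Integer labels 1..l (e.g. a theme-combination partition).
#' @return A k x l integer matrix of shared-residue counts.
#' @export
contingency <- function(d_labels, t_labels) {
  if (length(d_labels) != length(t_labels)) {
    abort("partitions must label the same residues (length mismatch)")
  }
  k <- max(d_labels); l <- max(t_labels)
  counts <- tabulate(d_labels + k * (t_labels - 1L), nbins = k * l)
  matrix(counts, nrow = k, ncol = l)
}

#' Mutual information of a contingency table
#'
#' Natural-log mutual information `sum (n_ij/N) ln(N n_ij / (d_i t_j))` with
#' the convention `0 ln 0 = 0`, together with the two marginal entropies.
#' Natural log is the convention of record throughout; AMI and SMI are
#' base-invariant but raw MI values are comparable only within one base.
#'
#' @param tab A contingency matrix from [contingency()].
#' @return A list with `mi` (nats), `h_d`, `h_t`.
#' @export
mutual_information <- function(tab) {
  N <- sum(tab)
  stopifnot(N > 0)
  d <- rowSums(tab); t <- colSums(tab)
  nz <- tab > 0
  lab <- log(d) %o% rep(1, ncol(tab)) + rep(1, nrow(tab)) %o% log(t)
  mi <- sum(tab[nz] * (log(tab[nz]) + log(N) - lab[nz])) / N
  ent <- function(m) { p <- m[m > 0] / N; -sum(p * log(p)) }
  list(mi = max(mi, 0), h_d = ent(d), h_t = ent(t))
}

# fast scalar MI between two label vectors (hot loop of the null analysis)
mi_value <- function(d_labels, t_labels, k = max(d_labels), l = max(t_labels)) {
  n <- length(d_labels)
  cnt <- tabulate(d_labels + k * (t_labels - 1L), nbins = k * l)
  d <- tabulate(d_labels, k); t <- tabulate(t_labels, l)
  lab <- log(d)[(seq_len(k * l) - 1L) %% k + 1L] +
    log(t)[(seq_len(k * l) - 1L) %/% k + 1L]
  nz <- cnt > 0L
  sum(cnt[nz] * (log(cnt[nz]) + log(n) - lab[nz])) / n
}

#' Expected mutual information under the fixed-marginal null
#'
#' Expectation of the MI of a table with the observed marginals when the two
#' partitions are paired at random (the generalized hypergeometric model):
#' each cell count follows a hypergeometric distribution, and
#' `EMI = sum_ij sum_m (m/N) ln(N m / (d_i t_j)) P_hyp(m; N, d_i, t_j)`.
#' Computed in log space via [stats::dhyper()]; always non-negative.
#'
#' @inheritParams mutual_information
#' @return Scalar expected MI (nats).
#' @export
expected_mi <- function(tab) {
  N <- sum(tab)
  d <- rowSums(tab); t <- colSums(tab)
  emi <- 0
  for (i in seq_along(d)) {
    for (j in seq_along(t)) {
      lo <- max(1, d[i] + t[j] - N); hi <- min(d[i], t[j])
      if (hi < lo) next
      m <- lo:hi
      emi <- emi + sum((m / N) * (log(N) + log(m) - log(d[i]) - log(t[j])) *
                         dhyper(m, t[j], N - t[j], d[i]))
    }
  }
  max(emi, 0)
}

# E[M_ij(x) * M_pq(y)] building blocks ----------------------------------------
#
# MI = sum_ij M_ij(n_ij) with M_ij(x) = (x/N) ln(N x / (d_i t_j)). Under the
# fixed-marginal permutation null the exact second moment decomposes into
# same-cell, same-row, same-column and disjoint-cell terms. The joint law of
# two cells in one row (or column) is multivariate hypergeometric; for two
# disjoint cells (i,j) and (p,q) we use the exact conditional chain
#   n_ij            ~ Hyper(N; t_j; d_i)
#   n_iq | n_ij     ~ Hyper(N - t_j; t_q; d_i - n_ij)
#   n_pq | n_iq     ~ Hyper(N - d_i; t_q - n_iq; d_p)
# (given row i's composition, the remaining labels are exchangeable and row p
# is a uniform subset of the remaining items). All pmfs via stats::dhyper.

mij_fun <- function(N) function(x, a, b) (x / N) * (log(N) + log(x) - log(a) - log(b))

#' Exact variance of MI under the fixed-marginal null
#'
#' Variance of the table's MI over random pairings of the two partitions with
#' both sets of cluster sizes fixed, computed from the exact second moment
#' (no sampling). Tiny negative results from floating cancellation are
#' clamped to zero; a negative beyond -1e-10 is an error.
#'
#' @inheritParams mutual_information
#' @return Scalar variance (nats^2).
#' @export
var_mi <- function(tab) {
  N <- sum(tab)
  d <- as.numeric(rowSums(tab)); t <- as.numeric(colSums(tab))
  k <- length(d); l <- length(t)
  if (k == 1L || l == 1L) return(0)
  M <- mij_fun(N)

  # per-cell supports (x = 0 contributes nothing since M(0) = 0)
  supp <- function(a, b) { lo <- max(1, a + b - N); hi <- min(a, b)
    if (hi < lo) integer(0) else lo:hi }

  e1 <- matrix(0, k, l)   # E[M_ij]
  e2_same <- 0
  for (i in seq_len(k)) for (j in seq_len(l)) {
    x <- supp(d[i], t[j])
    if (!length(x)) next
    p <- dhyper(x, t[j], N - t[j], d[i])
    mx <- M(x, d[i], t[j])
    e1[i, j] <- sum(mx * p)
    e2_same <- e2_same + sum(mx^2 * p)
  }

  # same row, two columns: (x, u) multivariate hypergeometric within row i
  e2_row <- 0
  lchoose_n <- lchoose(N, d)
  for (i in seq_len(k)) for (j in seq_len(l - 1)) for (q in (j + 1):l) {
    x <- supp(d[i], t[j]); u <- supp(d[i], t[q])
    if (!length(x) || !length(u)) next
    xg <- rep(x, times = length(u)); ug <- rep(u, each = length(x))
    ok <- xg + ug <= d[i] & d[i] - xg - ug <= N - t[j] - t[q]
    if (!any(ok)) next
    lp <- lchoose(t[j], xg[ok]) + lchoose(t[q], ug[ok]) +
      lchoose(N - t[j] - t[q], d[i] - xg[ok] - ug[ok]) - lchoose_n[i]
    e2_row <- e2_row +
      2 * sum(M(xg[ok], d[i], t[j]) * M(ug[ok], d[i], t[q]) * exp(lp))
  }

  # same column, two rows: transpose symmetry
  e2_col <- 0
  lchoose_m <- lchoose(N, t)
  for (j in seq_len(l)) for (i in seq_len(k - 1)) for (p in (i + 1):k) {
    x <- supp(d[i], t[j]); y <- supp(d[p], t[j])
    if (!length(x) || !length(y)) next
    xg <- rep(x, times = length(y)); yg <- rep(y, each = length(x))
    ok <- xg + yg <= t[j] & t[j] - xg - yg <= N - d[i] - d[p]
    if (!any(ok)) next
    lp <- lchoose(d[i], xg[ok]) + lchoose(d[p], yg[ok]) +
      lchoose(N - d[i] - d[p], t[j] - xg[ok] - yg[ok]) - lchoose_m[j]
    e2_col <- e2_col +
      2 * sum(M(xg[ok], d[i], t[j]) * M(yg[ok], d[p], t[j]) * exp(lp))
  }

  # disjoint cells (i,j), (p,q), i != p, j != q (ordered pairs, so each
  # unordered pair is counted twice as the square expansion requires)
  e2_cross <- 0
  for (i in seq_len(k)) for (p in seq_len(k)) {
    if (p == i) next
    for (q in seq_len(l)) {
      # g(u) = E[M_pq(n_pq) | n_iq = u]; depends only on (i, p, q)
      u <- 0:min(d[i], t[q])
      y_all <- supp(d[p], t[q])
      if (!length(y_all)) next
      my <- M(y_all, d[p], t[q])
      g <- vapply(u, function(uu) {
        rest <- N - d[i] - (t[q] - uu)
        if (rest < 0) return(0)  # u outside its own support; weight is 0
        sum(my * dhyper(y_all, t[q] - uu, rest, d[p]))
      }, numeric(1))
      for (j in seq_len(l)) {
        if (j == q) next
        x <- supp(d[i], t[j])
        if (!length(x)) next
        px <- dhyper(x, t[j], N - t[j], d[i])
        # P(u | x) as an x-by-u matrix, then contract against g
        pu <- outer(x, u, function(xx, uu)
          dhyper(uu, t[q], N - t[j] - t[q], d[i] - xx))
        e2_cross <- e2_cross +
          sum(M(x, d[i], t[j]) * px * as.vector(pu %*% g))
      }
    }
  }

  emi <- sum(e1)
  v <- e2_same + e2_row + e2_col + e2_cross - emi^2
  if (v < -1e-10) abort(paste0("negative MI variance: ", v))
  max(v, 0)
}

#' MI, AMI and SMI between a DE partition and a theme partition
#'
#' Adjusted mutual information `AMI = (MI - EMI) / (max(H_D, H_T) - EMI)`
#' equals 1 for identical partitions (up to relabeling) and 0 when the MI is
#' at its chance expectation; the max-entropy normalizer matches the
#' published code family for this statistic. Standardized mutual information
#' `SMI = (MI - EMI) / sd(MI)` is the number of null standard deviations the
#' observed MI sits above chance; it is reported as `NA` when the null
#' variance is zero (e.g. a single-cluster partition).
#'
#' @inheritParams contingency
#' @param exact_var Compute the exact null variance (needed for SMI); set
#'   `FALSE` to skip the most expensive step when only MI/AMI are needed.
#' @return A one-row tibble: `n`, `k`, `l`, `mi`, `h_d`, `h_t`, `emi`,
#'   `var_mi`, `ami`, `smi`.
#' @examples
#' mi_stats(rep(1:2, each = 10), rep(1:2, each = 10))
#' @export
mi_stats <- function(d_labels, t_labels, exact_var = TRUE) {
  tab <- contingency(d_labels, t_labels)
  m <- mutual_information(tab)
  emi <- expected_mi(tab)
  vm <- if (exact_var) var_mi(tab) else NA_real_
  hmax <- max(m$h_d, m$h_t)
  ami <- if (hmax - emi <= 0) {
    # both partitions trivial (single cluster): identical by convention
    if (hmax == 0) 1 else 0
  } else (m$mi - emi) / (hmax - emi)
  smi <- if (!exact_var || is.na(vm)) NA_real_
    else if (vm <= 0) NA_real_ else (m$mi - emi) / sqrt(vm)
  tibble(n = sum(tab), k = nrow(tab), l = ncol(tab),
         mi = m$mi, h_d = m$h_d, h_t = m$h_t, emi = emi, var_mi = vm,
         ami = ami, smi = smi)
}

#' Score every theme combination against every analyzed mode
#'
#' @param parts_de Named list of DE label vectors per mode (from
#'   [de_partitions()]; `NULL` entries are N/A modes).
#' @param parts_theme List of theme-partition label vectors (from
#'   [combination_partitions()]).
#' @param exact_var Compute exact null variances for SMI (default `TRUE`).
#' @return A tibble with one row per mode x combination: `mode`, `combo_id`,
#'   `mi`, `ami`, `smi` (N/A modes contribute `NA` rows).
#' @export
score_combinations <- function(parts_de, parts_theme, exact_var = TRUE) {
  purrr::imap_dfr(parts_de, function(dlab, mode_name) {
    k <- as.integer(mode_name)
    if (is.null(dlab)) {
      return(tibble(mode = k, combo_id = NA_integer_, mi = NA_real_,
                    ami = NA_real_, smi = NA_real_))
    }
    purrr::imap_dfr(parts_theme, function(tlab, ci) {
      s <- mi_stats(dlab, tlab, exact_var = exact_var)
      tibble(mode = k, combo_id = as.integer(ci),
             mi = s$mi, ami = s$ami, smi = s$smi)
    })
  })
}

#' Per-mode summary of AMI and SMI over all combinations
#'
#' Mean, minimum and maximum AMI and SMI per mode, averaged over all theme
#' combinations — the per-domain summary format of record. N/A modes (no DE
#' decomposition) are kept as rows of `NA`, and are excluded from any
#' domain-level averaging by the caller.
#'
#' @param scores Output of [score_combinations()].
#' @return A tibble with one row per mode: `mode`, `n_combinations`,
#'   `mean_ami`, `min_ami`, `max_ami`, `mean_smi`, `min_smi`, `max_smi`.
#' @export
mode_theme_summary <- function(scores) {
  scores |>
    dplyr::group_by(.data$mode) |>
    dplyr::summarise(
      n_combinations = sum(!is.na(.data$combo_id)),
      mean_ami = mean(.data$ami), min_ami = min(.data$ami),
      max_ami = max(.data$ami),
      mean_smi = mean(.data$smi), min_smi = min(.data$smi),
      max_smi = max(.data$smi),
      .groups = "drop"
    )
}
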
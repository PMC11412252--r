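#' Draw one random segment set
#'
#' Samples `size` consecutive-residue segments mimicking a domain's theme
#' annotation: lengths uniform-integer in `len_range` (clamped to the domain
#' length), starts uniform over the admissible positions. The defaults —
#' 30 segments of 30 to 175 residues — are the dataset-wide theme statistics
#' used to build the null.
#'
#' @param n Domain length.
#' @param size Number of segments per set (default 30).
#' @param len_range Integer `c(min, max)` segment length (default `c(30, 175)`).
#' @return A theme-shaped tibble (`theme_id`, `variation`, `start`, `end`,
#'   `length`) usable anywhere a theme table is.
#' @export
random_segment_set <- function(n, size = 30L, len_range = c(30L, 175L)) {
  lo <- min(len_range[1], n); hi <- min(len_range[2], n)
  stopifnot(lo >= 1, hi >= lo)
  len <- sample.int(hi - lo + 1L, size, replace = TRUE) + lo - 1L
  start <- vapply(len, function(L) sample.int(n - L + 1L, 1L), integer(1))
  tibble(theme_id = sprintf("rand%02d", seq_len(size)),
         variation = 0L,
         start = as.integer(start), end = as.integer(start + len - 1L),
         length = as.integer(len))
}

#' Rejection-sample valid random segment sets
#'
#' A set is valid only if at least one combination of its segments covers the
#' entire domain under the given thresholds (checked with
#' [has_combination()], without enumerating). Sets are drawn until `count`
#' valid ones are collected; the acceptance rate is recorded as an attribute
#' and reported.
#'
#' @inheritParams random_segment_set
#' @param count Number of valid sets required (default 1000).
#' @param max_overlap,max_gap Validity thresholds (default the (3, 8) preset).
#' @param max_attempts Attempt budget before erroring (default `50 * count`).
#' @return A list of `count` segment-set tibbles, with attributes `attempts`
#'   and `acceptance_rate`.
#' @export
valid_random_sets <- function(n, count = 1000L, size = 30L,
                              len_range = c(30L, 175L),
                              max_overlap = 3L, max_gap = 8L,
                              max_attempts = 50L * count) {
  sets <- vector("list", count)
  got <- 0L; attempts <- 0L
  while (got < count) {
    if (attempts >= max_attempts) {
      abort(paste0("could not draw ", count, " valid random sets in ",
                   max_attempts, " attempts (acceptance rate ",
                   signif(got / attempts, 3), ")"))
    }
    attempts <- attempts + 1L
    s <- random_segment_set(n, size, len_range)
    if (has_combination(s, n, max_overlap, max_gap)) {
      got <- got + 1L
      sets[[got]] <- s
    }
  }
  inform(paste0("drew ", count, " valid random sets in ", attempts,
                " attempts (acceptance rate ",
                signif(count / attempts, 3), ")"))
  attr(sets, "attempts") <- attempts
  attr(sets, "acceptance_rate") <- count / attempts
  sets
}

# max raw MI over a list of theme partitions against one DE partition
max_mi_over <- function(d_labels, parts_theme) {
  k <- max(d_labels)
  max(vapply(parts_theme, function(tl) mi_value(d_labels, tl, k = k),
             numeric(1)))
}

#' Monte-Carlo p-values for theme-DE correspondence
#'
#' For each analyzed mode, compares the maximum raw MI achieved by the real
#' theme combinations (`x`) with the distribution of the same maximum over
#' combinations of random segment sets (`y_s`). Two p-values are reported:
#' `p_parametric = 1 - T_cdf((x - mean(y)) / sd(y); df = S - 1)`, the
#' standardized-against-the-null form matching the original tooling, and the
#' assumption-free add-one empirical estimate
#' `p_empirical = (1 + #\{y_s >= x\}) / (S + 1)`. The empirical form is the
#' primary criterion. No multiple-testing correction is applied across modes
#' or domains: p-values are raw, per mode.
#'
#' @param parts_de Named list of DE label vectors per mode ([de_partitions()]).
#' @param parts_theme_real List of partitions of the real theme combinations.
#' @param random_sets List of segment-set tibbles ([valid_random_sets()]).
#' @param n Domain length.
#' @param max_overlap,max_gap Thresholds used to enumerate each random set's
#'   combinations (same path and `cap` as the real themes).
#' @param cap Enumeration cap per random set.
#' @return A tibble with one row per mode: `mode`, `real_max_mi`,
#'   `null_mean`, `null_sd`, `p_parametric`, `p_empirical`, `n_null`
#'   (N/A modes give `NA` rows).
#' @export
mode_pvalues <- function(parts_de, parts_theme_real, random_sets, n,
                         max_overlap = 3L, max_gap = 8L, cap = 1e5) {
  stopifnot(length(parts_theme_real) >= 1L, length(random_sets) >= 1L)
  # per random set: list of combination partitions (shared across modes)
  null_parts <- lapply(random_sets, function(s) {
    cb <- enumerate_combinations(s, n, max_overlap, max_gap, cap = cap)
    combination_partitions(cb, s, n)
  })
  S <- length(null_parts)
  purrr::imap_dfr(parts_de, function(dlab, mode_name) {
    k <- as.integer(mode_name)
    if (is.null(dlab)) {
      return(tibble(mode = k, real_max_mi = NA_real_, null_mean = NA_real_,
                    null_sd = NA_real_, p_parametric = NA_real_,
                    p_empirical = NA_real_, n_null = S))
    }
    x <- max_mi_over(dlab, parts_theme_real)
    y <- vapply(null_parts, function(ps) max_mi_over(dlab, ps), numeric(1))
    s_y <- sd(y)
    p_par <- if (is.na(s_y) || s_y == 0) NA_real_
      else 1 - pt((x - mean(y)) / s_y, df = S - 1)
    tibble(mode = k, real_max_mi = x, null_mean = mean(y), null_sd = s_y,
           p_parametric = p_par,
           p_empirical = (1 + sum(y >= x)) / (S + 1),
           n_null = S)
  })
}
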
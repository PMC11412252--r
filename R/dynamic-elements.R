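#' Maximal constant-sense runs of a sense vector
#'
#' Run-length encodes a per-residue sense vector into "dynamic segments":
#' maximal stretches of consecutive residues that fluctuate in the same sense
#' within one mode. Segments tile 1..n and alternate sense by construction.
#'
#' @param senses Integer vector over {+1, -1} (one mode's senses, from
#'   [mode_senses()]).
#' @return A tibble with columns `start`, `end` (inclusive local indices),
#'   `sense`, `length`.
#' @export
dynamic_segments <- function(senses) {
  stopifnot(length(senses) >= 1L, all(senses %in% c(-1L, 1L)))
  r <- rle(as.integer(senses))
  end <- cumsum(r$lengths)
  tibble(start = end - r$lengths + 1L, end = end,
         sense = r$values, length = r$lengths)
}

#' Merge short dynamic segments into dynamic elements
#'
#' Applies the minimum-length filter that turns dynamic segments into dynamic
#' elements (DEs): segments shorter than `min_len` residues are merged into a
#' neighboring longer segment until every run is at least `min_len` long. If
#' no input segment reaches `min_len`, the mode cannot be decomposed into DEs
#' at all and `NULL` is returned (an "N/A" mode).
#'
#' The one-sentence merge rule is determinized as: repeatedly take the
#' shortest segment below `min_len` (ties: the most N-terminal); merge it into
#' its longer neighbor (boundary segments have a single neighbor; interior
#' neighbor-length ties prefer the preceding neighbor); re-coalesce adjacent
#' equal-sense runs; stop when all runs reach `min_len`. Any fixed order is
#' defensible; this one is stated so results are reproducible.
#'
#' @param segments A segment tibble from [dynamic_segments()] (must tile 1..n).
#' @param min_len Minimum DE length in residues (default 15).
#' @return A tibble with `element_index` (1-based, N-terminal first), `start`,
#'   `end`, `sense`, `length`; or `NULL` when the mode has no segment of
#'   length `min_len` or more.
#' @export
smooth_to_elements <- function(segments, min_len = 15L) {
  stopifnot(nrow(segments) >= 1L)
  len <- segments$length
  if (max(len) < min_len) return(NULL)
  sense <- segments$sense
  repeat {
    short <- which(len < min_len)
    if (length(short) == 0L) break
    i <- short[which.min(len[short])]  # which.min takes the first on ties
    m <- length(len)
    target <- if (i == 1L) 2L
      else if (i == m) m - 1L
      else if (len[i + 1L] > len[i - 1L]) i + 1L
      else i - 1L  # longer neighbor; tie -> preceding
    # absorb run i into its target, then coalesce equal-sense neighbors
    keep <- seq_len(m)[-i]
    len[target] <- len[target] + len[i]
    len <- len[keep]; sense <- sense[keep]
    r <- rle(sense)
    if (any(r$lengths > 1L)) {
      grp <- rep(seq_along(r$lengths), r$lengths)
      len <- as.vector(tapply(len, grp, sum))
      sense <- r$values
    }
  }
  end <- cumsum(len)
  tibble(element_index = seq_along(len), start = end - len + 1L,
         end = as.integer(end), sense = as.integer(sense),
         length = as.integer(len))
}

#' Dynamic elements of the slow modes of a domain
#'
#' Convenience wrapper running [mode_senses()], [dynamic_segments()] and
#' [smooth_to_elements()] for each of the requested modes. Modes whose
#' segments are all shorter than `min_len` are reported as N/A (no element
#' rows; listed in the `na_modes` attribute).
#'
#' @inheritParams mode_vector
#' @param modes_idx Modes to analyze (default the seven slowest, the range
#'   over which collective motions dominate).
#' @param min_len Minimum DE length (default 15 residues).
#' @return A tibble with columns `mode`, `element_index`, `start`, `end`,
#'   `sense`, `length`, plus attribute `na_modes` (integer vector).
#' @examples
#' dom <- synth_domain(n = 120, seed = 7)
#' dynamic_elements(gnm_modes(dom))
#' @export
dynamic_elements <- function(modes, modes_idx = 1:7, min_len = 15L) {
  modes_idx <- modes_idx[modes_idx <= modes$n - modes$n_zero]
  na_modes <- integer(0)
  empty <- tibble(mode = integer(0), element_index = integer(0),
                  start = integer(0), end = integer(0), sense = integer(0),
                  length = integer(0))
  out <- purrr::map_dfr(modes_idx, function(k) {
    el <- smooth_to_elements(dynamic_segments(mode_senses(modes, k)), min_len)
    if (is.null(el)) {
      na_modes <<- c(na_modes, k)
      return(empty)
    }
    dplyr::mutate(el, mode = k, .before = 1L)
  })
  if (nrow(out) == 0L) out <- empty
  attr(out, "na_modes") <- na_modes
  out
}

#' Residue labels of a DE partition
#'
#' Labels each residue by the index of the containing dynamic element, giving
#' the k-cluster partition compared against theme partitions.
#'
#' @param elements An element tibble for a single mode ([smooth_to_elements()]
#'   output, or one mode's rows of [dynamic_elements()]).
#' @return Integer vector of length n with values 1..k, or `NULL` for `NULL`
#'   input (N/A mode).
#' @export
de_partition <- function(elements) {
  if (is.null(elements)) return(NULL)
  stopifnot(nrow(elements) >= 1L)
  rep(seq_len(nrow(elements)), elements$end - elements$start + 1L)
}

#' DE partitions for every analyzed mode
#'
#' @param elements Output of [dynamic_elements()].
#' @param modes_idx Modes to extract (default: all modes present or N/A).
#' @return A named list (one entry per mode, `NULL` for N/A modes) of integer
#'   label vectors.
#' @export
de_partitions <- function(elements, modes_idx = NULL) {
  present <- unique(elements$mode)
  modes_idx <- modes_idx %||% sort(c(present, attr(elements, "na_modes")))
  out <- lapply(modes_idx, function(k) {
    el <- elements[elements$mode == k, , drop = FALSE]
    if (nrow(el) == 0L) NULL else de_partition(el)
  })
  names(out) <- as.character(modes_idx)
  out
}
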
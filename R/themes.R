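#' Read and validate a theme annotation table
#'
#' Themes are sequence segments (by convention at least 35 residues) that
#' recur across protein space; they are inputs here, detected elsewhere by
#' profile-sequence similarity. The table uses domain-local 1-based inclusive
#' coordinates.
#'
#' @param path Path to a TSV with columns `theme_id`, `variation`, `start`,
#'   `end`.
#' @param n Domain length; intervals outside 1..n are an error.
#' @param min_len Minimum theme length (default 35; relax for synthetic
#'   fixtures).
#' @return A validated theme tibble (`theme_id`, `variation`, `start`, `end`,
#'   `length`).
#' @export
read_themes <- function(path, n, min_len = 35L) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           theme_id = readr::col_character(),
                           variation = readr::col_integer(),
                           start = readr::col_integer(),
                           end = readr::col_integer()))
  validate_themes(raw, n, min_len = min_len)
}

#' @rdname read_themes
#' @param themes A data frame with columns `theme_id`, `variation`, `start`,
#'   `end` (variation 0 marks a unique placement).
#' @export
validate_themes <- function(themes, n, min_len = 35L) {
  themes <- as_tibble(themes)
  need <- c("theme_id", "variation", "start", "end")
  if (!all(need %in% names(themes))) {
    abort(paste0("theme table must have columns: ", paste(need, collapse = ", ")))
  }
  bad <- which(themes$end < themes$start |
                 themes$start < 1L | themes$end > n)
  if (length(bad)) {
    abort(paste0("invalid theme interval in row(s) ",
                 paste(bad, collapse = ", "),
                 " (need 1 <= start <= end <= ", n, ")"))
  }
  short <- which(themes$end - themes$start + 1L < min_len)
  if (length(short)) {
    abort(paste0("theme(s) shorter than ", min_len, " residues in row(s) ",
                 paste(short, collapse = ", ")))
  }
  dup <- duplicated(themes[, need])
  if (any(dup)) {
    warn(paste0(sum(dup), " duplicate theme row(s) removed"))
    themes <- themes[!dup, , drop = FALSE]
  }
  dplyr::mutate(themes[, need],
                start = as.integer(.data$start), end = as.integer(.data$end),
                length = .data$end - .data$start + 1L)
}

# successor matrix + terminal flags under the overlap/gap constraints;
# themes must be sorted by (start, end)
combo_graph <- function(start, end, n, max_overlap, max_gap) {
  m <- length(start)
  can_start <- start <= max_gap + 1L
  can_end <- end >= n - max_gap
  succ <- vector("list", m)
  for (i in seq_len(m)) {
    j <- which(start > start[i] & end > end[i] &
                 start <= end[i] + max_gap + 1L &
                 start >= end[i] - max_overlap + 1L)
    succ[[i]] <- j
  }
  # reachability: can a tiling through theme i be completed to the C-terminus?
  can_finish <- can_end
  repeat {
    upd <- FALSE
    for (i in seq_len(m)) {
      if (!can_finish[i] && any(can_finish[succ[[i]]])) {
        can_finish[i] <- TRUE; upd <- TRUE
      }
    }
    if (!upd) break
  }
  list(succ = succ, can_start = can_start, can_end = can_end,
       can_finish = can_finish)
}

#' Enumerate theme combinations tiling a domain
#'
#' A theme combination is an ordered selection of themes, sorted by start,
#' that covers the domain under pairwise constraints: consecutive themes may
#' overlap by at most `max_overlap` residues or leave a gap of at most
#' `max_gap` residues, starts and ends are strictly increasing (a contained
#' theme adds no coverage), and the terminal gaps before the first and after
#' the last theme are each at most `max_gap`.
#'
#' Enumeration is exhaustive depth-first over themes sorted by (start, end).
#' If more than `cap` combinations exist, the function falls back to uniform
#' random sampling of extensions, returns `cap` distinct combinations, and
#' warns about the truncation (attribute `truncated`).
#'
#' The three threshold presets of record are (3, 8), (5, 10) and (5, 15).
#'
#' @param themes A validated theme tibble ([validate_themes()]).
#' @param n Domain length.
#' @param max_overlap,max_gap Constraint thresholds in residues.
#' @param cap Maximum number of combinations to return (default 100000).
#' @return A tibble with one row per combination: `combo_id`, `size`, and a
#'   list-column `members` of integer row indices into `themes`. Zero rows if
#'   no valid combination exists.
#' @export
enumerate_combinations <- function(themes, n, max_overlap = 3L, max_gap = 8L,
                                   cap = 1e5) {
  ord <- order(themes$start, themes$end)
  start <- themes$start[ord]; end <- themes$end[ord]
  g <- combo_graph(start, end, n, max_overlap, max_gap)
  roots <- which(g$can_start & g$can_finish)

  acc <- vector("list", 256L); n_acc <- 0L; overflow <- FALSE
  push <- function(combo) {
    if (n_acc >= cap) { overflow <<- TRUE; return(FALSE) }
    n_acc <<- n_acc + 1L
    if (n_acc > length(acc)) length(acc) <<- 2L * n_acc
    acc[[n_acc]] <<- combo
    TRUE
  }
  dfs <- function(path, i) {
    if (overflow) return()
    if (g$can_end[i] && !push(path)) return()
    for (j in g$succ[[i]]) {
      if (g$can_finish[j]) dfs(c(path, j), j)
    }
  }
  for (r in roots) {
    dfs(r, r)
    if (overflow) break
  }

  if (overflow) {
    warn(paste0("more than ", cap, " combinations; returning ", cap,
                " sampled uniformly over extensions"))
    seen <- new.env(hash = TRUE)
    acc <- vector("list", cap); n_acc <- 0L
    tries <- 0L
    while (n_acc < cap && tries < 50L * cap) {
      tries <- tries + 1L
      path <- sample(roots, 1L)
      repeat {
        i <- path[length(path)]
        opts <- g$succ[[i]][g$can_finish[g$succ[[i]]]]
        stop_ok <- g$can_end[i]
        pick <- sample.int(length(opts) + stop_ok, 1L)
        if (stop_ok && pick == length(opts) + 1L) break
        path <- c(path, opts[[pick]])
      }
      key <- paste(path, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        n_acc <- n_acc + 1L
        acc[[n_acc]] <- path
      }
    }
    acc <- acc[seq_len(n_acc)]
  } else {
    acc <- acc[seq_len(n_acc)]
  }

  out <- tibble(
    combo_id = seq_along(acc),
    size = vapply(acc, length, integer(1)),
    members = lapply(acc, function(p) ord[p])
  )
  attr(out, "truncated") <- overflow
  out
}

#' Does any full-coverage combination exist?
#'
#' Existence check (used as the validity rule for random segment sets) via
#' the reachability table of the combination graph, without enumerating.
#'
#' @inheritParams enumerate_combinations
#' @return `TRUE` if at least one valid combination exists.
#' @export
has_combination <- function(themes, n, max_overlap = 3L, max_gap = 8L) {
  ord <- order(themes$start, themes$end)
  g <- combo_graph(themes$start[ord], themes$end[ord], n, max_overlap, max_gap)
  any(g$can_start & g$can_finish)
}

#' Residue partition induced by a theme combination
#'
#' Converts a combination into a full partition of 1..n into contiguous
#' clusters, one per theme: overlapping residues go to the N-terminal theme
#' of the pair; interior gap residues go to the flanking theme with the
#' nearer boundary (equidistant residues to the preceding theme); residues
#' before the first theme go to it, and likewise after the last.
#'
#' @param starts,ends Integer vectors of the combination's theme intervals,
#'   sorted by start.
#' @param n Domain length.
#' @return Integer label vector of length n with values 1..l; every theme
#'   contributes at least one residue.
#' @export
combination_partition <- function(starts, ends, n) {
  m <- length(starts)
  stopifnot(m >= 1L, length(ends) == m)
  if (m == 1L) return(rep(1L, n))
  nxt <- starts[-1L]; prev_end <- ends[-m]
  cuts <- ifelse(nxt <= prev_end + 1L, prev_end,
                 (prev_end + nxt) %/% 2L)
  cuts <- c(0L, as.integer(cuts), as.integer(n))
  rep(seq_len(m), diff(cuts))
}

#' Partitions for every combination in an enumeration
#'
#' @param combos Output of [enumerate_combinations()].
#' @param themes The theme tibble the enumeration indexed into.
#' @param n Domain length.
#' @return A list of integer label vectors, one per combination.
#' @export
combination_partitions <- function(combos, themes, n) {
  lapply(combos$members, function(idx) {
    combination_partition(themes$start[idx], themes$end[idx], n)
  })
}

#' Combination table in long format
#'
#' @inheritParams combination_partitions
#' @return A tibble with `combo_id`, `position`, `theme_id`, `variation`,
#'   `start`, `end` suitable for TSV export.
#' @export
combinations_long <- function(combos, themes) {
  purrr::map2_dfr(combos$combo_id, combos$members, function(id, idx) {
    tibble(combo_id = id, position = seq_along(idx),
           theme_id = themes$theme_id[idx], variation = themes$variation[idx],
           start = themes$start[idx], end = themes$end[idx])
  })
}
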
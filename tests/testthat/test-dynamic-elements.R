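test_that("dynamic segments are the maximal constant-sense runs", {
  s <- c(1L, 1L, -1L, -1L, -1L, 1L)
  seg <- dynamic_segments(s)
  expect_equal(seg$start, c(1L, 3L, 6L))
  expect_equal(seg$end, c(2L, 5L, 6L))
  expect_equal(seg$sense, c(1L, -1L, 1L))

  one <- dynamic_segments(rep(1L, 20))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(1L, 20L))

  alt <- dynamic_segments(rep(c(1L, -1L), 10))
  expect_equal(nrow(alt), 20L)
  expect_true(all(alt$length == 1L))
})

test_that("the merge rule collapses short runs and flags undecomposable modes", {
  runs <- function(lens, first = 1L) {
    rep(rep_len(c(first, -first), length(lens)), lens)
  }
  # short interior run disappears and the flanks coalesce
  el <- smooth_to_elements(dynamic_segments(runs(c(20, 10, 20))))
  expect_equal(nrow(el), 1L)
  expect_equal(c(el$start, el$end), c(1L, 50L))

  # nothing below threshold: unchanged
  el2 <- smooth_to_elements(dynamic_segments(runs(c(20, 30, 25))))
  expect_equal(el2$length, c(20L, 30L, 25L))
  expect_equal(el2$sense, c(1L, -1L, 1L))
  expect_equal(el2$element_index, 1:3)

  # no run reaches 15 residues: the mode has no DE decomposition
  expect_null(smooth_to_elements(dynamic_segments(runs(c(5, 6, 5)))))
})

test_that("merge agrees with the residue-level oracle on random run patterns", {
  set.seed(18)
  mismatches <- 0L
  for (rep in 1:400) {
    lens <- sample(1:25, sample(2:7, 1), replace = TRUE)
    f <- sample(c(1L, -1L), 1)
    v <- rep(rep_len(c(f, -f), length(lens)), lens)
    got <- smooth_to_elements(dynamic_segments(v), min_len = 15L)
    want <- oracle_merge(v, min_len = 15L)
    agree <- if (is.null(want) || is.null(got)) {
      is.null(want) && is.null(got) &&
        max(rle(v)$lengths) < 15L
    } else {
      identical(got$start, want$start) && identical(got$end, want$end) &&
        identical(got$sense, want$sense)
    }
    if (!agree) mismatches <- mismatches + 1L
  }
  expect_equal(mismatches, 0L)
})

test_that("merge output tiles 1..n, alternates sense, conserves residues", {
  set.seed(71)
  for (rep in 1:60) {
    n <- sample(30:120, 1)
    lens <- integer(0)
    while (sum(lens) < n) lens <- c(lens, sample(1:40, 1))
    lens[length(lens)] <- lens[length(lens)] - (sum(lens) - n)
    lens <- lens[lens > 0]
    f <- sample(c(1L, -1L), 1)
    v <- rep(rep_len(c(f, -f), length(lens)), lens)
    el <- smooth_to_elements(dynamic_segments(v))
    if (is.null(el)) {
      expect_lt(max(rle(v)$lengths), 15L)
      next
    }
    expect_equal(el$start[1], 1L)
    expect_equal(el$end[nrow(el)], n)
    expect_equal(sum(el$length), n)
    expect_true(all(el$length >= 15L))
    if (nrow(el) > 1L) {
      expect_equal(el$start[-1], el$end[-nrow(el)] + 1L)
      expect_true(all(diff(el$sense) != 0L))
    }
    # global sense flip leaves the partition unchanged
    el_f <- smooth_to_elements(dynamic_segments(-v))
    expect_equal(el_f$start, el$start)
    expect_equal(el_f$sense, -el$sense)
  }
})

test_that("DE partitions label residues by containing element", {
  el <- tibble::tibble(element_index = 1:2, start = c(1L, 21L),
                       end = c(20L, 40L), sense = c(1L, -1L),
                       length = c(20L, 20L))
  expect_equal(de_partition(el), rep(1:2, each = 20))
  expect_equal(de_partition(el[1, ]), rep(1L, 20))
  expect_null(de_partition(NULL))

  # labels reconstruct the element boundaries exactly
  lab <- de_partition(el)
  r <- rle(lab)
  expect_equal(cumsum(r$lengths) - r$lengths + 1L, el$start)
  expect_equal(cumsum(r$lengths), el$end)
})

test_that("dynamic_elements reports N/A modes and keeps the rest", {
  dom <- synth_domain(n = 100, seed = 21)
  m <- gnm_modes(dom)
  el <- dynamic_elements(m, 1:7, min_len = 15L)
  expect_true(all(el$length >= 15L))
  analyzed <- sort(unique(el$mode))
  expect_true(all(analyzed %in% 1:7))
  # a huge min_len makes every mode N/A
  el_na <- dynamic_elements(m, 1:3, min_len = 1000L)
  expect_equal(nrow(el_na), 0L)
  expect_equal(attr(el_na, "na_modes"), 1:3)
  parts <- de_partitions(el_na, 1:3)
  expect_true(all(vapply(parts, is.null, logical(1))))
})
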
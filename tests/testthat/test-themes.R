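test_that("theme tables are validated, rejected or deduplicated as needed", {
  ok <- validate_themes(
    data.frame(theme_id = "T1", variation = 1L, start = 1L, end = 40L),
    n = 100, min_len = 35L)
  expect_equal(ok$length, 40L)

  expect_error(validate_themes(
    data.frame(theme_id = "T1", variation = 0L, start = 10L, end = 120L),
    n = 100), "row\\(s\\) 1")
  expect_error(validate_themes(
    data.frame(theme_id = "T1", variation = 0L, start = 50L, end = 40L),
    n = 100), "invalid theme interval")
  expect_error(validate_themes(
    data.frame(theme_id = "T1", variation = 0L, start = 1L, end = 20L),
    n = 100, min_len = 35L), "shorter")

  dup <- data.frame(theme_id = c("T1", "T1"), variation = 0L,
                    start = 1L, end = 40L)
  expect_warning(out <- validate_themes(dup, n = 100), "duplicate")
  expect_equal(nrow(out), 1L)

  # TSV round trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ok[, c("theme_id", "variation", "start", "end")], tsv)
  expect_equal(read_themes(tsv, n = 100), ok)
})

test_that("enumeration matches the brute-force subset oracle", {
  # the worked four-theme instance: only {(1,40),(41,100)} tiles n=100
  th <- tibble::tibble(theme_id = sprintf("t%d", 1:4), variation = 0L,
                       start = c(1L, 35L, 41L, 68L),
                       end = c(40L, 70L, 100L, 100L),
                       length = c(40L, 36L, 60L, 33L))
  got <- enumerate_combinations(th, 100, max_overlap = 5L, max_gap = 8L)
  want <- oracle_combinations(th, 100, 5L, 8L)
  expect_equal(nrow(got), length(want))
  expect_setequal(vapply(got$members, function(m) paste(sort(m), collapse = ","),
                         character(1)),
                  vapply(want, paste, character(1), collapse = ","))

  set.seed(404)
  for (rep in 1:60) {
    n <- sample(60:140, 1)
    m <- sample(4:10, 1)
    th <- random_theme_table(n, m, c(10L, 60L))
    o <- sample(c(0L, 3L, 5L), 1); g <- sample(c(5L, 8L, 15L), 1)
    got <- enumerate_combinations(th, n, o, g)
    want <- oracle_combinations(th, n, o, g)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_setequal(
        vapply(got$members, function(mm) paste(sort(mm), collapse = ","),
               character(1)),
        vapply(want, paste, character(1), collapse = ","))
    }
    expect_equal(has_combination(th, n, o, g), length(want) > 0L)
  }
})

test_that("combination count is monotone in the thresholds", {
  set.seed(77)
  for (rep in 1:15) {
    n <- sample(80:150, 1)
    th <- random_theme_table(n, 8L, c(15L, 70L))
    base <- nrow(enumerate_combinations(th, n, 3L, 8L))
    expect_gte(nrow(enumerate_combinations(th, n, 5L, 8L)), base)
    expect_gte(nrow(enumerate_combinations(th, n, 3L, 15L)), base)
  }
})

test_that("the enumeration cap falls back to sampled combinations", {
  # 12 mutually compatible short themes give > 100 tilings
  n <- 60L
  th <- tibble::tibble(theme_id = sprintf("t%02d", 1:12), variation = 0L,
                       start = as.integer(seq(1, 45, 4)))
  th$end <- th$start + 15L
  th$length <- 16L
  total <- nrow(enumerate_combinations(th, n, 10L, 10L, cap = 1e5))
  expect_gt(total, 100L)
  expect_warning(capped <- enumerate_combinations(th, n, 10L, 10L, cap = 50L),
                 "sampled")
  expect_equal(nrow(capped), 50L)
  expect_true(attr(capped, "truncated"))
  keys <- vapply(capped$members, paste, character(1), collapse = ",")
  expect_false(any(duplicated(keys)))
})

test_that("single full-length theme yields exactly one combination", {
  th <- tibble::tibble(theme_id = "t1", variation = 0L, start = 1L,
                       end = 100L, length = 100L)
  cb <- enumerate_combinations(th, 100, 3L, 8L)
  expect_equal(nrow(cb), 1L)
  expect_equal(combination_partitions(cb, th, 100)[[1]], rep(1L, 100))
})

test_that("partitionization follows the overlap and nearest-boundary rules", {
  # overlap goes to the N-terminal theme: boundary after residue 50
  lab <- combination_partition(c(1L, 49L), c(50L, 100L), 100L)
  expect_equal(rle(lab)$lengths, c(50L, 50L))
  # gap split by nearest boundary, equidistant to the preceding theme
  lab2 <- combination_partition(c(1L, 47L), c(40L, 100L), 100L)
  expect_equal(lab2[41:46], c(1L, 1L, 1L, 2L, 2L, 2L))
  # terminal residues attach to the first/last theme
  lab3 <- combination_partition(c(5L, 60L), c(59L, 95L), 100L)
  expect_equal(lab3[1:4], rep(1L, 4))
  expect_equal(lab3[96:100], rep(2L, 5))
})

test_that("every emitted combination partitions all n residues", {
  set.seed(99)
  checked <- 0L; bad <- 0L
  for (rep in 1:15) {
    n <- sample(80:160, 1)
    # a guaranteed near-tiling plus random decoys
    m <- sample(3:5, 1)
    cuts <- sort(sample(seq(20L, n - 20L), m - 1L))
    tile <- tibble::tibble(
      theme_id = sprintf("tile%d", seq_len(m)), variation = 0L,
      start = c(1L, cuts + 1L) + sample(-2:2, m, TRUE),
      end = c(cuts, n) + sample(-2:2, m, TRUE))
    tile$start <- pmax(1L, pmin(tile$start, n))
    tile$end <- pmax(tile$start, pmin(tile$end, n))
    tile$length <- tile$end - tile$start + 1L
    th <- dplyr::bind_rows(tile, random_theme_table(n, 4L, c(30L, 90L)))
    cb <- enumerate_combinations(th, n, 5L, 10L)
    if (nrow(cb) == 0L) next
    for (p in combination_partitions(cb, th, n)) {
      ok <- length(p) == n &&
        identical(sort(unique(p)), seq_len(max(p))) &&
        all(diff(p) %in% c(0L, 1L)) &&   # contiguous clusters
        all(tabulate(p) >= 1L)
      if (!ok) bad <- bad + 1L
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
  expect_equal(bad, 0L)
})
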
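test_that("contingency tables reconstruct both marginals", {
  d <- rep(1:2, each = 2)
  expect_equal(contingency(d, d), diag(c(2L, 2L)), ignore_attr = TRUE)
  expect_equal(contingency(rep(1L, 4), c(1L, 1L, 1L, 2L)),
               matrix(c(3L, 1L), 1), ignore_attr = TRUE)
  expect_error(contingency(1:3, 1:4), "length mismatch")

  set.seed(3)
  for (rep in 1:20) {
    dl <- sample(1:4, 50, TRUE); tl <- sample(1:3, 50, TRUE)
    tab <- contingency(dl, tl)
    expect_equal(rowSums(tab), tabulate(dl, 4), ignore_attr = TRUE)
    expect_equal(colSums(tab), tabulate(tl, 3), ignore_attr = TRUE)
  }
})

test_that("mutual information matches closed forms and its bounds", {
  m <- mutual_information(diag(c(2, 2)))
  expect_equal(m$mi, log(2))
  expect_equal(mutual_information(matrix(c(3, 1), 1))$mi, 0)

  set.seed(8)
  for (rep in 1:40) {
    tab <- random_contingency(sample(2:5, 1), sample(2:5, 1), 40)
    m <- mutual_information(tab)
    expect_gte(m$mi, 0)
    expect_lte(m$mi, min(m$h_d, m$h_t) + 1e-12)
    # the fast label-vector path agrees with the table path
    dl <- rep(rep(seq_len(nrow(tab)), ncol(tab)), as.vector(tab))
    tl <- rep(rep(seq_len(ncol(tab)), each = nrow(tab)), as.vector(tab))
    expect_equal(themedyn:::mi_value(dl, tl), m$mi)
  }
})

test_that("MI is log-base invariant up to the base factor, AMI exactly", {
  set.seed(12)
  tab <- random_contingency(3, 3, 36)
  m <- mutual_information(tab)
  # rescaling checks: log2 MI = MI / ln 2 by construction of the nats form
  expect_equal(m$mi / log(2),
               sum(ifelse(tab > 0, (tab / 36) * log2(36 * tab /
                 outer(rowSums(tab), colSums(tab))), 0)))
})

test_that("degenerate tables give zero EMI and variance", {
  expect_equal(expected_mi(matrix(c(5, 7, 3), 1)), 0)
  expect_equal(var_mi(matrix(c(5, 7, 3), 1)), 0)
  expect_equal(var_mi(matrix(c(5, 7, 3), 3)), 0)
})

test_that("analytic EMI and Var(MI) match a permutation oracle on small tables", {
  set.seed(2024)
  for (rep in 1:8) {
    tab <- random_contingency(sample(2:4, 1), sample(2:4, 1), 30)
    o <- oracle_perm_mi(tab, B = 20000L)
    expect_lt(abs(expected_mi(tab) - o$emi), 3 * o$se_emi)
    expect_lt(abs(sqrt(var_mi(tab)) - sqrt(o$vmi)), 3 * o$se_sd)
    expect_gte(expected_mi(tab), 0)
    expect_gte(var_mi(tab), 0)
  }
})

test_that("AMI is 1 for identical partitions, 0 at chance, relabel-invariant", {
  lab <- rep(1:3, c(10, 14, 6))
  s <- mi_stats(lab, lab)
  expect_equal(s$ami, 1)
  expect_equal(s$mi, s$h_d)

  # relabeling either partition changes nothing
  relab <- c(2L, 3L, 1L)[lab]
  s2 <- mi_stats(lab, relab)
  expect_equal(s2$ami, 1)

  set.seed(5)
  dl <- sample(1:3, 60, TRUE); tl <- sample(1:4, 60, TRUE)
  a <- mi_stats(dl, tl)
  b <- mi_stats(c(3L, 1L, 2L)[dl], c(4L, 3L, 2L, 1L)[tl])
  expect_equal(a$ami, b$ami, tolerance = 1e-12)
  expect_equal(a$smi, b$smi, tolerance = 1e-12)
  # max-entropy normalization makes AMI symmetric in its two arguments
  sw <- mi_stats(tl, dl)
  expect_equal(a$ami, sw$ami, tolerance = 1e-12)
  expect_equal(a$smi, sw$smi, tolerance = 1e-12)
})

test_that("SMI is missing when the null variance vanishes", {
  s <- mi_stats(rep(1L, 20), rep(1:2, each = 10))
  expect_true(is.na(s$smi))
  expect_equal(s$mi, 0)
})

test_that("per-mode summaries bracket the individual scores", {
  set.seed(9)
  dom <- synth_domain(n = 90, seed = 31)
  el <- dynamic_elements(gnm_modes(dom), 1:3)
  th <- plant_themes(el, target_mode = 1)
  cb <- enumerate_combinations(th, 90, 5L, 10L)
  pt <- combination_partitions(cb, th, 90)
  sc <- score_combinations(de_partitions(el, 1:3), pt)
  sm <- mode_theme_summary(sc)
  for (k in unique(sc$mode[!is.na(sc$combo_id)])) {
    rows <- sc[sc$mode == k, ]
    srow <- sm[sm$mode == k, ]
    expect_equal(srow$mean_ami, mean(rows$ami))
    expect_equal(srow$max_ami, max(rows$ami))
    expect_gte(srow$max_ami, srow$min_ami)
    expect_true(all(rows$ami <= srow$max_ami + 1e-12))
  }
  # single combination: mean = min = max
  sc1 <- score_combinations(de_partitions(el, 1:1), pt[1])
  sm1 <- mode_theme_summary(sc1)
  expect_equal(sm1$mean_ami, sm1$max_ami)
  expect_equal(sm1$mean_smi, sm1$min_smi)
})
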
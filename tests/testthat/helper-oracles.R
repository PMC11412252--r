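# Independent brute-force oracles used to pin down the package's algorithms.
# These deliberately take the dumbest correct route so they share no code
# with the implementation they check.

# --- DE merge rule, residue-level re-implementation -------------------------
# Repeatedly: recompute runs from the raw sense vector, pick the shortest
# run below min_len (ties: most N-terminal), overwrite its residues with the
# sense of its longer neighbor (boundary: the only neighbor; interior
# length tie: the preceding neighbor), and start over.
oracle_merge <- function(senses, min_len = 15L) {
  repeat {
    r <- rle(senses)
    if (max(r$lengths) < min_len) return(NULL)
    short <- which(r$lengths < min_len)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    m <- length(r$lengths)
    nb <- if (i == 1L) 2L else if (i == m) m - 1L else {
      if (r$lengths[i + 1L] > r$lengths[i - 1L]) i + 1L else i - 1L
    }
    ends <- cumsum(r$lengths)
    pos <- (ends[i] - r$lengths[i] + 1L):ends[i]
    senses[pos] <- r$values[nb]
  }
  r <- rle(senses)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends, sense = r$values)
}

# all sense vectors of length n with at most max_runs alternating runs
all_run_vectors <- function(n, max_runs = 6L) {
  out <- list()
  comp <- function(rem, parts) {
    if (rem == 0L) { out[[length(out) + 1L]] <<- parts; return(invisible()) }
    if (length(parts) >= max_runs) return(invisible())
    for (p in seq_len(rem)) comp(rem - p, c(parts, p))
  }
  comp(n, integer(0))
  vecs <- list()
  for (parts in out) {
    for (first in c(1L, -1L)) {
      s <- rep(rep_len(c(first, -first), length(parts)), parts)
      vecs[[length(vecs) + 1L]] <- s
    }
  }
  vecs
}

# --- combination enumeration by subset filtering ----------------------------
oracle_combinations <- function(themes, n, max_overlap, max_gap) {
  m <- nrow(themes)
  valid <- list()
  for (mask in seq_len(2^m - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    ord <- idx[order(themes$start[idx])]
    s <- themes$start[ord]; e <- themes$end[ord]
    if (any(duplicated(s))) next
    ok <- s[1] - 1L <= max_gap && n - e[length(e)] <= max_gap
    if (ok && length(ord) > 1L) {
      for (i in seq_len(length(ord) - 1L)) {
        if (s[i + 1L] <= s[i] || e[i + 1L] <= e[i]) { ok <- FALSE; break }
        ov <- e[i] - s[i + 1L] + 1L
        gp <- s[i + 1L] - e[i] - 1L
        if (ov > max_overlap || gp > max_gap) { ok <- FALSE; break }
      }
    }
    if (ok) valid[[length(valid) + 1L]] <- sort(ord)
  }
  valid
}

# --- permutation oracle for EMI / Var(MI) -----------------------------------
# Exact sampler of the fixed-marginal permutation null: tables are drawn by
# the nested multivariate-hypergeometric chain (row by row, column by column
# via rhyper), which is the distribution induced by randomly pairing the two
# label vectors. Vectorized over all B draws at once.
oracle_perm_mi <- function(tab, B) {
  N <- sum(tab); k <- nrow(tab); l <- ncol(tab)
  d <- rowSums(tab); t <- colSums(tab)
  ln <- log(N)
  lab <- log(d)[(seq_len(k * l) - 1L) %% k + 1L] +
    log(t)[(seq_len(k * l) - 1L) %/% k + 1L]
  cnt <- matrix(0, k * l, B)
  rem_t <- matrix(rep(t, B), l, B)
  for (i in seq_len(k)) {
    left <- rep(d[i], B)
    for (j in seq_len(l - 1L)) {
      after <- colSums(rem_t[(j + 1L):l, , drop = FALSE])
      nij <- stats::rhyper(B, rem_t[j, ], after, left)
      cnt[i + k * (j - 1L), ] <- nij
      left <- left - nij
      rem_t[j, ] <- rem_t[j, ] - nij
    }
    cnt[i + k * (l - 1L), ] <- left
    rem_t[l, ] <- rem_t[l, ] - left
  }
  mis <- (colSums(cnt * log(pmax(cnt, 1))) + colSums(cnt * (ln - lab))) / N
  m2 <- var(mis)
  m4 <- mean((mis - mean(mis))^4)  # MI's null is skewed: no normal shortcut
  list(emi = mean(mis), vmi = m2,
       se_emi = sd(mis) / sqrt(B),
       se_sd = sqrt(max(m4 - m2^2, 0) / (4 * m2 * B)))
}

random_contingency <- function(k, l, N) {
  repeat {
    tab <- matrix(tabulate(sample.int(k * l, N, replace = TRUE), k * l), k, l)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

random_theme_table <- function(n, m, len_range = c(8L, 40L)) {
  len <- sample(len_range[1]:min(len_range[2], n), m, replace = TRUE)
  start <- vapply(len, function(L) sample.int(n - L + 1L, 1L), integer(1))
  tibble::tibble(theme_id = sprintf("t%02d", seq_len(m)), variation = 0L,
                 start = as.integer(start), end = as.integer(start + len - 1L),
                 length = as.integer(len))
}

# minimal hand-written PDB text fixture
write_tiny_pdb <- function(path, resno, xyz, chain = "A", skip_ca_for = integer(0),
                           extra_lines = character(0)) {
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(resno)) {
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  N   ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
      serial, chain, resno[i], xyz[i, 1] - 1, xyz[i, 2], xyz[i, 3]))
    if (!(i %in% skip_ca_for)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, chain, resno[i], xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    }
  }
  writeLines(c(lines, extra_lines, "END"), path)
  path
}
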
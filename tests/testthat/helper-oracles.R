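# Independent brute-force oracles.  These deliberately re-derive each
# quantity with the most literal algorithm available (explicit loops,
# closed-form Gaussian) so that agreement with the package implementation
# is a genuine cross-check, not a tautology.

# Exact Gaussian KDE by double loop (no dnorm, no vectorisation).
oracle_gauss_density <- function(grid, xs, bw) {
  out <- numeric(length(grid))
  for (i in seq_along(grid)) {
    s <- 0
    for (x in xs) s <- s + exp(-(grid[i] - x)^2 / (2 * bw^2))
    out[i] <- s / (length(xs) * bw * sqrt(2 * pi))
  }
  out
}

# Peak counting under the shared definition (plateaus collapsed, strict
# maxima, rise above the higher adjacent valley of at least 1% of the curve
# maximum), coded with explicit while-loops.
oracle_count_peaks <- function(dens, prom = 0.01) {
  keep <- c(TRUE, diff(dens) != 0)
  v <- dens[keep]
  m <- length(v)
  if (m < 2) return(0L)
  cut <- prom * max(dens)
  peaks <- 0L
  for (j in seq_len(m)) {
    left <- if (j > 1) v[j - 1] else -Inf
    right <- if (j < m) v[j + 1] else -Inf
    if (!(v[j] > left && v[j] > right)) next
    lo_l <- v[j]; i <- j - 1
    while (i >= 1 && v[i] < v[j]) { lo_l <- min(lo_l, v[i]); i <- i - 1 }
    lo_r <- v[j]; i <- j + 1
    while (i <= m && v[i] < v[j]) { lo_r <- min(lo_r, v[i]); i <- i + 1 }
    if (j == 1) lo_l <- v[j]
    if (j == m) lo_r <- v[j]
    if (v[j] - max(lo_l, lo_r) >= cut) peaks <- peaks + 1L
  }
  peaks
}

oracle_kde_peaks <- function(lengths, bw, step = bw / 10) {
  grid <- seq(min(lengths) - 3 * bw, max(lengths) + 3 * bw, by = step)
  oracle_count_peaks(oracle_gauss_density(grid, lengths, bw))
}

# Linear scan through RAF cells for one SEQRES index.
oracle_seqres_to_atom <- function(record, i) {
  count <- 0L
  for (k in seq_len(nrow(record$cells))) {
    if (record$cells$seqres_aa[k] == ".") next
    count <- count + 1L
    if (count == i) {
      if (record$cells$atom_aa[k] != ".")
        return(list(resolved = TRUE, residue_id = record$cells$residue_id[k]))
      return(list(resolved = FALSE,
                  residue_id = if (record$version == "0.03")
                    record$cells$residue_id[k] else NA_character_))
    }
  }
  stop("index out of range")
}

# Exhaustive search for the nearest resolved residue(s).
oracle_nearest_resolved <- function(record, i) {
  cells <- record$cells
  sq <- which(cells$seqres_aa != ".")
  best <- Inf
  hits <- integer()
  for (p in seq_along(sq)) {
    if (cells$atom_aa[sq[p]] == ".") next
    d <- abs(p - i)
    if (d < best) { best <- d; hits <- p }
    else if (d == best) hits <- c(hits, p)
  }
  if (!length(hits))
    return(data.frame(residue_id = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  data.frame(residue_id = cells$residue_id[sq[hits]],
             distance = abs(hits - i), stringsAsFactors = FALSE)
}

# Re-derive the legacy B/M/E placeholders of a version-0.02 record from a
# converted 0.03 record: inverse of the id assignment.
strip_v3_ids <- function(record) {
  cells <- record$cells
  gap <- cells$atom_aa == "." & cells$seqres_aa != "."
  observed <- which(!gap)
  first_obs <- if (length(observed)) observed[1] else nrow(cells) + 1L
  last_obs <- if (length(observed)) observed[length(observed)] else 0L
  cells$residue_id[gap] <- vapply(which(gap), function(i) {
    if (i < first_obs) "B" else if (i > last_obs) "E" else "M"
  }, "")
  raf_record(record$pdb_id, record$chain_id, cells, version = "0.02",
             flags = record$flags)
}

# Random length sets for KDE oracle sweeps: 1-3 modes, modest noise.
random_length_instance <- function() {
  n_modes <- sample(1:3, 1)
  modes <- sample(60:300, n_modes)
  n <- sample(5:40, 1)
  lens <- round(modes[sample(n_modes, n, replace = TRUE)] +
                  stats::rnorm(n, 0, sample(1:8, 1)))
  pmax(lens, 10L)
}

random_inc_table <- function(n_rows) {
  codes <- heterogeneity_codes()$code
  out <- data.frame(
    sccs = sprintf("%s.%d.%d.%d", sample(letters[1:7], n_rows, replace = TRUE),
                   sample(1:300, n_rows, replace = TRUE),
                   sample(1:9, n_rows, replace = TRUE),
                   sample(1:9, n_rows, replace = TRUE)),
    code = sample(codes, n_rows, replace = TRUE),
    stringsAsFactors = FALSE)
  out$sids <- lapply(seq_len(n_rows), function(i) {
    k <- sample(0:4, 1)
    if (!k) character(0)
    else sprintf("d%04x%s_", sample(0:65535, k), sample(letters[1:4], k,
                                                        replace = TRUE))
  })
  out
}

random_rep_table <- function(n_rows) {
  start <- sample(1:200, n_rows, replace = TRUE)
  data.frame(
    sccs = sprintf("a.%d.1.%d", sample(1:300, n_rows, replace = TRUE),
                   sample(1:9, n_rows, replace = TRUE)),
    sid = sprintf("d%04x%s_", sample(0:65535, n_rows, replace = TRUE),
                  sample(letters[1:4], n_rows, replace = TRUE)),
    unit_start = as.character(start),
    unit_end = as.character(start + sample(5:60, n_rows, replace = TRUE)),
    stringsAsFactors = FALSE)
}
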
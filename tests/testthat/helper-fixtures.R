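# Shared fixtures and independent oracles, built in code at test time.

# small regular lattice cell table
make_lattice_cells <- function(nx = 4, ny = 3, P = 0, area = 1) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cell_table(cell_id = sprintf("c%03d", seq_len(nx * ny)),
             x = g$x, y = g$y,
             area = rep(area, length.out = nx * ny),
             P = rep(P, length.out = nx * ny))
}

# brute-force all-pairs AUC oracle (ties counted 1/2)
auc_bruteforce <- function(scores, presence) {
  pos <- scores[presence == 1]
  neg <- scores[presence == 0]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(pos) * length(neg))
}

# brute-force Benjamini-Hochberg step-up oracle
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) / m * q)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  reject
}

# all permutations of a small vector (for exhaustive null-model enumeration)
all_perms <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in all_perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}
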
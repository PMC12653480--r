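# Independent brute-force oracles and small fixture builders shared by
# the tests. These deliberately avoid the package's own code paths.

# conservation by literal counting over a character matrix column
brute_conservation <- function(mat) {
  valid_set <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
  t(apply(mat, 2, function(col) {
    v <- col[col %in% valid_set]
    if (length(v) == 0) return(c(Ci = 0, ni = 0))
    c(Ci = max(table(v)) / length(v), ni = length(v))
  }))
}

# all-pairs neighbor stats by explicit double loop
brute_neighbor_stats <- function(xyz, radius = 8.0) {
  n <- nrow(xyz)
  Ni <- integer(n); Di <- numeric(n)
  for (i in seq_len(n)) {
    dmin <- Inf; cnt <- 0L
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= radius) cnt <- cnt + 1L
      if (d < dmin) dmin <- d
    }
    Ni[i] <- cnt; Di[i] <- dmin
  }
  list(Ni = Ni, Di = Di)
}

# random proper rotation matrix
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# tiny deterministic aligned family
toy_family <- function() {
  aligned_family(c(a = "MKVLAW", b = "MKVLAW", c = "MKILGW", d = "MKILG-"))
}

# the seven TM ranges of a 356-residue OR with cytoplasmic N-terminus
or_topology <- function() {
  topology_spec(356, list(c(11, 31), c(42, 62), c(103, 123), c(157, 177),
                          c(234, 254), c(265, 285), c(336, 356)),
                "cytoplasmic")
}

# 5-taxon alignment whose columns are identical copies of one
# clade-informative column; every bootstrap resample is the alignment
# itself, so support must be unanimous
unanimous_family <- function(L = 40) {
  base <- c(t1 = "A", t2 = "A", t3 = "L", t4 = "L", t5 = "V")
  aligned_family(vapply(base, function(s) paste(rep(s, L), collapse = ""), ""))
}
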
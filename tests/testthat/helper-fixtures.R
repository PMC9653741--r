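# Small in-code fixtures and independent oracles shared across tests.

tiny_count_table <- function() {
  counts <- matrix(c(3, 10, 0,
                     4, 0, 2,
                     600, 600, 600,
                     399, 390, 398),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("asv1", "asv2", "asv3", "asv4"),
                                   c("s1", "s2", "s3")))
  lineage <- c(
    "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Blautia;Blautia_sp1",
    "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Blautia;Blautia_sp1",
    "Bacteria;Firmicutes;Clostridia;Lachnospirales;Lachnospiraceae;Roseburia;Roseburia_sp1",
    "Bacteria;Bacteroidota;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides")
  count_table(counts, lineage)
}

random_composition <- function(n, d, seed = 42) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * d), n, d,
              dimnames = list(sprintf("s%d", seq_len(n)),
                              sprintf("p%d", seq_len(d))))
  closure(m)
}

random_orthonormal_basis <- function(D, seed = 7) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(D * (D - 1)), D))))
  Q[, -1, drop = FALSE]   # orthogonal to 1, orthonormal columns
}

# exhaustive nearest-balance oracle: enumerate every disjoint nonempty
# (numerator, denominator) assignment of D taxa; returns the best score
# (inner product of unit contrast with b) and one maximizing assignment
exhaustive_nearest_balance <- function(b) {
  D <- length(b)
  stopifnot(D <= 10)
  assign_grid <- as.matrix(expand.grid(rep(list(0:2), D)))  # 0 out, 1 num, 2 den
  num <- assign_grid == 1
  den <- assign_grid == 2
  kp <- rowSums(num); km <- rowSums(den)
  valid <- kp > 0 & km > 0
  num <- num[valid, , drop = FALSE]; den <- den[valid, , drop = FALSE]
  kp <- kp[valid]; km <- km[valid]
  score <- sqrt(km / (kp * (kp + km))) * as.vector(num %*% b) -
    sqrt(kp / (km * (kp + km))) * as.vector(den %*% b)
  i <- which.max(score)
  list(score = score[i], num = which(num[i, ]), den = which(den[i, ]))
}

# expected Jaccard index between two independent uniform k-subsets of D
# elements (hypergeometric overlap), by exact enumeration
expected_random_jaccard <- function(k, D) {
  m <- 0:k
  p <- stats::dhyper(m, k, D - k, k)
  sum(p * m / (2 * k - m))
}


write_tmp_tsv <- function(df, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
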
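test_that("zero replacement substitutes on the count scale then closes", {
  m <- matrix(c(0, 10), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  comp <- zero_replace(count_table(m))
  expect_equal(unname(comp[1, ]), c(0.5, 10) / 10.5, tolerance = 1e-12)
  expect_equal(unname(zero_replace(count_table(
    matrix(c(0, 0, 1), 3, dimnames = list(letters[1:3], "s"))))[1, ]),
    c(0.25, 0.25, 0.5))
  # all-positive counts: plain closure
  m2 <- matrix(c(2, 3, 5, 10), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(zero_replace(count_table(m2)), closure(t(m2)))
  expect_error(zero_replace(count_table(
    matrix(c(0, 0), 2, dimnames = list(c("a", "b"), "s")))), "all-zero")
})

test_that("clr matches hand-computed values and rows sum to zero", {
  expect_equal(unname(clr(c(0.25, 0.25, 0.25, 0.25))), rep(0, 4))
  expect_equal(unname(clr(c(0.5, 0.25, 0.25))),
               c(2, -1, -1) * log(2) / 3, tolerance = 1e-12)
  comp <- random_composition(20, 12)
  expect_lt(max(abs(rowSums(clr(comp)))), 1e-10)
  expect_error(clr(c(0.5, 0, 0.5)), "zero_replace")
})

test_that("ilr is an isometry with exact round trip", {
  comp <- random_composition(15, 9)
  V <- ilr_basis(9)
  expect_equal(crossprod(V), diag(8), tolerance = 1e-12)
  expect_lt(max(abs(colSums(V))), 1e-12)
  y <- ilr(comp, V)
  expect_lt(max(abs(ilr_inverse(y, V) - comp)), 1e-10)
  # uniform composition -> origin
  expect_equal(unname(ilr(rep(1 / 9, 9), V)), rep(0, 8), tolerance = 1e-12)
  # ilr Euclidean distance equals Aitchison distance for ANY orthonormal basis
  V2 <- random_orthonormal_basis(9)
  d_ilr <- as.matrix(dist(ilr(comp, V2)))
  expect_equal(d_ilr, aitchison_distance(comp), tolerance = 1e-10)
  expect_error(ilr(comp, ilr_basis(5)), "basis")
})

test_that("Aitchison distance matches the hand example and its geometry", {
  x <- c(0.5, 0.25, 0.25); y <- c(0.25, 0.25, 0.5)
  d <- aitchison_distance(rbind(x, y))
  expect_equal(d[1, 2], log(2) * sqrt(2), tolerance = 1e-10)
  expect_equal(round(d[1, 2], 4), 0.9803)
  expect_equal(diag(d), c(x = 0, y = 0), ignore_attr = TRUE)
  # perturbation invariance d(x+p, y+p) = d(x, y)
  comp <- random_composition(6, 7)
  p <- random_composition(1, 7, seed = 9)[1, ]
  expect_equal(aitchison_distance(perturb(comp, p)), aitchison_distance(comp),
               tolerance = 1e-10)
  # triangle inequality on random triples
  d2 <- aitchison_distance(comp)
  for (tri in list(c(1, 2, 3), c(2, 4, 6), c(1, 5, 3))) {
    expect_lte(d2[tri[1], tri[3]], d2[tri[1], tri[2]] + d2[tri[2], tri[3]] + 1e-12)
  }
})

test_that("perturbation is the simplex group operation", {
  x <- random_composition(1, 6, seed = 2)[1, ]
  p <- random_composition(1, 6, seed = 3)[1, ]
  expect_equal(perturb(x, rep(1 / 6, 6)), x, tolerance = 1e-12)
  pinv <- closure(1 / p)
  expect_equal(perturb(perturb(x, p), pinv), x, tolerance = 1e-12)
  V <- ilr_basis(6)
  expect_equal(ilr(perturb(x, p), V), ilr(x, V) + ilr(p, V), tolerance = 1e-10)
})

test_that("sample-type correction centres stool on biopsy, basis-free", {
  stool <- random_composition(7, 10, seed = 21)
  biopsy <- random_composition(5, 10, seed = 22)
  corr <- sample_type_correction(stool, biopsy)
  V <- ilr_basis(10)
  expect_lt(max(abs(colMeans(ilr(corr, V)) - colMeans(ilr(biopsy, V)))), 1e-8)
  # basis invariance
  corr2 <- sample_type_correction(stool, biopsy,
                                  basis = random_orthonormal_basis(10))
  expect_lt(max(abs(corr - corr2)), 1e-8)
  # closed-form perturbation route: shift = gm(biopsy) (-) gm(stool)
  gm <- function(m) apply(m, 2L, function(v) exp(mean(log(v))))
  shift <- closure(gm(biopsy) / gm(stool))
  expect_lt(max(abs(corr - perturb(stool, shift))), 1e-8)
  # one stool + one biopsy: corrected stool IS the biopsy composition
  corr1 <- sample_type_correction(stool[1, , drop = FALSE],
                                  biopsy[1, , drop = FALSE])
  expect_equal(unname(corr1[1, ]), unname(biopsy[1, ]), tolerance = 1e-10)
})

test_that("taxonomic aggregation sums ASVs and conserves totals", {
  tab <- tiny_count_table()
  sp <- aggregate_to_rank(tab, "species")
  # two ASVs of the same species merge
  expect_equal(nrow(sp$counts), 3)
  merged <- sp$counts[grep("Blautia_sp1", rownames(sp$counts)), ]
  expect_equal(unname(merged), unname(tab$counts[1, ] + tab$counts[2, ]))
  # per-sample totals conserved at every rank
  for (r in c("phylum", "family", "genus", "species")) {
    agg <- aggregate_to_rank(tab, r)
    expect_equal(colSums(agg$counts), colSums(tab$counts))
  }
  # genus-level rows = distinct genus prefixes (unclassified grouped)
  gen <- aggregate_to_rank(tab, "genus")
  expect_equal(nrow(gen$counts), 3)  # Blautia, Roseburia, Bacteroides
  # taxon unclassified below family groups under a placeholder
  expect_true(any(grepl("unclassified", rownames(aggregate_to_rank(tab, "species")$counts))))
})
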
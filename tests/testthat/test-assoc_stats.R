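make_perm_fixture <- function(n = 24, D = 15, seed = 17) {
  set.seed(seed)
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     grp = sample(rep(c("a", "b"), n / 2)),
                     cov = rnorm(n))
  comp <- random_composition(n, D, seed = seed + 1)
  rownames(comp) <- meta$sample_id
  list(meta = meta, d = aitchison_distance(comp))
}

test_that("permanova matches the vegan oracle on covariate-adjusted designs", {
  skip_if_not_installed("vegan")
  fx <- make_perm_fixture()
  res <- permanova(fx$d, fx$meta, assoc_design("grp", covariates = "cov"),
                   n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(fx$d) ~ cov + grp, data = fx$meta,
                        permutations = 99, by = "terms")
  expect_equal(res$R2, ref["grp", "R2"], tolerance = 1e-8)
  expect_equal(res$F, ref["grp", "F"], tolerance = 1e-8)
  # and on the plain no-covariate design
  res2 <- permanova(fx$d, fx$meta, assoc_design("grp"), n_perm = 99, seed = 1)
  ref2 <- vegan::adonis2(as.dist(fx$d) ~ grp, data = fx$meta,
                         permutations = 99, by = "terms")
  expect_equal(res2$R2, ref2["grp", "R2"], tolerance = 1e-8)
  expect_equal(res2$F, ref2["grp", "F"], tolerance = 1e-8)
})

test_that("permanova saturates on point-separated groups", {
  n <- 16
  comp <- rbind(matrix(rep(c(0.7, 0.2, 0.1), each = 8), nrow = 8),
                matrix(rep(c(0.1, 0.2, 0.7), each = 8), nrow = 8))
  comp <- comp + 0  # two exact point compositions
  rownames(comp) <- sprintf("s%d", 1:n)
  meta <- data.frame(sample_id = rownames(comp),
                     grp = rep(c("x", "y"), each = 8))
  res <- permanova(aitchison_distance(comp), meta, assoc_design("grp"),
                   n_perm = 199, seed = 2)
  expect_gt(res$R2, 0.999)
  # add-one estimator: 1/(n_perm+1) unless a permutation recreates the
  # perfect split (possible by chance), which adds at most one tie here
  expect_lte(res$p, 2 / 200)
})

test_that("permanova conditions the factor on covariates", {
  # distance structure fully generated by a smooth covariate gradient
  set.seed(33)
  n <- 40
  cov <- sort(rnorm(n))
  base <- closure(exp(cbind(cov, -cov, cov / 2, 0 * cov)))
  rownames(base) <- sprintf("s%d", 1:n)
  meta <- data.frame(sample_id = rownames(base),
                     grp = sample(c("a", "b"), n, TRUE), cov = cov)
  d <- aitchison_distance(base)
  res <- permanova(d, meta, assoc_design("grp", covariates = "cov"),
                   n_perm = 99, seed = 3)
  expect_lt(res$R2, 0.05)
  expect_gt(res$p, 0.05)
})

test_that("permanova is invariant to sample reordering and validates input", {
  fx <- make_perm_fixture(seed = 19)
  res <- permanova(fx$d, fx$meta, assoc_design("grp"), n_perm = 49, seed = 1)
  ord <- sample(nrow(fx$d))
  res2 <- permanova(fx$d[ord, ord], fx$meta, assoc_design("grp"),
                    n_perm = 49, seed = 1)
  expect_equal(res$R2, res2$R2, tolerance = 1e-10)
  expect_equal(res$F, res2$F, tolerance = 1e-10)
  # factor constant within every stratum is unpermutable
  meta <- fx$meta
  meta$strat <- meta$grp
  expect_error(permanova(fx$d, meta, assoc_design("grp", strata = "strat")),
               "constant within every stratum")
  expect_error(permanova(fx$d[, 1:10], fx$meta, assoc_design("grp")),
               "symmetric")
})

test_that("BH adjustment matches hand-derived step-up values", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.5)), c(0.01, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # monotone in ranks and idempotent on already-adjusted monotone input
  set.seed(4)
  p <- runif(20)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("alpha associations find planted effects with batch correction", {
  set.seed(51)
  n <- 50
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     n_lesions = sample(c("1", ">1"), n, TRUE, c(0.6, 0.4)),
                     other = sample(c("p", "q"), n, TRUE),
                     batch = rep(c("B1", "B2"), length.out = n))
  x <- as.numeric(meta$n_lesions == sort(unique(meta$n_lesions))[2])
  alpha <- data.frame(sample_id = meta$sample_id,
                      shannon = 3 - 1.0 * x + 0.2 * (meta$batch == "B2") +
                        rnorm(n, sd = 0.3))
  res <- suppressMessages(alpha_association(alpha, meta,
                                            c("n_lesions", "other")))
  row <- res[res$factor == "n_lesions", ]
  expect_lt(row$slope, 0)
  expect_lt(row$q, 0.05)
  expect_true(all(res$q >= res$p - 1e-12))
  meta$const <- "z"
  expect_error(suppressMessages(alpha_association(alpha, meta, "const")),
               "constant")
  # permuted factor: p-values are roughly uniform
  ps <- vapply(1:60, function(i) {
    m <- meta; m$n_lesions <- sample(m$n_lesions)
    suppressMessages(alpha_association(alpha, m, "n_lesions"))$p
  }, numeric(1))
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.5), 0.65)
})

test_that("componentwise analysis transforms, models and adjusts", {
  set.seed(61)
  truth <- synthetic_truth(n_taxa = 30, beta = 0, depth_median = 3e3, seed = 5)
  coh <- generate_cohort(n_patients = 24, truth = truth, seed = 6)
  stool <- coh$metadata$sample_id[coh$metadata$sample_type == "stool"]
  tab <- subset_count_table(coh$counts, samples = stool)
  # planted: inflate a mid-abundance taxon for one factor level (the most
  # abundant taxon would shift the Shannon covariate itself)
  target <- names(sort(coh$truth$mu, decreasing = TRUE))[6]
  lev <- coh$metadata$n_lesions[match(stool, coh$metadata$sample_id)]
  boost <- coh$metadata$sample_id[coh$metadata$sample_type == "stool" &
                                    coh$metadata$n_lesions == ">1"]
  tab$counts[target, boost] <- round(tab$counts[target, boost] * 6)
  res <- suppressMessages(componentwise(tab, coh$metadata,
                                        assoc_design("n_lesions",
                                                     random = "batch"),
                                        seed = 7))
  expect_true(target %in% res$taxon[res$q < 0.05])
  expect_true(all(res$q >= res$p - 1e-12))
  # null cohorts: BH keeps the q < 0.05 fraction controlled
  fracs <- vapply(1:8, function(s) {
    c0 <- generate_cohort(n_patients = 24, truth = truth, seed = 100 + s)
    st <- c0$metadata$sample_id[c0$metadata$sample_type == "stool"]
    r0 <- suppressMessages(componentwise(
      subset_count_table(c0$counts, samples = st), c0$metadata,
      assoc_design("n_lesions", random = "batch"), seed = s))
    mean(r0$q < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
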
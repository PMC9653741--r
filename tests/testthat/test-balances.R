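test_that("balance contrasts are unit-norm zero-sum and value matches clr dot", {
  taxa <- sprintf("t%d", 1:8)
  bal <- balance(c("t1", "t4", "t5"), c("t2", "t7"))
  v <- balance_contrast(bal, taxa)
  expect_equal(sum(v), 0, tolerance = 1e-12)
  expect_equal(sum(v^2), 1, tolerance = 1e-12)
  expect_equal(unname(v["t1"]), sqrt(2 / (3 * 5)))
  expect_equal(unname(v["t2"]), -sqrt(3 / (2 * 5)))
  comp <- random_composition(10, 8, seed = 31)
  colnames(comp) <- taxa
  expect_equal(unname(balance_value(bal, comp)),
               unname(clr(comp) %*% v)[, 1], tolerance = 1e-10)
  # scale invariance and hand examples
  expect_equal(unname(balance_value(bal, comp[1, ] * 977)),
               unname(balance_value(bal, comp[1, ])), tolerance = 1e-10)
  expect_equal(unname(balance_value(balance("a", "b"), c(a = exp(1), b = 1))),
               sqrt(0.5), tolerance = 1e-10)
  expect_equal(round(unname(balance_value(balance("a", "b"),
                                          c(a = exp(1), b = 1))), 4), 0.7071)
  expect_equal(unname(balance_value(balance(c("a", "b"), c("c", "d")),
                                    c(a = 3, b = 3, c = 3, d = 3))), 0)
  expect_error(balance("a", "a"), "disjoint")
  expect_error(balance_value(bal, comp[, 1:5]), "missing balance taxa")
})

test_that("nearest balance reproduces hand-enumerated candidates", {
  nb <- nearest_balance(c(t1 = 1, t2 = -1, t3 = 0))
  expect_identical(nb$num, "t1")
  expect_identical(nb$den, "t2")
  expect_equal(attr(nb, "cosine"), 1, tolerance = 1e-12)
  # b = (2, 1, -3): argmax is {t1,t2} / {t3}; runner-up {t1}/{t3} at 0.9449
  nb2 <- nearest_balance(c(t1 = 2, t2 = 1, t3 = -3))
  expect_setequal(nb2$num, c("t1", "t2"))
  expect_identical(nb2$den, "t3")
  expect_equal(round(attr(nb2, "cosine"), 4), 0.9820)
  single <- balance_contrast(balance("t1", "t3"), c("t1", "t2", "t3"))
  expect_equal(round(sum(single * c(2, 1, -3)) / sqrt(14), 4), 0.9449)
  # antisymmetry: negating b swaps numerator and denominator
  set.seed(11)
  for (i in 1:10) {
    b <- setNames(rnorm(6), sprintf("t%d", 1:6))
    nb_pos <- nearest_balance(b); nb_neg <- nearest_balance(-b)
    expect_setequal(nb_pos$num, nb_neg$den)
    expect_setequal(nb_pos$den, nb_neg$num)
  }
  expect_error(nearest_balance(c(a = 1)), "two taxa")
  expect_error(nearest_balance(c(a = 1, b = 1)), "constant")
})

test_that("sorted-threshold search equals the exhaustive oracle (unit sample)", {
  set.seed(23)
  for (i in 1:60) {
    D <- sample(3:8, 1)
    b <- setNames(rnorm(D), sprintf("t%d", seq_len(D)))
    nb <- nearest_balance(b)
    oracle <- exhaustive_nearest_balance(b)
    expect_equal(attr(nb, "score"), oracle$score, tolerance = 1e-10)
  }
})

test_that("clr association slopes sum to zero and are calibrated", {
  set.seed(41)
  n <- 30; D <- 25
  meta <- data.frame(sample_id = sprintf("s%d", 1:n),
                     grp = sample(c("a", "b"), n, TRUE),
                     cov = rnorm(n))
  comp <- random_composition(n, D, seed = 55)
  rownames(comp) <- meta$sample_id
  Y <- clr(comp)
  fit <- clr_association(Y, meta, assoc_design("grp", covariates = "cov"))
  expect_equal(sum(fit$b), 0, tolerance = 1e-8)
  expect_length(fit$p, D)
  # type-I: fraction of p < 0.05 near nominal across null simulations
  ps <- unlist(lapply(1:40, function(s) {
    m <- data.frame(sample_id = meta$sample_id,
                    grp = sample(meta$grp), cov = rnorm(n))
    clr_association(Y, m, assoc_design("grp", covariates = "cov"))$p
  }))
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.075)
  expect_error(clr_association(Y, transform(meta, grp = "a"),
                               assoc_design("grp")), "constant")
})

test_that("paired designs reduce exactly to within-pair differences", {
  set.seed(61)
  n_pair <- 12
  meta <- data.frame(sample_id = sprintf("s%d", 1:(2 * n_pair)),
                     patient_id = rep(sprintf("p%d", 1:n_pair), each = 2),
                     sample_type = rep(c("stool", "biopsy"), n_pair))
  Y <- matrix(rnorm(2 * n_pair * 6), 2 * n_pair, 6,
              dimnames = list(meta$sample_id, sprintf("t%d", 1:6)))
  fit <- clr_association(Y, meta,
                         assoc_design("sample_type", random = "patient_id"))
  expect_identical(fit$method, "paired")
  # oracle: per-taxon one-sample t-test on (level2 - level1) differences
  lev2 <- sort(unique(meta$sample_type))[2]
  d <- Y[meta$sample_type == lev2, ] - Y[meta$sample_type != lev2, ]
  for (j in c(1, 4, 6)) {
    tt <- t.test(d[, j])
    expect_equal(unname(fit$b[j]), unname(tt$estimate), tolerance = 1e-10)
    expect_equal(unname(fit$p[j]), tt$p.value, tolerance = 1e-10)
  }
})

test_that("planted balance direction is recovered at large effect", {
  truth <- synthetic_truth(n_taxa = 80, beta = 8, depth_median = 1e4, seed = 3)
  coh <- generate_cohort(n_patients = 50, truth = truth, seed = 4)
  stool <- coh$metadata$sample_id[coh$metadata$sample_type == "stool"]
  tab <- subset_count_table(coh$counts, samples = stool)
  Y <- clr(zero_replace(tab))
  fit <- suppressMessages(clr_association(
    Y, coh$metadata, assoc_design("n_lesions", random = "batch")))
  contrast <- balance_contrast(truth$planted_balance, truth$taxa)
  cosine <- sum(fit$b * contrast) / sqrt(sum(fit$b^2))
  expect_gt(cosine, 0.9)
})

test_that("reproducible balance is deterministic and honors the threshold rule", {
  truth <- synthetic_truth(n_taxa = 40, beta = 4, depth_median = 5e3, seed = 8)
  coh <- generate_cohort(n_patients = 30, truth = truth, seed = 9)
  des <- assoc_design("n_lesions", random = "batch")
  stool <- coh$metadata$sample_id[coh$metadata$sample_type == "stool"]
  tab <- subset_count_table(coh$counts, samples = stool)
  f1 <- suppressMessages(reproducible_balance(tab, coh$metadata, des,
                                              n_iter = 60, seed = 5))
  f2 <- suppressMessages(reproducible_balance(tab, coh$metadata, des,
                                              n_iter = 60, seed = 5))
  expect_identical(f1$balance, f2$balance)
  expect_identical(f1$freq_num, f2$freq_num)
  expect_true(all(f1$freq_num >= 0 & f1$freq_num <= 1))
  # membership is exactly the strict > threshold rule on the frequencies
  expect_setequal(f1$balance$num, names(which(f1$freq_num > f1$threshold)))
  expect_setequal(f1$balance$den, names(which(f1$freq_den > f1$threshold)))
  # a null factor at a strict threshold yields the empty-balance marker
  set.seed(99)
  meta_null <- coh$metadata
  meta_null$noise <- rep(sample(c("u", "v"), 30, TRUE), each = 2)
  f0 <- suppressMessages(reproducible_balance(
    tab, meta_null, assoc_design("noise", random = "batch"),
    n_iter = 60, threshold = 0.95, seed = 6))
  expect_true(is.null(f0$balance) || length(f0$balance$num) <= 2)
  expect_length(f0$freq_num, 40)
  # serialization round trip
  path <- tempfile(fileext = ".json")
  write_balance_fit(f1, path)
  expect_setequal(unlist(jsonlite::read_json(path)$numerator), f1$balance$num)
  tabfit <- balance_fit_table(f1)
  expect_true(all(tabfit$reproducibility > f1$threshold))
})

test_that("external evaluation matches direct values and sums clades", {
  spp <- c("Bacteria;P1;C1;O1;Fam1;Gen1;sp1",
           "Bacteria;P1;C1;O1;Fam1;Gen1;sp2",
           "Bacteria;P2;C2;O2;Fam2;Gen2;sp3")
  rel <- matrix(c(0.01, 0.02, 0.97,
                  0.20, 0.30, 0.50), nrow = 2, byrow = TRUE,
                dimnames = list(c("e1", "e2"), spp))
  # exact species matches: identical to balance_value
  bal_exact <- balance(spp[1], spp[3])
  ev <- evaluate_balance_external(bal_exact, rel)
  expect_equal(ev$values, balance_value(bal_exact, rel), tolerance = 1e-12)
  # unclassified-at-species member -> summed clade abundance (0.01+0.02)
  bal_clade <- balance("Bacteria;P1;C1;O1;Fam1;Gen1;unclassified", spp[3])
  ev2 <- evaluate_balance_external(bal_clade, rel)
  expect_equal(unname(ev2$values[1]), sqrt(0.5) * log(0.03 / 0.97),
               tolerance = 1e-12)
  expect_error(evaluate_balance_external(
    balance("Bacteria;P9;unclassified", spp[3]), rel), "no species match")
  # planted group shift is detected
  set.seed(71)
  n <- 100
  g <- rep(c("healthy", "crc"), each = n)
  base <- matrix(rexp(2 * n * 3), 2 * n, 3, dimnames = list(NULL, spp))
  base[g == "crc", 1] <- base[g == "crc", 1] * 3
  rel2 <- closure(base)
  ev3 <- evaluate_balance_external(bal_exact, rel2, group = g)
  expect_lt(ev3$comparison$p[1], 0.05)
})

test_that("sample-type AUC separates a strong shift and is null-calibrated", {
  truth <- synthetic_truth(n_taxa = 60, depth_median = 5e3, seed = 12)
  coh <- generate_cohort(n_patients = 20, truth = truth, seed = 13)
  res <- suppressMessages(sample_type_auc(coh$counts, coh$metadata,
                                          n_iter = 25, balance_iter = 30,
                                          seed = 3))
  expect_gte(res$mean, 0.95)
  # exchangeable types (no shift): AUC near 1/2
  truth0 <- synthetic_truth(n_taxa = 60, delta_type_norm = 0,
                            depth_median = 5e3, seed = 14)
  coh0 <- generate_cohort(n_patients = 20, truth = truth0, seed = 15)
  res0 <- suppressMessages(sample_type_auc(coh0$counts, coh0$metadata,
                                           n_iter = 25, balance_iter = 30,
                                           seed = 4))
  expect_gt(res0$mean, 0.3)
  expect_lt(res0$mean, 0.7)
})
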
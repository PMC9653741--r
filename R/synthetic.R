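center <- function(v) v - mean(v)

#' Ground truth for a synthetic paired cohort
#'
#' Describes the logistic-normal/multinomial generative model used by
#' [generate_cohort()]: a baseline clr mean with low-rank + diagonal
#' covariance, a sample-type (stool vs biopsy) clr perturbation, per-batch
#' perturbations, a planted balance whose contrast shifts the clr profile by
#' `beta` per unit of the linked factor, patient random effects and
#' residual noise, and a log-normal read-depth distribution.
#'
#' @param n_taxa number of taxa (default 150).
#' @param n_batches number of processing batches (default 2).
#' @param beta planted balance effect size: the population mean difference
#'   in the planted balance value per unit factor (default 3, a strong planted
#'   association: the balance score separates the factor levels cleanly, as
#'   the detected balances in real paired cohorts do).
#' @param balance_size numerator and denominator sizes of the planted
#'   balance (default 5 and 5).
#' @param factor_name metadata column the planted balance is linked to
#'   (default `"n_lesions"`, coded 0 for `"1"` and 1 for `">1"`).
#' @param delta_type_norm clr-space norm of the stool-to-biopsy shift
#'   (default 8, large enough that intra-pair dissimilarity dominates
#'   inter-patient same-type dissimilarity, as in real paired cohorts).
#' @param delta_batch_norm clr-space norm of each batch perturbation
#'   (default 3; a minor effect of a few percent of variance).
#' @param sigma_patient sd of the per-patient random clr effect (default
#'   0.15).
#' @param sigma_resid sd of the per-sample residual clr noise (default
#'   0.15).
#' @param sigma_diag sd of the diagonal part of the inter-patient clr
#'   covariance (default 0.15).
#' @param rank,loading_sd low-rank part of the covariance: `rank` factors
#'   with N(0, loading_sd^2) loadings (defaults 5 and 0.07).
#' @param depth_median,depth_sdlog log-normal read-depth parameters
#'   (defaults 3e4 and 0.45, matching 16S libraries of roughly
#'   3e4 +/- 1.5e4 reads).
#' @param mu_spread spread of the sorted baseline clr means (default 1.5,
#'   about three orders of magnitude between rarest and commonest taxa).
#' @param seed integer RNG seed used to draw the truth's fixed vectors.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(n_taxa = 150, n_batches = 2, beta = 3,
                            balance_size = c(5, 5),
                            factor_name = "n_lesions",
                            delta_type_norm = 8, delta_batch_norm = 3,
                            sigma_patient = 0.15, sigma_resid = 0.15,
                            sigma_diag = 0.15, rank = 5, loading_sd = 0.07,
                            depth_median = 3e4, depth_sdlog = 0.45,
                            mu_spread = 1.5, seed = 1L) {
  stopifnot(n_taxa >= 10, all(balance_size >= 1),
            sum(balance_size) <= n_taxa,
            sigma_patient >= 0, sigma_resid >= 0, sigma_diag >= 0)
  set.seed(seed)
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  mu <- center(sort(stats::qnorm(stats::ppoints(n_taxa)) * mu_spread,
                    decreasing = TRUE))
  names(mu) <- taxa
  W <- matrix(stats::rnorm(n_taxa * rank, sd = loading_sd), n_taxa, rank)
  W <- apply(W, 2L, center)
  dt <- center(stats::rnorm(n_taxa))
  delta_type <- dt / sqrt(sum(dt^2)) * delta_type_norm
  names(delta_type) <- taxa
  delta_batch <- lapply(seq_len(n_batches), function(b) {
    v <- center(stats::rnorm(n_taxa))
    stats::setNames(v / sqrt(sum(v^2)) * delta_batch_norm, taxa)
  })
  # plant the balance on detectable taxa (above the 30th abundance
  # percentile): association search cannot recover taxa that the sequencing
  # depth barely observes
  eligible <- taxa[mu > stats::quantile(mu, 0.3)]
  members <- sample(eligible, sum(balance_size))
  planted <- balance(members[seq_len(balance_size[1])],
                     members[balance_size[1] + seq_len(balance_size[2])])
  structure(list(taxa = taxa, mu = mu, W = W, sigma_diag = sigma_diag,
                 delta_type = delta_type, delta_batch = delta_batch,
                 planted_balance = planted, beta = beta,
                 factor_name = factor_name,
                 sigma_patient = sigma_patient, sigma_resid = sigma_resid,
                 depth_median = depth_median, depth_sdlog = depth_sdlog,
                 n_batches = n_batches, seed = seed),
            class = "synthetic_truth")
}

synthetic_lineage <- function(taxa) {
  n <- length(taxa)
  n_phyla <- max(2L, min(8L, n %/% 15L))
  phylum <- sprintf("Phylum%02d", 1 + (seq_len(n) - 1) %% n_phyla)
  family <- sprintf("Family%02d", 1 + (seq_len(n) - 1) %% max(2L, n %/% 5L))
  paste("Bacteria", phylum, paste0("Class_", phylum),
        paste0("Order_", phylum), family,
        paste0("Genus_", family), paste0("sp_", taxa), sep = ";")
}

#' Generate a synthetic paired stool/biopsy cohort with known truth
#'
#' Per patient, a latent clr profile is drawn around the baseline mean
#' shifted along the planted balance contrast by `beta` times the patient's
#' factor value, plus a patient random effect and low-rank + diagonal
#' inter-patient variation. The stool sample is the latent profile plus
#' residual noise; the biopsy adds the sample-type perturbation; both
#' receive their batch's perturbation. clr profiles are mapped to the
#' simplex by softmax closure and counts are drawn multinomially at a
#' log-normal depth. Metadata marginals mimic a 50-patient precancerous
#' lesion cohort (Right:Left 17:33, single:multiple lesions 34:16,
#' small:large 27:23, NICE 10:40, pathway 32:17).
#'
#' @param n_patients number of patients (default 50; two samples each).
#' @param n_taxa number of taxa (default 150; ignored when `truth` given).
#' @param truth a [synthetic_truth()] (default: built from `seed`).
#' @param seed integer RNG seed for the cohort draw.
#' @return list with `counts` (a `count_table`), `metadata` (data.frame)
#'   and `truth`.
#' @export
generate_cohort <- function(n_patients = 50, n_taxa = 150, truth = NULL,
                            seed = 1L) {
  stopifnot(n_patients >= 4)
  if (is.null(truth)) truth <- synthetic_truth(n_taxa = n_taxa, seed = seed)
  taxa <- truth$taxa
  D <- length(taxa)
  contrast <- balance_contrast(truth$planted_balance, taxa)
  set.seed(seed)
  pid <- sprintf("P%03d", seq_len(n_patients))
  batch <- paste0("B", 1 + (seq_len(n_patients) - 1) %% truth$n_batches)
  draw_level <- function(levels, prob) sample(levels, n_patients, TRUE, prob)
  metadata_p <- data.frame(
    patient_id = pid, batch = batch,
    location = draw_level(c("Right", "Left"), c(17, 33)),
    n_lesions = draw_level(c("1", ">1"), c(34, 16)),
    size = draw_level(c("<10 mm", ">=10 mm"), c(27, 23)),
    nice = draw_level(c("1", ">1"), c(10, 40)),
    pathway = draw_level(c("adenoma-carcinoma", "serrated"), c(32, 17)),
    stringsAsFactors = FALSE)
  fac <- metadata_p[[truth$factor_name]]
  x <- as.numeric(fac == sort(unique(fac))[2])
  rank_w <- ncol(truth$W)
  n_samp <- 2L * n_patients
  clr_rows <- matrix(0, n_samp, D)
  sample_id <- character(n_samp)
  s_type <- character(n_samp)
  s_pid <- character(n_samp)
  for (i in seq_len(n_patients)) {
    latent <- truth$mu + truth$beta * x[i] * contrast +
      center(stats::rnorm(D, sd = truth$sigma_patient)) +
      center(as.vector(truth$W %*% stats::rnorm(rank_w))) +
      center(stats::rnorm(D, sd = truth$sigma_diag))
    db <- truth$delta_batch[[as.integer(sub("B", "", batch[i]))]]
    stool <- latent + center(stats::rnorm(D, sd = truth$sigma_resid)) + db
    biopsy <- latent + truth$delta_type +
      center(stats::rnorm(D, sd = truth$sigma_resid)) + db
    r <- 2L * i - 1L
    clr_rows[r, ] <- stool
    clr_rows[r + 1L, ] <- biopsy
    sample_id[c(r, r + 1L)] <- paste0(pid[i], c("_S", "_B"))
    s_type[c(r, r + 1L)] <- c("stool", "biopsy")
    s_pid[c(r, r + 1L)] <- pid[i]
  }
  depths <- pmax(500L, round(stats::rlnorm(n_samp, log(truth$depth_median),
                                           truth$depth_sdlog)))
  counts <- matrix(0L, D, n_samp, dimnames = list(taxa, sample_id))
  for (s in seq_len(n_samp)) {
    pr <- exp(clr_rows[s, ] - max(clr_rows[s, ]))
    counts[, s] <- stats::rmultinom(1, depths[s], pr / sum(pr))[, 1]
  }
  metadata <- data.frame(sample_id = sample_id, patient_id = s_pid,
                         sample_type = s_type, stringsAsFactors = FALSE)
  metadata <- merge(metadata, metadata_p, by = "patient_id", sort = FALSE)
  metadata <- metadata[match(sample_id, metadata$sample_id), ]
  rownames(metadata) <- NULL
  list(counts = count_table(counts, synthetic_lineage(taxa)),
       metadata = metadata, truth = truth)
}

#' Generate a cohort with planted co-abundance blocks
#'
#' Latent clr profiles are drawn from a Gaussian whose precision matrix has
#' off-diagonal entries `-pcor` exactly on within-block pairs (identity
#' elsewhere), so every within-block pair has partial correlation about
#' `pcor` and all other pairs are conditionally independent — the planted
#' graph a neighborhood-selection method is supposed to recover. Counts are
#' multinomial at fixed depth. `pcor = 0` gives fully independent
#' logistic-normal data (the null for edge-density calibration).
#'
#' @param n_samples number of samples (default 100).
#' @param n_taxa number of taxa (default 20).
#' @param block_sizes sizes of the correlated blocks (default c(5, 5)).
#' @param pcor within-block partial correlation (default 0.24; must stay
#'   below `1 / (max(block_sizes) - 1)` for positive definiteness).
#' @param mu_sd sd of the baseline clr means (default 0.5).
#' @param depth multinomial depth (default 5e3).
#' @param seed integer RNG seed.
#' @return list with `counts` (a `count_table`), `blocks` (list of member
#'   vectors) and `true_edges` (data.frame of within-block pairs).
#' @export
generate_block_cohort <- function(n_samples = 100, n_taxa = 20,
                                  block_sizes = c(5, 5), pcor = 0.24,
                                  mu_sd = 0.5, depth = 5e3, seed = 1L) {
  stopifnot(sum(block_sizes) <= n_taxa)
  if (any(block_sizes > 1) && pcor >= 1 / (max(block_sizes) - 1))
    stop("pcor too large for positive definiteness")
  set.seed(seed)
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  offs <- cumsum(c(0, block_sizes))
  blocks <- lapply(seq_along(block_sizes), function(b)
    taxa[offs[b] + seq_len(block_sizes[b])])
  omega <- diag(n_taxa)
  for (m in blocks) {
    i <- match(m, taxa)
    omega[i, i] <- -pcor
  }
  diag(omega) <- 1
  L <- chol(solve(omega))
  mu <- stats::rnorm(n_taxa, sd = mu_sd)
  Z <- sweep(matrix(stats::rnorm(n_samples * n_taxa), n_samples) %*% L,
             2L, mu, "+")
  counts <- apply(Z, 1L, function(z) {
    pr <- exp(z - max(z))
    stats::rmultinom(1, depth, pr / sum(pr))[, 1]
  })
  dimnames(counts) <- list(taxa, sprintf("s%03d", seq_len(n_samples)))
  pairs <- do.call(rbind, lapply(blocks[lengths(blocks) > 1], function(m) {
    cmb <- t(utils::combn(sort(m), 2))
    data.frame(taxon_a = cmb[, 1], taxon_b = cmb[, 2])
  }))
  list(counts = count_table(counts, synthetic_lineage(taxa)),
       blocks = blocks, true_edges = pairs)
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

#' Recovery metrics against the planted truth
#'
#' For a `balance_fit`: Jaccard of the recovered numerator/denominator sets
#' against the planted ones and the cosine between the full-data coefficient
#' vector and the planted contrast. For a network: edge precision and recall
#' against a set of true edges. For an estimated sample-type shift vector:
#' clr-space L2 error against the true perturbation.
#'
#' @param recovered a `balance_fit`, a `coabundance_network`, or a numeric
#'   clr shift vector.
#' @param truth a `synthetic_truth` (balance/shift) or a data.frame of true
#'   edges with columns taxon_a, taxon_b (network).
#' @return named list of metrics.
#' @export
truth_metrics <- function(recovered, truth) {
  if (inherits(recovered, "balance_fit")) {
    planted <- truth$planted_balance
    num <- if (is.null(recovered$balance)) character(0) else recovered$balance$num
    den <- if (is.null(recovered$balance)) character(0) else recovered$balance$den
    contrast <- balance_contrast(planted, truth$taxa)
    b <- recovered$b[truth$taxa]
    list(jaccard_num = jaccard(num, planted$num),
         jaccard_den = jaccard(den, planted$den),
         jaccard_union = jaccard(union(num, den),
                                 union(planted$num, planted$den)),
         cosine = sum(b * contrast) / sqrt(sum(b^2)))
  } else if (inherits(recovered, "coabundance_network")) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    est <- if (nrow(recovered$edges) > 0)
      key(recovered$edges$taxon_a, recovered$edges$taxon_b) else character(0)
    tru <- key(truth$taxon_a, truth$taxon_b)
    tp <- length(intersect(est, tru))
    list(precision = if (length(est) > 0) tp / length(est) else NA_real_,
         recall = tp / length(tru), n_edges = length(est))
  } else if (is.numeric(recovered)) {
    err <- recovered[truth$taxa] - truth$delta_type
    list(l2_error = sqrt(sum(err^2)),
         relative_error = sqrt(sum(err^2)) / sqrt(sum(truth$delta_type^2)))
  } else stop("unsupported recovery object")
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b lists of disjoint member vectors (or named membership
#'   vectors over the same elements).
#' @return the adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  to_membership <- function(p) {
    if (is.list(p)) {
      m <- rep(seq_along(p), lengths(p))
      names(m) <- unlist(p)
      m
    } else p
  }
  ma <- to_membership(a); mb <- to_membership(b)
  common <- intersect(names(ma), names(mb))
  ma <- ma[common]; mb <- mb[common]
  tab <- table(ma, mb)
  n <- length(common)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
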
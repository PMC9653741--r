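#' Association design shared by the statistical operations
#'
#' Bundles the tested factor, fixed covariates, random grouping and
#' permutation strata, all referring to metadata columns.
#'
#' @param factor name of the tested metadata column (binary or numeric for
#'   per-taxon models; any categorical for PERMANOVA).
#' @param covariates character vector of fixed covariate columns (e.g. the
#'   Shannon index).
#' @param random name of the random-grouping column (patient or batch), or
#'   `NULL`.
#' @param strata name of the permutation-strata column, or `NULL`.
#' @return an object of class `assoc_design`.
#' @export
assoc_design <- function(factor, covariates = character(0), random = NULL,
                         strata = NULL) {
  stopifnot(is.character(factor), length(factor) == 1L)
  structure(list(factor = factor, covariates = covariates,
                 random = random, strata = strata),
            class = "assoc_design")
}

#' A microbial balance: numerator vs denominator taxon groups
#'
#' A balance contrasts the geometric mean abundance of a numerator taxon set
#' against a denominator set. Its induced clr contrast vector carries
#' `+sqrt(k- / (k+ (k+ + k-)))` on numerator taxa and
#' `-sqrt(k+ / (k- (k+ + k-)))` on denominator taxa (zero elsewhere), has
#' unit Euclidean norm and entries summing to zero.
#'
#' @param num,den disjoint nonempty character vectors of taxon ids.
#' @return an object of class `balance`.
#' @export
balance <- function(num, den) {
  num <- as.character(num); den <- as.character(den)
  if (length(num) == 0 || length(den) == 0)
    stop("numerator and denominator must be nonempty")
  if (length(intersect(num, den)) > 0)
    stop("numerator and denominator must be disjoint")
  structure(list(num = num, den = den), class = "balance")
}

#' @export
print.balance <- function(x, ...) {
  cat(sprintf("balance: %d numerator vs %d denominator taxa\n",
              length(x$num), length(x$den)))
  cat("  num:", paste(x$num, collapse = ", "), "\n")
  cat("  den:", paste(x$den, collapse = ", "), "\n")
  invisible(x)
}

#' Contrast vector of a balance over a taxon universe
#'
#' @param bal a `balance`.
#' @param taxa character vector of all taxon ids (must contain the balance
#'   members).
#' @return named unit-norm, zero-sum numeric vector of length `length(taxa)`.
#' @export
balance_contrast <- function(bal, taxa) {
  miss <- setdiff(c(bal$num, bal$den), taxa)
  if (length(miss) > 0)
    stop("balance taxa missing from universe: ", paste(miss, collapse = ", "))
  kp <- length(bal$num); km <- length(bal$den)
  v <- stats::setNames(numeric(length(taxa)), taxa)
  v[bal$num] <- sqrt(km / (kp * (kp + km)))
  v[bal$den] <- -sqrt(kp / (km * (kp + km)))
  v
}

#' Evaluate a balance on samples
#'
#' `sqrt(k+ k- / (k+ + k-))` times the difference between the mean natural
#' log over numerator taxa and over denominator taxa. Equals the contrast
#' vector dotted with the sample's clr row, and is invariant to overall
#' scaling of the sample.
#'
#' @param bal a `balance`.
#' @param x strictly positive named vector (one sample) or samples x taxa
#'   matrix with taxon colnames; compositions or raw positive counts.
#' @return numeric balance value(s), one per sample.
#' @export
balance_value <- function(bal, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  miss <- setdiff(c(bal$num, bal$den), colnames(x))
  if (length(miss) > 0)
    stop("sample is missing balance taxa: ", paste(miss, collapse = ", "))
  sub <- x[, c(bal$num, bal$den), drop = FALSE]
  if (any(sub <= 0))
    stop("balance taxa must have strictly positive values; apply zero_replace() first")
  kp <- length(bal$num); km <- length(bal$den)
  num_mean <- rowMeans(log(x[, bal$num, drop = FALSE]))
  den_mean <- rowMeans(log(x[, bal$den, drop = FALSE]))
  sqrt(kp * km / (kp + km)) * (num_mean - den_mean)
}

factor_values <- function(meta, column) {
  x <- meta[[column]]
  if (is.null(x)) stop("metadata has no column '", column, "'")
  if (is.character(x) || is.factor(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) < 2) stop("factor '", column, "' is constant")
    if (length(lev) > 2)
      stop("factor '", column, "' must be binary or numeric for per-taxon models")
    out <- as.numeric(as.character(x) == lev[2])
    attr(out, "levels") <- lev
    out
  } else {
    if (length(unique(x)) < 2) stop("factor '", column, "' is constant")
    as.numeric(x)
  }
}

covariate_matrix <- function(meta, covariates) {
  if (length(covariates) == 0) return(NULL)
  miss <- setdiff(covariates, names(meta))
  if (length(miss) > 0)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  stats::model.matrix(stats::reformulate(covariates),
                      data = meta)[, -1, drop = FALSE]
}

# multiresponse least squares: slope of the column `which` of X for every
# column of Y, with t-based p-values sharing the one design matrix.
# Degenerate nuisance columns (constant or collinear, e.g. a batch dummy
# that became constant in a subsample) are dropped; only the tested column
# must stay estimable.
.multi_lm_slope <- function(X, Y, which) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    kept <- qr_x$pivot[seq_len(qr_x$rank)]
    if (!(which %in% kept))
      stop("tested factor is confounded with the other design columns")
    X <- X[, sort(kept), drop = FALSE]
    which <- match(which, sort(kept))
    qr_x <- qr(X)
  }
  coefs <- qr.coef(qr_x, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("not enough samples for the design")
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(sigma2 * xtx_inv[which, which])
  b <- coefs[which, ]
  t <- b / se
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0] <- NA_real_
  list(b = b, p = p)
}

is_paired_design <- function(meta, design) {
  if (is.null(design$random)) return(FALSE)
  g <- meta[[design$random]]
  if (is.null(g)) stop("metadata has no column '", design$random, "'")
  x <- meta[[design$factor]]
  sizes <- table(g)
  if (!all(sizes == 2)) return(FALSE)
  all(tapply(as.character(x), g, function(v) length(unique(v)) == 2))
}

#' Per-taxon clr association coefficients
#'
#' For every taxon, the slope of its clr value on the tested factor, with
#' fixed covariates and the random grouping honored. Paired designs (exactly
#' two samples per group, factor varying within every group) are fit exactly
#' via within-group differences; a 2-level random grouping falls back to a
#' fixed effect (logged via `message`); otherwise a random intercept is fit
#' with `lme4`, with normal-approximation p-values.
#'
#' @param clr_table samples x taxa matrix of clr values (rownames are sample
#'   ids).
#' @param meta metadata data.frame with a `sample_id` column covering all
#'   rows of `clr_table`.
#' @param design an [assoc_design()].
#' @return list with `b` (named slope vector), `p` (per-taxon p-values) and
#'   `method` (one of `"paired"`, `"fixed"`, `"lmm"`).
#' @export
clr_association <- function(clr_table, meta, design) {
  meta <- meta[match(rownames(clr_table), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing for sample(s): ",
         paste(setdiff(rownames(clr_table), meta$sample_id), collapse = ", "))
  x <- factor_values(meta, design$factor)
  Z <- covariate_matrix(meta, design$covariates)
  if (is_paired_design(meta, design)) {
    g <- as.character(meta[[design$random]])
    groups <- unique(g)
    first <- vapply(groups, function(gg) which(g == gg)[1], integer(1))
    second <- vapply(groups, function(gg) which(g == gg)[2], integer(1))
    lo <- ifelse(x[first] <= x[second], first, second)
    hi <- ifelse(x[first] <= x[second], second, first)
    dY <- clr_table[hi, , drop = FALSE] - clr_table[lo, , drop = FALSE]
    dx <- x[hi] - x[lo]
    dZ <- if (is.null(Z)) NULL else Z[hi, , drop = FALSE] - Z[lo, , drop = FALSE]
    X <- cbind(dx, dZ)
    fit <- .multi_lm_slope(X, dY, which = 1L)
    return(list(b = fit$b, p = fit$p, method = "paired"))
  }
  if (!is.null(design$random)) {
    g <- factor(meta[[design$random]])
    if (nlevels(g) <= 2) {
      message("random grouping '", design$random,
              "' has <= 2 levels; using fixed-effect fallback")
      G <- if (nlevels(g) == 2) stats::model.matrix(~g)[, -1, drop = FALSE] else NULL
      X <- cbind(1, x, Z, G)
      fit <- .multi_lm_slope(X, clr_table, which = 2L)
      return(list(b = fit$b, p = fit$p, method = "fixed"))
    }
    df <- data.frame(x = x, g = g)
    if (!is.null(Z)) df <- cbind(df, as.data.frame(Z))
    covs <- setdiff(names(df), c("g"))
    form <- stats::as.formula(paste("y ~", paste(covs, collapse = " + "), "+ (1 | g)"))
    b <- p <- stats::setNames(numeric(ncol(clr_table)), colnames(clr_table))
    for (j in seq_len(ncol(clr_table))) {
      df$y <- clr_table[, j]
      fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
      cf <- summary(fit)$coefficients
      b[j] <- cf["x", "Estimate"]
      p[j] <- 2 * stats::pnorm(-abs(cf["x", "t value"]))
    }
    return(list(b = b, p = p, method = "lmm"))
  }
  X <- cbind(1, x, Z)
  fit <- .multi_lm_slope(X, clr_table, which = 2L)
  list(b = fit$b, p = fit$p, method = "fixed")
}

#' Nearest balance to a clr coefficient vector
#'
#' Finds the balance whose unit-norm contrast vector maximizes the inner
#' product (equivalently, cosine similarity) with `b`. Candidates are the
#' sorted-threshold family: taxa ordered by decreasing coefficient, the top
#' `k+` forming the numerator and the bottom `k-` the denominator, for all
#' `k+ + k- <= D`; a rearrangement argument shows the global optimum lies in
#' this family (verified against exhaustive search in the test suite). Ties
#' are broken by fewer total taxa, then lexicographically smallest member
#' ids.
#'
#' @param b named numeric vector of per-taxon coefficients (length >= 2,
#'   not all equal).
#' @param tol numerical tolerance for score ties.
#' @return a `balance` with attributes `cosine` (similarity to `b`) and
#'   `score` (inner product with `b`).
#' @export
nearest_balance <- function(b, tol = 1e-12) {
  D <- length(b)
  if (D < 2) stop("need at least two taxa")
  if (length(unique(b)) == 1) stop("coefficient vector is constant")
  ids <- names(b)
  if (is.null(ids)) ids <- sprintf("t%d", seq_len(D))
  ord <- order(-b, ids)     # decreasing b, ties by id for determinism
  bs <- b[ord]; ids <- ids[ord]
  top <- cumsum(bs)                      # sum of k+ largest
  bot <- cumsum(rev(bs))                 # sum of k- smallest
  kp <- seq_len(D - 1)
  best <- list(score = -Inf)
  # score(kp,km) = sqrt(km/(kp(kp+km))) top[kp] - sqrt(kp/(km(kp+km))) bot[km]
  score_mat <- matrix(-Inf, D - 1, D - 1)
  for (i in kp) {
    km <- seq_len(D - i)
    tot <- i + km
    score_mat[i, km] <- sqrt(km / (i * tot)) * top[i] - sqrt(i / (km * tot)) * bot[km]
  }
  mx <- max(score_mat)
  cand <- which(score_mat >= mx - tol, arr.ind = TRUE)
  sizes <- cand[, 1] + cand[, 2]
  cand <- cand[sizes == min(sizes), , drop = FALSE]
  if (nrow(cand) > 1) {       # lexicographic member-id tie-break
    keys <- apply(cand, 1L, function(rc)
      paste(sort(c(ids[seq_len(rc[1])], ids[D - seq_len(rc[2]) + 1])),
            collapse = "\r"))
    cand <- cand[order(keys)[1], , drop = FALSE]
  }
  i <- cand[1, 1]; j <- cand[1, 2]
  bal <- balance(ids[seq_len(i)], rev(ids[D - seq_len(j) + 1]))
  attr(bal, "score") <- score_mat[i, j]
  attr(bal, "cosine") <- score_mat[i, j] / sqrt(sum(b^2))
  bal
}

#' Reproducibility-filtered nearest balance
#'
#' Runs the clr-association fit and nearest-balance search on `n_iter`
#' random subsamples (fraction `subsample_fraction` of patients for paired
#' designs, of samples otherwise) and keeps the taxa assigned to the
#' numerator (resp. denominator) in more than `threshold` of the iterations.
#' Also returns the full-data coefficient vector and nearest balance.
#'
#' @param data a `count_table`.
#' @param meta metadata data.frame covering the table's samples.
#' @param design an [assoc_design()].
#' @param n_iter number of subsampling iterations (default 500).
#' @param subsample_fraction fraction retained per iteration (default 0.5).
#' @param threshold reproducibility frequency cutoff, as a fraction of
#'   iterations (default 0.8; strictly greater-than rule).
#' @param seed integer RNG seed.
#' @param pseudocount zero replacement (default 0.5).
#' @return an object of class `balance_fit`: list with `balance` (the
#'   reproducibility-filtered balance, or `NULL` when either side is empty),
#'   `full_balance`, `b`, `p`, `freq_num`, `freq_den`, `cosine`, `method`
#'   and the parameters.
#' @export
reproducible_balance <- function(data, meta, design, n_iter = 500,
                                 subsample_fraction = 0.5, threshold = 0.8,
                                 seed = 1L, pseudocount = 0.5) {
  meta <- validate_metadata(meta, data)
  meta <- meta[match(sample_ids(data), meta$sample_id), , drop = FALSE]
  comp <- zero_replace(data, pseudocount)
  Y <- clr(comp)
  full <- clr_association(Y, meta, design)
  full_bal <- nearest_balance(full$b)
  paired <- is_paired_design(meta, design)
  units <- if (paired) unique(as.character(meta[[design$random]])) else meta$sample_id
  n_take <- max(2L, round(subsample_fraction * length(units)))
  taxa <- colnames(Y)
  freq_num <- freq_den <- stats::setNames(numeric(length(taxa)), taxa)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    fit <- NULL
    for (try in 1:100) {
      take <- sample(units, n_take)
      rows <- if (paired) which(as.character(meta[[design$random]]) %in% take)
              else which(meta$sample_id %in% take)
      xs <- meta[[design$factor]][rows]
      if (length(unique(xs[!is.na(xs)])) < 2) next
      fit <- tryCatch(suppressMessages(
        clr_association(Y[rows, , drop = FALSE], meta[rows, , drop = FALSE],
                        design)),
        error = function(e) NULL)  # e.g. factor confounded in this draw
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("could not draw an analyzable subsample")
    bal <- nearest_balance(fit$b)
    freq_num[bal$num] <- freq_num[bal$num] + 1
    freq_den[bal$den] <- freq_den[bal$den] + 1
  }
  freq_num <- freq_num / n_iter
  freq_den <- freq_den / n_iter
  num <- taxa[freq_num > threshold]
  den <- taxa[freq_den > threshold]
  final <- if (length(num) > 0 && length(den) > 0) balance(num, den) else NULL
  cosine <- if (!is.null(final)) {
    v <- balance_contrast(final, taxa)
    sum(v * full$b) / sqrt(sum(full$b^2))
  } else NA_real_
  structure(list(balance = final, full_balance = full_bal, b = full$b,
                 p = full$p, freq_num = freq_num, freq_den = freq_den,
                 cosine = cosine, method = full$method, n_iter = n_iter,
                 subsample_fraction = subsample_fraction,
                 threshold = threshold, seed = seed),
            class = "balance_fit")
}

#' @export
print.balance_fit <- function(x, ...) {
  if (is.null(x$balance)) {
    cat("balance_fit: no reproducible balance (a side fell below threshold",
        x$threshold, ")\n")
  } else {
    cat(sprintf("balance_fit (%s, %d iterations, threshold %.2f):\n",
                x$method, x$n_iter, x$threshold))
    print(x$balance)
    cat(sprintf("  cosine with full-data coefficients: %.4f\n", x$cosine))
  }
  invisible(x)
}

#' Serialize a balance fit as JSON / as a plot-ready TSV
#'
#' The TSV has one row per balance member: taxon, side (num/den), full-data
#' clr coefficient and reproducibility frequency.
#'
#' @param fit a `balance_fit`.
#' @param path output path.
#' @export
write_balance_fit <- function(fit, path) {
  obj <- list(
    numerator = if (is.null(fit$balance)) character(0) else fit$balance$num,
    denominator = if (is.null(fit$balance)) character(0) else fit$balance$den,
    coefficients = as.list(fit$b),
    freq_numerator = as.list(fit$freq_num),
    freq_denominator = as.list(fit$freq_den),
    cosine = fit$cosine, method = fit$method,
    n_iter = fit$n_iter, threshold = fit$threshold)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_balance_fit
#' @export
balance_fit_table <- function(fit) {
  if (is.null(fit$balance)) return(data.frame(taxon = character(0),
                                              side = character(0),
                                              coefficient = numeric(0),
                                              reproducibility = numeric(0)))
  rbind(
    data.frame(taxon = fit$balance$num, side = "num",
               coefficient = fit$b[fit$balance$num],
               reproducibility = fit$freq_num[fit$balance$num]),
    data.frame(taxon = fit$balance$den, side = "den",
               coefficient = fit$b[fit$balance$den],
               reproducibility = fit$freq_den[fit$balance$den]))
}

strip_unclassified <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  parts <- parts[tolower(trimws(parts)) != "unclassified"]
  paste(parts, collapse = ";")
}

#' Evaluate a balance on an external species-level relative-abundance table
#'
#' Balance members are matched to columns by id; a member unclassified at
#' the species level is replaced by the summed abundance of all species in
#' its deepest classified clade. Optionally compares balance values between
#' groups with a linear model.
#'
#' @param bal a `balance` whose member ids are lineage-style strings.
#' @param relabund samples x species matrix of relative abundances with
#'   species ids as colnames.
#' @param lineage named character vector mapping each column to its full
#'   lineage (default: the colnames themselves).
#' @param group optional per-sample grouping for the comparison; the first
#'   sorted level is the reference.
#' @return list with `values` (per-sample balance values) and `comparison`
#'   (data.frame of level, estimate, p; `NULL` when `group` is missing).
#' @export
evaluate_balance_external <- function(bal, relabund, lineage = NULL,
                                      group = NULL) {
  relabund <- as.matrix(relabund)
  if (is.null(lineage)) lineage <- stats::setNames(colnames(relabund), colnames(relabund))
  members <- c(bal$num, bal$den)
  matched <- matrix(NA_real_, nrow(relabund), length(members),
                    dimnames = list(rownames(relabund), members))
  for (m in members) {
    if (m %in% colnames(relabund)) {
      matched[, m] <- relabund[, m]
    } else {
      prefix <- strip_unclassified(m)
      if (!nzchar(prefix))
        stop("balance taxon '", m, "' has no classified clade prefix")
      hits <- startsWith(unname(lineage), prefix)
      if (!any(hits))
        stop("no species match for balance taxon '", m,
             "' (clade prefix '", prefix, "')")
      matched[, m] <- rowSums(relabund[, hits, drop = FALSE])
    }
  }
  if (any(matched <= 0))
    stop("matched abundances contain zeros; replace zeros upstream")
  values <- balance_value(balance(bal$num, bal$den), matched)
  comparison <- NULL
  if (!is.null(group)) {
    g <- factor(group)
    fit <- stats::lm(values ~ g)
    cf <- summary(fit)$coefficients
    rows <- grep("^g", rownames(cf))
    comparison <- data.frame(level = sub("^g", "", rownames(cf)[rows]),
                             estimate = cf[rows, "Estimate"],
                             p = cf[rows, "Pr(>|t|)"], row.names = NULL)
  }
  list(values = values, comparison = comparison)
}

auc_score <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of the stool-vs-biopsy balance score
#'
#' Repeated patient-level train/test splits: on each training split the
#' reproducibility-filtered stool-vs-biopsy balance is fit, test samples are
#' scored by their balance value, and the AUC of the score against the true
#' sample type is recorded. Splits leaving a class absent are redrawn.
#'
#' @param data a `count_table` containing both sample types.
#' @param meta metadata with `sample_id`, `patient_id` and `sample_type`.
#' @param n_iter number of cross-validation iterations (default 500).
#' @param seed integer RNG seed.
#' @param test_fraction fraction of patients held out (default 0.25).
#' @param balance_iter subsampling iterations of the inner balance fit
#'   (default 100).
#' @param threshold,pseudocount passed to [reproducible_balance()].
#' @return list with `mean`, `sd` and the vector of per-iteration `auc`.
#' @export
sample_type_auc <- function(data, meta, n_iter = 500, seed = 1L,
                            test_fraction = 0.25, balance_iter = 100,
                            threshold = 0.8, pseudocount = 0.5) {
  meta <- validate_metadata(meta, data)
  meta <- meta[match(sample_ids(data), meta$sample_id), , drop = FALSE]
  if (length(unique(meta$sample_type)) < 2)
    stop("both sample types must be present")
  design <- assoc_design("sample_type", random = "patient_id")
  comp <- zero_replace(data, pseudocount)
  patients <- unique(meta$patient_id)
  n_test <- max(1L, round(test_fraction * length(patients)))
  positive_level <- sort(unique(as.character(meta$sample_type)))[2]
  set.seed(seed)
  aucs <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    for (try in 1:100) {
      test_p <- sample(patients, n_test)
      test_rows <- meta$patient_id %in% test_p
      if (length(unique(meta$sample_type[test_rows])) == 2 &&
          length(unique(meta$sample_type[!test_rows])) == 2) break
      if (try == 100) stop("could not draw a split containing both classes")
    }
    train <- subset_count_table(data, samples = meta$sample_id[!test_rows])
    fit <- suppressMessages(reproducible_balance(
      train, meta[!test_rows, , drop = FALSE], design,
      n_iter = balance_iter, threshold = threshold, pseudocount = pseudocount,
      seed = sample.int(2^31 - 1, 1)))
    bal <- if (is.null(fit$balance)) fit$full_balance else fit$balance
    scores <- balance_value(bal, comp[meta$sample_id[test_rows], , drop = FALSE])
    aucs[it] <- auc_score(scores,
                          meta$sample_type[test_rows] == positive_level)
  }
  list(mean = mean(aucs), sd = stats::sd(aucs), auc = aucs)
}
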
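gower_center <- function(d) {
  d <- as.matrix(d)
  a <- -0.5 * d^2
  n <- nrow(a)
  j <- diag(n) - matrix(1 / n, n, n)
  j %*% a %*% j
}

hat_matrix <- function(X) {
  qr_x <- qr(X)
  Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
  tcrossprod(Q)
}

strata_permutation <- function(strata) {
  idx <- seq_along(strata)
  for (s in unique(strata)) {
    rows <- which(strata == s)
    if (length(rows) > 1) idx[rows] <- rows[sample.int(length(rows))]
  }
  idx
}

#' Covariate-adjusted PERMANOVA with permutation strata
#'
#' Partitions the Gower-centered inner-product matrix of a distance matrix
#' between nested hat matrices: covariates (plus intercept) first, then the
#' tested factor, mirroring sequential "correction for" adjustment. The
#' partial R2 is `tr((H1 - H0) G) / tr(G)` and the pseudo-F statistic is
#' `[tr((H1 - H0) G) / df_factor] / [tr((I - H1) G) / df_resid]`. The
#' permutation null permutes sample identities within strata only, keeping
#' the design fixed and relabelling the distance matrix, and the p-value
#' uses the add-one estimator (never exactly zero).
#'
#' @param dist square symmetric distance matrix with sample ids as dimnames.
#' @param meta metadata data.frame with `sample_id` covering the matrix.
#' @param design an [assoc_design()]; `design$strata` names the strata
#'   column, `design$covariates` the fixed covariates. The factor may be
#'   categorical with any number of levels.
#' @param n_perm number of permutations (default 999).
#' @param seed integer RNG seed.
#' @return object of class `permanova_result`: list with `factor`, `R2`,
#'   `F`, `p`, `n_perm`, `df_factor`, `df_resid`.
#' @export
permanova <- function(dist, meta, design, n_perm = 999, seed = 1L) {
  d <- as.matrix(dist)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  ids <- rownames(d)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing for some samples")
  x <- meta[[design$factor]]
  if (is.null(x)) stop("metadata has no column '", design$factor, "'")
  keep <- !is.na(x)
  if (length(design$covariates) > 0)
    for (cv in design$covariates) keep <- keep & !is.na(meta[[cv]])
  if (!all(keep)) {
    d <- d[keep, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    x <- x[keep]
  }
  n <- nrow(d)
  strata <- if (is.null(design$strata)) rep(1L, n) else meta[[design$strata]]
  xf <- if (is.numeric(x)) x else factor(x)
  if ((is.factor(xf) && nlevels(xf) < 2) || (is.numeric(xf) && length(unique(xf)) < 2))
    stop("factor '", design$factor, "' is constant")
  if (!is.numeric(xf)) {
    const_within <- all(tapply(as.character(xf), strata,
                               function(v) length(unique(v)) == 1))
    if (const_within && length(unique(strata)) < n)
      stop("factor '", design$factor,
           "' is constant within every stratum and cannot be permuted")
  }
  Z <- covariate_matrix(meta, design$covariates)
  X0 <- cbind(rep(1, n), Z)
  Xf <- if (is.numeric(xf)) matrix(xf, ncol = 1) else
    stats::model.matrix(~xf)[, -1, drop = FALSE]
  X1 <- cbind(X0, Xf)
  H0 <- hat_matrix(X0)
  H1 <- hat_matrix(X1)
  df_factor <- qr(X1)$rank - qr(X0)$rank
  df_resid <- n - qr(X1)$rank
  if (df_factor < 1 || df_resid < 1) stop("degenerate design")
  G <- gower_center(d)
  A <- H1 - H0
  R <- diag(n) - H1
  f_stat <- function(Gp) {
    num <- sum(A * Gp) / df_factor
    den <- sum(R * Gp) / df_resid
    num / den
  }
  F_obs <- f_stat(G)
  R2 <- sum(A * G) / sum(diag(G))
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    p <- strata_permutation(strata)
    if (f_stat(G[p, p]) >= F_obs) exceed <- exceed + 1L
  }
  structure(list(factor = design$factor, R2 = R2, F = F_obs,
                 p = (1 + exceed) / (n_perm + 1), n_perm = n_perm,
                 df_factor = df_factor, df_resid = df_resid, n = n),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: %s  R2 = %.4f  pseudo-F = %.3f  p = %.4g (%d perms, n = %d)\n",
              x$factor, x$R2, x$F, x$p, x$n_perm, x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment with monotonicity enforcement, capped at 1, input
#' order preserved (delegates to `stats::p.adjust(method = "BH")`).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values (q-values).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

fit_factor_model <- function(y, meta, factor, covariates = character(0),
                             random = NULL) {
  x <- factor_values(meta, factor)
  if (stats::var(y) == 0) stop("response is constant")
  Z <- covariate_matrix(meta, covariates)
  if (!is.null(random)) {
    g <- factor(meta[[random]])
    if (nlevels(g) > 2) {
      df <- data.frame(y = y, x = x, g = g)
      if (!is.null(Z)) df <- cbind(df, as.data.frame(Z))
      covs <- setdiff(names(df), c("y", "g"))
      form <- stats::as.formula(paste("y ~", paste(covs, collapse = " + "),
                                      "+ (1 | g)"))
      fit <- suppressMessages(lme4::lmer(form, data = df, REML = TRUE))
      cf <- summary(fit)$coefficients
      return(list(slope = cf["x", "Estimate"],
                  p = 2 * stats::pnorm(-abs(cf["x", "t value"])),
                  method = "lmm"))
    }
    message("random grouping '", random, "' has <= 2 levels; fixed-effect fallback")
    G <- if (nlevels(g) == 2) stats::model.matrix(~g)[, -1, drop = FALSE] else NULL
    X <- cbind(1, x, Z, G)
  } else {
    X <- cbind(1, x, Z)
  }
  fit <- .multi_lm_slope(X, matrix(y, ncol = 1), which = 2L)
  list(slope = unname(fit$b), p = unname(fit$p), method = "fixed")
}

#' Associate alpha diversity with metadata factors
#'
#' Linear model of the diversity index on each factor, with the batch as a
#' random intercept (fixed-effect fallback when the batch has only two
#' levels, logged) and optional fixed covariates; Benjamini-Hochberg
#' adjustment across the tested factors.
#'
#' @param alpha data.frame from [alpha_diversity()] (columns `sample_id`
#'   plus indices).
#' @param meta metadata data.frame.
#' @param factors character vector of metadata columns to test.
#' @param index which alpha column to model (default `"shannon"`).
#' @param batch name of the batch column used as random grouping (or
#'   `NULL`).
#' @param covariates fixed covariates.
#' @return data.frame with columns factor, slope, p, q.
#' @export
alpha_association <- function(alpha, meta, factors, index = "shannon",
                              batch = "batch", covariates = character(0)) {
  meta <- meta[match(alpha$sample_id, meta$sample_id), , drop = FALSE]
  y <- alpha[[index]]
  if (is.null(y)) stop("alpha table has no column '", index, "'")
  res <- lapply(factors, function(f) {
    ok <- !is.na(meta[[f]])
    fit <- fit_factor_model(y[ok], meta[ok, , drop = FALSE], f,
                            covariates = covariates,
                            random = if (is.null(batch)) NULL else batch)
    data.frame(factor = f, slope = fit$slope, p = fit$p, method = fit$method)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out
}

#' Component-wise per-taxon association analysis
#'
#' The classical (non-compositional) route: rarefy to equal depth, convert
#' to proportions, apply the arcsine square-root transform
#' `T(p) = asin(sqrt(p))`, and fit each taxon with a linear model of the
#' transformed proportion on the factor with the Shannon index as a fixed
#' covariate and the batch as random grouping (fixed-effect fallback for a
#' 2-level batch); Benjamini-Hochberg adjustment across taxa.
#'
#' @param table a `count_table`.
#' @param meta metadata data.frame.
#' @param design an [assoc_design()]; `design$random` names the batch
#'   column.
#' @param depth rarefaction depth (default: minimum per-sample total,
#'   capped at 2442 when that is feasible).
#' @param seed integer RNG seed for rarefaction.
#' @return data.frame with columns taxon, slope, p, q.
#' @export
componentwise <- function(table, meta, design, depth = NULL, seed = 1L) {
  totals <- colSums(table$counts)
  if (is.null(depth)) depth <- min(min(totals), 2442)
  rar <- rarefy(table, depth = depth, seed = seed)
  meta <- meta[match(sample_ids(rar), meta$sample_id), , drop = FALSE]
  props <- t(rar$counts) / depth                  # samples x taxa
  Tm <- asin(sqrt(props))
  sh <- apply(rar$counts, 2L, shannon)
  meta$.shannon <- sh
  covs <- unique(c(design$covariates, ".shannon"))
  x <- factor_values(meta, design$factor)
  Z <- covariate_matrix(meta, covs)
  random <- design$random
  use_lmm <- !is.null(random) && nlevels(factor(meta[[random]])) > 2
  keep <- apply(Tm, 2L, stats::var) > 0
  Tm <- Tm[, keep, drop = FALSE]
  if (use_lmm) {
    res <- vapply(seq_len(ncol(Tm)), function(j) {
      fit <- fit_factor_model(Tm[, j], meta, design$factor,
                              covariates = covs, random = random)
      c(fit$slope, fit$p)
    }, numeric(2))
    slope <- res[1, ]; p <- res[2, ]
  } else {
    G <- NULL
    if (!is.null(random)) {
      g <- factor(meta[[random]])
      if (nlevels(g) == 2) {
        message("random grouping '", random,
                "' has <= 2 levels; fixed-effect fallback")
        G <- stats::model.matrix(~g)[, -1, drop = FALSE]
      }
    }
    fit <- .multi_lm_slope(cbind(1, x, Z, G), Tm, which = 2L)
    slope <- fit$b; p <- fit$p
  }
  data.frame(taxon = colnames(Tm), slope = unname(slope), p = unname(p),
             q = bh_adjust(unname(p)), row.names = NULL)
}

#' Write association results as TSV
#' @param res data.frame of results.
#' @param path output path.
#' @export
write_results_tsv <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
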
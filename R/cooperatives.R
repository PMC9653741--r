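#' Prevalence filter for network analysis
#'
#' Keeps taxa whose count exceeds `min_count` reads in more than
#' `min_samples` samples (both inequalities strict). Idempotent.
#'
#' @param table a `count_table`.
#' @param min_count read-count threshold (default 10).
#' @param min_samples sample-count threshold (default 10).
#' @return a filtered `count_table`.
#' @export
prevalence_filter <- function(table, min_count = 10, min_samples = 10) {
  keep <- rowSums(table$counts > min_count) > min_samples
  if (!any(keep))
    stop("no taxa pass the prevalence filter; relax min_count/min_samples")
  subset_count_table(table, taxa = rownames(table$counts)[keep])
}

#' Sparse co-abundance network by neighborhood selection
#'
#' clr-transforms the zero-replaced counts and, for every taxon, fits an
#' L1-penalized regression of its clr values on all the others over a
#' log-spaced path of `n_lambda` penalties from the empty-model penalty
#' `lambda_max` down to `lambda_min_ratio * lambda_max`. Over `n_subsamples`
#' random subsamples (fraction `subsample_ratio` of the samples), directed
#' selections are symmetrized per subsample with the "or" rule and the
#' penalty is chosen by the StARS stability criterion (densest penalty with
#' monotonized mean edge instability `2 f (1 - f)` at most `stars_beta`).
#' The network keeps edges whose selection frequency at the chosen penalty
#' is at least `stability_threshold`.
#'
#' @param table a `count_table` (apply [prevalence_filter()] first).
#' @param n_subsamples number of subsamples (default 10).
#' @param n_lambda number of penalties on the path (default 10).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.2); set `lambda_absolute = TRUE` to treat it as an absolute
#'   penalty floor instead.
#' @param seed integer RNG seed.
#' @param subsample_ratio fraction of samples per subsample (default 0.8).
#' @param stability_threshold edge selection-frequency cutoff (default 0.8).
#' @param stars_beta StARS instability budget (default 0.05).
#' @param lambda_absolute interpret `lambda_min_ratio` as an absolute value.
#' @param pseudocount zero replacement (default 0.5).
#' @return object of class `coabundance_network`: list with `nodes`, `edges`
#'   (data.frame taxon_a, taxon_b, frequency), `lambda` (chosen), `lambdas`
#'   (path), `instability` and `params`.
#' @export
mb_network <- function(table, n_subsamples = 10, n_lambda = 10,
                       lambda_min_ratio = 0.2, seed = 1L,
                       subsample_ratio = 0.8, stability_threshold = 0.8,
                       stars_beta = 0.05, lambda_absolute = FALSE,
                       pseudocount = 0.5) {
  Y <- clr(zero_replace(table, pseudocount))
  n <- nrow(Y); D <- ncol(Y)
  n_sub <- floor(subsample_ratio * n)
  if (n_sub < 10) stop("too few samples for stability subsampling (need >= 13)")
  Ys <- scale(Y)
  lambda_max <- max(vapply(seq_len(D), function(j)
    max(abs(crossprod(Ys[, -j], Ys[, j]))) / n, numeric(1)))
  lambda_min <- if (lambda_absolute) lambda_min_ratio else
    lambda_min_ratio * lambda_max
  lambdas <- exp(seq(log(lambda_max), log(lambda_min), length.out = n_lambda))
  freq <- array(0, dim = c(n_lambda, D, D))
  set.seed(seed)
  for (s in seq_len(n_subsamples)) {
    rows <- sample.int(n, n_sub)
    sel <- array(FALSE, dim = c(n_lambda, D, D))
    for (j in seq_len(D)) {
      fit <- glmnet::glmnet(Ys[rows, -j, drop = FALSE], Ys[rows, j],
                            lambda = lambdas, standardize = FALSE,
                            intercept = TRUE)
      beta <- as.matrix(fit$beta)     # (D-1) x n_fitted
      for (l in seq_len(ncol(beta))) {
        nb <- which(beta[, l] != 0)
        sel[l, j, (seq_len(D)[-j])[nb]] <- TRUE
      }
    }
    sym <- sel | aperm(sel, c(1, 3, 2))   # "or" rule within the subsample
    freq <- freq + sym
  }
  freq <- freq / n_subsamples
  upper <- upper.tri(matrix(0, D, D))
  instability <- vapply(seq_len(n_lambda), function(l) {
    th <- freq[l, , ][upper]
    mean(2 * th * (1 - th))
  }, numeric(1))
  mono <- cummax(instability)            # monotonize from sparsest
  ok <- which(mono <= stars_beta)
  l_opt <- if (length(ok) > 0) max(ok) else 1L
  th <- freq[l_opt, , ]
  hits <- which(upper & th >= stability_threshold, arr.ind = TRUE)
  taxa <- colnames(Y)
  edges <- data.frame(taxon_a = taxa[hits[, 1]], taxon_b = taxa[hits[, 2]],
                      frequency = th[hits], row.names = NULL)
  structure(list(nodes = taxa, edges = edges, lambda = lambdas[l_opt],
                 lambdas = lambdas, instability = instability,
                 params = list(n_subsamples = n_subsamples,
                               n_lambda = n_lambda,
                               lambda_min_ratio = lambda_min_ratio,
                               subsample_ratio = subsample_ratio,
                               stability_threshold = stability_threshold,
                               stars_beta = stars_beta, seed = seed)),
            class = "coabundance_network")
}

#' @export
print.coabundance_network <- function(x, ...) {
  cat(sprintf("coabundance_network: %d nodes, %d edges (lambda = %.4f)\n",
              length(x$nodes), nrow(x$edges), x$lambda))
  invisible(x)
}

#' Write a network as edge-list TSV
#' @param net a `coabundance_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Louvain cooperatives from a co-abundance network
#'
#' Modularity-maximizing partition of the network's non-isolated nodes
#' (isolated nodes are excluded). Deterministic given `seed`. An edgeless
#' network yields an empty list.
#'
#' @param net a `coabundance_network` (or an `igraph` graph).
#' @param seed integer RNG seed.
#' @return list of character vectors, one per cooperative.
#' @export
louvain_clusters <- function(net, seed = 1L) {
  g <- if (inherits(net, "igraph")) net else {
    if (nrow(net$edges) == 0) return(list())
    igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE)
  }
  if (igraph::ecount(g) == 0) return(list())
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  split(igraph::V(g)$name, igraph::membership(comm))
}

#' Associate cooperative balances with metadata factors
#'
#' Each cooperative's members form the numerator of a balance whose
#' denominator is every other analyzed taxon; per-sample balance values are
#' modelled on each factor with a linear model (optional covariates from the
#' design), and p-values are Benjamini-Hochberg adjusted across the
#' cluster x factor grid. Run this separately per sample type and per batch.
#'
#' @param table the (filtered) `count_table` the network was built from.
#' @param clusters list of member-taxon character vectors from
#'   [louvain_clusters()].
#' @param meta metadata data.frame.
#' @param factors character vector of metadata columns to test.
#' @param covariates fixed covariates.
#' @param pseudocount zero replacement (default 0.5).
#' @return data.frame with columns cluster, factor, slope, p, q and an
#'   attribute `"balances"` holding the cooperative `balance` objects.
#' @export
cooperative_association <- function(table, clusters, meta, factors,
                                    covariates = character(0),
                                    pseudocount = 0.5) {
  meta <- meta[match(sample_ids(table), meta$sample_id), , drop = FALSE]
  taxa <- taxa_ids(table)
  comp <- zero_replace(table, pseudocount)
  bals <- lapply(clusters, function(members) {
    rest <- setdiff(taxa, members)
    if (length(rest) == 0)
      stop("cooperative spans all analyzed taxa; denominator is empty")
    balance(members, rest)
  })
  rows <- list()
  for (ci in seq_along(bals)) {
    vals <- balance_value(bals[[ci]], comp)
    for (f in factors) {
      ok <- !is.na(meta[[f]])
      fit <- fit_factor_model(vals[ok], meta[ok, , drop = FALSE], f,
                              covariates = covariates, random = NULL)
      rows[[length(rows) + 1]] <- data.frame(
        cluster = ci, factor = f, slope = fit$slope, p = fit$p)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  attr(out, "balances") <- bals
  out
}
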
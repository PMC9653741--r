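#' Rarefy a count table to equal depth
#'
#' Per sample, exactly `depth` reads are drawn without replacement
#' (multivariate hypergeometric). Samples with fewer than `depth` total
#' reads are dropped with a warning. Deterministic given `seed`.
#'
#' @param table a `count_table`.
#' @param depth positive integer target depth (default: the minimum
#'   per-sample total).
#' @param seed integer RNG seed.
#' @return a rarefied `count_table`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1L) {
  totals <- colSums(table$counts)
  if (is.null(depth)) depth <- min(totals)
  if (depth <= 0) stop("depth must be positive")
  drop <- names(totals)[totals < depth]
  if (length(drop) > 0) {
    warning("dropping ", length(drop), " sample(s) below depth ", depth, ": ",
            paste(drop, collapse = ", "))
    table <- subset_count_table(table, samples = setdiff(sample_ids(table), drop))
  }
  counts <- table$counts
  set.seed(seed)
  out <- apply(counts, 2L, function(cnt) {
    pool <- rep.int(seq_along(cnt), cnt)
    tabulate(pool[sample.int(length(pool), depth)], nbins = length(cnt))
  })
  dimnames(out) <- dimnames(counts)
  count_table(out, table$lineage)
}

#' Shannon diversity of one sample (nats)
#'
#' \eqn{-\sum p_i \ln p_i} over nonzero proportions.
#'
#' @param counts non-negative per-taxon counts with positive total.
#' @return non-negative real, at most `log(` observed richness `)`.
#' @export
shannon <- function(counts) {
  if (sum(counts) <= 0) stop("sample total must be positive")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' chao1 richness estimate of one sample
#'
#' `S_obs + F1^2 / (2 F2)` when doubletons are present; bias-corrected
#' fallback `S_obs + F1 (F1 - 1) / 2` when `F2 = 0`. `F1`, `F2` are the
#' singleton and doubleton counts.
#'
#' @param counts non-negative per-taxon counts with positive total.
#' @return estimate, never below observed richness.
#' @export
chao1 <- function(counts) {
  if (sum(counts) <= 0) stop("sample total must be positive")
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Alpha diversity table (Shannon and chao1) per sample
#'
#' @param table a `count_table` (typically rarefied first).
#' @return data.frame with columns `sample_id`, `shannon`, `chao1`.
#' @export
alpha_diversity <- function(table) {
  data.frame(sample_id = sample_ids(table),
             shannon = apply(table$counts, 2L, shannon),
             chao1 = apply(table$counts, 2L, chao1),
             row.names = NULL)
}

#' Write an alpha-diversity table as TSV
#' @param alpha data.frame from [alpha_diversity()].
#' @param path output path.
#' @export
write_alpha_diversity <- function(alpha, path) {
  utils::write.table(alpha, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
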
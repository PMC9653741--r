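#' Close rows of a positive matrix to unit sum
#'
#' @param x positive numeric vector, or matrix with samples as rows.
#' @return same shape, each sample summing to 1.
#' @export
closure <- function(x) {
  if (is.matrix(x)) sweep(x, 1L, rowSums(x), "/") else x / sum(x)
}

#' Replace zero counts and close to compositions
#'
#' Zeros are substituted by `pseudocount` on the count scale (nonzero counts
#' untouched), then each sample is closed to sum 1. Output is a strictly
#' positive samples x taxa matrix.
#'
#' @param table a `count_table`, or a taxa x samples (or samples x taxa when
#'   `samples_as_rows = TRUE`) numeric matrix.
#' @param pseudocount positive replacement for zero counts (default 0.5).
#' @param samples_as_rows interpret a plain matrix as samples x taxa.
#' @return samples x taxa matrix of relative abundances (rows sum to 1).
#' @export
zero_replace <- function(table, pseudocount = 0.5, samples_as_rows = FALSE) {
  stopifnot(pseudocount > 0)
  m <- if (inherits(table, "count_table")) t(table$counts)
       else if (samples_as_rows) as.matrix(table) else t(as.matrix(table))
  allzero <- rowSums(m) == 0
  if (any(allzero))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(m)[allzero], collapse = ", "))
  m[m == 0] <- pseudocount
  closure(m)
}

check_composition <- function(comp, what = "composition") {
  comp <- as.matrix(comp)
  if (any(comp <= 0))
    stop(what, " has nonpositive entries; apply zero_replace() first")
  comp
}

#' Centered log-ratio transform
#'
#' Per sample (row), the natural log of each part minus the mean log;
#' rows of the result sum to 0.
#'
#' @param comp strictly positive samples x parts matrix (or vector).
#' @return matrix of the same shape.
#' @export
clr <- function(comp) {
  vec <- is.null(dim(comp))
  if (vec) comp <- matrix(comp, nrow = 1L, dimnames = list(NULL, names(comp)))
  comp <- check_composition(comp)
  lg <- log(comp)
  out <- lg - rowMeans(lg)
  if (vec) out[1L, ] else out
}

clr_inverse <- function(y) {
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, nrow = 1L, dimnames = list(NULL, names(y)))
  out <- closure(exp(y))
  if (vec) out[1L, ] else out
}

#' Orthonormal ilr contrast basis
#'
#' Default basis: normalized Helmert contrasts in part order (a pivot-style
#' sequential binary partition). Columns sum to zero, are pairwise
#' orthogonal, and have unit norm, so `t(V) %*% V = I` of size D-1.
#'
#' @param D number of parts (>= 2).
#' @return D x (D-1) basis matrix.
#' @export
ilr_basis <- function(D) {
  stopifnot(D >= 2)
  H <- stats::contr.helmert(D)
  sweep(H, 2L, sqrt(colSums(H^2)), "/")
}

#' Isometric log-ratio transform and its inverse
#'
#' `ilr()` maps compositions to D-1 orthonormal coordinates
#' (`clr(x) %*% basis`); `ilr_inverse()` maps back to the simplex. The round
#' trip is exact to numerical precision and Euclidean distance in ilr space
#' equals the Aitchison distance for any orthonormal basis.
#'
#' @param comp strictly positive samples x parts matrix (or vector).
#' @param basis D x (D-1) orthonormal contrast matrix (default
#'   `ilr_basis(D)`).
#' @return samples x (D-1) coordinate matrix.
#' @export
ilr <- function(comp, basis = NULL) {
  vec <- is.null(dim(comp))
  if (vec) comp <- matrix(comp, nrow = 1L, dimnames = list(NULL, names(comp)))
  D <- ncol(comp)
  if (is.null(basis)) basis <- ilr_basis(D)
  if (nrow(basis) != D) stop("basis has ", nrow(basis), " rows, expected ", D)
  out <- clr(comp) %*% basis
  if (vec) out[1L, ] else out
}

#' @param y samples x (D-1) ilr coordinate matrix (or vector).
#' @rdname ilr
#' @export
ilr_inverse <- function(y, basis) {
  vec <- is.null(dim(y))
  if (vec) y <- matrix(y, nrow = 1L)
  if (ncol(y) != ncol(basis))
    stop("coordinate dimension ", ncol(y), " does not match basis ", ncol(basis))
  out <- clr_inverse(y %*% t(basis))
  colnames(out) <- rownames(basis)
  if (vec) out[1L, ] else out
}

#' Aitchison distance matrix
#'
#' Euclidean distance between clr-transformed samples. Input must be a
#' strictly positive composition matrix (apply `zero_replace()` upstream).
#'
#' @param comp samples x parts composition matrix.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
aitchison_distance <- function(comp) {
  as.matrix(stats::dist(clr(comp)))
}

#' Write / read a distance matrix as square TSV
#'
#' @param d symmetric matrix with ids as dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(data.frame(sample_id = rownames(d), d, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Perturbation: the simplex group operation
#'
#' Componentwise product followed by closure. Shifts in ilr space correspond
#' to perturbations: `ilr(perturb(x, p)) == ilr(x) + ilr(p)`.
#'
#' @param x composition vector or samples x parts matrix.
#' @param p composition vector with the same parts.
#' @return perturbed composition(s).
#' @export
perturb <- function(x, p) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(p))
    closure(sweep(x, 2L, p, "*"))
  } else {
    stopifnot(length(x) == length(p))
    closure(x * p)
  }
}

#' Shift luminal (stool) compositions toward the mucosal (biopsy) centre
#'
#' Both tables are mapped to ilr coordinates; every stool sample is shifted
#' by the difference between the mean biopsy and mean stool coordinate
#' vectors; the inverse ilr transform returns corrected compositions. After
#' correction the mean ilr coordinate of the stool samples equals that of
#' the biopsies exactly. The result does not depend on the basis choice:
#' it equals perturbation of each stool sample by the ratio of the closed
#' per-taxon geometric-mean compositions of biopsy and stool.
#'
#' @param stool,biopsy strictly positive samples x parts matrices sharing
#'   the same parts.
#' @param basis optional orthonormal ilr basis.
#' @return corrected stool composition matrix.
#' @export
sample_type_correction <- function(stool, biopsy, basis = NULL) {
  stool <- check_composition(stool, "stool")
  biopsy <- check_composition(biopsy, "biopsy")
  if (ncol(stool) != ncol(biopsy) ||
      (!is.null(colnames(stool)) && !is.null(colnames(biopsy)) &&
       !identical(colnames(stool), colnames(biopsy))))
    stop("stool and biopsy tables must share the same parts")
  if (is.null(basis)) basis <- ilr_basis(ncol(stool))
  ys <- ilr(stool, basis)
  yb <- ilr(biopsy, basis)
  shift <- colMeans(yb) - colMeans(ys)
  out <- ilr_inverse(sweep(ys, 2L, shift, "+"), basis)
  dimnames(out) <- dimnames(stool)
  out
}

split_lineage <- function(lineage) {
  parts <- strsplit(lineage, ";", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- trimws(p)
    p[!nzchar(p) | tolower(p) == "na"] <- "unclassified"
    length(p) <- length(RANKS)
    p[is.na(p)] <- "unclassified"
    p
  }, character(length(RANKS))))
}

#' Aggregate a count table to a taxonomic rank
#'
#' Counts are summed over taxa sharing the lineage prefix up to `rank`;
#' taxa unclassified at `rank` are grouped under explicit `"unclassified"`
#' placeholders keyed by their deepest classified prefix. Per-sample totals
#' are conserved exactly.
#'
#' @param table a `count_table` whose lineages follow domain...species.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return a `count_table` with one row per distinct rank-level prefix.
#' @export
aggregate_to_rank <- function(table, rank) {
  rank <- match.arg(rank, RANKS)
  r <- match(rank, RANKS)
  lin <- split_lineage(table$lineage)
  key <- apply(lin[, seq_len(r), drop = FALSE], 1L, paste, collapse = ";")
  agg <- rowsum(table$counts, group = key, reorder = TRUE)
  count_table(agg, rownames(agg))
}
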
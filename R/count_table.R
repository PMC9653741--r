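RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Taxon-by-sample count table
#'
#' The universal input container: a non-negative integer matrix with taxa as
#' rows and samples as columns, plus one taxonomic lineage string per taxon
#' (semicolon-delimited, ordered domain to species, missing ranks allowed as
#' explicit `"unclassified"` placeholders).
#'
#' @param counts numeric matrix (taxa x samples) of non-negative integers,
#'   with unique rownames (taxon ids) and colnames (sample ids).
#' @param lineage character vector of semicolon-delimited lineages, one per
#'   taxon (recycled to `"unclassified"` chains if `NULL`).
#' @return an object of class `count_table`: a list with elements `counts`
#'   and `lineage`.
#' @export
count_table <- function(counts, lineage = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numeric values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "double"
  if (is.null(lineage)) lineage <- rep("unclassified", nrow(counts))
  if (length(lineage) != nrow(counts))
    stop("lineage length must equal number of taxa")
  names(lineage) <- rownames(counts)
  structure(list(counts = counts, lineage = lineage), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d taxa x %d samples, %.0f total reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

taxa_ids <- function(table) rownames(table$counts)
sample_ids <- function(table) colnames(table$counts)

#' Subset a count table by taxa and/or samples
#'
#' @param table a `count_table`.
#' @param taxa,samples character or integer indices; `NULL` keeps all.
#' @return a `count_table`.
#' @export
subset_count_table <- function(table, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- rownames(table$counts)
  if (is.null(samples)) samples <- colnames(table$counts)
  count_table(table$counts[taxa, samples, drop = FALSE], table$lineage[taxa])
}

#' Read a taxon-by-sample count table
#'
#' TSV dialect: tab-separated, header row of sample ids, first column the
#' taxon id, second column the semicolon-delimited lineage (the common
#' QIIME2-export shape). BIOM-style JSON is accepted read-only via the
#' `biomformat` package.
#'
#' @param path path to the file.
#' @param format `"tsv"` (default) or `"biom"`.
#' @return a `count_table`.
#' @export
read_count_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM requires the 'biomformat' package")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    om <- biomformat::observation_metadata(b)
    lin <- if (is.null(om)) NULL else
      apply(as.data.frame(om), 1L, function(r) paste(r[!is.na(r) & nzchar(r)], collapse = ";"))
    return(count_table(m, lin))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 3)
    stop("expected >= 3 columns (taxon id, lineage, samples): ", path)
  ids <- raw[[1]]
  lineage <- raw[[2]]
  vals <- raw[, -(1:2), drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric count '%s' at taxon '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  neg <- which(num < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf("negative count '%s' at taxon '%s', sample '%s'",
                 vals[neg[1, 1], neg[1, 2]], ids[neg[1, 1]], colnames(vals)[neg[1, 2]]))
  rownames(num) <- ids
  count_table(num, lineage)
}

#' Write a count table as TSV
#'
#' @param table a `count_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(taxon_id = rownames(table$counts),
                   lineage = unname(table$lineage),
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample metadata table
#'
#' Expects a TSV with a header containing at least `sample_id`; typical
#' columns are `patient_id`, `sample_type` (stool/biopsy), `batch` and the
#' lesion characteristics (location, nice, n_lesions, size, macroscopic,
#' braf, nras, histology, pathway). Missing values allowed.
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                            stringsAsFactors = FALSE, quote = "")
  validate_metadata(meta)
  meta
}

validate_metadata <- function(meta, table = NULL) {
  if (!"sample_id" %in% names(meta)) stop("metadata must have a sample_id column")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (all(c("patient_id", "sample_type") %in% names(meta))) {
    tab <- table(meta$patient_id, meta$sample_type)
    if (any(tab > 1))
      stop("each patient may have at most one sample of each type")
  }
  if (!is.null(table)) {
    miss <- setdiff(colnames(table$counts), meta$sample_id)
    if (length(miss) > 0)
      stop("samples without metadata: ", paste(miss, collapse = ", "))
  }
  invisible(meta)
}

#' Remove likely contaminant taxa using a negative-control library
#'
#' A taxon is removed (whole row) when its relative abundance in the
#' batch's negative-control library is at least `tau` times its mean
#' relative abundance across the batch's biological samples. Apply once per
#' PCR batch, passing that batch's control and restricting `samples` to the
#' batch. An all-zero control leaves the table unchanged.
#'
#' @param table a `count_table` of biological samples.
#' @param control named numeric vector of per-taxon counts in the
#'   negative-control library (names are taxon ids; taxa absent from the
#'   control are treated as zero).
#' @param tau positive ratio threshold (default 1).
#' @param samples optional sample ids over which the biological mean
#'   relative abundance is computed (default: all samples in `table`).
#' @return list with elements `table` (filtered `count_table`) and
#'   `removed` (character vector of removed taxon ids).
#' @export
remove_contaminants <- function(table, control, tau = 1, samples = NULL) {
  stopifnot(tau > 0)
  if (is.null(names(control)) && length(control) == nrow(table$counts))
    names(control) <- rownames(table$counts)
  extra <- setdiff(names(control), rownames(table$counts))
  if (length(extra) > 0)
    stop("control taxa not in table: ", paste(extra, collapse = ", "))
  if (sum(control) == 0)
    return(list(table = table, removed = character(0)))
  if (is.null(samples)) samples <- colnames(table$counts)
  ctrl <- stats::setNames(rep(0, nrow(table$counts)), rownames(table$counts))
  ctrl[names(control)] <- control
  ctrl_rel <- ctrl / sum(ctrl)
  sub <- table$counts[, samples, drop = FALSE]
  rel <- sweep(sub, 2L, colSums(sub), "/")
  mean_rel <- rowMeans(rel)
  removed <- rownames(table$counts)[ctrl_rel >= tau * mean_rel & ctrl_rel > 0]
  keep <- setdiff(rownames(table$counts), removed)
  list(table = subset_count_table(table, taxa = keep), removed = removed)
}

# canonical pre-aggregation vocabularies and their aggregated values
.agg_maps <- list(
  location = c("cecum" = "Right", "ascending colon" = "Right",
               "transverse colon" = "Right",
               "descending colon" = "Left", "sigmoid colon" = "Left",
               "rectum" = "Left",
               "right" = "Right", "left" = "Left"),
  nice = c("1" = "1", "2" = ">1", "3" = ">1", ">1" = ">1"),
  size = c("<5 mm" = "<10 mm", "6-9 mm" = "<10 mm",
           "10-14 mm" = ">=10 mm", "15-19 mm" = ">=10 mm", ">20 mm" = ">=10 mm",
           "<10 mm" = "<10 mm", ">=10 mm" = ">=10 mm")
)

.aggregate_column <- function(x, map, colname) {
  xs <- trimws(tolower(as.character(x)))
  xs <- gsub("–|—", "-", xs)       # en/em dash -> hyphen
  xs <- gsub("≥", ">=", xs)             # >= sign
  names(map) <- tolower(names(map))
  out <- unname(map[xs])
  unknown <- unique(x[!is.na(x) & is.na(out)])
  if (length(unknown) > 0)
    stop(sprintf("unknown %s value(s): %s", colname,
                 paste(unknown, collapse = ", ")))
  out
}

#' Aggregate lesion-characteristic categories
#'
#' Collapses fine-grained lesion categories into the coarse levels used in
#' the statistical analysis: location (cecum/ascending/transverse -> Right;
#' descending/sigmoid/rectum -> Left), NICE category (1 -> "1"; 2,3 -> ">1"),
#' number of lesions (1 -> "1"; 2 or more -> ">1"), and size (<5 mm, 6-9 mm
#' -> "<10 mm"; 10-14, 15-19, >20 mm -> ">=10 mm"). Idempotent: already
#' aggregated values pass through unchanged. Unknown categories raise an
#' error naming them; missing values are preserved.
#'
#' @param raw metadata data.frame; only the columns `location`, `nice`,
#'   `n_lesions`, `size` (those present) are transformed.
#' @return the metadata with aggregated columns.
#' @export
aggregate_metadata <- function(raw) {
  out <- raw
  if ("location" %in% names(out))
    out$location <- .aggregate_column(out$location, .agg_maps$location, "location")
  if ("nice" %in% names(out))
    out$nice <- .aggregate_column(out$nice, .agg_maps$nice, "nice")
  if ("n_lesions" %in% names(out)) {
    x <- as.character(out$n_lesions)
    res <- ifelse(is.na(x), NA_character_,
                  ifelse(x == ">1", ">1",
                         ifelse(suppressWarnings(!is.na(as.numeric(x))) &
                                  suppressWarnings(as.numeric(x)) >= 2, ">1",
                                ifelse(x == "1", "1", NA_character_))))
    unknown <- unique(x[!is.na(x) & is.na(res)])
    if (length(unknown) > 0)
      stop("unknown n_lesions value(s): ", paste(unknown, collapse = ", "))
    out$n_lesions <- res
  }
  if ("size" %in% names(out))
    out$size <- .aggregate_column(out$size, .agg_maps$size, "size")
  out
}
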
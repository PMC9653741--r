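#' Pipeline configuration
#'
#' Validated bundle of paths and parameters for [run_pipeline()]. Unknown
#' keys are rejected.
#'
#' @param counts,metadata input paths (TSV) or in-memory objects.
#' @param out_dir output directory.
#' @param ranks taxonomic ranks to analyze (default species, genus, family,
#'   order, class, phylum).
#' @param factors metadata columns screened for association (default
#'   location, n_lesions, size, nice, pathway).
#' @param rarefaction_depth depth for diversity/componentwise (default: min
#'   sample total, capped at 2442).
#' @param pseudocount zero replacement (default 0.5).
#' @param n_balance_iter,subsample_fraction,balance_threshold
#'   nearest-balance reproducibility parameters (defaults 500, 0.5, 0.8).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param fdr_gate BH threshold gating balance analysis on beta-diversity
#'   significance (default 0.05).
#' @param n_auc_iter cross-validation iterations for the sample-type AUC
#'   (default 100).
#' @param network_params list passed to [mb_network()].
#' @param seed master RNG seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, metadata, out_dir = NULL,
                            ranks = c("species", "genus", "family", "order",
                                      "class", "phylum"),
                            factors = c("location", "n_lesions", "size",
                                        "nice", "pathway"),
                            rarefaction_depth = NULL, pseudocount = 0.5,
                            n_balance_iter = 500, subsample_fraction = 0.5,
                            balance_threshold = 0.8, n_perm = 999,
                            fdr_gate = 0.05, n_auc_iter = 100,
                            network_params = list(), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(pseudocount > 0, n_balance_iter >= 1,
            subsample_fraction > 0, subsample_fraction <= 1,
            balance_threshold >= 0, balance_threshold <= 1,
            n_perm >= 1, fdr_gate > 0, fdr_gate <= 1)
  structure(cfg, class = "pipeline_config")
}

derive_seed <- function(seed, offset) (as.integer(seed) + 7919L * offset) %% 2147483647L

#' Run the end-to-end paired-cohort analysis
#'
#' Stages: metadata aggregation and validation, optional contaminant
#' removal, per-rank taxonomic aggregation, rarefied alpha diversity
#' (Shannon/chao1, Wilcoxon stool vs biopsy), the paired stool-vs-biopsy
#' comparison (stratified PERMANOVA with Shannon correction, reproducible
#' nearest balance, ilr correction, cross-validated AUC), PERMANOVA factor
#' screening per rank and sample type with batch + Shannon correction,
#' nearest balances for the factors passing the beta-diversity FDR gate,
#' cooperatives per sample type and batch, and the component-wise analysis.
#' All result tables are written under `out_dir` (when given) together with
#' a machine-readable run manifest of every seed and decision.
#'
#' @param config a [pipeline_config()].
#' @param controls optional named list `batch -> named control count
#'   vector` for contaminant removal.
#' @return a result bundle (named list), invisibly also written to disk.
#' @export
run_pipeline <- function(config, controls = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  table <- if (inherits(config$counts, "count_table")) config$counts
           else read_count_table(config$counts)
  meta <- if (is.data.frame(config$metadata)) config$metadata
          else read_metadata(config$metadata)
  meta <- aggregate_metadata(meta)
  validate_metadata(meta, table)
  manifest <- list(seed = config$seed, stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  if (!is.null(controls)) {
    removed_all <- character(0)
    for (b in names(controls)) {
      ids <- meta$sample_id[meta$batch == b]
      res <- remove_contaminants(table, controls[[b]],
                                 samples = intersect(ids, sample_ids(table)))
      table <- res$table
      removed_all <- union(removed_all, res$removed)
    }
    log_stage("contaminants", removed = removed_all)
  }

  by_rank <- lapply(stats::setNames(config$ranks, config$ranks),
                    function(r) aggregate_to_rank(table, r))
  species <- if ("species" %in% config$ranks) by_rank[["species"]] else table

  depth <- config$rarefaction_depth
  if (is.null(depth)) depth <- min(min(colSums(species$counts)), 2442)
  rare <- rarefy(species, depth, seed = derive_seed(config$seed, 1L))
  alpha <- alpha_diversity(rare)
  meta_a <- meta[match(alpha$sample_id, meta$sample_id), ]
  wilcox <- stats::setNames(lapply(c("shannon", "chao1"), function(idx)
    stats::wilcox.test(alpha[[idx]][meta_a$sample_type == "stool"],
                       alpha[[idx]][meta_a$sample_type == "biopsy"])$p.value),
    c("shannon", "chao1"))
  log_stage("diversity", depth = depth, seed = derive_seed(config$seed, 1L),
            wilcoxon_p = wilcox)
  meta$shannon <- alpha$shannon[match(meta$sample_id, alpha$sample_id)]

  comp <- zero_replace(species, config$pseudocount)
  dmat <- aitchison_distance(comp)
  type_design <- assoc_design("sample_type", covariates = "shannon",
                              random = "patient_id", strata = "patient_id")
  type_perm <- permanova(dmat, meta, type_design, n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 2L))
  type_fit <- suppressMessages(reproducible_balance(
    species, meta, type_design, n_iter = config$n_balance_iter,
    subsample_fraction = config$subsample_fraction,
    threshold = config$balance_threshold,
    seed = derive_seed(config$seed, 3L), pseudocount = config$pseudocount))
  stool_ids <- meta$sample_id[meta$sample_type == "stool"]
  biopsy_ids <- meta$sample_id[meta$sample_type == "biopsy"]
  corrected <- sample_type_correction(comp[stool_ids, , drop = FALSE],
                                      comp[biopsy_ids, , drop = FALSE])
  auc <- sample_type_auc(species, meta, n_iter = config$n_auc_iter,
                         seed = derive_seed(config$seed, 4L),
                         balance_iter = max(20L, config$n_balance_iter %/% 10L),
                         pseudocount = config$pseudocount)
  log_stage("sample_type", permanova = unclass(type_perm),
            auc_mean = auc$mean, auc_sd = auc$sd)

  screen <- list()
  for (r in names(by_rank)) {
    for (st in c("stool", "biopsy")) {
      ids <- meta$sample_id[meta$sample_type == st]
      sub <- subset_count_table(by_rank[[r]], samples = ids)
      dsub <- aitchison_distance(zero_replace(sub, config$pseudocount))
      for (f in config$factors) {
        if (!f %in% names(meta)) next
        ok <- !is.na(meta[[f]][match(ids, meta$sample_id)])
        if (length(unique(meta[[f]][match(ids, meta$sample_id)][ok])) < 2) next
        res <- permanova(dsub, meta,
                         assoc_design(f, covariates = c("batch", "shannon")),
                         n_perm = config$n_perm,
                         seed = derive_seed(config$seed, 5L))
        screen[[length(screen) + 1]] <-
          data.frame(rank = r, sample_type = st, factor = f, R2 = res$R2,
                     F = res$F, p = res$p)
      }
    }
  }
  screen <- do.call(rbind, screen)
  # BH over the factor x rank grid within each sample type
  screen$q <- NA_real_
  for (st in unique(screen$sample_type)) {
    rows <- screen$sample_type == st
    screen$q[rows] <- bh_adjust(screen$p[rows])
  }

  balances <- list()
  hits <- screen[screen$q < config$fdr_gate, , drop = FALSE]
  if (nrow(hits) > 0) {
    for (i in seq_len(nrow(hits))) {
      st <- hits$sample_type[i]; r <- hits$rank[i]; f <- hits$factor[i]
      ids <- meta$sample_id[meta$sample_type == st &
                              !is.na(meta[[f]])]
      sub <- subset_count_table(by_rank[[r]], samples = ids)
      fit <- suppressMessages(reproducible_balance(
        sub, meta, assoc_design(f, random = "batch"),
        n_iter = config$n_balance_iter,
        subsample_fraction = config$subsample_fraction,
        threshold = config$balance_threshold,
        seed = derive_seed(config$seed, 6L + i),
        pseudocount = config$pseudocount))
      balances[[paste(st, r, f, sep = ".")]] <- fit
    }
  }

  coops <- list()
  for (st in c("stool", "biopsy")) {
    for (b in unique(meta$batch)) {
      ids <- meta$sample_id[meta$sample_type == st & meta$batch == b]
      if (length(ids) < 15) next
      sub <- subset_count_table(species, samples = ids)
      filt <- tryCatch(prevalence_filter(sub), error = function(e) NULL)
      if (is.null(filt) || nrow(filt$counts) < 3) next
      net <- do.call(mb_network, c(list(table = filt,
                                        seed = derive_seed(config$seed, 100L)),
                                   config$network_params))
      clusters <- louvain_clusters(net, seed = derive_seed(config$seed, 101L))
      assoc <- if (length(clusters) > 0)
        cooperative_association(filt, clusters, meta, config$factors)
      else NULL
      coops[[paste(st, b, sep = ".")]] <-
        list(network = net, clusters = clusters, associations = assoc)
    }
  }

  compwise <- list()
  for (st in c("stool", "biopsy")) {
    ids <- meta$sample_id[meta$sample_type == st]
    sub <- subset_count_table(species, samples = ids)
    for (f in config$factors) {
      if (!f %in% names(meta)) next
      m <- meta[match(sample_ids(sub), meta$sample_id), ]
      ok_ids <- m$sample_id[!is.na(m[[f]])]
      if (length(unique(m[[f]][!is.na(m[[f]])])) < 2) next
      res <- suppressMessages(componentwise(
        subset_count_table(sub, samples = ok_ids), meta,
        assoc_design(f, random = "batch"),
        seed = derive_seed(config$seed, 7L)))
      res$sample_type <- st; res$factor <- f
      compwise[[paste(st, f, sep = ".")]] <- res
    }
  }

  bundle <- list(metadata = meta, alpha = alpha, wilcoxon = wilcox,
                 sample_type = list(permanova = type_perm, balance = type_fit,
                                    corrected_stool = corrected, auc = auc),
                 screen = screen, balances = balances,
                 cooperatives = coops, componentwise = compwise,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_alpha_diversity(bundle$alpha, file.path(out_dir, "alpha_diversity.tsv"))
  write_results_tsv(bundle$screen, file.path(out_dir, "permanova_screen.tsv"))
  write_balance_fit(bundle$sample_type$balance,
                    file.path(out_dir, "sample_type_balance.json"))
  utils::write.table(
    data.frame(sample_id = rownames(bundle$sample_type$corrected_stool),
               bundle$sample_type$corrected_stool, check.names = FALSE),
    file.path(out_dir, "corrected_stool.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$balances))
    write_balance_fit(bundle$balances[[nm]],
                      file.path(out_dir, paste0("balance_", nm, ".json")))
  for (nm in names(bundle$cooperatives)) {
    co <- bundle$cooperatives[[nm]]
    write_network(co$network, file.path(out_dir, paste0("network_", nm, ".tsv")))
    if (!is.null(co$associations))
      write_results_tsv(co$associations,
                        file.path(out_dir, paste0("cooperatives_", nm, ".tsv")))
  }
  if (length(bundle$componentwise) > 0)
    write_results_tsv(do.call(rbind, bundle$componentwise),
                      file.path(out_dir, "componentwise.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
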
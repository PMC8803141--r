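# End-to-end orchestration: simulate -> (emit/process reads) -> summarize ->
# essentiality -> fitness at two time points -> classification -> optional
# enrichment, with a ground-truth recovery report.

.default_config <- list(
  outdir = NULL,
  seed = 1L,
  replicon_id = "chr",
  genome_length = 50000L,
  n_genes = 40L,
  gc_fraction = 0.5,
  mean_gene_length = 900,
  n_essential = 4L,
  n_loss = 3L,
  loss_log2 = -3,
  n_gain = 2L,
  gain_log2 = 2,
  insertions_per_bp = 1 / 10.3,
  mean_reads_per_site = 20,
  nb_dispersion = 0.3,
  n_replicates = 2L,
  timepoint_scales = c(TL30 = 1.0, TL90 = 1.6),
  emit_reads = FALSE,
  read_length = 100L,
  error_rate = 0,
  tag_seq = "TGTTAGGCCT",
  barcode_bases = 6L,
  max_mismatch = 2L,
  min_junction_len = 20L,
  end_trim_fraction = 0,
  collapse_strands = FALSE,
  llr_lo = -2,
  llr_hi = 2,
  essentiality_fallback_threshold = 0.005,
  lfc_threshold = 1,
  alpha = 0.005,
  prior_count = 0.5,
  enrich_alpha = 0.005,
  term_map = NULL)

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (a 50 kb / 40-gene demonstration screen
#' with paper-scale insertion density, two replicates and two treated time
#' points at selection strengths 1.0 and 1.6) and overrides the named
#' entries. Unknown keys are rejected. Configurations round-trip through
#' YAML via [read_config()]/[write_config()].
#'
#' @param ... named overrides of the default entries.
#' @return A named list of class `tn_config`.
#' @export
#' @examples
#' cfg <- tn_config(genome_length = 20000L, n_genes = 15L, seed = 7L)
tn_config <- function(...) {
  over <- list(...)
  if (length(over)) {
    .assert(!is.null(names(over)) && all(nzchar(names(over))),
            "config overrides must be named", "tn_config_error")
    unknown <- setdiff(names(over), names(.default_config))
    .assert(!length(unknown),
            paste("unknown config keys:", paste(unknown, collapse = ", ")),
            "tn_config_error")
  }
  cfg <- utils::modifyList(.default_config, over, keep.null = TRUE)
  .assert(!is.null(cfg$seed), "seed is mandatory", "tn_config_error")
  .assert(cfg$n_essential + cfg$n_loss + cfg$n_gain <= cfg$n_genes,
          "more effect genes than genes", "tn_config_error")
  structure(cfg, class = c("tn_config", "list"))
}

#' Read / write a pipeline configuration (YAML)
#' @param path YAML file path.
#' @param config a [tn_config()].
#' @return `read_config` returns a validated [tn_config()];
#'   `write_config` invisibly returns `path`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  ts <- y$timepoint_scales
  if (!is.null(ts)) y$timepoint_scales <- unlist(ts)
  do.call(tn_config, y)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$timepoint_scales <- as.list(cfg$timepoint_scales)
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

# deterministic assignment of ground-truth roles to genes
.assign_effects <- function(genome, cfg) {
  set.seed(derive_seed(cfg$seed, "effects"))
  ids <- sample(genome$genes$gene_id)
  ess <- ids[seq_len(cfg$n_essential)]
  loss <- ids[cfg$n_essential + seq_len(cfg$n_loss)]
  gain <- ids[cfg$n_essential + cfg$n_loss + seq_len(cfg$n_gain)]
  effect_map(genome, essential = ess,
             fitness_log2 = c(setNames(rep(cfg$loss_log2, length(loss)), loss),
                              setNames(rep(cfg$gain_log2, length(gain)), gain)))
}

.sample_counts_matrix <- function(stats_list) {
  mat <- vapply(stats_list, function(s) s$read_count,
                numeric(nrow(stats_list[[1]])))
  rownames(mat) <- stats_list[[1]]$gene_id
  mat
}

#' Run the full simulated screen end to end
#'
#' Simulates a genome, effect map and master insertion library, produces
#' control and treated replicate profiles by multinomial resampling (each
#' treated time point at its own selection strength), optionally emits and
#' re-processes barcoded junction reads (exercising the full read-handling
#' funnel), summarizes per-gene statistics, calls essentiality on the mean
#' control insertion index, excludes the essential genome, runs the exact
#' test per time point, gates significance, classifies time points, and —
#' because the ground truth is known — computes a recovery report. All
#' artifacts are written as TSV/JSON under `config$outdir` (if set)
#' together with a frozen copy of the configuration.
#'
#' @param config a [tn_config()].
#' @return list with `genome`, `effects`, `profiles`, `gene_stats`,
#'   `essentiality` (model + calls), `fitness` (per time point),
#'   `timepoints`, `report` (read-processing funnel, when reads were
#'   emitted), `recovery`, `enrichment` (when a term map is configured),
#'   and `summary`.
#' @export
run_pipeline <- function(config = tn_config()) {
  cfg <- if (inherits(config, "tn_config")) config else do.call(tn_config, config)
  genome <- generate_genome(cfg$genome_length, cfg$n_genes, cfg$gc_fraction,
                            mean_gene_length = cfg$mean_gene_length,
                            seed = cfg$seed, replicon_id = cfg$replicon_id)
  effects <- .assign_effects(genome, cfg)
  library0 <- simulate_library(
    genome, effects, insertions_per_bp = cfg$insertions_per_bp,
    mean_reads_per_site = cfg$mean_reads_per_site,
    nb_dispersion = cfg$nb_dispersion, seed = cfg$seed,
    sample_id = "master_library")

  scales <- c(TL0 = 0, cfg$timepoint_scales)
  profiles <- list()
  for (ti in seq_along(scales)) {
    for (rep_i in seq_len(cfg$n_replicates)) {
      sid <- sprintf("%s_%d", names(scales)[ti], rep_i)
      profiles[[sid]] <- apply_selection(
        library0, genome, effects,
        seed = derive_seed(cfg$seed, "replicate", ti * 100L + rep_i),
        scale = scales[[ti]], sample_id = sid)
    }
  }

  report <- NULL
  if (isTRUE(cfg$emit_reads)) {
    barcodes <- .make_barcodes(names(profiles), cfg$barcode_bases, cfg$seed)
    reads <- do.call(rbind, lapply(names(profiles), function(sid) {
      emit_reads(profiles[[sid]], genome, tag_seq = cfg$tag_seq,
                 barcode = barcodes[[sid]], read_length = cfg$read_length,
                 error_rate = cfg$error_rate,
                 seed = derive_seed(cfg$seed, "reads", match(sid, names(profiles))))
    }))
    reads <- reads[order(reads$read_id), , drop = FALSE] # mix samples
    proc <- process_reads(reads, genome, barcodes, cfg$tag_seq,
                          max_mismatch = cfg$max_mismatch,
                          min_junction_len = cfg$min_junction_len,
                          collapse_strands = cfg$collapse_strands)
    profiles <- proc$profiles
    report <- proc$report
  }

  gene_stats <- lapply(profiles, summarize_genes, genome = genome,
                       end_trim_fraction = cfg$end_trim_fraction,
                       collapse_strands = cfg$collapse_strands)
  ctrl_ids <- grep("^TL0_", names(profiles), value = TRUE)
  mean_index <- rowMeans(vapply(gene_stats[ctrl_ids],
                                function(s) s$insertion_index,
                                numeric(nrow(genome$genes))))
  pseudo <- 1 / (2 * max(genome$genes$length_bp))
  # small screens (or unimodal index data) cannot support the mixture fit;
  # fall back to a fixed insertion-index threshold well below the library
  # density, which insertion-free genes sit under and insertable genes never do
  model <- tryCatch(fit_essentiality_mixture(mean_index, pseudo = pseudo),
                    tn_degenerate_fit = function(e) NULL,
                    tn_error = function(e) NULL)
  calls <- if (!is.null(model)) {
    call_essentiality(mean_index, model, llr_lo = cfg$llr_lo,
                      llr_hi = cfg$llr_hi, gene_id = genome$genes$gene_id)
  } else {
    data.frame(gene_id = genome$genes$gene_id, insertion_index = mean_index,
               log2_likelihood_ratio = NA_real_,
               call = ifelse(mean_index < cfg$essentiality_fallback_threshold,
                             "essential", "nonessential"),
               stringsAsFactors = FALSE)
  }
  nonessential <- calls$gene_id[calls$call != "essential"]

  fitness <- list()
  sig_sets <- list()
  for (tp in names(cfg$timepoint_scales)) {
    trt_ids <- grep(paste0("^", tp, "_"), names(profiles), value = TRUE)
    samples <- c(ctrl_ids, trt_ids)
    mat <- .sample_counts_matrix(gene_stats[samples])
    mat <- mat[nonessential, , drop = FALSE]
    res <- fitness_test(mat, c(rep("control", length(ctrl_ids)),
                               rep("treated", length(trt_ids))),
                        lfc_threshold = cfg$lfc_threshold, alpha = cfg$alpha,
                        prior_count = cfg$prior_count)
    fitness[[tp]] <- res
    sig_sets[[tp]] <- res$gene_id[res$sig_class != "ns"]
  }
  timepoints <- if (length(sig_sets) >= 2) {
    classify_timepoints(sig_sets[[1]], sig_sets[[2]])
  } else NULL

  enrichment <- NULL
  if (!is.null(cfg$term_map)) {
    tm <- if (is.character(cfg$term_map)) read_term_map(cfg$term_map) else
      cfg$term_map
    sig_all <- sort(unique(unlist(sig_sets)))
    enrichment <- enrich(sig_all, tm, background = genome$genes$gene_id,
                         alpha = cfg$enrich_alpha)
  }

  recovery <- recovery_report(effects, calls, fitness, gene_stats,
                              scales = cfg$timepoint_scales)
  out <- list(config = cfg, genome = genome, effects = effects,
              profiles = profiles, gene_stats = gene_stats,
              essentiality = list(model = model, calls = calls),
              fitness = fitness, timepoints = timepoints, report = report,
              enrichment = enrichment, recovery = recovery,
              summary = render_report(fitness, timepoints))
  if (!is.null(cfg$outdir)) .write_artifacts(out, cfg$outdir)
  out
}

.make_barcodes <- function(sample_ids, width, seed) {
  set.seed(derive_seed(seed, "misc"))
  repeat {
    bc <- vapply(sample_ids, function(s)
      paste(sample(c("A", "C", "G", "T"), width, TRUE), collapse = ""), "")
    ok <- !anyDuplicated(bc)
    if (ok) return(bc)
  }
}

.write_artifacts <- function(out, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_config(out$config, fp("config.yaml"))
  write_genome(out$genome, fp("genome.fasta"), fp("genes.gff3"))
  write_effects(out$effects, fp("truth_effects.tsv"))
  for (sid in names(out$profiles))
    write_profile(out$profiles[[sid]], fp(sprintf("sites_%s.tsv", sid)))
  for (sid in names(out$gene_stats))
    write_gene_stats(out$gene_stats[[sid]], fp(sprintf("genes_%s.tsv", sid)))
  ess <- out$essentiality$calls
  write.table(ess, fp("essentiality.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (tp in names(out$fitness))
    write.table(out$fitness[[tp]], fp(sprintf("fitness_%s.tsv", tp)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$enrichment))
    write.table(out$enrichment, fp("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(out$report)) write_report(out$report, fp("processing.json"))
  jsonlite::write_json(out$summary, fp("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  jsonlite::write_json(out$recovery, fp("recovery.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Ground-truth recovery report for a simulated screen
#'
#' Confusion table of true effect class versus gated class per time point
#' (over non-essential truth genes; margins equal the simulated counts),
#' essentiality sensitivity/specificity, log2 fold-change RMSE over
#' true-effect genes with at least `min_reads` control reads, and replicate
#' r-squared of control insertion indices.
#'
#' @param effects ground-truth effect map.
#' @param calls essentiality calls data.frame.
#' @param fitness named list of per-time-point fitness tables.
#' @param gene_stats named list of per-sample gene summaries.
#' @param scales named selection strengths per time point.
#' @param min_reads control-read floor for the RMSE stratum (default 200).
#' @return Nested list of recovery metrics.
#' @export
recovery_report <- function(effects, calls, fitness, gene_stats,
                            scales = c(TL30 = 1), min_reads = 200) {
  truth_class <- ifelse(effects$essential, "essential",
                        ifelse(effects$fitness_log2 < 0, "loss",
                               ifelse(effects$fitness_log2 > 0, "gain",
                                      "neutral")))
  names(truth_class) <- effects$gene_id
  ess_called <- calls$gene_id[calls$call == "essential"]
  is_ess <- effects$essential
  sens <- if (any(is_ess))
    mean(effects$gene_id[is_ess] %in% ess_called) else NA_real_
  fpr <- mean(effects$gene_id[!is_ess] %in% ess_called)

  conf <- list(); rmse <- list()
  for (tp in names(fitness)) {
    res <- fitness[[tp]]
    tc <- truth_class[res$gene_id]
    tc[tc == "essential"] <- "neutral" # essential truths excluded upstream
    conf[[tp]] <- as.data.frame(table(truth = factor(tc, c("loss", "neutral", "gain")),
                                      called = factor(res$sig_class,
                                                      c("loss", "ns", "gain"))))
    eff <- effects$fitness_log2[match(res$gene_id, effects$gene_id)] *
      (scales[[tp]] %||% 1)
    true_eff <- eff != 0
    deep <- res$mean_control_count >= min_reads
    sel <- true_eff & deep & is.finite(eff)
    rmse[[tp]] <- if (any(sel))
      sqrt(mean((res$log2fc[sel] - eff[sel])^2)) else NA_real_
  }

  ctrl <- grep("^TL0_", names(gene_stats), value = TRUE)
  r2 <- NA_real_
  if (length(ctrl) >= 2) {
    keep_ids <- effects$gene_id[!effects$essential]
    a <- gene_stats[[ctrl[1]]]; b <- gene_stats[[ctrl[2]]]
    r2 <- replicate_correlation(a[a$gene_id %in% keep_ids, ],
                                b[b$gene_id %in% keep_ids, ])$r_squared
  }
  list(essentiality = list(sensitivity = sens, false_positive_rate = fpr),
       confusion = conf, log2fc_rmse = rmse, replicate_r_squared = r2)
}

#' Human-readable run summary
#'
#' Emits the data behind a ranked fold-change curve (fold changes sorted
#' ascending per time point), per-class counts, and the both/early/late
#' significant-set sizes.
#'
#' @param fitness named list of per-time-point fitness tables (may be
#'   empty).
#' @param timepoints output of [classify_timepoints()] or `NULL`.
#' @return list with `classes`, `ranked_log2fc`, `sets`.
#' @export
render_report <- function(fitness, timepoints = NULL) {
  classes <- lapply(fitness, function(res)
    as.list(table(factor(res$sig_class, c("loss", "gain", "ns")))))
  ranked <- lapply(fitness, function(res) {
    o <- order(res$log2fc)
    data.frame(rank = seq_along(o), gene_id = res$gene_id[o],
               log2fc = res$log2fc[o], sig_class = res$sig_class[o],
               stringsAsFactors = FALSE)
  })
  sets <- if (!is.null(timepoints))
    lapply(timepoints, length) else NULL
  list(classes = classes, ranked_log2fc = ranked, sets = sets)
}
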
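# End-to-end orchestration: curate -> align -> essential dynamics -> Isomap
# -> annotate -> project variants -> report. Produces deterministic CSV/TSV
# artifacts, best-effort plots, and a JSON summary of headline numbers.

#' Configure an analysis run
#'
#' @param pdb_dir directory of input PDB files.
#' @param out_dir output directory (created if needed).
#' @param manifest PDB entry identifiers to load; default: the bundled
#'   FGFR2-TKD set. For synthetic or third-party collections pass the
#'   entries present in `pdb_dir`.
#' @param reference_id trace `"ENTRY:CHAIN"` used as superposition
#'   reference (default `"1GJO:A"`).
#' @param required_positions residue numbers required of every retained
#'   chain (default: the functional-region union).
#' @param k Isomap neighbor count (default 8).
#' @param dims embedding dimension, 2 or 3 (default 2).
#' @param max_m components for the reconstruction-error curves (default 6).
#' @param variant_pdbs named character vector of predicted-variant PDB
#'   files to place out-of-sample (names = variant labels), or `NULL`.
#' @param annotate attach bundled FGFR2 labels to embeddings; set `FALSE`
#'   for collections absent from the annotation tables.
#' @param plots write PNG figure twins (default `TRUE`).
#' @param seed integer seed recorded in the summary (the pipeline itself is
#'   deterministic; the seed feeds any synthetic upstream steps).
#' @return A validated `run_config` list.
#' @export
run_config <- function(pdb_dir, out_dir,
                       manifest = fgfr2_structures()$entry,
                       reference_id = "1GJO:A",
                       required_positions = fgfr2_required_positions(),
                       k = 8L, dims = 2L, max_m = 6L,
                       variant_pdbs = NULL, annotate = TRUE,
                       plots = TRUE, seed = 1L) {
  if (!dir.exists(pdb_dir)) stop("pdb_dir does not exist: ", pdb_dir)
  if (!dims %in% 2:3) stop("dims must be 2 or 3")
  if (k < 1L) stop("k must be >= 1")
  if (!is.null(variant_pdbs)) {
    bad <- variant_pdbs[!file.exists(variant_pdbs)]
    if (length(bad)) stop("variant PDB files not found: ",
                          paste(bad, collapse = ", "))
    if (is.null(names(variant_pdbs)))
      names(variant_pdbs) <- toupper(sub("\\.pdb$", "",
                                         basename(variant_pdbs),
                                         ignore.case = TRUE))
  }
  structure(list(pdb_dir = pdb_dir, out_dir = out_dir, manifest = manifest,
                 reference_id = reference_id,
                 required_positions = required_positions,
                 k = as.integer(k), dims = as.integer(dims),
                 max_m = as.integer(max_m), variant_pdbs = variant_pdbs,
                 annotate = isTRUE(annotate), plots = isTRUE(plots),
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  attr(res, "elapsed") <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res
}

#' Run the full analysis pipeline
#'
#' Executes curation, reference superposition, the essential-dynamics fit,
#' the Isomap embedding, label annotation and (optionally) variant
#' placement, writing every artifact under `config$out_dir`:
#' `curation.tsv`, `aligned.csv` (+ JSON sidecar), `variance.csv`,
#' `error_curves.tsv`, `profile_pc1..3.tsv`, `pca_embedding.csv`,
#' `isomap_embedding.csv`, `variants.csv` (when variants are given),
#' `summary.json`, and PNG plots when enabled. CSV/TSV outputs are
#' deterministic for a fixed config.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results (`report`,
#'   `aligned`, `model`, `isomap`, `labels`, `variants`, `summary`,
#'   `timings`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  timings <- list()

  loaded <- stage("curate", load_ensemble(config$pdb_dir, config$manifest,
                                          config$required_positions))
  timings$curate <- attr(loaded, "elapsed")
  write_curation_tsv(loaded$report, out("curation.tsv"))

  aligned <- stage("align", align_ensemble(loaded$ensemble,
                                           config$reference_id))
  timings$align <- attr(aligned, "elapsed")
  write_ensemble_csv(aligned, out("aligned.csv"))

  model <- stage("pca", essential_dynamics(aligned))
  timings$pca <- attr(model, "elapsed")
  vt <- variance_table(model)
  utils::write.csv(vt, out("variance.csv"), row.names = FALSE)
  curves <- reconstruction_error(model, aligned, config$max_m)
  utils::write.table(curves, out("error_curves.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (pc in seq_len(min(3L, length(model$singular_values)))) {
    prof <- displacement_profile(model, pc)
    utils::write.table(as.data.frame(prof), out(sprintf("profile_pc%d.tsv", pc)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  iso <- stage("isomap", isomap(aligned, k = config$k, d = config$dims))
  timings$isomap <- attr(iso, "elapsed")

  labels <- NULL
  if (config$annotate)
    labels <- stage("annotate", label_traces(aligned$trace_ids))
  pca_embed <- data.frame(trace_id = aligned$trace_ids,
                          model$scores[, seq_len(min(config$dims,
                                                     ncol(model$scores))),
                                       drop = FALSE],
                          stringsAsFactors = FALSE)
  iso_embed <- data.frame(trace_id = aligned$trace_ids, iso$embedding,
                          stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    keep <- c("mutation", "region_symbols", "region_name", "status", "disease")
    pca_embed <- cbind(pca_embed, labels[, keep])
    iso_embed <- cbind(iso_embed, labels[, keep])
  }
  utils::write.csv(pca_embed, out("pca_embedding.csv"), row.names = FALSE)
  utils::write.csv(iso_embed, out("isomap_embedding.csv"), row.names = FALSE)

  variants <- NULL
  if (!is.null(config$variant_pdbs)) {
    variants <- stage("variants", {
      ref_trace <- ensemble_trace(aligned, config$reference_id)
      rows <- lapply(names(config$variant_pdbs), function(v) {
        traces <- read_ca_traces(config$variant_pdbs[[v]])
        tr <- traces[[1]]
        proj <- place_variant(model, ref_trace, tr, m = config$dims)
        data.frame(variant = v, trace_id = trace_id(tr),
                   shared_residues = length(model$common_residues),
                   as.data.frame(proj), stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
    timings$variants <- attr(variants, "elapsed")
    utils::write.csv(variants, out("variants.csv"), row.names = FALSE)
  }

  summary <- list(
    n_chains = nrow(aligned$matrix),
    pc1_variance_pct = 100 * model$variance_fractions[1],
    n_residues = length(aligned$common_residues),
    n_coordinates = ncol(aligned$matrix),
    cumulative_top2_pct = cumulative_variance(model, min(2L, length(model$variance_fractions))),
    cumulative_top3_pct = cumulative_variance(model, min(3L, length(model$variance_fractions))),
    n_removed_chains = sum(!loaded$report$retained),
    reference_id = config$reference_id,
    isomap_k = config$k,
    max_reconstruction_rmsd = max(curves$rmsd[curves$m == 1L]),
    seed = config$seed)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  if (config$plots) {
    plot_png <- function(file, expr) {
      grDevices::png(out(file), width = 900, height = 700, res = 110)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr
    }
    plot_png("variance.png", plot(model, type = "variance",
                                  main = "Cumulative variance"))
    plot_png("pca_embedding.png", plot(model, type = "scores",
                                       main = "PC1-PC2 embedding"))
    plot_png("isomap_embedding.png", plot(iso))
    for (pc in seq_len(min(3L, length(model$singular_values))))
      plot_png(sprintf("profile_pc%d.png", pc),
               plot(displacement_profile(model, pc)))
  }

  invisible(list(report = loaded$report, aligned = aligned, model = model,
                 isomap = iso, labels = labels, variants = variants,
                 summary = summary, timings = timings))
}
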
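# Reading PDB coordinate files into C-alpha traces, curating chains against
# required functional positions, and assembling a common-residue ensemble
# matrix. Parsing itself is delegated to bio3d; this module owns the
# trace/ensemble contracts used by the rest of the package.

#' Construct a C-alpha trace
#'
#' A `ca_trace` holds one chain's ordered CA coordinates together with its
#' author residue numbering (including insertion codes). It is the atomic
#' unit of every ensemble in this package.
#'
#' @param entry_id 4-character PDB identifier (any case; stored upper-case).
#' @param chain_id single-character chain label.
#' @param resno integer vector of author residue numbers.
#' @param coords numeric matrix with one (x, y, z) row per residue, in
#'   Angstrom.
#' @param insert character vector of insertion codes (`""` when absent).
#'
#' @return An object of class `ca_trace` with fields `entry_id`, `chain_id`,
#'   `resno`, `insert`, `residues` (residue identifier strings, e.g. `"659"`
#'   or `"100A"`) and `coords`.
#' @export
ca_trace <- function(entry_id, chain_id, resno, coords,
                     insert = rep("", length(resno))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  resno <- as.integer(resno)
  insert[is.na(insert)] <- ""
  if (nrow(coords) != length(resno) || length(insert) != length(resno))
    stop("coords must have one row per residue")
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z)")
  ids <- paste0(resno, insert)
  if (anyDuplicated(ids))
    stop("duplicate residue identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ord <- order(resno, insert)
  if (any(ord != seq_along(ord))) {
    resno <- resno[ord]; insert <- insert[ord]
    coords <- coords[ord, , drop = FALSE]
    ids <- ids[ord]
  }
  rownames(coords) <- ids
  structure(list(entry_id = toupper(entry_id), chain_id = chain_id,
                 resno = resno, insert = insert, residues = ids,
                 coords = coords),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s chain %s: %d residues (%s..%s)\n",
              x$entry_id, x$chain_id, length(x$resno),
              x$residues[1], x$residues[length(x$residues)]))
  invisible(x)
}

trace_id <- function(trace) paste0(trace$entry_id, ":", trace$chain_id)

#' Extract per-chain CA traces from a PDB file
#'
#' Reads a PDB coordinate file (ATOM/HETATM records) and returns one
#' [ca_trace] per chain. Only CA atoms are kept; for residues with alternate
#' locations the conformer with the highest occupancy wins (ties broken by
#' the lexicographically first altloc identifier); for multi-model entries
#' only the first model is read. Residues that carry backbone atoms but no
#' CA are omitted from the trace and listed in the `missing_ca` attribute of
#' the result.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param entry_id entry identifier to stamp on the traces; defaults to the
#'   file base name (upper-cased).
#'
#' @return A named list of [ca_trace] objects (names `"ENTRY:CHAIN"`), with
#'   attribute `missing_ca`: a data.frame (`entry`, `chain`, `resno`) of
#'   residues present in the file but lacking a CA record.
#' @export
read_ca_traces <- function(pdb, entry_id = NULL) {
  if (length(pdb) > 1L || !file.exists(pdb[1])) {
    # treat as in-memory PDB text
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(pdb, path)
    if (is.null(entry_id)) entry_id <- "XXXX"
  } else {
    path <- pdb
    if (is.null(entry_id))
      entry_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path),
                              ignore.case = TRUE))
  }
  structure_data <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB input '", basename(path),
                             "': ", conditionMessage(e), call. = FALSE))
  atoms <- structure_data$atom
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  ca <- atoms[atoms$elety == "CA" & atoms$resid != "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    stop("no CA atoms found in '", basename(path), "'", call. = FALSE)
  ca$insert[is.na(ca$insert)] <- ""
  ca$alt[is.na(ca$alt)] <- ""
  ca$o[is.na(ca$o)] <- 1
  # altloc resolution: highest occupancy, tie -> lexicographically first alt
  key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  ord <- order(key, -ca$o, ca$alt)
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(key[ord]), , drop = FALSE]

  # residues with atoms but no CA (per chain), for the gap report
  prot <- atoms[atoms$type == "ATOM", , drop = FALSE]
  prot$insert[is.na(prot$insert)] <- ""
  all_res <- unique(prot[, c("chain", "resno", "insert")])
  ca_key <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  res_key <- paste(all_res$chain, all_res$resno, all_res$insert, sep = "\r")
  gaps <- all_res[!(res_key %in% ca_key), , drop = FALSE]

  traces <- lapply(split(ca, ca$chain), function(ch) {
    ca_trace(entry_id, ch$chain[1], ch$resno,
             cbind(ch$x, ch$y, ch$z), ch$insert)
  })
  names(traces) <- vapply(traces, trace_id, "")
  missing_ca <- if (nrow(gaps) > 0L)
    data.frame(entry = entry_id, chain = gaps$chain, resno = gaps$resno,
               stringsAsFactors = FALSE)
  else
    data.frame(entry = character(), chain = character(), resno = integer(),
               stringsAsFactors = FALSE)
  structure(traces, missing_ca = missing_ca)
}

#' Curate chains against required residue positions
#'
#' A chain is removed if and only if it lacks at least one required residue
#' position. The default positions are the union of the FGFR2-TKD functional
#' region ranges (see [fgfr2_required_positions()]), following the rule that
#' chains missing any important region are dropped before analysis.
#'
#' @param traces list of [ca_trace] objects.
#' @param required_positions integer vector of residue numbers that every
#'   retained chain must contain.
#'
#' @return A `curation_report`: a data.frame with columns `entry`, `chain`,
#'   `retained` (logical) and `reason` (`""` for retained chains, otherwise
#'   `"Missing residue <positions>"`). The required positions are stored in
#'   the `required_positions` attribute.
#' @export
curate_chains <- function(traces, required_positions = fgfr2_required_positions()) {
  if (length(traces) == 0L) stop("no traces supplied")
  if (length(required_positions) == 0L) stop("required_positions is empty")
  required_positions <- sort(unique(as.integer(required_positions)))
  rows <- lapply(traces, function(tr) {
    missing <- setdiff(required_positions, tr$resno)
    data.frame(entry = tr$entry_id, chain = tr$chain_id,
               retained = length(missing) == 0L,
               reason = if (length(missing)) paste0("Missing residue ",
                                                    paste(missing, collapse = ", "))
                        else "",
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report <- report[order(report$entry, report$chain), , drop = FALSE]
  rownames(report) <- NULL
  structure(report, required_positions = required_positions,
            class = c("curation_report", "data.frame"))
}

#' Assemble a common-residue ensemble matrix
#'
#' Restricts every trace to the residues shared by all traces (intersection
#' of residue identifier sets, ascending) and flattens each trace into one
#' row of x, y, z coordinates per residue.
#'
#' @param traces list of at least two [ca_trace] objects (typically the
#'   retained chains of a [curate_chains()] report).
#'
#' @return A `trace_ensemble`: list with `matrix` (n x 3R), `trace_ids`
#'   (`"ENTRY:CHAIN"`), `common_residues` (residue identifier strings) and
#'   `resno` (their integer residue numbers).
#' @export
build_ensemble <- function(traces) {
  if (length(traces) < 2L) stop("need at least two traces")
  keys <- lapply(traces, function(tr) tr$residues)
  common <- Reduce(intersect, keys)
  if (length(common) == 0L) {
    sizes <- vapply(traces, function(tr) length(tr$residues), 0L)
    culprit <- trace_id(traces[[which.min(sizes)]])
    stop("no residues common to all traces (most restrictive trace: ",
         culprit, ")")
  }
  ref <- traces[[1]]
  idx <- match(common, ref$residues)
  ord <- order(ref$resno[idx], ref$insert[idx])
  common <- common[ord]
  mat <- t(vapply(traces, function(tr) {
    as.vector(t(tr$coords[match(common, tr$residues), , drop = FALSE]))
  }, numeric(3L * length(common))))
  ids <- vapply(traces, trace_id, "")
  rownames(mat) <- ids
  colnames(mat) <- paste0("r", rep(common, each = 3L), "_", c("x", "y", "z"))
  structure(list(matrix = mat, trace_ids = ids, common_residues = common,
                 resno = ref$resno[match(common, ref$residues)]),
            class = "trace_ensemble")
}

#' @export
print.trace_ensemble <- function(x, ...) {
  cat(sprintf("<trace_ensemble> %d traces x %d common residues (%d columns)\n",
              nrow(x$matrix), length(x$common_residues), ncol(x$matrix)))
  invisible(x)
}

#' Extract one trace of an ensemble as a `ca_trace`
#'
#' @param ensemble a `trace_ensemble`.
#' @param id trace identifier `"ENTRY:CHAIN"`.
#' @return A [ca_trace] restricted to the ensemble's common residues.
#' @export
ensemble_trace <- function(ensemble, id) {
  i <- match(id, ensemble$trace_ids)
  if (is.na(i))
    stop("unknown trace id '", id, "'; available: ",
         paste(ensemble$trace_ids, collapse = ", "))
  xyz <- matrix(ensemble$matrix[i, ], ncol = 3L, byrow = TRUE)
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  insert <- sub("^[-0-9]+", "", ensemble$common_residues)
  ca_trace(parts[1], parts[2], ensemble$resno, xyz, insert)
}

#' Convert a `ca_trace` to a flattened 3R coordinate vector
#'
#' @param trace a [ca_trace].
#' @param residues optional residue identifiers to restrict/order by; an
#'   error lists any that the trace lacks.
#' @return Numeric vector of length `3 * length(residues)`.
#' @export
flatten_trace <- function(trace, residues = trace$residues) {
  idx <- match(residues, trace$residues)
  if (anyNA(idx))
    stop("trace ", trace_id(trace), " lacks residues: ",
         paste(residues[is.na(idx)], collapse = ", "))
  as.vector(t(trace$coords[idx, , drop = FALSE]))
}

#' Write a curation report as TSV
#'
#' @param report a [curate_chains()] report.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curation_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an ensemble as CSV plus JSON sidecar
#'
#' The CSV holds the n x 3R matrix with residue-named columns; the sidecar
#' (`<path>.json`) records `trace_ids`, `common_residues` and `resno` so the
#' ensemble round-trips exactly.
#'
#' @param ensemble a `trace_ensemble`.
#' @param path CSV output file.
#' @return `path`, invisibly (`write_ensemble_csv`); a `trace_ensemble`
#'   (`read_ensemble_csv`).
#' @export
write_ensemble_csv <- function(ensemble, path) {
  df <- data.frame(trace_id = ensemble$trace_ids, ensemble$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(trace_ids = ensemble$trace_ids,
                  common_residues = ensemble$common_residues,
                  resno = ensemble$resno)
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
read_ensemble_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$trace_id
  structure(list(matrix = mat, trace_ids = df$trace_id,
                 common_residues = as.character(side$common_residues),
                 resno = as.integer(side$resno)),
            class = "trace_ensemble")
}

#' Load, curate and assemble an ensemble from a directory of PDB files
#'
#' Convenience wrapper over [read_ca_traces()], [curate_chains()] and
#' [build_ensemble()]: reads every entry of `manifest` from `pdb_dir`
#' (expecting `<entry>.pdb`, case-insensitive), removes chains missing a
#' required position and assembles the retained chains.
#'
#' @param pdb_dir directory holding PDB files.
#' @param manifest character vector of PDB entry identifiers; defaults to
#'   the bundled FGFR2-TKD entry set (excluded entries dropped).
#' @param required_positions passed to [curate_chains()].
#' @return List with `ensemble` (a `trace_ensemble`), `report` (the
#'   curation report) and `missing_ca` (combined gap report).
#' @export
load_ensemble <- function(pdb_dir,
                          manifest = fgfr2_structures()$entry,
                          required_positions = fgfr2_required_positions()) {
  files <- list.files(pdb_dir, pattern = "\\.(pdb|ent)$", full.names = TRUE,
                      ignore.case = TRUE)
  names(files) <- toupper(sub("\\.(pdb|ent)$", "", basename(files),
                              ignore.case = TRUE))
  missing <- setdiff(toupper(manifest), names(files))
  if (length(missing))
    stop("PDB files not found in '", pdb_dir, "': ",
         paste(missing, collapse = ", "))
  parsed <- lapply(toupper(manifest), function(e) read_ca_traces(files[[e]], e))
  traces <- do.call(c, lapply(parsed, unclass))
  gaps <- do.call(rbind, lapply(parsed, attr, "missing_ca"))
  report <- curate_chains(traces, required_positions)
  keep <- paste0(report$entry, ":", report$chain)[report$retained]
  ids <- vapply(traces, trace_id, "")
  list(ensemble = build_ensemble(traces[ids %in% keep]),
       report = report, missing_ca = gaps)
}
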
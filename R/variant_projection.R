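# Evaluation of externally predicted structures against known counterparts
# and out-of-sample placement of modeled variants into a fitted
# essential-dynamics space. The fitted model is frozen: predicted traces are
# superposed onto the fitting reference and projected, never refitted.

#' Least RMSD between a predicted and a known CA trace
#'
#' Restricts both traces to their shared residue set and superposes them
#' optimally ([kabsch()]); the least RMSD on that set is the prediction
#' error.
#'
#' @param predicted,known [ca_trace] objects.
#' @return List with `rmsd` (Angstrom) and `shared_residues` (count).
#' @export
evaluate_prediction <- function(predicted, known) {
  shared <- intersect(predicted$residues, known$residues)
  if (length(shared) < 3L)
    stop("fewer than 3 shared residues (", length(shared), ")")
  a <- predicted$coords[match(shared, predicted$residues), , drop = FALSE]
  b <- known$coords[match(shared, known$residues), , drop = FALSE]
  list(rmsd = kabsch(a, b)$lrmsd, shared_residues = length(shared))
}

#' Place a modeled variant structure into a fitted component space
#'
#' Superposes the predicted trace onto the reference trace (restricted to
#' the model's common residues) by [kabsch()], then projects it with the
#' frozen [essential_dynamics()] model. The placement is invariant to the
#' pose the predicted coordinates arrive in.
#'
#' @param model an `ed_model` fitted on the reference-aligned ensemble.
#' @param reference the reference [ca_trace] the ensemble was aligned to
#'   (e.g. `ensemble_trace(aligned, "1GJO:A")`).
#' @param predicted the modeled variant [ca_trace]; must cover all common
#'   residues of the fit (missing ones are listed in the error).
#' @param m number of leading component coordinates to return (default 2).
#' @return 1 x m projection matrix (columns `PC1..PCm`).
#' @export
place_variant <- function(model, reference, predicted, m = 2L) {
  if (is.null(model$common_residues))
    stop("model carries no residue identifiers; fit it on a trace_ensemble")
  common <- model$common_residues
  missing <- setdiff(common, predicted$residues)
  if (length(missing))
    stop("predicted trace lacks common residues: ",
         paste(missing, collapse = ", "))
  pred <- matrix(flatten_trace(predicted, common), ncol = 3L, byrow = TRUE)
  ref <- matrix(flatten_trace(reference, common), ncol = 3L, byrow = TRUE)
  tf <- kabsch(pred, ref)
  posed <- as.vector(t(apply_transform(pred, tf)))
  predict(model, posed, m = m)
}

#' Nearest labeled neighbors of a point in an embedding
#'
#' Ranks the labeled embedding points by Euclidean distance to `query`;
#' ties are broken by lexicographic `trace_id` order.
#'
#' @param embedding n x d coordinate matrix with row names, or a
#'   data.frame whose first column is `trace_id` followed by coordinate
#'   columns.
#' @param labels data.frame with a `trace_id` column (e.g.
#'   [label_traces()] output) aligned to the embedding rows.
#' @param query length-d numeric vector.
#' @param j number of neighbors to return.
#' @return data.frame of the `j` nearest rows of `labels` with an added
#'   `distance` column, nearest first.
#' @export
nearest_labels <- function(embedding, labels, query, j = 3L) {
  if (is.data.frame(embedding)) {
    ids <- embedding[[1]]
    coords <- as.matrix(embedding[, -1, drop = FALSE])
  } else {
    coords <- as.matrix(embedding)
    ids <- rownames(coords)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(coords)))
  }
  if (nrow(coords) == 0L) stop("embedding is empty")
  if (j > nrow(coords)) stop("j exceeds the number of embedded points")
  dist <- sqrt(colSums((t(coords) - query)^2))
  ord <- order(dist, ids)[seq_len(j)]
  idx <- match(ids[ord], labels$trace_id)
  out <- labels[idx, , drop = FALSE]
  out$distance <- dist[ord]
  rownames(out) <- NULL
  out
}
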
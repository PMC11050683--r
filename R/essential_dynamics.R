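# Essential dynamics: PCA of an aligned conformational ensemble via SVD of
# the centered coordinate matrix. The fitted object carries the average
# trace, orthonormal principal axes (rows), the singular value spectrum and
# the training projections, and supports out-of-sample projection and
# reconstruction.

#' Fit an essential-dynamics (PCA) model to an aligned ensemble
#'
#' Centers the n x 3R coordinate matrix on its column mean (the average
#' trace) and takes its singular value decomposition. The principal
#' components are the right singular vectors; component `i` captures a
#' fraction of the total structural variance equal to its squared singular
#' value over the sum of all squared singular values. At most
#' `min(n - 1, 3R)` components are retained (the centered matrix has rank at
#' most `n - 1`).
#'
#' A deterministic sign convention is applied: each component is flipped so
#' that its largest-magnitude loading is positive (ties broken by the lowest
#' coordinate index), with the training scores flipped accordingly, so
#' repeated fits and cross-implementation comparisons are reproducible.
#'
#' @param x a `trace_ensemble` (already aligned onto a common reference; see
#'   [align_ensemble()]) or a plain n x 3R numeric matrix.
#'
#' @return An object of class `ed_model`: list with `average_trace` (3R),
#'   `components` (m x 3R orthonormal rows), `singular_values` (descending),
#'   `variance_fractions` (summing to 1), `scores` (n x m training
#'   projections), `n_traces`, `trace_ids`, `common_residues` and `resno`
#'   (the latter three `NULL` for plain matrices).
#' @export
essential_dynamics <- function(x) {
  mat <- if (inherits(x, "trace_ensemble")) x$matrix else as.matrix(x)
  if (nrow(mat) < 2L) stop("need at least two traces to fit")
  avg <- colMeans(mat)
  centered <- sweep(mat, 2L, avg)
  s <- svd(centered)
  m <- min(nrow(mat) - 1L, ncol(mat))
  sv <- s$d[seq_len(m)]
  total <- sum(s$d^2)
  if (total < 1e-20) {
    warning("all traces are identical; spectrum is zero")
    fractions <- rep(0, m)
  } else {
    fractions <- sv^2 / total
  }
  comps <- t(s$v[, seq_len(m), drop = FALSE])
  scores <- s$u[, seq_len(m), drop = FALSE] %*% diag(sv, nrow = m)
  # sign convention: largest-|loading| entry of each component positive
  for (i in seq_len(m)) {
    peak <- which.max(abs(comps[i, ]))
    if (comps[i, peak] < 0) {
      comps[i, ] <- -comps[i, ]
      scores[, i] <- -scores[, i]
    }
  }
  ids <- if (inherits(x, "trace_ensemble")) x$trace_ids else rownames(mat)
  rownames(scores) <- ids
  colnames(scores) <- paste0("PC", seq_len(m))
  structure(list(average_trace = avg,
                 components = comps,
                 singular_values = sv,
                 variance_fractions = fractions,
                 scores = scores,
                 n_traces = nrow(mat),
                 trace_ids = ids,
                 common_residues = if (inherits(x, "trace_ensemble"))
                   x$common_residues else NULL,
                 resno = if (inherits(x, "trace_ensemble")) x$resno else NULL),
            class = "ed_model")
}

#' @export
print.ed_model <- function(x, ...) {
  cat(sprintf("<ed_model> %d traces, %d coordinates, %d components\n",
              x$n_traces, length(x$average_trace),
              length(x$singular_values)))
  k <- min(6L, length(x$variance_fractions))
  cat("variance captured:",
      paste0("PC", seq_len(k), " ",
             sprintf("%.2f%%", 100 * x$variance_fractions[seq_len(k)]),
             collapse = ", "), "\n")
  cat(sprintf("cumulative over top %d: %.2f%%\n", k,
              cumulative_variance(x, k)))
  invisible(x)
}

#' @export
summary.ed_model <- function(object, ...) {
  vf <- object$variance_fractions
  out <- data.frame(pc = seq_along(vf),
                    singular_value = object$singular_values,
                    variance_pct = 100 * vf,
                    cumulative_pct = 100 * cumsum(vf))
  class(out) <- c("summary.ed_model", "data.frame")
  out
}

#' @export
print.summary.ed_model <- function(x, ...) {
  cat("Essential-dynamics variance spectrum\n")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more components)\n", sep = "")
  invisible(x)
}

#' Cumulative variance captured by the top components
#'
#' @param model an `ed_model`.
#' @param m number of leading components to include.
#' @return Percentage in `[0, 100]`.
#' @export
cumulative_variance <- function(model, m) {
  if (m < 1L || m > length(model$variance_fractions))
    stop("m must be in 1..", length(model$variance_fractions))
  100 * sum(model$variance_fractions[seq_len(m)])
}

#' Project traces into the fitted component space
#'
#' Computes `(trace - average_trace) %*% t(components)` for each supplied
#' trace: the standard linear projection, applicable out-of-sample to
#' structures that were not part of the fit (e.g. computationally modeled
#' variants, once superposed onto the fitting reference).
#'
#' @param object an `ed_model`.
#' @param newdata length-3R vector, n x 3R matrix, `trace_ensemble`, or
#'   [ca_trace] covering the model's common residues. Defaults to the
#'   training scores.
#' @param m number of leading components to return (default: all).
#' @param ... unused.
#' @return An n x m score matrix (a 1-row matrix for a single trace).
#' @export
predict.ed_model <- function(object, newdata = NULL, m = NULL, ...) {
  if (is.null(m)) m <- length(object$singular_values)
  if (m < 1L || m > length(object$singular_values))
    stop("m must be in 1..", length(object$singular_values))
  if (is.null(newdata))
    return(object$scores[, seq_len(m), drop = FALSE])
  mat <- project_input_matrix(object, newdata)
  sc <- sweep(mat, 2L, object$average_trace) %*%
    t(object$components[seq_len(m), , drop = FALSE])
  colnames(sc) <- paste0("PC", seq_len(m))
  sc
}

project_input_matrix <- function(model, newdata) {
  p <- length(model$average_trace)
  if (inherits(newdata, "ca_trace")) {
    if (is.null(model$common_residues))
      stop("model carries no residue identifiers; supply a coordinate vector")
    newdata <- flatten_trace(newdata, model$common_residues)
  }
  if (inherits(newdata, "trace_ensemble")) newdata <- newdata$matrix
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != p)
    stop("trace length ", ncol(newdata), " does not match model (", p, ")")
  newdata
}

#' Reconstruct a Cartesian trace from component-space coordinates
#'
#' Inverts the projection: `p %*% components + average_trace`, with `p`
#' zero-padded to the model size when fewer coordinates are given. With all
#' components, project-then-reconstruct is the identity on the fitted rows.
#'
#' @param model an `ed_model`.
#' @param p numeric vector of leading component coordinates (length <= m),
#'   or a matrix with one such vector per row.
#' @return A length-3R vector (or n x 3R matrix) of coordinates.
#' @export
reconstruct <- function(model, p) {
  single <- is.null(dim(p))
  if (single) p <- matrix(p, nrow = 1L)
  m <- length(model$singular_values)
  if (ncol(p) > m)
    stop("projection has ", ncol(p), " coordinates but model has only ",
         m, " components")
  out <- p %*% model$components[seq_len(ncol(p)), , drop = FALSE]
  out <- sweep(out, 2L, -model$average_trace)
  colnames(out) <- names(model$average_trace)
  if (single) out[1, ] else out
}

#' Reconstruction-error curves
#'
#' For each trace and each `m` in `1..max_m`, the RMSD (in the aligned
#' frame, no re-superposition) between the original trace and its
#' reconstruction from the first `m` projection coordinates. Curves are
#' non-increasing in `m` and reach 0 at full rank.
#'
#' @param model an `ed_model`.
#' @param aligned the aligned `trace_ensemble` (or matrix) the model was
#'   fitted on.
#' @param max_m largest number of components to include (default 6).
#' @return A data.frame with columns `trace_id`, `m`, `rmsd`.
#' @export
reconstruction_error <- function(model, aligned, max_m = 6L) {
  mat <- project_input_matrix(model, aligned)
  max_m <- min(max_m, length(model$singular_values))
  sc <- predict(model, mat)
  ids <- if (inherits(aligned, "trace_ensemble")) aligned$trace_ids
         else rownames(mat)
  if (is.null(ids)) ids <- paste0("trace", seq_len(nrow(mat)))
  out <- expand.grid(trace_id = ids, m = seq_len(max_m),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$rmsd <- NA_real_
  for (m in seq_len(max_m)) {
    rec <- reconstruct(model, sc[, seq_len(m), drop = FALSE])
    err <- sqrt(rowSums((mat - rec)^2) / (ncol(mat) / 3))
    out$rmsd[out$m == m] <- err
  }
  out[order(match(out$trace_id, ids), out$m), , drop = FALSE]
}

#' Per-residue displacement profile of a principal component
#'
#' The magnitude of motion each residue contributes to a component: the
#' Euclidean norm of the residue's (x, y, z) loading triplet within the
#' unit-norm component row. Optionally scaled by the singular value to
#' express displacement amplitude over the ensemble rather than mode shape.
#'
#' @param model an `ed_model`.
#' @param pc 1-based component index.
#' @param scale if `TRUE`, multiply by the component's singular value.
#' @return A `displacement_profile`: data.frame with columns `residue`
#'   (identifier or index), `resno`, `magnitude` and, when residue numbers
#'   are available, `region` (functional region symbol, see
#'   [assign_region()]); attribute `pc` records the component.
#' @export
displacement_profile <- function(model, pc, scale = FALSE) {
  if (pc < 1L || pc > length(model$singular_values))
    stop("pc must be in 1..", length(model$singular_values))
  comp <- model$components[pc, ]
  mags <- sqrt(colSums(matrix(comp^2, nrow = 3L)))
  if (scale) mags <- mags * model$singular_values[pc]
  resno <- model$resno
  if (is.null(resno)) resno <- seq_along(mags)
  residues <- model$common_residues
  if (is.null(residues)) residues <- as.character(resno)
  out <- data.frame(residue = residues, resno = resno, magnitude = mags,
                    region = assign_region(resno), stringsAsFactors = FALSE)
  structure(out, pc = pc, scaled = scale,
            class = c("displacement_profile", "data.frame"))
}

#' @export
plot.displacement_profile <- function(x, ...) {
  graphics::plot(x$resno, x$magnitude, type = "h",
                 xlab = "residue", ylab = "displacement magnitude",
                 main = paste0("PC", attr(x, "pc"), " displacement profile"),
                 ...)
  invisible(x)
}

#' @export
plot.ed_model <- function(x, type = c("scores", "variance"), m = 2L, ...) {
  type <- match.arg(type)
  if (type == "variance") {
    vf <- 100 * cumsum(x$variance_fractions)
    k <- min(10L, length(vf))
    graphics::plot(seq_len(k), vf[seq_len(k)], type = "b",
                   xlab = "number of components",
                   ylab = "cumulative variance (%)", ylim = c(0, 100), ...)
    graphics::abline(h = 90, lty = 3)
  } else {
    sc <- x$scores
    graphics::plot(sc[, 1], sc[, min(m, ncol(sc))],
                   xlab = "PC1", ylab = paste0("PC", min(m, ncol(sc))), ...)
    if (!is.null(rownames(sc)))
      graphics::text(sc[, 1], sc[, min(m, ncol(sc))], rownames(sc),
                     pos = 3, cex = 0.6)
  }
  invisible(x)
}

#' Variance table of a fitted model
#'
#' @param model an `ed_model`.
#' @return data.frame with `pc`, `variance_pct`, `cumulative_pct`.
#' @export
variance_table <- function(model) {
  vf <- model$variance_fractions
  data.frame(pc = seq_along(vf), variance_pct = 100 * vf,
             cumulative_pct = 100 * cumsum(vf))
}
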
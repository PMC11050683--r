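# Synthetic CA-trace ensembles with known ground truth: a smooth base
# trace, a few orthonormal motion modes with set amplitudes (optionally
# localized to residue windows), isotropic Gaussian coordinate noise and
# arbitrary rigid-body poses. Every downstream stage (superposition, PCA,
# Isomap, variant placement) is validated against these ensembles. All
# randomness runs through R's Mersenne-Twister with the caller's RNG state
# restored afterwards, so a given seed reproduces bit-exactly.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a smooth helix-like base CA trace
#'
#' A parametric helical curve with consecutive-CA spacing 3.8 +/- 0.1
#' Angstrom (the canonical C-alpha virtual bond length), perturbed by a
#' small seed-dependent low-frequency wobble so distinct seeds give
#' distinct, still-smooth curves.
#'
#' @param R residue count (>= 4).
#' @param seed integer seed; the curve is a deterministic function of it.
#' @return R x 3 coordinate matrix.
#' @export
make_base_trace <- function(R, seed = 1L) {
  if (R < 4L) stop("R must be >= 4")
  with_seed(seed, {
    omega <- 100 * pi / 180          # 100 degrees per residue
    radius <- 2.3
    chord2 <- 4 * radius^2 * sin(omega / 2)^2
    rise <- sqrt(3.8^2 - chord2)     # exact 3.8 A spacing for the clean helix
    i <- seq_len(R) - 1L
    base <- cbind(radius * cos(omega * i), radius * sin(omega * i), rise * i)
    # low-frequency wobble, small enough to keep spacing within +/- 0.1 A
    phase <- stats::runif(3, 0, 2 * pi)
    freq <- stats::runif(3, 0.02, 0.05)
    amp <- 0.35
    base + amp * cbind(sin(freq[1] * i + phase[1]),
                       sin(freq[2] * i + phase[2]),
                       sin(freq[3] * i + phase[3]))
  })
}

#' Random orthonormal motion modes
#'
#' `K` mutually orthonormal 3R-vectors drawn from the Haar-uniform
#' distribution (QR of a Gaussian matrix).
#'
#' @param R residue count.
#' @param K mode count.
#' @param seed integer seed.
#' @return K x 3R matrix with orthonormal rows.
#' @export
random_modes <- function(R, K, seed = 1L) {
  with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(3 * R * K), nrow = 3 * R)))
    t(q[, seq_len(K), drop = FALSE])
  })
}

#' Motion mode localized to a residue window
#'
#' A unit-norm 3R-vector whose support lies entirely in the coordinates of
#' residues `window[1]..window[2]`; modes built on disjoint windows are
#' orthogonal by construction.
#'
#' @param R residue count.
#' @param window inclusive residue index interval `c(lo, hi)` within 1..R.
#' @param seed integer seed.
#' @return Length-3R unit vector.
#' @export
localized_mode <- function(R, window, seed = 1L) {
  lo <- window[1]; hi <- window[2]
  if (lo > hi || lo < 1L || hi > R) stop("window must be within 1..R")
  with_seed(seed, {
    v <- numeric(3 * R)
    idx <- as.vector(vapply(lo:hi, function(r) (3 * (r - 1) + 1):(3 * r),
                            numeric(3)))
    v[idx] <- stats::rnorm(length(idx))
    v / sqrt(sum(v^2))
  })
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Specify a synthetic conformational ensemble
#'
#' @param n_traces number of traces (>= 2).
#' @param n_residues residues per trace (>= 4).
#' @param modes K x 3R matrix of mutually orthonormal motion modes; default
#'   [random_modes()] for `length(amplitudes)` modes.
#' @param amplitudes per-mode coefficient standard deviations (Angstrom),
#'   descending.
#' @param noise_sigma per-coordinate Gaussian noise standard deviation.
#' @param pose_jitter apply a random rigid motion to each trace.
#' @param seed integer seed controlling every random draw.
#' @return An `ensemble_spec` list, validated.
#' @export
ensemble_spec <- function(n_traces = 52L, n_residues = 263L,
                          modes = NULL, amplitudes = c(3, 1.2, 0.8),
                          noise_sigma = 0.1, pose_jitter = TRUE,
                          seed = 1L) {
  if (n_traces < 2L) stop("n_traces must be >= 2")
  if (is.null(modes) && length(amplitudes) > 0L)
    modes <- random_modes(n_residues, length(amplitudes), seed = seed + 1000L)
  if (length(amplitudes)) {
    if (is.unsorted(rev(amplitudes))) stop("amplitudes must be descending")
    if (nrow(modes) != length(amplitudes) ||
        ncol(modes) != 3L * n_residues)
      stop("modes must be K x 3R with K = length(amplitudes)")
    gram <- modes %*% t(modes)
    if (max(abs(gram - diag(nrow(modes)))) > 1e-8)
      stop("modes are not mutually orthonormal")
  }
  structure(list(n_traces = as.integer(n_traces),
                 n_residues = as.integer(n_residues),
                 modes = modes, amplitudes = amplitudes,
                 noise_sigma = noise_sigma, pose_jitter = pose_jitter,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a synthetic trace ensemble with ground truth
#'
#' Each trace is `base + sum_k c_ik * mode_k + noise`, with coefficients
#' `c_ik ~ N(0, amplitude_k^2)`, then (optionally) put into a random
#' rigid-body pose. The returned ground truth records the base trace, the
#' drawn coefficients and the applied poses, so recovery of the planted
#' spectrum and modes can be checked exactly.
#'
#' @param spec an [ensemble_spec()].
#' @return List with `ensemble` (a `trace_ensemble`, trace ids
#'   `"SYN:1"`, ...) and `truth` (list: `base_trace`, `coefficients`
#'   n x K, `modes`, `poses`).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  R <- spec$n_residues; n <- spec$n_traces
  K <- length(spec$amplitudes)
  base <- as.vector(t(make_base_trace(R, seed = spec$seed)))
  with_seed(spec$seed, {
    coeff <- matrix(stats::rnorm(n * max(K, 1L)), nrow = n)
    if (K > 0L) coeff <- sweep(coeff[, seq_len(K), drop = FALSE], 2L,
                               spec$amplitudes, `*`)
    else coeff <- matrix(numeric(0), nrow = n, ncol = 0L)
    mat <- matrix(rep(base, each = n), nrow = n)
    if (K > 0L) mat <- mat + coeff %*% spec$modes
    if (spec$noise_sigma > 0)
      mat <- mat + matrix(stats::rnorm(n * 3 * R, sd = spec$noise_sigma),
                          nrow = n)
    poses <- vector("list", n)
    if (spec$pose_jitter) {
      for (i in seq_len(n)) {
        rot <- random_rotation()
        trans <- stats::runif(3, -20, 20)
        poses[[i]] <- structure(list(rotation = rot, translation = trans),
                                class = "rigid_transform")
        mat[i, ] <- as.vector(t(apply_transform(
          matrix(mat[i, ], ncol = 3L, byrow = TRUE), poses[[i]])))
      }
    }
    ids <- paste0("SYN:", seq_len(n))
    rownames(mat) <- ids
    colnames(mat) <- paste0("r", rep(seq_len(R), each = 3L), "_",
                            c("x", "y", "z"))
    ensemble <- structure(list(matrix = mat, trace_ids = ids,
                               common_residues = as.character(seq_len(R)),
                               resno = seq_len(R)),
                          class = "trace_ensemble")
    list(ensemble = ensemble,
         truth = list(base_trace = base, coefficients = coeff,
                      modes = spec$modes, poses = poses))
  })
}

#' Write a CA trace as a PDB file
#'
#' One ATOM record per residue (CA only), fixed-width PDB format, so the
#' file is parseable by [read_ca_traces()] and round-trips coordinates to
#' the format's 3-decimal precision.
#'
#' @param trace a [ca_trace].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_pdb <- function(trace, path) {
  n <- length(trace$resno)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(trace$coords)),
                   resno = trace$resno,
                   insert = trace$insert,
                   chain = rep(trace$chain_id, n),
                   resid = rep("ALA", n), elety = rep("CA", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
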
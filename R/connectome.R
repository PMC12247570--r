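#' Generate a synthetic structural connectome
#'
#' Region-to-region connection weights follow an exponential distance rule
#' with multiplicative lognormal noise: `w_ij = exp(-d_ij / decay_length) *
#' LogNormal(0, sigma)`, symmetrized, with the diagonal zeroed and the matrix
#' scaled so the maximum entry is 1.  Distances are Euclidean between cortical
#' region barycenters and subcortical node positions.
#'
#' @param parcellation A `parcellation` (including subcortical nodes).
#' @param decay_length Exponential decay length in mm (> 0).
#' @param seed Integer seed.
#' @param sigma Lognormal sd of the multiplicative noise.
#' @return An object of class `connectome`: list with `weights` (n x n,
#'   nonnegative, symmetric, zero diagonal, max 1) and `positions` (n x 3).
#' @export
generate_connectome <- function(parcellation, decay_length = 60, seed = 1L,
                                sigma = 0.5) {
  if (decay_length <= 0) stop("decay_length must be positive")
  pos <- rbind(parcellation$barycenters,
               if (!is.null(parcellation$subcortical))
                 as.matrix(parcellation$subcortical[, c("x", "y", "z")]))
  n <- nrow(pos)
  if (n < 2) stop("need at least 2 regions")
  d <- as.matrix(dist(pos))
  set.seed(seed)
  noise <- matrix(rlnorm(n * n, 0, sigma), n, n)
  w <- exp(-d / decay_length) * noise
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w <- w / max(w)
  dimnames(w) <- NULL
  structure(list(weights = w, positions = pos), class = "connectome")
}

#' Write / read a connectome weight matrix as CSV
#' @param connectome A `connectome`.
#' @param path CSV path.
#' @return `write_connectome_csv` returns `path` invisibly;
#'   `read_connectome_csv` returns a `connectome` (positions absent).
#' @export
write_connectome_csv <- function(connectome, path) {
  write.csv(connectome$weights, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path) {
  w <- as.matrix(read.csv(path))
  dimnames(w) <- NULL
  structure(list(weights = w, positions = NULL), class = "connectome")
}
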
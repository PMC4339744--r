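#' Validate a relationship matrix
#'
#' Checks symmetry and positive definiteness of a relationship matrix
#' `Phi`.  Exact duplicates of an individual (e.g. both members of a
#' monozygotic twin pair genotyped) make `Phi` singular; such matrices are
#' rejected unless a ridge is requested, in which case `ridge * I` is
#' added to the diagonal.
#'
#' @param phi symmetric `N x N` matrix.
#' @param ridge non-negative diagonal inflation applied when `phi` is not
#'   numerically positive definite (smallest eigenvalue below `tol`);
#'   `NULL` (default) means reject instead.
#' @param tol eigenvalue threshold declaring singularity.
#' @return `phi` (possibly ridged), invisibly checked.
#' @export
validate_relmatrix <- function(phi, ridge = NULL, tol = 1e-8) {
  if (!is.matrix(phi) || nrow(phi) != ncol(phi))
    stop("relationship matrix must be square")
  if (max(abs(phi - t(phi))) > 1e-8)
    stop("relationship matrix must be symmetric")
  ev_min <- min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < tol) {
    if (is.null(ridge))
      stop(sprintf(paste0("relationship matrix is numerically singular ",
                          "(min eigenvalue %.3g); supply a ridge (e.g. 1e-6) ",
                          "or remove duplicate individuals"), ev_min))
    phi <- phi + diag(ridge, nrow(phi))
  }
  phi
}

#' Genomic relationship matrix from dense null markers
#'
#' Standardized-genotype cross-product (GCTA/EMMAX form): entry
#' `(a, b) = mean_m (x_am - 2 p_m)(x_bm - 2 p_m) / (2 p_m (1 - p_m))`
#' over polymorphic markers `m`.  The diagonal uses the same standardized
#' cross-product (no inbreeding correction term).  Monomorphic markers are
#' excluded with a warning; missing genotypes are mean-imputed before
#' standardization.
#'
#' @param X `N x M` matrix of minor-allele counts in `{0, 1, 2}` (`NA`
#'   allowed).
#' @param freqs optional per-marker allele frequencies in (0, 1); when
#'   `NULL`, estimated as half the observed column mean.
#' @return Symmetric `N x N` matrix with attributes `source = "genomic"`
#'   and `n_markers` (markers retained).
#' @export
grm_from_genotypes <- function(X, freqs = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("at least one marker is required")
  if (is.null(freqs)) freqs <- colMeans(X, na.rm = TRUE) / 2
  if (length(freqs) != ncol(X))
    stop("freqs must have one entry per marker")
  poly <- is.finite(freqs) & freqs > 0 & freqs < 1
  if (!all(poly)) {
    warning(sum(!poly), " monomorphic marker(s) excluded from GRM")
    X <- X[, poly, drop = FALSE]
    freqs <- freqs[poly]
  }
  if (ncol(X) == 0L) stop("all markers monomorphic; cannot compute GRM")
  ctr <- sweep(X, 2L, 2 * freqs, `-`)
  ctr[is.na(ctr)] <- 0          # mean imputation after centering
  sdv <- sqrt(2 * freqs * (1 - freqs))
  std <- sweep(ctr, 2L, sdv, `/`)
  G <- tcrossprod(std) / ncol(X)
  dimnames(G) <- list(rownames(X), rownames(X))
  structure(G, source = "genomic", n_markers = ncol(X))
}

#' Read and write relationship matrices
#'
#' GCTA-style plain-text GRM: one line per lower-triangle entry with
#' columns `i j n_markers value` (1-based indices, `j <= i`).  `read_grm`
#' accepts an optional id file (two columns `FID IID`) to label rows.
#'
#' @param phi relationship matrix.
#' @param path output file.
#' @param n_markers marker count recorded per entry (taken from the
#'   `n_markers` attribute when present).
#' @export
write_grm <- function(phi, path, n_markers = NULL) {
  if (is.null(n_markers))
    n_markers <- attr(phi, "n_markers") %||% 0L
  n <- nrow(phi)
  idx <- which(lower.tri(phi, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  df <- data.frame(i = idx[, 1L], j = idx[, 2L], n = n_markers,
                   value = phi[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @param ids optional character vector of row labels.
#' @export
read_grm <- function(path, ids = NULL) {
  df <- utils::read.table(path, col.names = c("i", "j", "n", "value"))
  n <- max(df$i)
  phi <- matrix(0, n, n)
  phi[cbind(df$i, df$j)] <- df$value
  phi[cbind(df$j, df$i)] <- df$value
  if (!is.null(ids)) dimnames(phi) <- list(ids, ids)
  structure(phi, source = "genomic", n_markers = df$n[1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
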
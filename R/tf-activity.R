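#' Infer transcription-factor activity along pseudotime by lasso regression
#'
#' At each pseudotime grid point t, the vector of fitted gene profiles
#' y(t) is regressed on the binary gene x TF target matrix M by solving
#' \code{min_a ||y(t) - M a||^2 + alpha * ||a||_1} with cyclic coordinate
#' descent (soft-thresholding updates). With \code{alpha = 0} the exact
#' least-squares solution is returned.
#'
#' @param profiles a \code{\link{fit_gene_profiles}} result (single path)
#'   or a gene x grid matrix of profile values.
#' @param target_matrix gene x TF binary matrix; rows must align with the
#'   profile genes.
#' @param alpha nonnegative L1 penalty weight.
#' @return list of class \code{tf_activity}: \code{activity} (TF x grid
#'   matrix), \code{alpha}, \code{grid}.
#' @export
infer_tf_activity <- function(profiles, target_matrix, alpha = 1) {
  if (inherits(profiles, "fitted_profiles")) {
    pr <- Filter(Negate(is.null), profiles$paths)[[1]]
    y <- pr$values
    grid <- pr$grid
  } else {
    y <- as.matrix(profiles)
    grid <- seq_len(ncol(y))
  }
  m <- as.matrix(target_matrix)
  if (nrow(m) != nrow(y))
    stop("infer_tf_activity: target_matrix rows must align with profile genes")
  if (ncol(m) < 1) stop("infer_tf_activity: need >= 1 TF")
  if (all(m == 0)) stop("infer_tf_activity: all-zero target matrix")
  stopifnot(alpha >= 0)
  n <- nrow(m)
  act <- matrix(0, ncol(m), ncol(y),
                dimnames = list(colnames(m), NULL))
  if (alpha == 0) {
    act[] <- qr.coef(qr(m), y)
    act[is.na(act)] <- 0
  } else {
    for (j in seq_len(ncol(y))) act[, j] <- .lasso_cd(m, y[, j], alpha)
  }
  structure(list(activity = act, alpha = alpha, grid = grid),
            class = "tf_activity")
}

# cyclic coordinate descent for min_a ||y - M a||^2 + alpha ||a||_1
.lasso_cd <- function(m, y, alpha, tol = 1e-10, max_iter = 10000) {
  p <- ncol(m)
  a <- numeric(p)
  mtm <- colSums(m^2)
  r <- y  # residual y - M a
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (j in seq_len(p)) {
      if (mtm[j] == 0) next
      rho <- sum(m[, j] * r) + mtm[j] * a[j]
      new_a <- sign(rho) * max(0, abs(rho) - alpha / 2) / mtm[j]
      if (new_a != a[j]) {
        r <- r - m[, j] * (new_a - a[j])
        delta <- max(delta, abs(new_a - a[j]))
        a[j] <- new_a
      }
    }
    if (delta < tol) break
  }
  a
}

#' Synthetic TF target matrix for testing
#'
#' Builds a binary gene x TF matrix in which each TF targets a given gene
#' set; useful for constructing identifiable activity-inference fixtures.
#'
#' @param gene_ids all gene ids (rows).
#' @param targets named list: TF name -> character vector of target genes.
#' @return binary matrix with one column per TF.
#' @export
make_target_matrix <- function(gene_ids, targets) {
  m <- matrix(0, length(gene_ids), length(targets),
              dimnames = list(gene_ids, names(targets)))
  for (tf in names(targets)) m[intersect(targets[[tf]], gene_ids), tf] <- 1
  m
}
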
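#' Expression-reduction matrix from targeting profiles
#'
#' Builds the families x guides matrix whose entries are the weighted
#' targeting efficiencies
#' \deqn{coeff_{ij} = \sum_{s=0}^{3} p_s f_{ij}^{s},}
#' where \eqn{f_{ij}^{s}} is the fraction of family \eqn{i}'s considered
#' members at exactly \eqn{s} mismatches from guide \eqn{j} and \eqn{p_s} is
#' the mismatch penalty vector. Pairs absent from the profile table get
#' coefficient 0. In a one-guide-per-family library the matrix is square with
#' ON-target entries on the diagonal.
#'
#' @param profiles data.frame of \code{\link{build_targeting_profile}} rows
#'   (columns \code{guide_id, family_id, f0..f3}).
#' @param penalties Penalty vector of length 4 with values in [0, 1]
#'   (default \code{\link{default_penalties}}).
#' @param families Row order; defaults to sorted unique profile families.
#' @param guides Column order; defaults to sorted unique profile guides.
#' @return Numeric matrix of class \code{"reduction_matrix"} (families x
#'   guides, entries in [0, 1]).
#' @export
build_reduction_matrix <- function(profiles, penalties = default_penalties(),
                                   families = NULL, guides = NULL) {
  if (length(penalties) != 4L || anyNA(penalties) ||
      any(penalties < 0) || any(penalties > 1)) {
    stop("penalties must be 4 values in [0, 1] (one per mismatch level 0-3)")
  }
  need <- c("guide_id", "family_id", "f0", "f1", "f2", "f3")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns: ", paste(need, collapse = ", "))
  }
  families <- families %||% sort(unique(profiles$family_id))
  guides <- guides %||% sort(unique(profiles$guide_id))
  M <- matrix(0, nrow = length(families), ncol = length(guides),
              dimnames = list(families, guides))
  keep <- profiles$family_id %in% families & profiles$guide_id %in% guides
  pr <- profiles[keep, , drop = FALSE]
  coeff <- as.matrix(pr[, c("f0", "f1", "f2", "f3")]) %*% as.numeric(penalties)
  M[cbind(pr$family_id, pr$guide_id)] <- coeff
  structure(M, class = c("reduction_matrix", "matrix", "array"))
}

#' @export
print.reduction_matrix <- function(x, ...) {
  cat(sprintf("<reduction_matrix> %d families x %d guides; diag mean %.3f, off-diag mass %.3f\n",
              nrow(x), ncol(x),
              if (nrow(x) == ncol(x)) mean(diag(unclass(x))) else NA_real_,
              sum(unclass(x)) - if (nrow(x) == ncol(x)) sum(diag(unclass(x))) else 0))
  print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
  if (nrow(x) > 5 || ncol(x) > 5) cat("...\n")
  invisible(x)
}

#' Deconvolve observed fitness into per-family contributions
#'
#' Solves the linear system relating the observed fitness of each
#' guide-carrying variant to the underlying per-family fitness contributions
#' under the additive (non-epistatic) model. With the default
#' \code{"guide-major"} orientation the equation for variant \eqn{j} is
#' \deqn{O_j = \sum_i coeff_{ij} R_i,} i.e. the system matrix is the
#' transpose of the reduction matrix; \code{"family-major"} uses the matrix
#' as stored.
#'
#' A direct solve is used while the condition number stays below
#' \code{cond_threshold}; otherwise a minimum-norm least-squares solution via
#' the SVD is returned with a warning.
#'
#' @param observed Named numeric or \code{fitness_vector} of observed log2
#'   relative fitness, aligned to the guide (column) order of \code{M}.
#' @param M \code{\link{build_reduction_matrix}} output (families x guides).
#' @param orientation \code{"guide-major"} (default) or \code{"family-major"}.
#' @param cond_threshold Condition-number cutoff for the direct solve
#'   (default \code{1e6}).
#' @return Object of class \code{"deconvolution_result"}: list with
#'   \code{R} (a \code{fitness_vector} with role \code{"estimated_R"}, named
#'   by family), \code{residuals}, \code{condition_number}, \code{solver},
#'   \code{orientation}.
#' @export
deconvolve <- function(observed, M, orientation = c("guide-major", "family-major"),
                       cond_threshold = 1e6) {
  orientation <- match.arg(orientation)
  A <- if (orientation == "guide-major") t(unclass(M)) else unclass(M)
  o <- as.numeric(unclass(observed))
  if (length(o) != nrow(A)) {
    stop("observed fitness has length ", length(o), " but the system has ",
         nrow(A), " equations")
  }
  eq_names <- rownames(A)
  if (!is.null(names(observed)) && !is.null(eq_names) &&
      !identical(names(observed), eq_names)) {
    if (!setequal(names(observed), eq_names)) {
      stop("observed fitness names do not match the guide set of M")
    }
    o <- o[match(eq_names, names(observed))]
  }
  sv <- svd(A)
  pos <- sv$d > max(sv$d) * .Machine$double.eps * max(dim(A))
  cond <- if (all(pos)) max(sv$d) / min(sv$d) else Inf
  if (is.finite(cond) && cond < cond_threshold) {
    solver <- "direct"
    R <- solve(A, o)
  } else {
    solver <- "least-squares"
    warning("system is singular or ill-conditioned (condition number ",
            format(cond, digits = 3), "); returning the minimum-norm least-squares solution")
    d_inv <- ifelse(pos, 1 / sv$d, 0)
    R <- sv$v %*% (d_inv * crossprod(sv$u, o))
    R <- as.numeric(R)
  }
  names(R) <- colnames(A)
  resid <- as.numeric(A %*% R - o)
  names(resid) <- eq_names
  structure(
    list(R = structure(R, class = "fitness_vector", role = "estimated_R",
                       day = attr(observed, "day"),
                       reference_day = attr(observed, "reference_day"),
                       n_replicates = attr(observed, "n_replicates")),
         residuals = resid,
         residual_norm = sqrt(sum(resid^2)),
         condition_number = cond,
         solver = solver,
         orientation = orientation),
    class = "deconvolution_result")
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat(sprintf("<deconvolution_result> %d families; solver = %s (condition number %s); residual norm %.3g\n",
              length(x$R), x$solver, format(x$condition_number, digits = 3),
              x$residual_norm))
  invisible(x)
}

#' Estimated-versus-observed consistency regression
#'
#' OLS of the deconvolved per-family fitness on the observed per-guide
#' fitness (aligned by the family/guide bijection), with the Pearson
#' correlation — a diagnostic of how much the off-target correction moves
#' the estimates.
#'
#' @param observed Observed fitness vector.
#' @param result A \code{deconvolution_result} (or an estimated fitness
#'   vector).
#' @return List: \code{slope, intercept, r, n}.
#' @export
consistency_report <- function(observed, result) {
  est <- if (inherits(result, "deconvolution_result")) result$R else result
  o <- as.numeric(unclass(observed)); e <- as.numeric(unclass(est))
  if (length(o) < 2L || length(e) < 2L) stop("need at least 2 values per vector")
  if (length(o) != length(e)) stop("observed and estimated lengths differ")
  .ols_xy(o, e, what = "consistency regression")
}
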
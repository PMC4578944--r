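#' Tissue specificity measure (SPM)
#'
#' For an expression profile `x` over `T` tissues, `SPM_t = x_t /
#' sqrt(sum_u x_u^2)` — the cosine of the profile against the unit axis of
#' tissue `t`.  Every `SPM_t` lies in `[0, 1]` and the squared values sum
#' to 1.  A gene is conventionally called tissue-specific when some
#' `SPM_t > 0.5`, i.e. expression in one tissue outweighs the combined
#' expression in all others.
#'
#' @param profile non-negative numeric vector (one gene across tissues) or
#'   a genes-by-tissues matrix.
#' @return Numeric vector (or matrix, matching the input) of SPM values.
#' @export
compute_spm <- function(profile) {
  if (is.matrix(profile)) {
    res <- t(apply(profile, 1, compute_spm))
    dimnames(res) <- dimnames(profile)
    return(res)
  }
  if (any(profile < 0)) stop("expression values must be non-negative")
  nrm <- sqrt(sum(profile^2))
  if (nrm == 0) stop("undefined SPM: all-zero expression profile")
  profile / nrm
}

#' Flag tissue-specific genes by the SPM > threshold rule
#'
#' @param profile_matrix genes-by-tissues expression matrix.
#' @param threshold SPM cutoff (default 0.5).
#' @return Logical vector, one entry per gene.
#' @export
spm_specific <- function(profile_matrix, threshold = 0.5) {
  spm <- compute_spm(profile_matrix)
  apply(spm, 1, function(v) any(v > threshold))
}

#' Merge tissues into integrative tissues
#'
#' Collapses tissue columns into group columns by the per-group mean,
#' preserving scale so SPM can be recomputed on the merged matrix.
#'
#' @param profile_matrix genes-by-tissues matrix with column names.
#' @param grouping named character vector mapping each tissue (name) to its
#'   integrative tissue (value).
#' @return Genes-by-groups matrix.
#' @export
merge_tissues <- function(profile_matrix, grouping) {
  stopifnot(is.matrix(profile_matrix))
  tissues <- colnames(profile_matrix)
  if (is.null(tissues)) stop("profile matrix must have tissue column names")
  missing <- setdiff(tissues, names(grouping))
  if (length(missing))
    stop("no group for tissue(s): ", paste(missing, collapse = ", "))
  groups <- unique(unname(grouping[tissues]))
  out <- sapply(groups, function(g) {
    cols <- tissues[grouping[tissues] == g]
    rowMeans(profile_matrix[, cols, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(rownames(profile_matrix),
                                                       groups))
  colnames(out) <- groups
  out
}
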
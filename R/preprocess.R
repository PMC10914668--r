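# Preprocess: floor the pKi scale and sign-invert agonist sites to obtain
# the adjusted matrix that all downstream similarity analysis consumes.

#' Subtract the pKi floor
#'
#' Shifts every observed pKi down by a fixed floor constant so that the
#' weakest measurable affinity scores 0. The floor defaults to 4
#' (Ki = 100 uM), the bottom of the measurable range in the human binding
#' literature this pipeline targets; synthetic data with other ranges can
#' override it.
#'
#' @param x an `affinity_matrix`.
#' @param floor floor constant on the pKi scale (default 4).
#' @return an `affinity_matrix` with floored values and `floor_constant`
#'   recorded; a warning is emitted if any observed pKi lies below the floor.
#' @export
floor_adjust <- function(x, floor = 4) {
  stopifnot(inherits(x, "affinity_matrix"))
  if (sum(x$observed) == 0L) stop("floor_adjust: matrix has no observed cells")
  v <- x$values
  if (any(v[x$observed] < floor))
    warning("floor_adjust: observed pKi value(s) below the floor constant ",
            floor, "; floored scores will be negative")
  v[x$observed] <- v[x$observed] - floor
  new_affinity_matrix(v, provenance = x$provenance, floor_constant = floor)
}

#' Sign-invert agonist and partial-agonist sites
#'
#' Agonism is functionally opposite to antagonism at the same receptor, so
#' floored affinities at sites annotated agonist or partial agonist are
#' multiplied by -1; without the inversion an agonist and an antagonist with
#' equal affinity would be indistinguishable. Partial and full agonists are
#' treated identically (a single binary flip): graded intrinsic activity is
#' not modeled.
#'
#' @param x a floored `affinity_matrix` (see [floor_adjust()]).
#' @param agonism an `agonism_table`; pairs absent from it are antagonists.
#' @param strict if `TRUE`, an annotation referencing a drug or receptor not
#'   present in the matrix is an error; by default it is a warning and the
#'   entry is ignored.
#' @return an `adjusted_matrix`: list with signed `values`, `observed` mask
#'   (identical to the input mask), `floor_constant`, and the logical
#'   `inverted` cell mask.
#' @export
apply_agonism_inversion <- function(x, agonism = NULL, strict = FALSE) {
  stopifnot(inherits(x, "affinity_matrix"))
  v <- x$values
  flip <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  if (!is.null(agonism) && nrow(agonism) > 0) {
    ag <- agonism[agonism$mode %in% c("agonist", "partial_agonist"), , drop = FALSE]
    unknown <- !(ag$drug %in% rownames(v)) | !(ag$receptor %in% colnames(v))
    if (any(unknown)) {
      msg <- paste0("agonism annotation(s) reference unknown drug/receptor: ",
                    paste(utils::head(paste(ag$drug[unknown], ag$receptor[unknown],
                                            sep = ":"), 5), collapse = ", "))
      if (strict) stop(msg) else warning(msg)
      ag <- ag[!unknown, , drop = FALSE]
    }
    flip[cbind(ag$drug, ag$receptor)] <- TRUE
  }
  v[flip] <- -v[flip]
  structure(list(values = v, drugs = rownames(v), receptors = colnames(v),
                 observed = x$observed, floor_constant = x$floor_constant,
                 inverted = flip),
            class = "adjusted_matrix")
}

#' @export
print.adjusted_matrix <- function(x, ...) {
  cat(sprintf("adjusted affinity matrix: %d drugs x %d receptors, floor %g, %d inverted (agonist) cell(s)\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$floor_constant)) NA_real_ else x$floor_constant,
              sum(x$inverted)))
  invisible(x)
}

#' Floor and sign-invert in one step
#'
#' Convenience wrapper: [floor_adjust()] then [apply_agonism_inversion()].
#'
#' @inheritParams floor_adjust
#' @inheritParams apply_agonism_inversion
#' @return an `adjusted_matrix`.
#' @export
adjust_affinities <- function(x, agonism = NULL, floor = 4, strict = FALSE) {
  apply_agonism_inversion(floor_adjust(x, floor = floor), agonism,
                          strict = strict)
}
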
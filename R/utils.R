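#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov median rnorm runif rbinom sd predict
#' @importFrom utils read.delim write.table
NULL

# lowercase + trim: the only name normalization applied (synonyms must be
# resolved explicitly by the caller via a mapping file, never heuristically)
normalize_name <- function(x) tolower(trimws(as.character(x)))

#' Derive independent per-stage seeds from one master seed
#'
#' Every source of randomness in the package consumes an explicit seed; a
#' pipeline run expands its single master seed into named per-stage seeds so
#' that no stage reads global RNG state left over from another.
#'
#' @param master integer master seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, all in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, stages) {
  stopifnot(is.numeric(master), length(master) == 1L, length(stages) >= 1L)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master) %% .Machine$integer.max)
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

as_values <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, c("affinity_matrix", "adjusted_matrix"))) return(x$values)
  stop("cannot extract a drug x receptor matrix from an object of class ",
       paste(class(x), collapse = "/"))
}

# TSV writers/readers shared by all artifact exports; empty string encodes NA
write_matrix_tsv <- function(values, path, key = "drug") {
  df <- data.frame(rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- key
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_matrix_tsv <- function(path, key = "drug") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
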
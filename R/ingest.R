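# Ingest: parse Ki binding records and companion tables, apply the inclusion
# filters, and assemble the drug x receptor pKi affinity matrix.

#' Parse a table of Ki binding records
#'
#' Reads a delimited text export of receptor-binding measurements (one row
#' per published measurement, as in a PDSP-style Ki database extract) into a
#' validated record table. Rows whose Ki is non-numeric or non-positive are
#' dropped and counted.
#'
#' @param path path to a CSV/TSV file.
#' @param col_map named character vector mapping the canonical fields
#'   `drug`, `receptor`, `species`, `ki_nM` (and optionally `source_id`) to
#'   column names in the file.
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.csv` gives `","`, anything else tab).
#' @return a `data.frame` of class `ki_records` with columns `drug`,
#'   `receptor`, `species`, `ki_nM`, `source_id`; drug/receptor/species are
#'   lowercased and trimmed. The number of dropped rows is available as
#'   `attr(x, "n_dropped")`.
#' @export
parse_ki_table <- function(path, col_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("cannot read Ki table: no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  default_map <- c(drug = "drug", receptor = "receptor", species = "species",
                   ki_nM = "ki_nM", source_id = "source_id")
  if (!is.null(col_map)) default_map[names(col_map)] <- col_map
  needed <- c("drug", "receptor", "species", "ki_nM")
  missing_cols <- setdiff(default_map[needed], names(raw))
  if (length(missing_cols) > 0)
    stop("Ki table schema error: columns not found: ",
         paste(missing_cols, collapse = ", "))
  src <- if (default_map[["source_id"]] %in% names(raw))
    as.character(raw[[default_map[["source_id"]]]]) else NA_character_
  rec <- data.frame(
    drug      = normalize_name(raw[[default_map[["drug"]]]]),
    receptor  = normalize_name(raw[[default_map[["receptor"]]]]),
    species   = normalize_name(raw[[default_map[["species"]]]]),
    ki_nM     = suppressWarnings(as.numeric(raw[[default_map[["ki_nM"]]]])),
    source_id = src,
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(rec$ki_nM) | rec$ki_nM <= 0 | rec$drug == "" | rec$receptor == ""
  if (any(bad)) message("parse_ki_table: dropped ", sum(bad),
                        " record(s) with invalid Ki or empty names")
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL
  structure(rec, n_dropped = sum(bad), class = c("ki_records", "data.frame"))
}

#' Keep only records measured in human tissue
#'
#' Binding constants differ between species orthologs, so the fingerprint is
#' built exclusively from human-tissue assays. Matching is case-insensitive
#' exact equality to `"human"` after trimming; no fuzzy matching.
#'
#' @param records a `ki_records` data frame (or any data frame with a
#'   `species` column).
#' @return the human-tissue subset, same class.
#' @export
filter_human <- function(records) {
  keep <- normalize_name(records$species) == "human"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert Ki to pKi
#'
#' pKi is the negative decadic log of Ki in molar units; with Ki supplied in
#' nM this is `9 - log10(Ki)`. Higher pKi means higher affinity
#' (Ki = 1 nM gives pKi 9; Ki = 100 uM gives pKi 4).
#'
#' @param ki positive numeric vector of inhibition constants.
#' @param unit `"nM"` (default, the PDSP convention) or `"M"`.
#' @return numeric vector of pKi values.
#' @export
ki_to_pki <- function(ki, unit = c("nM", "M")) {
  unit <- match.arg(unit)
  if (any(!is.finite(ki) | ki <= 0))
    stop("ki_to_pki: Ki values must be positive and finite")
  if (unit == "nM") 9 - log10(ki) else -log10(ki)
}

new_affinity_matrix <- function(values, provenance = NULL, floor_constant = NULL) {
  structure(list(values = values,
                 drugs = rownames(values),
                 receptors = colnames(values),
                 observed = !is.na(values),
                 provenance = provenance,
                 floor_constant = floor_constant),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("affinity matrix: %d drugs x %d receptors, %d observed cells (%.1f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$observed),
              100 * mean(x$observed)))
  if (!is.null(x$floor_constant))
    cat(sprintf("  floored at pKi = %g\n", x$floor_constant))
  invisible(x)
}

#' Assemble the drug x receptor pKi affinity matrix
#'
#' Replicate measurements of the same (drug, receptor) pair are collapsed to
#' their median Ki (the median is robust to the outliers common in binding
#' assays), then inclusion filters are applied in a single pass: receptors
#' observed for fewer than `min_drugs_per_receptor` drugs are removed first,
#' then drugs observed at fewer than `min_receptors_per_drug` of the
#' remaining receptors, then receptor columns whose observed Ki values are
#' all identical (such columns carry no discriminating information). Ki is
#' converted to pKi last; since the median commutes with the monotone log
#' transform, aggregating before or after conversion is equivalent.
#'
#' @param records `ki_records` data frame.
#' @param min_drugs_per_receptor minimum observed drugs to retain a receptor.
#' @param min_receptors_per_drug minimum observed receptors to retain a drug.
#' @param cascade if `TRUE`, iterate the two count filters to a fixed point
#'   (removing a drug can push a receptor back below threshold); the single
#'   pass is the default.
#' @param drop_constant remove receptor columns constant across observed
#'   drugs (default `TRUE`).
#' @return an `affinity_matrix`: list with `values` (pKi, `NA` = missing),
#'   `observed` mask, and `provenance` (per-cell record counts).
#' @export
build_affinity_matrix <- function(records,
                                  min_drugs_per_receptor = 5L,
                                  min_receptors_per_drug = 5L,
                                  cascade = FALSE,
                                  drop_constant = TRUE) {
  if (is.null(records) || nrow(records) == 0L)
    stop("build_affinity_matrix: no records supplied")
  drug <- normalize_name(records$drug)
  receptor <- normalize_name(records$receptor)
  ki <- tapply(records$ki_nM, list(drug, receptor), median)
  counts <- table(factor(drug, levels = rownames(ki)),
                  factor(receptor, levels = colnames(ki)))
  obs <- !is.na(ki)

  keep_col <- colSums(obs) >= min_drugs_per_receptor
  obs2 <- obs[, keep_col, drop = FALSE]
  keep_row <- rowSums(obs2) >= min_receptors_per_drug
  if (cascade) {
    repeat {
      o <- obs[keep_row, keep_col, drop = FALSE]
      kc <- colSums(obs[keep_row, , drop = FALSE]) >= min_drugs_per_receptor
      kr <- rowSums(obs[, kc, drop = FALSE]) >= min_receptors_per_drug
      if (identical(kc, keep_col) && identical(kr, keep_row)) break
      keep_col <- kc; keep_row <- kr
    }
  }
  ki <- ki[keep_row, keep_col, drop = FALSE]
  counts <- counts[keep_row, keep_col, drop = FALSE]
  if (nrow(ki) == 0L || ncol(ki) == 0L)
    stop("build_affinity_matrix: all drugs or receptors removed by the ",
         "minimum-data filters")
  if (drop_constant) {
    constant <- apply(ki, 2, function(v) {
      v <- v[!is.na(v)]
      length(v) > 0 && length(unique(v)) == 1L
    })
    ki <- ki[, !constant, drop = FALSE]
    counts <- counts[, !constant, drop = FALSE]
    if (ncol(ki) == 0L)
      stop("build_affinity_matrix: every receptor column was constant")
  }
  values <- ki
  values[!is.na(ki)] <- ki_to_pki(ki[!is.na(ki)])
  new_affinity_matrix(values, provenance = unclass(counts))
}

# canonical 16-effect schema: 13 side effects + 3 efficacy measures
#' The canonical 16-column clinical effect schema
#'
#' Thirteen common antipsychotic adverse effects plus efficacy for total,
#' positive and negative psychotic symptoms, as scored by umbrella reviews of
#' network meta-analyses.
#'
#' @return named character vector mapping effect name to kind
#'   (`"side_effect"` or `"efficacy"`).
#' @export
clinical_effect_schema <- function() {
  c(weight_gain = "side_effect", parkinsonism = "side_effect",
    akathisia = "side_effect", anticholinergic = "side_effect",
    sedation = "side_effect", prolactin = "side_effect",
    qtc_prolongation = "side_effect", postural_hypotension = "side_effect",
    dystonia = "side_effect", tardive_dyskinesia = "side_effect",
    seizure = "side_effect", dyslipidemia = "side_effect",
    dysglycemia = "side_effect",
    efficacy_total = "efficacy", efficacy_positive = "efficacy",
    efficacy_negative = "efficacy")
}

new_clinical_profile <- function(scores, effect_kind) {
  structure(list(drugs = rownames(scores), effects = colnames(scores),
                 scores = scores, observed = !is.na(scores),
                 effect_kind = effect_kind),
            class = "clinical_profile")
}

#' @export
print.clinical_profile <- function(x, ...) {
  cat(sprintf("clinical profile: %d drugs x %d effects (%d side effects, %d efficacy), %.1f%% observed\n",
              nrow(x$scores), ncol(x$scores),
              sum(x$effect_kind == "side_effect"),
              sum(x$effect_kind == "efficacy"), 100 * mean(x$observed)))
  invisible(x)
}

#' Parse a drug x clinical-effect score table
#'
#' @param path TSV with a header row; first column drug names, remaining
#'   columns effect scores (empty cells = missing).
#' @param effect_kind optional named character vector effect -> kind
#'   (`side_effect`/`efficacy`). Defaults to [clinical_effect_schema()] for
#'   recognized columns; unrecognized columns are `side_effect` unless their
#'   name starts with `"efficacy"`.
#' @param strict error on effect columns absent from the canonical schema.
#' @return a `clinical_profile` object.
#' @export
parse_clinical_table <- function(path, effect_kind = NULL, strict = FALSE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = c("", "NA"))
  drugs <- normalize_name(df[[1]])
  if (anyDuplicated(drugs))
    stop("parse_clinical_table: duplicated drug row(s): ",
         paste(unique(drugs[duplicated(drugs)]), collapse = ", "))
  scores <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(scores) <- "double"
  rownames(scores) <- drugs
  schema <- clinical_effect_schema()
  unknown <- setdiff(colnames(scores), names(schema))
  if (strict && length(unknown) > 0)
    stop("parse_clinical_table: effect column(s) not in the canonical ",
         "schema: ", paste(unknown, collapse = ", "))
  if (is.null(effect_kind)) {
    effect_kind <- ifelse(colnames(scores) %in% names(schema),
                          schema[colnames(scores)],
                          ifelse(grepl("^efficacy", colnames(scores)),
                                 "efficacy", "side_effect"))
    names(effect_kind) <- colnames(scores)
  }
  new_clinical_profile(scores, effect_kind[colnames(scores)])
}

#' Construct a grouping scheme (drug -> category map)
#'
#' @param assignment named character vector: names are drugs, values
#'   category labels.
#' @param name scheme label, e.g. `"derived_clusters"`, `"nbn"`.
#' @return a `grouping_scheme` with `n_categories` = number of distinct
#'   labels.
#' @export
grouping_scheme <- function(assignment, name) {
  stopifnot(!is.null(names(assignment)), all(names(assignment) != ""))
  if (anyDuplicated(names(assignment)))
    stop("grouping_scheme: drug(s) listed twice: ",
         paste(unique(names(assignment)[duplicated(names(assignment))]),
               collapse = ", "))
  assignment <- stats::setNames(as.character(assignment),
                                normalize_name(names(assignment)))
  structure(list(name = name, assignment = assignment,
                 n_categories = length(unique(assignment))),
            class = "grouping_scheme")
}

#' @export
print.grouping_scheme <- function(x, ...) {
  cat(sprintf("grouping scheme '%s': %d drugs in %d categories\n",
              x$name, length(x$assignment), x$n_categories))
  invisible(x)
}

#' Parse a two-column drug -> category table
#'
#' @param path TSV with header; first column drug, second category label.
#' @param name scheme label.
#' @return a `grouping_scheme`.
#' @export
parse_grouping <- function(path, name) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("parse_grouping: expected two columns in ", path)
  grouping_scheme(stats::setNames(as.character(df[[2]]),
                                  normalize_name(df[[1]])), name)
}

#' Construct an agonism annotation table
#'
#' Records the functional mode of specific (drug, receptor) pairs; any pair
#' not listed defaults to antagonist.
#'
#' @param drug,receptor,mode equal-length vectors; `mode` must be one of
#'   `antagonist`, `agonist`, `partial_agonist`.
#' @return an `agonism_table` data frame.
#' @export
agonism_table <- function(drug = character(), receptor = character(),
                          mode = character()) {
  mode <- as.character(mode)
  bad <- setdiff(mode, c("antagonist", "agonist", "partial_agonist"))
  if (length(bad) > 0)
    stop("agonism_table: unknown mode(s): ", paste(unique(bad), collapse = ", "))
  structure(data.frame(drug = normalize_name(drug),
                       receptor = normalize_name(receptor),
                       mode = mode, stringsAsFactors = FALSE),
            class = c("agonism_table", "data.frame"))
}

#' Parse an agonism annotation TSV (drug, receptor, mode)
#'
#' @param path TSV with header columns `drug`, `receptor`, `mode`.
#' @return an `agonism_table`.
#' @export
parse_agonism <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("drug", "receptor", "mode")
  if (!all(need %in% names(df)))
    stop("parse_agonism: expected columns drug, receptor, mode in ", path)
  agonism_table(df$drug, df$receptor, df$mode)
}

#' Export an affinity or adjusted matrix as TSV
#'
#' Drugs as rows, receptors as columns, empty string for missing cells.
#'
#' @param x an `affinity_matrix` or `adjusted_matrix`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_affinity_tsv <- function(x, path) {
  write_matrix_tsv(as_values(x), path)
}
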
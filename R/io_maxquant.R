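#' Column dialect for MaxQuant proteinGroups tables
#'
#' MaxQuant names corrected reporter-ion columns
#' `"Reporter intensity corrected <channel>"` for single-experiment searches
#' and `"Reporter intensity corrected <channel> <experiment>"` when
#' experiments (here: technical replicates) are defined. The dialect holds
#' the naming template plus which peptide-count column drives the
#' low-evidence filter.
#'
#' @param intensity_template glue-like template resolved per observation;
#'   `{channel}` and `{replicate}` are substituted.
#' @param peptides_column column used as the peptide count; MaxQuant offers
#'   `"Peptides"` (all peptides, the default here) and
#'   `"Razor + unique peptides"`.
#' @param id_column,gene_column,contaminant_column,reverse_column,site_column
#'   remaining column names; defaults match MaxQuant 1.5.x.
#' @return list of class `mq_dialect`.
#' @export
maxquant_dialect <- function(intensity_template = "Reporter intensity corrected {channel} {replicate}",
                             peptides_column = "Peptides",
                             id_column = "Protein IDs",
                             gene_column = "Gene names",
                             contaminant_column = "Potential contaminant",
                             reverse_column = "Reverse",
                             site_column = "Only identified by site") {
  structure(list(intensity_template = intensity_template,
                 peptides_column = peptides_column,
                 id_column = id_column, gene_column = gene_column,
                 contaminant_column = contaminant_column,
                 reverse_column = reverse_column,
                 site_column = site_column),
            class = "mq_dialect")
}

resolve_intensity_column <- function(dialect, channel, replicate) {
  out <- gsub("{channel}", channel, dialect$intensity_template, fixed = TRUE)
  trimws(gsub("{replicate}", replicate, out, fixed = TRUE))
}

mq_flag <- function(x) {
  if (is.null(x)) return(rep(FALSE, 0L))
  !is.na(x) & trimws(as.character(x)) == "+"
}

#' Read a MaxQuant proteinGroups table
#'
#' Parses the tab-separated proteinGroups.txt, extracts the corrected
#' reporter-ion intensity column for every (replicate, channel) observation
#' declared in the layout, and decodes the "+"-marker quality-flag columns.
#' Missing numeric cells parse as 0 (MaxQuant leaves unquantified channels
#' empty); any other unparsable numeric cell is an error naming the row.
#'
#' @param path path to a proteinGroups.txt-style TSV file.
#' @param layout a [tmt_layout] declaring the experiment observations.
#' @param dialect a [maxquant_dialect]; controls column naming.
#' @return An object of class `protein_groups`: list with `annotations`
#'   (data.frame: `protein_id` primary accession, `protein_ids`,
#'   `gene_names`, `peptides`, `contaminant`, `reverse`, `only_by_site`)
#'   and `intensities` (proteins x observations numeric matrix, columns
#'   keyed as in [layout_observations]).
#' @export
read_protein_groups <- function(path, layout, dialect = maxquant_dialect()) {
  stopifnot(inherits(layout, "tmt_layout"))
  tbl <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  protein_groups_from_table(tbl, layout, dialect)
}

#' @rdname read_protein_groups
#' @param table an in-memory proteinGroups-style data.frame (as produced by
#'   [generate_experiment]); same contract as reading from disk.
#' @export
protein_groups_from_table <- function(table, layout, dialect = maxquant_dialect()) {
  stopifnot(inherits(layout, "tmt_layout"), is.data.frame(table))
  obs <- layout_observations(layout)
  cols <- mapply(resolve_intensity_column, channel = obs$channel,
                 replicate = obs$replicate,
                 MoreArgs = list(dialect = dialect), USE.NAMES = FALSE)
  missing_cols <- setdiff(c(dialect$id_column, dialect$peptides_column, cols),
                          names(table))
  if (length(missing_cols))
    stop("proteinGroups table lacks required column(s): ",
         paste(sQuote(missing_cols), collapse = ", "))

  n <- nrow(table)
  intens <- matrix(0, nrow = n, ncol = length(cols),
                   dimnames = list(NULL, obs$key))
  for (j in seq_along(cols)) {
    raw <- table[[cols[j]]]
    if (is.numeric(raw)) {
      v <- as.numeric(raw)
      v[is.na(v)] <- 0
    } else {
      chr <- trimws(as.character(raw))
      chr[is.na(chr) | chr == "" | chr == "NA" | chr == "NaN"] <- "0"
      v <- suppressWarnings(as.numeric(chr))
      if (anyNA(v))
        stop(sprintf("unparsable intensity in column '%s', row %d: '%s'",
                     cols[j], which(is.na(v))[1L], chr[which(is.na(v))[1L]]))
    }
    if (any(v < 0))
      stop(sprintf("negative intensity in column '%s', row %d",
                   cols[j], which(v < 0)[1L]))
    intens[, j] <- v
  }

  pep <- suppressWarnings(as.numeric(table[[dialect$peptides_column]]))
  if (anyNA(pep))
    stop(sprintf("unparsable peptide count in row %d", which(is.na(pep))[1L]))

  ids <- as.character(table[[dialect$id_column]])
  genes <- if (dialect$gene_column %in% names(table))
    as.character(table[[dialect$gene_column]]) else rep(NA_character_, n)
  flag_col <- function(cn) {
    if (cn %in% names(table)) mq_flag(table[[cn]]) else rep(FALSE, n)
  }
  ann <- data.frame(
    protein_id = primary_accession(ids),
    protein_ids = ids,
    gene_names = genes,
    peptides = pep,
    contaminant = flag_col(dialect$contaminant_column),
    reverse = flag_col(dialect$reverse_column),
    only_by_site = flag_col(dialect$site_column),
    stringsAsFactors = FALSE)
  rownames(intens) <- ann$protein_id

  structure(list(annotations = ann, intensities = intens, layout = layout),
            class = "protein_groups")
}

# First accession of a ";"-separated MaxQuant protein-group id string.
primary_accession <- function(ids) {
  vapply(strsplit(as.character(ids), ";", fixed = TRUE),
         function(x) if (length(x)) trimws(x[1L]) else NA_character_,
         character(1L))
}

#' @export
print.protein_groups <- function(x, ...) {
  cat(sprintf("protein_groups: %d protein groups x %d reporter observations (%s layout)\n",
              nrow(x$intensities), ncol(x$intensities), x$layout$type))
  invisible(x)
}

#' @export
dim.protein_groups <- function(x) dim(x$intensities)

subset_protein_groups <- function(pg, keep) {
  pg$annotations <- pg$annotations[keep, , drop = FALSE]
  rownames(pg$annotations) <- NULL
  pg$intensities <- pg$intensities[keep, , drop = FALSE]
  pg
}

#' Protein-level quality filtering
#'
#' Removes, in order: potential contaminants, reverse (decoy) hits, proteins
#' only identified by a modification site, proteins with fewer than
#' `min_peptides` peptides, and finally proteins with a zero intensity in
#' any declared (replicate, channel) observation. Each protein is counted
#' once, under the first rule that removes it.
#'
#' @param pg a `protein_groups` object.
#' @param min_peptides minimum peptide count retained (default 2, i.e.
#'   proteins with fewer than two peptides are discarded).
#' @return list with `kept` (the filtered `protein_groups`) and `report`
#'   (class `filter_report`: tallies per removal rule).
#' @export
apply_quality_filters <- function(pg, min_peptides = 2L) {
  stopifnot(inherits(pg, "protein_groups"), min_peptides >= 0)
  ann <- pg$annotations
  n <- nrow(ann)
  removed <- rep(NA_character_, n)
  mark <- function(removed, cond, label) {
    ifelse(is.na(removed) & cond, label, removed)
  }
  removed <- mark(removed, ann$contaminant, "contaminant")
  removed <- mark(removed, ann$reverse, "reverse")
  removed <- mark(removed, ann$only_by_site, "only_by_site")
  removed <- mark(removed, ann$peptides < min_peptides, "low_peptides")
  has_zero <- if (n) apply(pg$intensities <= 0, 1L, any) else logical(0L)
  removed <- mark(removed, has_zero, "zero_intensity")

  report <- structure(list(
    n_input = n,
    n_removed_contaminant = sum(removed == "contaminant", na.rm = TRUE),
    n_removed_reverse = sum(removed == "reverse", na.rm = TRUE),
    n_removed_only_by_site = sum(removed == "only_by_site", na.rm = TRUE),
    n_removed_low_peptides = sum(removed == "low_peptides", na.rm = TRUE),
    n_removed_zero_intensity = sum(removed == "zero_intensity", na.rm = TRUE),
    n_kept = sum(is.na(removed))
  ), class = "filter_report")

  list(kept = subset_protein_groups(pg, is.na(removed)), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Protein-group quality filter: %d in, %d kept\n",
    "  removed: %d contaminant, %d reverse, %d only-by-site,\n",
    "           %d low-peptide, %d zero-intensity\n"),
    x$n_input, x$n_kept, x$n_removed_contaminant, x$n_removed_reverse,
    x$n_removed_only_by_site, x$n_removed_low_peptides,
    x$n_removed_zero_intensity))
  invisible(x)
}

#' Write a filter report as a JSON sidecar
#'
#' @param report a `filter_report`.
#' @param path output file path.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a reference accession list
#'
#' One accession per line, as distributed by curated databases of known
#' ADP-ribosylated proteins (ADPriboDB-style). Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path text file path.
#' @return character vector of accessions.
#' @export
read_reference_accessions <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Annotate proteins against a reference accession set
#'
#' A protein is flagged as a known target if any accession in its group
#' matches the reference after stripping isoform suffixes (`P09874-2` is
#' compared as `P09874`) on both sides.
#'
#' @param ids character vector of MaxQuant `";"`-separated protein-group id
#'   strings (or plain accessions).
#' @param reference character vector of reference accessions.
#' @return logical vector, one element per protein group.
#' @export
annotate_known_targets <- function(ids, reference) {
  strip <- function(x) sub("-\\d+$", "", trimws(x))
  ref <- unique(strip(reference))
  if (!length(ref)) {
    warning("empty reference accession set: no proteins annotated")
    return(rep(FALSE, length(ids)))
  }
  vapply(strsplit(as.character(ids), ";", fixed = TRUE),
         function(acc) any(strip(acc) %in% ref), logical(1L))
}
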
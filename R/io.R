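# Delimited-table I/O with schema validation. Plain TSV (or CSV, detected
# from the header line) is the canonical interchange format of the pipeline.

# column types understood by read_table schemas
.COLTYPES <- c("character", "numeric", "integer", "group", "generation", "fraction")

detect_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (!length(line)) stop("empty file: ", path)
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t"
  else if (lengths(regmatches(line, gregexpr(",", line))) > 0) ","
  else "\t"
}

#' Read a delimited table with schema validation
#'
#' Delimiter (tab or comma) is auto-detected from the header. Every schema
#' column must be present; typed conversion failures are reported with file,
#' row and column; extra columns are kept as character.
#'
#' @param path file path.
#' @param columns named character vector column -> type, one of
#'   `r paste0('"', .COLTYPES, '"', collapse = ", ")` ("group", "generation"
#'   and "fraction" are validated label types).
#' @param optional names of schema columns allowed to be absent.
#' @param key columns whose combination must be unique across rows.
#' @return data.frame with typed columns.
#' @export
read_table <- function(path, columns, optional = character(0), key = NULL) {
  if (!file.exists(path)) config_error("file not found: ", path)
  check_in(unname(columns), .COLTYPES, "schema types")
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  missing <- setdiff(setdiff(names(columns), optional), names(df))
  if (length(missing))
    config_error(path, ": missing required column(s): ",
                 paste(missing, collapse = ", "))
  for (col in intersect(names(columns), names(df))) {
    type <- columns[[col]]
    raw <- df[[col]]
    if (type %in% c("numeric", "integer")) {
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !(raw %in% c("NA", "")))
      if (length(bad))
        config_error(path, ": non-numeric value '", raw[bad[1]],
                     "' in column '", col, "', row ", bad[1])
      df[[col]] <- if (type == "integer") as.integer(round(val)) else val
    } else if (type == "group") {
      bad <- which(!raw %in% .GROUPS)
      if (length(bad))
        config_error(path, ": invalid group '", raw[bad[1]], "' in row ", bad[1])
    } else if (type == "generation") {
      bad <- which(!raw %in% .GENERATIONS)
      if (length(bad))
        config_error(path, ": invalid generation '", raw[bad[1]], "' in row ", bad[1])
    } else if (type == "fraction") {
      bad <- which(!raw %in% .FRACTIONS)
      if (length(bad))
        config_error(path, ": invalid fraction '", raw[bad[1]], "' in row ", bad[1])
    }
  }
  if (!is.null(key)) {
    kv <- do.call(paste, c(df[key], sep = "\r"))
    if (anyDuplicated(kv))
      config_error(path, ": duplicate key (", paste(key, collapse = ", "),
                   ") in row ", which(duplicated(kv))[1])
  }
  df
}

#' Write a pipeline table as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format trait table
#'
#' Expected columns: `animal_id`, `group`, `generation`, `trait`, `value`;
#' `covariate` optional. (animal_id, trait, generation) must be unique.
#'
#' @param path TSV/CSV path.
#' @return validated data.frame usable by [fit_two_group_model()].
#' @export
read_trait_table <- function(path) {
  read_table(path,
             columns = c(animal_id = "character", group = "group",
                         generation = "generation", trait = "character",
                         value = "numeric", covariate = "numeric"),
             optional = "covariate",
             key = c("animal_id", "trait", "generation"))
}

#' Read an expression matrix from counts + group-map files
#'
#' @param counts_path TSV, genes x samples, first column gene ids, header =
#'   sample ids.
#' @param groups_path TSV with columns `sample`, `group`.
#' @param lengths_path optional TSV with columns `gene_id`, `length_bp`;
#'   default 1 kb per gene.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(counts_path, groups_path, lengths_path = NULL) {
  sep <- detect_delim(counts_path)
  raw <- utils::read.table(counts_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat))
    config_error(counts_path, ": non-numeric count cells present")
  rownames(mat) <- genes
  groups <- read_table(groups_path,
                       columns = c(sample = "character", group = "group"),
                       key = "sample")
  len <- 1000
  if (!is.null(lengths_path)) {
    lt <- read_table(lengths_path,
                     columns = c(gene_id = "character", length_bp = "numeric"),
                     key = "gene_id")
    len <- stats::setNames(lt$length_bp, lt$gene_id)
    missing <- setdiff(genes, names(len))
    if (length(missing))
      config_error(lengths_path, ": no length for gene(s): ",
                   paste(utils::head(missing, 3), collapse = ", "))
  }
  expression_matrix(mat, stats::setNames(groups$group, groups$sample),
                    gene_length_bp = len)
}

#' Read a metabolite table from intensities + metadata + fraction-map files
#'
#' @param intensities_path TSV, metabolites x samples, first column ids.
#' @param meta_path TSV with columns `sample`, `group`, `generation`.
#' @param fractions_path TSV with columns `metabolite_id`, `fraction`.
#' @param internal_standards character vector of standard metabolite ids.
#' @return a [metabolite_table()].
#' @export
read_metabolite_table <- function(intensities_path, meta_path, fractions_path,
                                  internal_standards = character(0)) {
  sep <- detect_delim(intensities_path)
  raw <- utils::read.table(intensities_path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat))
    config_error(intensities_path, ": non-numeric intensity cells present")
  rownames(mat) <- ids
  meta <- read_table(meta_path,
                     columns = c(sample = "character", group = "group",
                                 generation = "generation"),
                     key = "sample")
  fr <- read_table(fractions_path,
                   columns = c(metabolite_id = "character", fraction = "fraction"),
                   key = "metabolite_id")
  metabolite_table(mat,
                   fraction_of = stats::setNames(fr$fraction, fr$metabolite_id),
                   group_of = stats::setNames(meta$group, meta$sample),
                   generation_of = stats::setNames(meta$generation, meta$sample),
                   internal_standards = internal_standards)
}

# write an expression_matrix / metabolite_table as the same TSVs the readers
# accept, plus a ground-truth sidecar when present
write_expression_bundle <- function(em, prefix) {
  counts <- data.frame(gene_id = em$gene_ids, em$counts, check.names = FALSE)
  write_table(counts, paste0(prefix, "_counts.tsv"))
  write_table(data.frame(sample = em$sample_ids, group = unname(em$group_of)),
              paste0(prefix, "_groups.tsv"))
  write_table(data.frame(gene_id = em$gene_ids,
                         length_bp = unname(em$gene_length_bp)),
              paste0(prefix, "_lengths.tsv"))
  tr <- attr(em, "truth")
  if (!is.null(tr)) write_table(tr, paste0(prefix, "_truth.tsv"))
  invisible(prefix)
}

write_metabolite_bundle <- function(mt, prefix) {
  write_table(data.frame(metabolite_id = mt$metabolite_ids, mt$intensities,
                         check.names = FALSE),
              paste0(prefix, "_intensities.tsv"))
  write_table(data.frame(sample = mt$sample_ids, group = unname(mt$group_of),
                         generation = unname(mt$generation_of)),
              paste0(prefix, "_meta.tsv"))
  write_table(data.frame(metabolite_id = mt$metabolite_ids,
                         fraction = unname(mt$fraction_of)),
              paste0(prefix, "_fractions.tsv"))
  tr <- attr(mt, "truth")
  if (!is.null(tr)) write_table(tr, paste0(prefix, "_truth.tsv"))
  invisible(prefix)
}
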
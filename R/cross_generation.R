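# Cross-generation bookkeeping: classify effects by the generation observed,
# partition DET/DAM identifier sets into the seven Venn regions of the
# F1/F2/F3 comparison, and check direction concordance of shared identifiers.

#' Partition three identifier sets into their Venn regions
#'
#' Inputs are deduplicated. "Inherited" sets follow the inclusive definition:
#' everything shared with F1 regardless of the third set's membership
#' (`inherited_F2 = F1 n F2`, `inherited_F3 = F1 n F3`); the seven exclusive
#' regions are also returned.
#'
#' @param setF1,setF2,setF3 character vectors of identifiers (DETs or DAMs)
#'   called in each generation.
#' @return object of class `venn_partition`: `region_sets` (named list with
#'   regions `F1only`, `F2only`, `F3only`, `F1F2only`, `F1F3only`, `F2F3only`,
#'   `F1F2F3`), `inherited_F2`, `inherited_F3`, and `counts`.
#' @export
venn_partition <- function(setF1, setF2, setF3) {
  f1 <- unique(as.character(setF1))
  f2 <- unique(as.character(setF2))
  f3 <- unique(as.character(setF3))
  all_ids <- sort(union(union(f1, f2), f3))
  in1 <- all_ids %in% f1; in2 <- all_ids %in% f2; in3 <- all_ids %in% f3
  region_sets <- list(
    F1only  = all_ids[in1 & !in2 & !in3],
    F2only  = all_ids[!in1 & in2 & !in3],
    F3only  = all_ids[!in1 & !in2 & in3],
    F1F2only = all_ids[in1 & in2 & !in3],
    F1F3only = all_ids[in1 & !in2 & in3],
    F2F3only = all_ids[!in1 & in2 & in3],
    F1F2F3  = all_ids[in1 & in2 & in3])
  structure(list(region_sets = region_sets,
                 inherited_F2 = all_ids[in1 & in2],
                 inherited_F3 = all_ids[in1 & in3],
                 counts = vapply(region_sets, length, 1L)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition:\n")
  print(x$counts)
  cat("inherited by F2 (F1 n F2):", length(x$inherited_F2),
      "| inherited by F3 (F1 n F3):", length(x$inherited_F3), "\n")
  invisible(x)
}

#' Direction concordance of identifiers shared across generations
#'
#' @param records named list generation -> data.frame with columns `id` (or
#'   `gene_id`/`metabolite_id`) and `direction` ("up"/"down").
#' @return data.frame, one row per identifier present in >= 2 generations:
#'   `id`, one `dir_<generation>` column per input generation, `concordant`
#'   (TRUE when every present direction is identical).
#' @export
direction_concordance <- function(records) {
  if (is.null(names(records)) || !all(names(records) %in% .GENERATIONS))
    config_error("records must be a named list with generation names")
  per_gen <- lapply(names(records), function(gen) {
    df <- records[[gen]]
    idcol <- intersect(c("id", "gene_id", "metabolite_id"), names(df))[1]
    if (is.na(idcol) || !"direction" %in% names(df))
      config_error("each record table needs an id column and 'direction'")
    check_in(df$direction, c("up", "down"), paste0("direction (", gen, ")"))
    dup <- unique(df[, c(idcol, "direction")])
    clash <- dup[[idcol]][duplicated(dup[[idcol]])]
    if (length(clash))
      stop("contradictory directions within ", gen, " for id(s): ",
           paste(unique(clash), collapse = ", "))
    stats::setNames(dup$direction, dup[[idcol]])
  })
  names(per_gen) <- names(records)
  ids <- sort(unique(unlist(lapply(per_gen, names))))
  dirs <- vapply(per_gen, function(d) unname(d[ids]), character(length(ids)))
  if (length(ids) == 1L) dirs <- matrix(dirs, nrow = 1,
                                        dimnames = list(NULL, names(per_gen)))
  n_present <- rowSums(!is.na(dirs))
  keep <- n_present >= 2L
  if (!any(keep))
    return(data.frame(id = character(0), concordant = logical(0)))
  concord <- apply(dirs[keep, , drop = FALSE], 1, function(r) {
    r <- r[!is.na(r)]; length(unique(r)) == 1L
  })
  out <- data.frame(id = ids[keep], stringsAsFactors = FALSE)
  for (gen in names(per_gen)) out[[paste0("dir_", gen)]] <- dirs[keep, gen]
  out$concordant <- concord
  rownames(out) <- NULL
  out
}

#' Effect class of a generation
#'
#' F1 animals were themselves exposed to the cryopreservation-transfer
#' procedure as embryos (direct effect); the F2 germline was exposed as
#' primordial germ cells within the F1 embryo (intergenerational); F3 is the
#' first fully unexposed generation (transgenerational).
#'
#' @param generation "F1", "F2" or "F3" (vectorised).
#' @return "direct", "intergenerational" or "transgenerational".
#' @export
classify_effect <- function(generation) {
  map <- c(F1 = "direct", F2 = "intergenerational", F3 = "transgenerational")
  check_in(generation, names(map), "generation")
  unname(map[as.character(generation)])
}
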
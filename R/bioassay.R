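# Bioassay records: ChEMBL-style curation filters, grouping into assays,
# size-proportional assay sampling and within-assay pair sampling.

.CHEMBL_FILTERS <- list(
  list(name = "standard_type", test = function(r) r$standard_type %in% c("IC50", "Ki", "Kd")),
  list(name = "standard_relation", test = function(r) r$standard_relation == "="),
  list(name = "standard_units", test = function(r) r$standard_units == "nM"),
  list(name = "assay_type", test = function(r) r$assay_type == "B"),
  list(name = "target_type", test = function(r) r$target_type == "SINGLE PROTEIN"),
  list(name = "component_type", test = function(r) r$component_type == "PROTEIN"),
  list(name = "molecule_type", test = function(r) r$molecule_type == "Small molecule"),
  list(name = "bao_format", test = function(r) r$bao_format == "BAO_0000357")
)

.ASSAY_COLUMNS <- c("assay_id", "target_id", "ligand_id", "standard_type",
                    "standard_relation", "standard_value", "standard_units",
                    "assay_type", "target_type", "component_type",
                    "molecule_type", "bao_format")

#' Read a bioassay affinity table
#'
#' Expects a CSV or TSV with the ChEMBL-style columns `assay_id`,
#' `target_id`, `ligand_id`, `standard_type`, `standard_relation`,
#' `standard_value` (nM), `standard_units`, `assay_type`, `target_type`,
#' `component_type`, `molecule_type`, `bao_format`.
#'
#' @param path file path; delimiter guessed from the extension.
#' @return a data frame of affinity records.
#' @export
read_assay_table <- function(path) {
  .assert(file.exists(path), paste0("assay table not found: ", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  missing <- setdiff(.ASSAY_COLUMNS, names(df))
  .assert(length(missing) == 0L,
          paste0("assay table missing columns: ", paste(missing, collapse = ", ")))
  df
}

#' Apply the eight ChEMBL curation filters
#'
#' A record survives iff it passes all eight criteria (affinity type in
#' IC50/Ki/Kd; relation '='; units nM; binding assay type 'B'; target type
#' 'SINGLE PROTEIN'; component type 'PROTEIN'; molecule type
#' 'Small molecule'; BAO format 'BAO_0000357'). Removals are attributed to
#' the first failed criterion in that order; records missing a required
#' field are removed with reason `missing_field`.
#'
#' @param records data frame of affinity records (see [read_assay_table()]).
#' @return list with `records` (the survivors) and `report`
#'   (a `curation_report`).
#' @export
apply_chembl_filters <- function(records) {
  .assert(is.data.frame(records), "records must be a data frame")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    r <- records[i, , drop = FALSE]
    need <- c(.ASSAY_COLUMNS)
    vals <- lapply(need, function(cn) if (cn %in% names(r)) r[[cn]] else NA)
    if (any(vapply(vals, function(v) is.null(v) || is.na(v), logical(1)))) {
      reason[i] <- "missing_field"
      next
    }
    for (f in .CHEMBL_FILTERS) {
      if (!isTRUE(f$test(r))) {
        reason[i] <- f$name
        break
      }
    }
  }
  surviving <- records[is.na(reason), , drop = FALSE]
  removed_counts <- table(factor(reason[!is.na(reason)],
                                 levels = c(vapply(.CHEMBL_FILTERS, `[[`, "", "name"),
                                            "missing_field")))
  by_type <- table(factor(surviving$standard_type, levels = c("IC50", "Ki", "Kd")))
  report <- structure(list(
    input = n,
    surviving = nrow(surviving),
    removed = as.list(removed_counts),
    surviving_by_type = as.list(by_type),
    assays_removed_size1 = NA_integer_,
    assays_removed_mixed_type = NA_integer_
  ), class = "curation_report")
  list(records = surviving, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("Curation report:", x$input, "records in,", x$surviving, "surviving\n")
  rm <- unlist(x$removed)
  rm <- rm[rm > 0]
  if (length(rm)) {
    for (nm in names(rm)) cat("  removed (", nm, "): ", rm[[nm]], "\n", sep = "")
  }
  if (!is.na(x$assays_removed_size1)) {
    cat("  assays dropped, single record:", x$assays_removed_size1, "\n")
    cat("  assays dropped, mixed affinity type:", x$assays_removed_mixed_type, "\n")
  }
  invisible(x)
}

#' Write a curation report as JSON
#' @param report a `curation_report`.
#' @param path output path.
#' @export
write_curation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Group filtered records into bioassays
#'
#' Groups by `assay_id`, drops assays with a single protein-ligand pair and
#' assays spanning more than one affinity type, and collapses duplicate
#' (assay, ligand) measurements to their geometric mean.
#'
#' @param records filtered affinity records.
#' @param report optional `curation_report` to annotate with assay-level
#'   exclusion counts.
#' @return list of `bioassay` objects (fields: assay_id, target_id,
#'   ligand_id, value_nM, measure_type, size). If `report` is supplied the
#'   result carries it in `attr(, "report")`.
#' @export
group_into_assays <- function(records, report = NULL) {
  .assert(is.data.frame(records), "records must be a data frame")
  out <- list()
  n_size1 <- 0L
  n_mixed <- 0L
  if (nrow(records) > 0L) {
    for (aid in unique(records$assay_id)) {
      sub <- records[records$assay_id == aid, , drop = FALSE]
      if (length(unique(sub$standard_type)) > 1L) {
        n_mixed <- n_mixed + 1L
        next
      }
      # duplicate (assay, ligand) rows -> geometric mean value
      vals <- tapply(sub$standard_value, sub$ligand_id,
                     function(v) exp(mean(log(v))))
      ligs <- names(vals)
      if (length(ligs) < 2L) {
        n_size1 <- n_size1 + 1L
        next
      }
      out[[length(out) + 1L]] <- structure(list(
        assay_id = aid,
        target_id = sub$target_id[1L],
        ligand_id = ligs,
        value_nM = unname(as.numeric(vals)),
        measure_type = sub$standard_type[1L],
        size = length(ligs)
      ), class = "bioassay")
    }
  }
  if (!is.null(report)) {
    report$assays_removed_size1 <- n_size1
    report$assays_removed_mixed_type <- n_mixed
    attr(out, "report") <- report
  }
  out
}

#' @export
print.bioassay <- function(x, ...) {
  cat("bioassay", x$assay_id, "(", x$measure_type, "):", x$size,
      "ligands on target", x$target_id, "\n")
  invisible(x)
}

#' Map a raw affinity measurement type to its task
#'
#' IC50 stays its own task; Ki and Kd are merged into the single K task
#' (they quantify the same dissociation-style constant, and Kd data alone
#' would be too scarce to carry a task).
#'
#' @param measure_type one of "IC50", "Ki", "Kd".
#' @return "IC50" or "K".
#' @export
map_label_type <- function(measure_type) {
  .assert(length(measure_type) == 1L, "measure_type must be scalar")
  switch(measure_type,
         IC50 = "IC50",
         Ki = "K",
         Kd = "K",
         stop("unsupported affinity label type: ", measure_type, call. = FALSE))
}

#' Sample a bioassay with probability proportional to its size
#'
#' @param assays list of `bioassay` objects.
#' @return one `bioassay`.
#' @export
sample_assay <- function(assays) {
  .assert(length(assays) >= 1L, "no assays to sample from")
  sizes <- vapply(assays, `[[`, numeric(1), "size")
  assays[[sample.int(length(assays), 1L, prob = sizes)]]
}

#' Sample a bioassay-specific data pair
#'
#' Draws two distinct ligands uniformly without replacement from one assay
#' (order random) and attaches their stored affinity values. Exactly tied
#' values are redrawn a bounded number of times since the ranking label is
#' undefined at ties.
#'
#' @param assay a `bioassay` of size >= 2.
#' @param max_retries redraw budget for tied values.
#' @return an `assay_pair` with target_id, ligand_a/b, value_a/b (nM),
#'   measure_type and task_type.
#' @export
sample_pair <- function(assay, max_retries = 10L) {
  .assert(inherits(assay, "bioassay"), "assay must be a bioassay")
  .assert(assay$size >= 2L, "assay must contain at least two ligands")
  for (try in seq_len(max_retries + 1L)) {
    idx <- sample.int(assay$size, 2L)
    if (assay$value_nM[idx[1L]] != assay$value_nM[idx[2L]]) {
      return(structure(list(
        assay_id = assay$assay_id,
        target_id = assay$target_id,
        ligand_a = assay$ligand_id[idx[1L]],
        ligand_b = assay$ligand_id[idx[2L]],
        value_a = assay$value_nM[idx[1L]],
        value_b = assay$value_nM[idx[2L]],
        measure_type = assay$measure_type,
        task_type = map_label_type(assay$measure_type)
      ), class = "assay_pair"))
    }
  }
  stop("could not sample an untied pair from assay ", assay$assay_id,
       " after ", max_retries, " retries", call. = FALSE)
}

#' Within-assay ranking label
#'
#' Returns 1 iff `value_a > value_b` on the raw nM scale (the indicator the
#' ranking heads are trained against), 0 otherwise. Ties violate the
#' precondition.
#'
#' @param value_a,value_b affinity values in nM, or pass an `assay_pair` as
#'   `value_a`.
#' @return 0 or 1.
#' @export
ranking_label <- function(value_a, value_b = NULL) {
  if (inherits(value_a, "assay_pair")) {
    value_b <- value_a$value_b
    value_a <- value_a$value_a
  }
  .assert(is.numeric(value_a) && is.numeric(value_b), "values must be numeric")
  .assert(all(value_a != value_b), "ranking label undefined for tied values")
  as.integer(value_a > value_b)
}

#' Convert an nM affinity to the pAff scale
#'
#' pAff = 9 - log10(value in nM) = -log10(molar value); 1 nM maps to 9.
#' This is the regression target scale: squared error on raw nM would be
#' dominated by weak binders, and the p-scale is the field norm.
#'
#' @param value_nM affinity in nM, > 0.
#' @return dimensionless pAff.
#' @export
to_paffinity <- function(value_nM) {
  .assert(is.numeric(value_nM) && all(value_nM > 0), "affinity must be positive")
  9 - log10(value_nM)
}

#' @rdname to_paffinity
#' @param paff pAff value.
#' @export
from_paffinity <- function(paff) {
  10^(9 - paff)
}
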
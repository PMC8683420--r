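# The species x benefit incidence table and its analysis views.

#' Construct a benefit matrix
#'
#' @param x binary (0/1) matrix or data.frame; rownames are species (or
#'   genus) labels, colnames are benefit types.
#' @param level `"species"` or `"genus"`.
#' @return a `benefit_matrix`: integer matrix with a `level` attribute.
#'   Rows must be non-empty (a beneficial taxon carries at least one
#'   benefit) and benefit names unique.
#' @export
benefit_matrix <- function(x, level = c("species", "genus")) {
  level <- match.arg(level)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("benefit matrix needs row (taxon) and column (benefit) names")
  }
  if (anyDuplicated(colnames(x))) stopf("benefit names must be unique")
  if (anyDuplicated(rownames(x))) stopf("taxon names must be unique")
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    rows <- unique(rownames(x)[(bad - 1) %% nrow(x) + 1])
    stopf("non-binary cell values in rows: %s", paste(rows, collapse = ", "))
  }
  storage.mode(x) <- "integer"
  zero <- rownames(x)[rowSums(x) == 0]
  if (length(zero)) {
    stopf("all-zero rows (taxa with no benefit): %s", paste(zero, collapse = ", "))
  }
  structure(x, level = level, class = c("benefit_matrix", class(x)))
}

#' @export
print.benefit_matrix <- function(x, ...) {
  cat(sprintf("benefit matrix: %d %s x %d benefits, %d records\n",
              nrow(x), attr(x, "level"), ncol(x), sum(x)))
  invisible(x)
}

benefit_level <- function(x) attr(x, "level") %||% "species"

#' Read a benefit matrix from CSV
#'
#' Wide format: first column = species, remaining columns = one per benefit
#' (0/1 cells). Long format (`format = "long"`): two columns, species and
#' benefit, one record per row; duplicate records collapse to a single
#' presence.
#'
#' @param path CSV path.
#' @param format `"wide"` or `"long"`.
#' @param level taxon level of the rows.
#' @return a `benefit_matrix`.
#' @export
read_benefit_matrix <- function(path, format = c("wide", "long"),
                                level = c("species", "genus")) {
  format <- match.arg(format)
  level <- match.arg(level)
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stopf("empty benefit table: %s", path)
  if (format == "long") {
    sp <- as.character(df[[1]])
    ben <- as.character(df[[2]])
    tab <- table(sp, ben)
    m <- (unclass(tab) > 0) + 0L
    dimnames(m) <- dimnames(tab)
    return(benefit_matrix(m, level))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m)) stopf("non-numeric cells in wide benefit table")
  benefit_matrix(m, level)
}

#' Write a benefit matrix to CSV (wide format)
#' @param matrix a `benefit_matrix`.
#' @param path output path.
#' @param id_column name of the taxon column.
#' @export
write_benefit_matrix <- function(matrix, path, id_column = benefit_level(matrix)) {
  df <- data.frame(rownames(matrix), as.data.frame(unclass(matrix)[, , drop = FALSE]),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Collapse a species-level benefit matrix to genus level
#'
#' A genus carries a benefit iff any of its species does (union semantics),
#' mirroring the collapse of congeneric records into single genus-level
#' observations.
#'
#' @param matrix a species-level `benefit_matrix`.
#' @param taxonomy a `taxonomy_map` covering every species row.
#' @return a genus-level `benefit_matrix`.
#' @export
collapse_to_genus <- function(matrix, taxonomy) {
  if (benefit_level(matrix) != "species") stopf("expected a species-level matrix")
  gen <- clade_of(taxonomy, rownames(matrix), "genus")
  agg <- rowsum(unclass(matrix) + 0, gen)
  benefit_matrix((agg > 0) + 0L, level = "genus")
}

#' Restrict to species with at least one beneficial congeneric
#'
#' Keeps rows whose genus contains two or more beneficial species; on the
#' full dataset this yields the "congeneric" analysis view.
#'
#' @param matrix a species-level `benefit_matrix`.
#' @param taxonomy a `taxonomy_map`.
#' @return a `benefit_matrix` (possibly with zero rows, with a warning when
#'   every genus is a singleton).
#' @export
congeneric_subset <- function(matrix, taxonomy) {
  if (benefit_level(matrix) != "species") stopf("expected a species-level matrix")
  gen <- clade_of(taxonomy, rownames(matrix), "genus")
  sizes <- table(gen)
  keep <- sizes[gen] >= 2
  if (!any(keep)) {
    warnf("all beneficial genera are singletons; congeneric subset is empty")
    out <- unclass(matrix)[0, , drop = FALSE]
    return(structure(out, level = "species",
                     class = c("benefit_matrix", class(out))))
  }
  benefit_matrix(unclass(matrix)[keep, , drop = FALSE], level = "species")
}

#' Species providing at least a minimum number of benefit types
#'
#' @param matrix a species-level `benefit_matrix`.
#' @param min_benefits threshold k (>= 1); results nest across thresholds.
#' @return character vector of species labels with row sum >= k.
#' @export
multibeneficial_subset <- function(matrix, min_benefits) {
  if (min_benefits < 1) stopf("'min_benefits' must be >= 1")
  if (min_benefits > ncol(matrix)) {
    warnf("min_benefits (%d) exceeds the number of benefit types (%d)",
          min_benefits, ncol(matrix))
    return(character(0))
  }
  rownames(matrix)[rowSums(unclass(matrix)) >= min_benefits]
}

#' The 25 reference benefit categories
#'
#' The standard major-category vocabulary the analyses are usually run
#' against, shipped as a plain-text reference file. Inputs are not required
#' to use it.
#'
#' @return character vector of 25 category names.
#' @export
benefit_categories <- function() {
  path <- system.file("extdata", "benefit_categories.txt",
                      package = "phylobenefit", mustWork = TRUE)
  readLines(path, warn = FALSE)
}

#' Abort when matrix taxa are missing from the tree
#'
#' All analyses assume full overlap between the benefit table and the
#' phylogeny; rather than silently dropping taxa this reports the
#' mismatches and errors.
#'
#' @param matrix a `benefit_matrix`.
#' @param tree a `phylo`.
#' @return invisibly, the matched taxon labels.
#' @export
reconcile_taxa <- function(matrix, tree) {
  missing <- setdiff(rownames(matrix), tree$tip.label)
  if (length(missing)) {
    stopf(paste0("reconciliation failure: %d matrix taxa absent from the tree ",
                 "(first few: %s)"),
          length(missing),
          paste(utils::head(missing, 5), collapse = ", "))
  }
  invisible(rownames(matrix))
}
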
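# Tip -> genus -> family lookup used by the genus/family groupings.

#' Construct a taxonomy map
#'
#' @param tip,genus,family character vectors of equal length, or a
#'   data.frame with those columns passed as `tip`.
#' @return a `taxonomy_map`: data.frame with columns tip, genus, family.
#'   Every genus must map to exactly one family; tips must be unique.
#' @export
taxonomy_map <- function(tip, genus = NULL, family = NULL) {
  if (is.data.frame(tip)) {
    df <- tip
    need <- c("tip", "genus", "family")
    if (!all(need %in% names(df))) {
      stopf("taxonomy data.frame needs columns: %s", paste(need, collapse = ", "))
    }
    df <- df[need]
  } else {
    df <- data.frame(tip = as.character(tip), genus = as.character(genus),
                     family = as.character(family), stringsAsFactors = FALSE)
  }
  df[] <- lapply(df, as.character)
  if (anyNA(df) || any(!nzchar(unlist(df)))) {
    stopf("taxonomy entries must be non-missing and non-empty")
  }
  if (anyDuplicated(df$tip)) {
    stopf("duplicate tips in taxonomy: %s",
          paste(unique(df$tip[duplicated(df$tip)]), collapse = ", "))
  }
  fam_per_genus <- tapply(df$family, df$genus, function(x) length(unique(x)))
  bad <- names(fam_per_genus)[fam_per_genus > 1]
  if (length(bad)) {
    stopf("genus mapped to more than one family: %s", paste(bad, collapse = ", "))
  }
  class(df) <- c("taxonomy_map", "data.frame")
  df
}

#' Read a taxonomy table from CSV
#'
#' Expects header columns `tip,genus,family`.
#'
#' @param path CSV file path.
#' @return a `taxonomy_map`.
#' @export
read_taxonomy_csv <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  taxonomy_map(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a taxonomy table to CSV
#' @param taxonomy a `taxonomy_map`.
#' @param path output CSV path.
#' @export
write_taxonomy_csv <- function(taxonomy, path) {
  write.csv(as.data.frame(unclass(taxonomy)), path, row.names = FALSE)
  invisible(path)
}

# Look up the genus (or family) of each tip; error on unmapped tips.
clade_of <- function(taxonomy, tips, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  idx <- match(tips, taxonomy$tip)
  if (anyNA(idx)) {
    stopf("tips missing from taxonomy: %s",
          paste(tips[is.na(idx)], collapse = ", "))
  }
  taxonomy[[rank]][idx]
}

#' Tips belonging to a named genus or family
#' @param taxonomy a `taxonomy_map`.
#' @param clade genus or family name.
#' @param rank `"genus"` or `"family"`.
#' @return character vector of tip labels.
#' @export
tips_in_clade <- function(taxonomy, clade, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  taxonomy$tip[taxonomy[[rank]] == clade]
}
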
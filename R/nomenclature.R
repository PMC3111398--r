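#' @name nomenclature
#' @title HLA allele nomenclature at two- and four-digit resolution
#'
#' @description
#' Classical HLA alleles are named by locus and one or two two-digit fields:
#' `A*02` is an intermediate-resolution ("antigen level", 2-digit) name and
#' `A*02:01` (equivalently the pre-2010 spelling `A*0201`) a high-resolution
#' (4-digit) name. Typing assays sometimes cannot distinguish a set of
#' alleles and report an ambiguity set such as `B*57:01/B*57:03`; a
#' prediction is credited if it matches any member of the set.
#'
#' These helpers parse both spellings, reduce alleles to intermediate
#' resolution and test predictions against (possibly ambiguous) truth.
NULL

.hla_loci <- c("A", "B", "C", "DRB1", "DQB1", "DPB1")

#' Construct an HLA allele
#'
#' @param locus one of `"A","B","C","DRB1","DQB1","DPB1"`.
#' @param field1 two-digit character field (e.g. `"02"`).
#' @param field2 optional second two-digit field; `NA` for an
#'   intermediate-resolution allele.
#' @return An object of class `hla_allele`.
#' @export
hla_allele <- function(locus, field1, field2 = NA_character_) {
  locus <- as.character(locus)
  if (!locus %in% .hla_loci)
    stop_hla("unknown HLA locus: ", locus)
  field1 <- as.character(field1)
  field2 <- as.character(field2)
  if (is.na(field1) || !grepl("^[0-9]{2}$", field1))
    stop_hla("field1 must be a two-digit string, got: ", field1)
  if (!is.na(field2) && !grepl("^[0-9]{2}$", field2))
    stop_hla("field2 must be a two-digit string or NA, got: ", field2)
  structure(list(locus = locus, field1 = field1, field2 = field2),
            class = "hla_allele")
}

#' Parse an HLA allele name
#'
#' Accepts `"A*0201"`, `"A*02:01"`, `"0201"`, `"02:01"`, `"B*07"` etc.
#' Colon and no-colon spellings parse identically.
#'
#' @param text allele name, with or without the `LOCUS*` prefix.
#' @param locus locus the allele belongs to; required when `text` carries no
#'   prefix, checked for consistency when it does.
#' @return An `hla_allele`.
#' @export
parse_allele <- function(text, locus = NULL) {
  text <- trimws(as.character(text))
  if (!nzchar(text) || is.na(text)) stop_hla("empty allele name")
  if (grepl("*", text, fixed = TRUE)) {
    parts <- strsplit(text, "*", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_hla("malformed allele name: ", text)
    prefix <- parts[1]
    if (!prefix %in% .hla_loci) stop_hla("unknown HLA locus: ", prefix)
    if (!is.null(locus) && prefix != locus)
      stop_hla("allele ", text, " does not belong to locus ", locus)
    locus <- prefix
    text <- parts[2]
  }
  if (is.null(locus)) stop_hla("locus required to parse bare allele: ", text)
  digits <- gsub(":", "", text, fixed = TRUE)
  if (!grepl("^[0-9]+$", digits))
    stop_hla("malformed allele fields: ", text)
  if (nchar(digits) == 2L) {
    hla_allele(locus, digits)
  } else if (nchar(digits) == 4L) {
    hla_allele(locus, substr(digits, 1, 2), substr(digits, 3, 4))
  } else {
    stop_hla("allele fields must have 2 or 4 digits: ", text)
  }
}

#' Parse an allele or an ambiguity set
#'
#' Alternatives are joined by `"/"`, e.g. `"B*57:01/B*57:03"`. All members
#' must share the locus and resolution.
#'
#' @inheritParams parse_allele
#' @return An object of class `allele_set` (a list of `hla_allele`).
#' @export
parse_allele_set <- function(text, locus = NULL) {
  pieces <- strsplit(trimws(as.character(text)), "/", fixed = TRUE)[[1]]
  pieces <- pieces[nzchar(pieces)]
  if (!length(pieces)) stop_hla("empty allele set")
  alleles <- lapply(pieces, parse_allele, locus = locus)
  allele_set(alleles)
}

#' @rdname parse_allele_set
#' @param alleles a list of `hla_allele` objects at a common locus and
#'   resolution.
#' @export
allele_set <- function(alleles) {
  if (inherits(alleles, "hla_allele")) alleles <- list(alleles)
  if (!length(alleles)) stop_hla("an allele set must be non-empty")
  loci <- vapply(alleles, function(a) a$locus, "")
  if (length(unique(loci)) != 1L)
    stop_hla("allele set mixes loci: ", paste(unique(loci), collapse = ", "))
  res <- vapply(alleles, function(a) is.na(a$field2), TRUE)
  if (length(unique(res)) != 1L)
    stop_hla("allele set mixes resolutions")
  keys <- vapply(alleles, allele_key, "")
  alleles <- alleles[!duplicated(keys)]
  structure(alleles, class = "allele_set")
}

#' Resolution-level key of an allele ("02" or "02:01")
#' @param a an `hla_allele`.
#' @export
allele_key <- function(a) {
  if (is.na(a$field2)) a$field1 else paste0(a$field1, ":", a$field2)
}

#' Resolution of an allele or allele key
#' @param a an `hla_allele`.
#' @return `"intermediate"` (2-digit) or `"high"` (4-digit).
#' @export
allele_resolution <- function(a) {
  if (is.na(a$field2)) "intermediate" else "high"
}

#' Reduce to intermediate (2-digit) resolution
#'
#' Drops the second field; idempotent. For an `allele_set` the reduction is
#' applied element-wise and duplicates collapse.
#'
#' @param a an `hla_allele` or `allele_set`.
#' @export
to_intermediate <- function(a) {
  if (inherits(a, "allele_set")) {
    return(allele_set(lapply(unclass(a), to_intermediate)))
  }
  hla_allele(a$locus, a$field1)
}

# Key-level reduction used on the model's hot path: "02:01" -> "02".
reduce_key <- function(keys) sub(":.*$", "", keys)

#' Match a predicted allele against (possibly ambiguous) truth
#'
#' The prediction, reduced to the truth's resolution, matches if it equals
#' any member of the truth set. The prediction must be at least as resolved
#' as the truth.
#'
#' @param pred an `hla_allele`.
#' @param truth an `hla_allele` or `allele_set`.
#' @return `TRUE`/`FALSE`.
#' @export
alleles_match <- function(pred, truth) {
  if (inherits(truth, "hla_allele")) truth <- allele_set(list(truth))
  tl <- truth[[1]]$locus
  if (pred$locus != tl)
    stop_hla("locus mismatch: prediction at ", pred$locus, ", truth at ", tl)
  truth_res <- allele_resolution(truth[[1]])
  if (truth_res == "high" && allele_resolution(pred) == "intermediate")
    stop_hla("prediction is at lower resolution than the truth")
  pk <- allele_key(pred)
  if (truth_res == "intermediate") pk <- reduce_key(pk)
  pk %in% vapply(unclass(truth), allele_key, "")
}

#' @export
print.hla_allele <- function(x, ...) {
  cat(x$locus, "*", allele_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.allele_set <- function(x, ...) {
  keys <- vapply(unclass(x), function(a) paste0(a$locus, "*", allele_key(a)), "")
  cat(paste(keys, collapse = "/"), "\n")
  invisible(x)
}

#' Consolidate allele keys through an ambiguity map
#'
#' Typing labs resolve ambiguous calls into sets of alternates; when cohorts
#' are combined those sets must be harmonized. The map is a named list
#' (allele key -> character vector of alternates); keys absent from the map
#' pass through as singletons.
#'
#' @param key an allele key such as `"57:01"`.
#' @param ambiguity_map named list of character vectors, or `NULL`.
#' @return Character vector of alternate keys (always includes `key`'s
#'   mapped set or `key` itself).
#' @export
consolidate_ambiguity <- function(key, ambiguity_map = NULL) {
  if (is.null(ambiguity_map) || is.null(ambiguity_map[[key]])) return(key)
  unique(ambiguity_map[[key]])
}
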
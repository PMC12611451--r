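#' @keywords internal
#' Map unicode hyphen/dash variants (U+2010..U+2014, U+2212) to ASCII "-".
normalize_hyphens <- function(x) {
  gsub("[‐‑‒–—−]", "-", x)
}

#' Normalize a miRNA identifier to canonical form
#'
#' Brings mixed-style miRNA names (as found in published tables, which freely
#' mix `miR-623`, `mir-623` and `MIR-623`) onto the canonical
#' `hsa-miR-...` / `hsa-let-...` form:
#' unicode hyphen variants become ASCII hyphens, a missing species prefix is
#' filled in with `hsa-`, the `mir` token is case-corrected to `miR`, and the
#' remainder (accession number and any `-3p`/`-5p` arm suffix) is lower-cased.
#' The function is idempotent and vectorized.
#'
#' @param raw Character vector of raw miRNA identifiers.
#' @return Character vector of canonical identifiers, same length as `raw`.
#' @examples
#' normalize_mirna_id(c("mir-623", "MIR-4722-5P", "hsa-miR-942-5p", "let-7a"))
#' @export
normalize_mirna_id <- function(raw) {
  if (!is.character(raw)) stop("`raw` must be a character vector", call. = FALSE)
  if (length(raw) == 0L) return(character(0))
  x <- trimws(normalize_hyphens(raw))
  if (anyNA(x) || any(!nzchar(x))) {
    stop("miRNA identifiers must be non-empty strings", call. = FALSE)
  }
  lx <- tolower(x)
  bare <- grepl("^(mir|let)(-|$)", lx)
  lx[bare] <- paste0("hsa-", lx[bare])
  sub("^([a-z]{3,4})-mir", "\\1-miR", lx)
}

#' Normalize a circRNA identifier
#'
#' circRNA names are treated as opaque strings: nomenclature is inconsistent
#' across databases, so no cross-database reconciliation is attempted. Only
#' whitespace trimming and unicode-hyphen normalization are applied.
#'
#' @param raw Character vector of raw circRNA identifiers.
#' @return Character vector of trimmed identifiers.
#' @export
normalize_circ_id <- function(raw) {
  if (!is.character(raw)) stop("`raw` must be a character vector", call. = FALSE)
  x <- trimws(normalize_hyphens(raw))
  if (length(x) && (anyNA(x) || any(!nzchar(x)))) {
    stop("circRNA identifiers must be non-empty strings", call. = FALSE)
  }
  x
}

#' Normalize a gene symbol
#'
#' Gene symbols are upper-cased and whitespace-trimmed; unicode hyphens are
#' mapped to ASCII (e.g. HLA‐A -> HLA-A).
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_gene_symbol <- function(raw) {
  if (!is.character(raw)) stop("`raw` must be a character vector", call. = FALSE)
  x <- toupper(trimws(normalize_hyphens(raw)))
  if (length(x) && (anyNA(x) || any(!nzchar(x)))) {
    stop("gene symbols must be non-empty strings", call. = FALSE)
  }
  x
}
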
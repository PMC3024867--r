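# Controlled vocabularies: domain signatures -> (subunit, family) tokens and
# synteny marker definitions. Both ship as editable TSV files under
# inst/extdata so users can extend them for their own annotation sources.

#' PTS enzyme II families recognized by the catalogue
#' @export
PTS_FAMILIES <- c("FRU_MAN_SOR", "FRU_MANNITOL", "GLUCOSE", "LACTOSE",
                  "GLUCITOL", "GALACTITOL", "ASCORBATE", "UNKNOWN")

#' Domain-signature vocabulary
#'
#' Maps domain signature accessions (Pfam-style) to a normalized label and,
#' for PTS enzyme II signatures, a subunit (IIA/IIB/IIC/IID) and a substrate
#' family. Marker signatures (sigma-54, SIS, transposase) have empty
#' subunit/family fields. The fructose/mannose/sorbose family is the only
#' one with a IID subunit.
#'
#' @param path optional path to a custom vocabulary TSV with columns
#'   signature_id, label, subunit, family.
#' @return data.frame with those four columns.
#' @export
pts_vocab <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pts_domain_vocab.tsv", package = "ptsHGT")
  }
  v <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE)
  for (col in c("subunit", "family")) {
    if (is.null(v[[col]])) v[[col]] <- NA_character_
    v[[col]][is.na(v[[col]])] <- ""
  }
  stopifnot(all(c("signature_id", "label") %in% names(v)))
  if (anyDuplicated(v$signature_id)) stop("duplicate signature_id in vocabulary")
  v
}

#' Synteny-marker vocabulary
#'
#' Maps marker types (sigma54, sis, is_element) to domain labels and
#' case-insensitive product-text regexes. Domain evidence outranks text.
#'
#' @param path optional path to a custom marker TSV with columns marker,
#'   domain_label, product_regex.
#' @return data.frame with those three columns.
#' @export
marker_vocab <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_vocab.tsv", package = "ptsHGT")
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Look up the signature accession for a (family, subunit) pair
#' @keywords internal
vocab_signature <- function(family, subunit, vocab = pts_vocab()) {
  hit <- vocab$signature_id[vocab$family == family & vocab$subunit == subunit]
  if (length(hit) == 0L) stop("no signature for ", family, " ", subunit)
  hit[1]
}
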
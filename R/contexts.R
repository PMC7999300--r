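#' @importFrom stats rpois rbinom runif rnorm pbinom setNames lm coef
#'   p.adjust pt fisher.test median complete.cases t.test
#' @importFrom utils read.table write.table
NULL

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a character vector of sequences
#' @noRd
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' The six pyrimidine-reference substitution types
#' @noRd
SUB_TYPES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical ordering of the 96 trinucleotide substitution classes
#'
#' Classes are labelled `F[R>A]T` where `F`/`T` are the 5' and 3' flanking
#' bases and `R>A` is the substitution expressed on the pyrimidine strand.
#' Ordering is substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then 5'
#' flank (A,C,G,T), then 3' flank (A,C,G,T). This ordering is fixed and is
#' the index convention for every spectrum in the package.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(context_classes())
context_classes <- function() {
  unlist(lapply(SUB_TYPES, function(st) {
    unlist(lapply(BASES, function(f5) {
      vapply(BASES, function(f3) {
        paste0(f5, "[", st, "]", f3)
      }, character(1))
    }))
  }), use.names = FALSE)
}

#' The 32 pyrimidine-centred trinucleotides, in class order
#' @return Character vector of length 32 (16 NCN then 16 NTN).
#' @export
pyrimidine_triplets <- function() {
  unlist(lapply(c("C", "T"), function(ctr) {
    unlist(lapply(BASES, function(f5) {
      vapply(BASES, function(f3) paste0(f5, ctr, f3), character(1))
    }))
  }), use.names = FALSE)
}

#' Triplet underlying each of the 96 classes
#' @noRd
class_triplet <- function(classes = context_classes()) {
  paste0(substr(classes, 1, 1), substr(classes, 3, 3), substr(classes, 7, 7))
}

#' Collapse a raw trinucleotide + substitution onto its pyrimidine class
#'
#' Substitutions with a purine (A/G) reference base are mapped to the
#' reverse-complement strand, so every event is reported with a C or T
#' reference. Returns NA for triplets containing non-ACGT characters.
#'
#' @param triplet Character vector of genomic 3-mers centred on the mutated
#'   base (as read on the reference forward strand).
#' @param alt Character vector of alternate bases (forward strand).
#' @return Character vector of class labels as in [context_classes()].
#' @export
collapse_context <- function(triplet, alt) {
  stopifnot(length(triplet) == length(alt))
  ref <- substr(triplet, 2, 2)
  ok <- grepl("^[ACGT]{3}$", triplet) & alt %in% BASES
  out <- rep(NA_character_, length(triplet))
  if (!any(ok)) return(out)
  tri <- triplet[ok]; al <- alt[ok]; rf <- ref[ok]
  pur <- rf %in% c("A", "G")
  tri[pur] <- revcomp(tri[pur])
  al[pur] <- COMPLEMENT[al[pur]]
  rf[pur] <- substr(tri[pur], 2, 2)
  out[ok] <- paste0(
    substr(tri, 1, 1), "[", rf, ">", al, "]", substr(tri, 3, 3)
  )
  out
}
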
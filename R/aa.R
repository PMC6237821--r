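#' @keywords internal
"_PACKAGE"

# canonical 20 amino acids, 3-letter (title case) and 1-letter codes
AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W",
         "Y", "V")

#' Normalise an amino-acid code to the canonical 3-letter form
#'
#' Accepts 1-letter or 3-letter codes in any letter case and returns the
#' title-case 3-letter code (`"Arg"`, `"Trp"`, ...).
#'
#' @param code character vector of amino-acid codes.
#' @return character vector of canonical 3-letter codes.
#' @export
aa_canonical <- function(code) {
  code <- as.character(code)
  out <- character(length(code))
  for (i in seq_along(code)) {
    x <- code[i]
    if (is.na(x)) stop("missing amino-acid code")
    if (nchar(x) == 1L) {
      j <- match(toupper(x), AA1)
    } else if (nchar(x) == 3L) {
      j <- match(tolower(x), tolower(AA3))
    } else {
      j <- NA_integer_
    }
    if (is.na(j)) stop("non-canonical amino-acid code: '", x, "'")
    out[i] <- AA3[j]
  }
  out
}

#' Convert a canonical 3-letter code to 1-letter
#' @param code3 character vector of 3-letter codes.
#' @return character vector of 1-letter codes.
#' @export
aa_three_to_one <- function(code3) {
  AA1[match(aa_canonical(code3), AA3)]
}
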
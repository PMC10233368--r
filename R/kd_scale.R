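#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the 20 standard amino acids, from
#' Kyte & Doolittle (1982).  The scale spans -4.5 (Arg) to +4.5 (Ile);
#' positive values are hydrophobic.
#'
#' @format Named numeric vector of length 20; names are one-letter
#'   amino-acid codes.
#' @export
kd_scale <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Per-residue Kyte-Doolittle hydropathy values
#'
#' Maps each residue of an amino-acid sequence to its Kyte-Doolittle
#' hydropathy value.  No window smoothing is applied: position `i` of the
#' result is exactly the scale value of residue `i`, so that N-terminal
#' positional signals (e.g. in signal peptides) are not blurred.
#'
#' @param sequence Single amino-acid string using the 20 standard
#'   one-letter codes (case-insensitive).
#' @return Numeric vector of hydropathy values, one per residue, named by
#'   residue.
#' @examples
#' kd_values("MKI")
#' @export
kd_values <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("'sequence' must be a single amino-acid string")
  if (nchar(sequence) == 0L)
    stop("'sequence' must be nonempty")
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(aa %in% names(kd_scale)))
  if (length(bad) > 0L)
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1L]], bad[1L]))
  kd_scale[aa]
}
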
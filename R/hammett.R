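#' @include AllClasses.R
NULL

#' Read a Hammett sigma table
#'
#' CSV schema: `substituent, sigma_meta, sigma_para`; lines starting with `#`
#' are comments. The hydrogen row must map to (0, 0) and all values must be
#' finite.
#'
#' @param path CSV file; defaults to the bundled compilation.
#' @return data.frame of class `HammettTable` with the three columns above.
#' @seealso [encodeSubstrate()], [writeHammettTable()]
#' @export
readHammettTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "hammett_sigma.csv", package = "TreeMPNN")
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("substituent", "sigma_meta", "sigma_para")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("Hammett table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  tab <- tab[need]
  if (anyDuplicated(tab$substituent)) stop("duplicate substituent symbols")
  if (!all(is.finite(tab$sigma_meta)) || !all(is.finite(tab$sigma_para)))
    stop("sigma values must be finite")
  h <- tab[tab$substituent == "H", ]
  if (nrow(h) != 1L || h$sigma_meta != 0 || h$sigma_para != 0)
    stop("the table must contain H with sigma (0, 0)")
  class(tab) <- c("HammettTable", "data.frame")
  tab
}

#' Write a Hammett sigma table
#'
#' @param table a `HammettTable` data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeHammettTable <- function(table, path) {
  write.csv(as.data.frame(table)[c("substituent", "sigma_meta", "sigma_para")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode an aryl bromide substrate as a two-element Hammett vector
#'
#' A mono-substituted aryl bromide is represented as `(sigma_meta,
#' sigma_para)`: the tabulated sigma constant of its substituent in the
#' position it occupies, zero in the other position (the Hammett constant of
#' the hydrogen at the unsubstituted position). Ortho substitution is outside
#' the model and rejected.
#'
#' @param substituent substituent symbol present in `table`.
#' @param position `"meta"` or `"para"`.
#' @param table a `HammettTable` from [readHammettTable()].
#' @return named numeric vector `c(sigma_meta = , sigma_para = )`.
#' @examples
#' tab <- readHammettTable()
#' encodeSubstrate("CN", "meta", tab)   # (sigma_m^CN, 0)
#' encodeSubstrate("H", "para", tab)    # (0, 0)
#' @export
encodeSubstrate <- function(substituent, position, table) {
  if (!position %in% c("meta", "para"))
    stop(sprintf(
      "unsupported position '%s': only meta and para substitution is modeled",
      position))
  row <- match(substituent, table$substituent)
  if (is.na(row))
    stop(sprintf("unknown substituent '%s'; available: %s", substituent,
                 paste(table$substituent, collapse = ", ")))
  if (position == "meta")
    c(sigma_meta = table$sigma_meta[row], sigma_para = 0)
  else
    c(sigma_meta = 0, sigma_para = table$sigma_para[row])
}
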
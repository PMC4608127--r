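#' Load the physicochemical propensity scales
#'
#' Six per-residue scales -- hydrophilicity, flexibility, accessibility,
#' polarity, exposed surface and turns -- drawn from classical propensity
#' tables widely used in sequence-based structure prediction (Parker
#' hydrophilicity, Karplus-Schulz flexibility, an interior/surface
#' transfer-derived accessibility scale, Grantham polarity, Emini surface
#' probability, Chou-Fasman turn propensity). Each scale is min-max
#' normalized to `[0, 1]` at load; the unknown residue `X` maps to each
#' scale's mean. The bundled file is a user-replaceable config.
#'
#' @param path optional path to a replacement TSV with columns `aa` plus
#'   the six scale names.
#' @return A 21 x 6 numeric matrix (rows A..V plus `X`), values in `[0,1]`.
#' @export
physchem_scales <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physchem_scales.tsv", package = "rsapred")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  scale_names <- c("hydrophilicity", "flexibility", "accessibility",
                   "polarity", "exposed_surface", "turns")
  if (!all(c("aa", scale_names) %in% names(tab)) || nrow(tab) != 20L) {
    abort_format("scale table must have 20 rows: aa + six scale columns")
  }
  m <- as.matrix(tab[scale_names])
  rownames(m) <- tab$aa
  if (any(!is.finite(m))) abort_format("non-finite scale value")
  # min-max normalize each scale so feature magnitudes are comparable
  m <- apply(m, 2L, function(v) (v - min(v)) / (max(v) - min(v)))
  rownames(m) <- tab$aa
  m <- rbind(m, X = colMeans(m))
  m
}
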
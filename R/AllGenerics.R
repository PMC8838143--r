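#' @include AllClasses.R
NULL

#' Per-class, per-split record counts
#'
#' @param x a \linkS4class{LesionManifest}.
#' @return integer matrix with one row per label and one column per split.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' Structural counts of an architecture
#'
#' Counts convolutional layers, kernels and learnable parameters of a network
#' description without instantiating any weights.
#'
#' @param x a \linkS4class{LCNetConfig} or \linkS4class{LCNetModel}.
#' @return a \linkS4class{NetworkStats}.
#' @export
setGeneric("networkStats", function(x) standardGeneric("networkStats"))

#' Manifest records
#'
#' @param x a \linkS4class{LesionManifest}.
#' @return the record data.frame.
#' @export
setGeneric("records", function(x) standardGeneric("records"))
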
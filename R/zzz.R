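#' @useDynLib ligandblob, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm quantile median setNames rnorm runif
#' @importFrom utils read.delim write.table
NULL
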
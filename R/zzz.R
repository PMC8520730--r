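#' @import methods
#' @importFrom stats runif dnorm convolve setNames
#' @importFrom utils write.table
#' @importFrom tools file_ext
#' @keywords internal
"_PACKAGE"
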
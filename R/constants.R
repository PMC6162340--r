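# shared sequence constants; loaded before the module files

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")
NONSTOP_CODONS <- setdiff(
  as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0)),
  STOP_CODONS)

`%||%` <- function(x, y) if (is.null(x)) y else x
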
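# internal helpers

# coerce sequences (DNAStringSet or character) to a named character vector
asSeqVector <- function(x) {
  if (is.character(x)) return(x)
  setNames(as.character(x), names(x))
}
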
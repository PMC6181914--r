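#' @keywords internal
"_PACKAGE"

# Canonical amino-acid order used throughout the package (PAML/phangorn order).
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
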
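# Canonical RNA alphabet; fixes the column order of every one-hot matrix,
# logo, and CGR corner in the package.
RNA_ALPHABET <- c("A", "C", "G", "U")
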
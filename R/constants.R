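# Shared alphabets and codon sets used across modules.

# the four concrete RNA residues and the standard bacterial stop codons
RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

# the 61 sense codons (fixture bodies are built from these)
NON_STOP_CODONS <- local({
  grid <- expand.grid(RNA_BASES, RNA_BASES, RNA_BASES)
  sort(setdiff(apply(grid, 1L, paste, collapse = ""), STOP_CODONS))
})

# IUPAC nucleotide codes, RNA reading (U replaces T)
IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)
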
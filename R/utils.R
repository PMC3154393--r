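# Internal helpers shared across the package.

# The 20 standard amino acids, in the conventional one-letter order.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

PHOSPHO_RESIDUES <- c("S", "T", "Y")

# Approximate background amino-acid frequencies of a eukaryotic proteome
# (UniProt-like averages), used as the default composition of synthetic
# proteomes. Must sum to 1.
AA_BACKGROUND <- local({
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  f / sum(f)
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Canonical site identity string; protein ids cannot contain tab characters
# (enforced by the readers), so "\t" is a safe separator.
site_key <- function(protein_id, position, residue) {
  paste(protein_id, position, residue, sep = "\t")
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("phossat_data_error", "error")))
}
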
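# Generates inst/extdata/pb_substitution_matrix_synthetic.tsv.
#
# The published PB substitution matrix is not redistributed here; this
# synthetic stand-in is derived from the bundled PB reference vectors:
#   M(x, y) = (45 - rmsda(ref_x, ref_y)) / 22.5
# so identical blocks score +2, blocks whose reference windows differ by an
# angular rmsd of 45 degrees score 0, and the normalized-score similarity
# cutoff of -0.42 corresponds to a mean angular dissimilarity of about
# 54.5 degrees between aligned blocks.  Run from the repository root:
#   Rscript data-raw/pb_substitution_matrix.R

defs <- read.delim("inst/extdata/pb_definitions.tsv")
ref <- as.matrix(defs[, -1])
rownames(ref) <- defs$letter

wrapd <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
rmsda <- function(w, r) sqrt(mean(wrapd(w, r)^2))

n <- nrow(ref)
M <- matrix(0, n, n, dimnames = list(rownames(ref), rownames(ref)))
for (i in seq_len(n))
  for (j in seq_len(n))
    M[i, j] <- (45 - rmsda(ref[i, ], ref[j, ])) / 22.5
M <- round((M + t(M)) / 2, 4)  # numerically exact symmetry

out <- data.frame(letter = rownames(M), M, check.names = FALSE)
write.table(out, "inst/extdata/pb_substitution_matrix_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", nrow(M), "x", ncol(M), "matrix; diagonal =",
    unique(diag(M)), "\n")
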
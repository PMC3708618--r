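# Shared fixtures: toy substitution matrices, probe chains, oracles.

# small substitution matrix over a sub-alphabet; augmented internally by
# align_global, so a subset of a..p is enough
toy_matrix <- function(letters_used = c("m", "k"),
                       diag_val = 2, off_val = -1) {
  n <- length(letters_used)
  M <- matrix(off_val, n, n, dimnames = list(letters_used, letters_used))
  diag(M) <- diag_val
  M
}

# constant matrix (all pairs score v); diagonal trivially each row's max
const_matrix <- function(v) {
  M <- matrix(v, 16, 16, dimnames = list(letters[1:16], letters[1:16]))
  M
}

# 12-residue probe chain embedding a PB reference vector's 5-residue
# fragment twice (plus a 2-residue tail), with >4.5 A breaks between the
# embeddings so only the fragment centres are assignable
pb_probe_chain <- function(v) {
  v <- as.numeric(v)
  phi5 <- c(v[4], v[2], v[4], v[6], v[8])
  psi5 <- c(v[1], v[3], v[5], v[7], v[5])
  shift_x <- function(ch, dx) {
    for (a in c("N", "CA", "C")) ch[[a]][, 1] <- ch[[a]][, 1] + dx
    ch
  }
  f1 <- build_backbone(phi5, psi5)
  f2 <- shift_x(build_backbone(phi5, psi5), 50)
  f3 <- shift_x(build_backbone(c(v[4], v[4]), c(v[5], v[5])), 100)
  backbone_chain("A", 1:12, rep("", 12), rep("A", 12),
                 rbind(f1$N, f2$N, f3$N), rbind(f1$CA, f2$CA, f3$CA),
                 rbind(f1$C, f2$C, f3$C))
}

# independent run-length oracle for segmentation: per-column SCR/SVR labels
oracle_segment_labels <- function(distances, scr_max = 3, min_len = 3) {
  cand <- is.na(distances) | distances > scr_max
  n <- length(cand)
  lab <- rep("SCR", n)
  i <- 1L
  while (i <= n) {
    if (cand[i]) {
      j <- i
      while (j < n && cand[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) lab[i:j] <- "SVR"
      i <- j + 1L
    } else i <- i + 1L
  }
  lab
}

# region_set -> per-column labels
regions_to_labels <- function(regions) {
  n <- max(regions$end)
  lab <- character(n)
  for (i in seq_len(nrow(regions)))
    lab[regions$start[i]:regions$end[i]] <- regions$kind[i]
  lab
}

# random proper rotation matrix
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.1, pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# enumeration oracle wrapper on letter strings
enum_score <- function(x, y, M, gap_open = -5, gap_extend = -0.5) {
  Mz <- pbsvr:::augment_z(M)
  xi <- match(strsplit(x, "")[[1]], rownames(Mz)) - 1L
  yi <- match(strsplit(y, "")[[1]], rownames(Mz)) - 1L
  pbsvr:::enum_align_score_cpp(xi, yi, Mz, gap_open, gap_extend)
}

# all strings of length 1..max_len over an alphabet
all_strings <- function(alphabet, max_len) {
  unlist(lapply(seq_len(max_len), function(L) {
    g <- do.call(expand.grid, rep(list(alphabet), L))
    apply(as.matrix(g), 1, paste, collapse = "")
  }))
}
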
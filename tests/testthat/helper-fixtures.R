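# Small in-code fixtures shared across test files.

# deterministic toy marker matrix: 2 populations x 3 individuals, 5 loci
toy_marker_matrix <- function() {
  bands <- rbind(
    c(1L, 1L, 0L, 0L, 1L),
    c(1L, 0L, 0L, 1L, 1L),
    c(1L, 1L, 1L, 0L, 1L),
    c(0L, 0L, 1L, 1L, 0L),
    c(0L, 1L, 1L, 1L, 0L),
    c(0L, 0L, 1L, 0L, 0L))
  rownames(bands) <- paste0("ind", 1:6)
  colnames(bands) <- paste0("L", 1:5)
  marker_matrix(bands, setNames(rep(c("A", "B"), each = 3),
                                rownames(bands)))
}

# brute-force Phi_PT from first principles (independent of the package
# implementation): explicit sums of squares and variance components
brute_phi_pt <- function(bands, grp) {
  grp <- factor(grp)
  d2 <- as.matrix(dist(bands))^2
  n <- nrow(bands)
  k <- nlevels(grp)
  ss_tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) ss_tot <- ss_tot + d2[i, j]
  }
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in levels(grp)) {
    idx <- which(grp == g)
    for (a in idx) {
      for (b in idx) if (a < b) ss_w <- ss_w + d2[a, b] / length(idx)
    }
  }
  n_g <- as.vector(table(grp))
  ms_a <- (ss_tot - ss_w) / (k - 1)
  ms_w <- ss_w / (n - k)
  n0 <- (n - sum(n_g^2) / n) / (k - 1)
  s2a <- (ms_a - ms_w) / n0
  s2a / (s2a + ms_w)
}

# small metadata fixture (fast)
small_meta <- function(seed = 1) gen_metadata(n_pops = 6, seed = seed)

# all permutations of 1:n (tiny n only)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos)
    }
  }
  out
}
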
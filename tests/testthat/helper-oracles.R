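## Independent oracles shared across test files. These deliberately avoid
## the package's vectorized code paths: plain double loops and exhaustive
## enumeration only.

## all permutations of a vector (for K <= 8 brute force)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

## exhaustive enumeration of the mixture marginal over all K^N assignments
enum_marginal_log_lik <- function(cloud, X, s) {
  N <- nrow(cloud$positions); K <- nrow(X)
  grid <- expand.grid(rep(list(seq_len(K)), N))
  terms <- apply(grid, 1, function(z)
    augmented_log_likelihood(cloud, X, as.integer(z), s))
  m <- max(terms)
  m + log(sum(exp(terms - m))) - N * log(K)
}

## double-loop pair feature sum
loop_features <- function(X, exponents) {
  K <- nrow(X)
  out <- numeric(length(exponents))
  for (l in seq_along(exponents)) {
    acc <- 0
    for (i in 1:(K - 1)) for (j in (i + 1):K)
      acc <- acc + sqrt(sum((X[i, ] - X[j, ])^2))^exponents[l]
    out[l] <- acc
  }
  out
}

## central finite-difference gradient of pair features
fd_feature_gradients <- function(X, spec, h = 1e-6) {
  L <- length(spec$exponents); K <- nrow(X)
  G <- lapply(seq_len(L), function(l) matrix(0, K, 3))
  for (i in seq_len(K)) for (j in 1:3) {
    Xp <- X; Xp[i, j] <- X[i, j] + h
    Xm <- X; Xm[i, j] <- X[i, j] - h
    fp <- pair_features(Xp, spec); fm <- pair_features(Xm, spec)
    for (l in seq_len(L)) G[[l]][i, j] <- (fp[l] - fm[l]) / (2 * h)
  }
  G
}

## finite-difference Laplacian over all 3K coordinates
fd_feature_laplacians <- function(X, spec, h = 1e-4) {
  f0 <- pair_features(X, spec)
  out <- numeric(length(f0))
  for (i in seq_len(nrow(X))) for (j in 1:3) {
    Xp <- X; Xp[i, j] <- X[i, j] + h
    Xm <- X; Xm[i, j] <- X[i, j] - h
    out <- out + (pair_features(Xp, spec) + pair_features(Xm, spec) - 2 * f0) / h^2
  }
  out
}

## open-path length under a visit order
path_len <- function(X, ord) {
  D <- as.matrix(dist(X))
  sum(D[cbind(ord[-length(ord)], ord[-1])])
}

## brute-force shortest open path
brute_tsp <- function(X) {
  K <- nrow(X)
  best <- Inf; bp <- NULL
  for (p in all_perms(seq_len(K))) {
    l <- path_len(X, p)
    if (l < best) { best <- l; bp <- p }
  }
  list(order = bp, length = best)
}

## minimal synthetic PDB text
pdb_line <- function(record = "ATOM", serial, name, resname, chain = "A",
                     resseq, x, y, z, occ = 1.0, altloc = " ",
                     element = "") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, resname, chain, resseq,
          x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

## optimal bead-to-truth matching error over all permutations (small K)
matched_center_error <- function(X, centers) {
  best <- Inf
  for (p in all_perms(seq_len(nrow(centers))))
    best <- min(best, max(sqrt(rowSums((X - centers[p, , drop = FALSE])^2))))
  best
}
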
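# Straight-line reference computation for the six-sample worked example.
# Deliberately independent of the secrank package: every quantity is
# computed here with explicit loops and base R only, and written as
# plain-text fixtures that the test suite compares the package against.
#
# Run from anywhere:  Rscript generate.R [output_dir]
# (default output_dir: the directory containing this script)

args <- commandArgs(trailingOnly = TRUE)
script_arg <- sub("^--file=", "", grep("^--file=", commandArgs(), value = TRUE))
out_dir <- if (length(args) >= 1) args[1] else dirname(script_arg[1])

ids <- c("s1", "s2", "s3", "s4", "s5", "s6")
X <- rbind(
  c(0.0, 0.0),
  c(0.4, 0.3),
  c(1.0, -0.2),
  c(4.0, 3.0),
  c(4.6, 3.4),
  c(5.0, 2.6)
)
y <- c(1, 0, 0, 0, 0, 0) # s1 is the single labelled query
alpha <- 0.5
n <- nrow(X)

# pairwise Euclidean distances, explicit double loop
D <- matrix(0, n, n)
for (i in 1:n) {
  for (j in 1:n) {
    D[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  }
}

# sigma: mean of the 15 distinct pairwise distances
pair_d <- c()
for (i in 1:(n - 1)) {
  for (j in (i + 1):n) {
    pair_d <- c(pair_d, D[i, j])
  }
}
sigma <- sum(pair_d) / length(pair_d)

# Gaussian kernel weights, zero diagonal
W <- matrix(0, n, n)
for (i in 1:n) {
  for (j in 1:n) {
    if (i != j) W[i, j] <- exp(-D[i, j]^2 / (2 * sigma^2))
  }
}

# symmetric normalisation
deg <- rowSums(W)
L <- matrix(0, n, n)
for (i in 1:n) {
  for (j in 1:n) {
    L[i, j] <- W[i, j] / sqrt(deg[i] * deg[j])
  }
}

# closed-form propagation fixed point
fstar <- (1 - alpha) * solve(diag(n) - alpha * L, y)

fmt <- function(x) formatC(x, format = "g", digits = 17)
write_mat <- function(M, path) {
  lines <- c(paste(c("id", ids), collapse = "\t"))
  for (i in 1:n) {
    lines <- c(lines, paste(c(ids[i], fmt(M[i, ])), collapse = "\t"))
  }
  writeLines(lines, path)
}

write_mat(D, file.path(out_dir, "distances.tsv"))
writeLines(c("sigma", fmt(sigma)), file.path(out_dir, "sigma.tsv"))
write_mat(W, file.path(out_dir, "W.tsv"))
write_mat(L, file.path(out_dir, "L.tsv"))
writeLines(c("id\tfstar", paste(ids, fmt(fstar), sep = "\t")),
           file.path(out_dir, "fstar.tsv"))
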
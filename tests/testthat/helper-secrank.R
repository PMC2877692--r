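# Shared builders for the test suite. Everything is generated in code,
# seeded, and small enough to run in well under a second.

tiny_table <- function() {
  tibble::tibble(
    id = c("a", "b", "c"),
    f1 = c(0, 3, 1),
    f2 = c(0, 4, 1)
  )
}

random_table <- function(n, m, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * m), n, m)
  out <- tibble::as_tibble(as.data.frame(X))
  names(out) <- paste0("f", seq_len(m))
  dplyr::bind_cols(tibble::tibble(id = sprintf("s%03d", seq_len(n))), out)
}

random_ngraph <- function(n, m = 5, seed = 1) {
  tbl <- random_table(n, m, seed)
  normalize_affinity(build_graph(tbl))
}

# Affinity graph from an explicit weight matrix (for hand-built
# topologies such as path graphs).
graph_from_W <- function(W, sigma = 1) {
  secrank:::new_affinity_graph(W, sigma, as.character(seq_len(nrow(W))))
}

write_tiny_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
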
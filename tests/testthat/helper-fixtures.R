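# Shared fixtures built in code.

mini_pathway_file <- function() {
  system.file("extdata", "synthetic_mini_mitocarta_pathways.tsv",
              package = "mitotyper")
}

mini_gene_file <- function() {
  system.file("extdata", "synthetic_mini_mitocarta_genes.tsv",
              package = "mitotyper")
}

mini_fixture_hierarchy <- function() {
  load_mitocarta(mini_pathway_file(), species = "human",
                 gene_file = mini_gene_file())
}

# random strictly-positive pathway x sample score matrix
random_scores <- function(n_pathways, n_samples, seed) {
  set.seed(seed)
  matrix(rlnorm(n_pathways * n_samples, meanlog = 2, sdlog = 1.5),
         n_pathways, n_samples,
         dimnames = list(paste0("P", seq_len(n_pathways)),
                         paste0("S", seq_len(n_samples))))
}

# 50 genes x 4 samples; s4 is a compositional outlier (a handful of genes
# dominate its library), the classic case TMM is built to absorb
make_tmm_fixture <- function() {
  set.seed(421)
  base <- rlnorm(50, log(80), 1)
  counts <- vapply(c(1, 1.5, 0.7, 1), function(depth) {
    rpois(50, base * depth)
  }, numeric(50))
  counts[1:5, 4] <- counts[1:5, 4] + c(4000, 2500, 3000, 1500, 2000)
  dimnames(counts) <- list(paste0("g", 1:50), paste0("s", 1:4))
  counts
}

write_toy_gct <- function(mat, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.2", con)
  writeLines(paste(nrow(mat), ncol(mat), sep = "\t"), con)
  header <- paste(c("Name", "Description", colnames(mat)), collapse = "\t")
  writeLines(header, con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i], "na", mat[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}
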
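# Small builders shared across test files.

toy_matrix <- function() {
  x <- rbind(A = c(20, 21, 22, 23),
             B = c(25, 26, 27, 28),
             C = c(18, 20, 19, 23))
  colnames(x) <- paste0("s", 1:4)
  x
}

random_cq <- function(n_genes = 4, n_samples = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n_genes * n_samples, 15, 30), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  cq_matrix(x)
}

tiny_annotations <- function(samples, classes) {
  data.frame(
    sample_id = samples,
    population_class = classes,
    population_id = ifelse(classes == "susceptible", "S1", "R1"),
    treatment = rep(c("untreated", "treated"), length.out = length(samples)),
    timepoint = rep(c("1h", "24h"), length.out = length(samples)),
    biological_replicate = seq_along(samples),
    stringsAsFactors = FALSE
  )
}

long_cq_file <- function(path, genes = c("g1", "g2"), samples = c("s1", "s2"),
                         n_rep = 3, base = 20) {
  df <- expand.grid(technical_replicate = seq_len(n_rep), gene = genes,
                    sample_id = samples, stringsAsFactors = FALSE)
  df$cq <- base + match(df$gene, genes) + 0.1 * df$technical_replicate
  write.table(df[, c("sample_id", "gene", "technical_replicate", "cq")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
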